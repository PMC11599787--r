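#' Nc mean negativity of an averaged, referenced waveform
#'
#' The target metric of the closed loop: within the broad Nc analysis window
#' (250-800 ms post-stimulus by default) the most negative sample is located,
#' the "biggest negative deflection" is taken as the maximal contiguous run of
#' strictly negative samples containing that minimum (clipped to the window),
#' and the metric is the positive magnitude of the mean amplitude over that
#' run. If no sample in the window is negative the metric is 0 and the
#' deflection span is empty. Ties between equal global minima in distinct runs
#' are broken towards the earlier run, making the metric a deterministic
#' function of the waveform.
#'
#' @param waveform numeric vector of amplitudes in microvolts.
#' @param times numeric vector of sample times in ms, same length as
#'   `waveform`.
#' @param window length-2 numeric, analysis window in ms (default
#'   `c(250, 800)`).
#' @return an object of class `nc_result`: list with `mean_negativity`
#'   (µV, >= 0), `deflection_span` (ms pair or NULL), `peak_latency` (ms or
#'   NA), and `window_mean_amplitude` (signed µV over the full window).
#' @examples
#' t <- seq(0, 1000, by = 2)
#' w <- ifelse(t >= 300 & t <= 500, -10, 0)
#' nc_mean_negativity(w, t)$mean_negativity  # 10
#' @export
nc_mean_negativity <- function(waveform, times, window = c(250, 800)) {
  stopifnot(is.numeric(waveform), is.numeric(times),
            length(waveform) == length(times), length(window) == 2L)
  if (window[1] < min(times) || window[2] > max(times)) {
    stop("analysis window lies outside the waveform time span", call. = FALSE)
  }
  in_win <- which(times >= window[1] & times <= window[2])
  w <- waveform[in_win]
  t <- times[in_win]
  window_mean <- mean(w)

  res <- list(
    mean_negativity = 0,
    deflection_span = NULL,
    peak_latency = NA_real_,
    window_mean_amplitude = window_mean
  )
  if (!any(w < 0)) {
    class(res) <- "nc_result"
    return(res)
  }
  peak_i <- which.min(w)  # earliest global minimum wins ties
  # grow the strictly-negative run containing the peak, clipped to the window
  lo <- peak_i
  while (lo > 1L && w[lo - 1L] < 0) lo <- lo - 1L
  hi <- peak_i
  while (hi < length(w) && w[hi + 1L] < 0) hi <- hi + 1L

  res$mean_negativity <- -mean(w[lo:hi])
  res$deflection_span <- c(t[lo], t[hi])
  res$peak_latency <- t[peak_i]
  class(res) <- "nc_result"
  res
}

#' Nc mean amplitude over the full analysis window
#'
#' The traditional group-level variant: the signed arithmetic mean of all
#' samples inside the closed window, with no deflection search.
#'
#' @inheritParams nc_mean_negativity
#' @return signed mean amplitude in µV.
#' @export
nc_window_mean_amplitude <- function(waveform, times, window = c(250, 800)) {
  stopifnot(is.numeric(waveform), is.numeric(times),
            length(waveform) == length(times), length(window) == 2L)
  if (window[1] < min(times) || window[2] > max(times)) {
    stop("analysis window lies outside the waveform time span", call. = FALSE)
  }
  mean(waveform[times >= window[1] & times <= window[2]])
}

#' @export
print.nc_result <- function(x, ...) {
  if (is.null(x$deflection_span)) {
    cat("Nc mean negativity: 0 (no negative deflection in window)\n")
  } else {
    cat(sprintf("Nc mean negativity: %.3f uV over %g-%g ms (peak at %g ms)\n",
                x$mean_negativity, x$deflection_span[1], x$deflection_span[2],
                x$peak_latency))
  }
  cat(sprintf("Window mean amplitude: %.3f uV\n", x$window_mean_amplitude))
  invisible(x)
}
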