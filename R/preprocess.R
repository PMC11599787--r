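#' Default EEG channel montage
#'
#' Six fronto-central channels of interest plus the two posterior reference
#' channels, in the fixed order used throughout the package.
#' @return character vector of 8 channel labels.
#' @export
nbo_channels <- function() {
  c("Fz", "FC1", "FC2", "C1", "C2", "Cz", "P7", "P8")
}

#' Block preprocessing configuration
#'
#' Bundles every tunable of the block-wise preprocessing chain: segmentation
#' span, epoch and baseline windows, band-pass edges, mirror-padding length,
#' artifact-rejection thresholds and the quality gate.
#'
#' @param segment_span ms pair, raw segment cut around each stimulus marker
#'   (default -500..1000, i.e. 1500 ms).
#' @param epoch_span ms pair, epoch retained after filtering (default -100..800).
#' @param baseline_span ms pair, baseline window (default -100..0).
#' @param band Hz pair, band-pass edges (default 0.1-20 Hz).
#' @param pad_samples mirror-padding length in samples per end (default 1000).
#' @param amplitude_thresh µV, absolute-amplitude rejection threshold
#'   (default 200; per-subject practice allows 250).
#' @param range_thresh µV, peak-to-peak rejection threshold (default 400).
#' @param flat_thresh µV, minimum peak-to-peak below which a channel counts as
#'   flat (default 0.1).
#' @param min_clean_trials minimum artifact-free trials per block for the
#'   metric to be passed on (default 10).
#' @param trial_clean_rule `"all"` (a trial is clean only if clean on all
#'   channels of interest; default) or `"majority"`.
#' @param channels_of_interest labels of the 6 fronto-central channels.
#' @param reference_channels labels of the 2 posterior reference channels.
#' @param sample_rate Hz (default 500).
#' @return a `preprocess_config` list; the zero-phase Butterworth filters
#'   (order-2 high-pass at the low edge, order-4 low-pass at the high edge)
#'   are pre-designed and cached in the object.
#' @export
preprocess_config <- function(segment_span = c(-500, 1000),
                              epoch_span = c(-100, 800),
                              baseline_span = c(-100, 0),
                              band = c(0.1, 20),
                              pad_samples = 1000L,
                              amplitude_thresh = 200,
                              range_thresh = 400,
                              flat_thresh = 0.1,
                              min_clean_trials = 10L,
                              trial_clean_rule = c("all", "majority"),
                              channels_of_interest = nbo_channels()[1:6],
                              reference_channels = nbo_channels()[7:8],
                              sample_rate = 500) {
  trial_clean_rule <- match.arg(trial_clean_rule)
  stopifnot(
    epoch_span[1] >= segment_span[1], epoch_span[2] <= segment_span[2],
    baseline_span[1] >= epoch_span[1], baseline_span[2] <= epoch_span[2],
    band[1] > 0, band[1] < band[2],
    amplitude_thresh > 0, range_thresh > 0, flat_thresh > 0,
    pad_samples > 0, min_clean_trials >= 1
  )
  nyq <- sample_rate / 2
  cfg <- list(
    segment_span = segment_span, epoch_span = epoch_span,
    baseline_span = baseline_span, band = band,
    pad_samples = as.integer(pad_samples),
    amplitude_thresh = amplitude_thresh, range_thresh = range_thresh,
    flat_thresh = flat_thresh, min_clean_trials = as.integer(min_clean_trials),
    trial_clean_rule = trial_clean_rule,
    channels_of_interest = channels_of_interest,
    reference_channels = reference_channels,
    sample_rate = sample_rate,
    filt_hp = signal::butter(2, band[1] / nyq, type = "high"),
    filt_lp = signal::butter(4, band[2] / nyq, type = "low")
  )
  class(cfg) <- "preprocess_config"
  cfg
}

segment_times <- function(cfg) {
  step <- 1000 / cfg$sample_rate
  seq(cfg$segment_span[1], cfg$segment_span[2] - step, by = step)
}

epoch_times <- function(cfg) {
  st <- segment_times(cfg)
  st[st >= cfg$epoch_span[1] & st <= cfg$epoch_span[2]]
}

#' Cut a continuous multichannel stream into stimulus-locked segments
#'
#' @param continuous numeric matrix, channels x samples, µV, sampled at
#'   `cfg$sample_rate`; rownames are channel labels.
#' @param markers numeric vector of stimulus-onset times in ms from stream
#'   start.
#' @param cfg a [preprocess_config()].
#' @return list of channels x samples segment matrices, one per marker, each
#'   covering `cfg$segment_span` relative to its marker; attribute `"times"`
#'   holds the within-segment time axis (ms).
#' @export
segment_block <- function(continuous, markers, cfg = preprocess_config()) {
  stopifnot(is.matrix(continuous), is.numeric(markers))
  step <- 1000 / cfg$sample_rate
  offsets <- round(cfg$segment_span[1] / step):(round(cfg$segment_span[2] / step) - 1L)
  times <- offsets * step
  lapply(seq_along(markers), function(k) {
    m_idx <- round(markers[k] / step) + 1L
    idx <- m_idx + offsets
    if (idx[1] < 1L || idx[length(idx)] > ncol(continuous)) {
      stop(sprintf(
        "segment out of bounds: marker %d at %g ms does not fit in the stream",
        k, markers[k]), call. = FALSE)
    }
    seg <- continuous[, idx, drop = FALSE]
    attr(seg, "times") <- times
    seg
  })
}

# Mirror (symmetric, edge not repeated) extension by np samples per side;
# reflects repeatedly when np exceeds the signal length.
mirror_index <- function(n, np) {
  i <- (1L - np):(n + np)
  p <- (i - 1L) %% (2L * (n - 1L))
  ifelse(p < (n - 1L), p + 1L, 2L * (n - 1L) - p + 1L)
}

mirror_pad <- function(x, np) x[mirror_index(length(x), np)]

# Squared-magnitude (zero-phase, forward-backward) response of the cascaded
# Butterworth high-pass + low-pass on the length-N DFT grid. Cached per
# configuration.
.resp_cache <- new.env(parent = emptyenv())
zero_phase_response <- function(cfg, N) {
  key <- paste(c(cfg$band, cfg$sample_rate, N), collapse = "|")
  if (!is.null(.resp_cache[[key]])) return(.resp_cache[[key]])
  z <- exp(-2i * pi * (0:(N - 1)) / N)
  mag2 <- function(filt) {
    num <- outer(z, seq_along(filt$b) - 1, `^`) %*% filt$b
    den <- outer(z, seq_along(filt$a) - 1, `^`) %*% filt$a
    Mod(num / den)^2
  }
  resp <- as.numeric(mag2(cfg$filt_hp) * mag2(cfg$filt_lp))
  .resp_cache[[key]] <- resp
  resp
}

#' Preprocess one raw segment into a baseline-corrected epoch
#'
#' Applies, per channel and in order: linear detrend, mean removal, mirror
#' padding (`pad_samples` per end), zero-phase 0.1-20 Hz Butterworth band-pass
#' (cascaded high-pass and low-pass, each applied forward and backward — i.e.
#' the squared-magnitude response, realised on the padded signal in the
#' frequency domain), removal of the padding, cropping to the epoch window,
#' and subtraction of the baseline-window mean.
#'
#' @param segment channels x samples matrix covering `cfg$segment_span`.
#' @param cfg a [preprocess_config()].
#' @return channels x samples epoch matrix on the `cfg$epoch_span` grid, with
#'   attribute `"times"` (ms).
#' @export
preprocess_segment <- function(segment, cfg = preprocess_config()) {
  st <- segment_times(cfg)
  if (!is.matrix(segment) || ncol(segment) != length(st)) {
    stop("segment does not cover the configured segment span", call. = FALSE)
  }
  np <- cfg$pad_samples
  n <- ncol(segment)
  xs_c <- seq_len(n) - (n + 1) / 2
  sxx <- sum(xs_c^2)
  keep <- st >= cfg$epoch_span[1] & st <= cfg$epoch_span[2]
  et <- st[keep]
  bl <- et >= cfg$baseline_span[1] & et <= cfg$baseline_span[2]

  # detrend + demean, all channels at once
  slopes <- as.numeric(segment %*% xs_c) / sxx
  x <- segment - rowMeans(segment) - outer(slopes, xs_c)
  # mirror pad and zero-phase band-pass in the frequency domain
  xp <- x[, mirror_index(n, np), drop = FALSE]
  N <- ncol(xp)
  resp <- zero_phase_response(cfg, N)
  spec <- stats::mvfft(t(xp)) * resp
  y <- t(Re(stats::mvfft(spec, inverse = TRUE))) / N
  # unpad, crop, baseline-correct
  y <- y[, (np + 1L):(np + n), drop = FALSE][, keep, drop = FALSE]
  out <- y - rowMeans(y[, bl, drop = FALSE])
  dimnames(out) <- list(rownames(segment), NULL)
  attr(out, "times") <- et
  out
}

#' Build an epoch set from preprocessed segments
#'
#' @param epochs list of channels x samples epoch matrices (all on the same
#'   time grid) as returned by [preprocess_segment()].
#' @return an `epoch_set`: list with `data` (trials x channels x samples
#'   array), `channels`, and `times` (ms).
#' @export
epoch_set <- function(epochs) {
  stopifnot(length(epochs) >= 1L)
  times <- attr(epochs[[1L]], "times")
  channels <- rownames(epochs[[1L]])
  arr <- array(NA_real_,
               dim = c(length(epochs), length(channels), length(times)),
               dimnames = list(NULL, channels, NULL))
  for (i in seq_along(epochs)) arr[i, , ] <- epochs[[i]]
  structure(list(data = arr, channels = channels, times = times),
            class = "epoch_set")
}

#' Flag artifact-contaminated trial-channels
#'
#' An entry (trial, channel) is rejected if the absolute amplitude anywhere in
#' the epoch exceeds `amplitude_thresh`, the peak-to-peak range exceeds
#' `range_thresh`, or the peak-to-peak range falls below `flat_thresh`
#' (consistently flat channel). Applied to all channels, references included.
#'
#' @param epochs an [epoch_set()].
#' @param cfg a [preprocess_config()].
#' @return an `artifact_mask`: list with `rejected` (trials x channels logical,
#'   TRUE = rejected) and `reason` (same shape, `"amplitude"`, `"range"`,
#'   `"flat"` or NA).
#' @export
detect_artifacts <- function(epochs, cfg = preprocess_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_tr <- dim(epochs$data)[1L]
  n_ch <- dim(epochs$data)[2L]
  rejected <- matrix(FALSE, n_tr, n_ch, dimnames = list(NULL, epochs$channels))
  reason <- matrix(NA_character_, n_tr, n_ch,
                   dimnames = list(NULL, epochs$channels))
  for (t in seq_len(n_tr)) {
    for (c in seq_len(n_ch)) {
      x <- epochs$data[t, c, ]
      rng <- max(x) - min(x)
      if (max(abs(x)) > cfg$amplitude_thresh) {
        rejected[t, c] <- TRUE; reason[t, c] <- "amplitude"
      } else if (rng > cfg$range_thresh) {
        rejected[t, c] <- TRUE; reason[t, c] <- "range"
      } else if (rng < cfg$flat_thresh) {
        rejected[t, c] <- TRUE; reason[t, c] <- "flat"
      }
    }
  }
  structure(list(rejected = rejected, reason = reason),
            class = "artifact_mask")
}

#' Block-level quality gate
#'
#' A trial is artifact-free when it is clean on the channels of interest
#' (all six under the default rule, a majority under `"majority"`). The block
#' passes when at least `min_clean_trials` trials are artifact-free. The
#' report also carries per-channel clean-trial counts and the percentage of
#' clean channel-trials out of the 6 x 12 = 72 recorded.
#'
#' @param mask an [detect_artifacts()] result covering all 8 channels.
#' @param cfg a [preprocess_config()].
#' @return a `qc_report`: list with `clean_trial_count`, `per_channel_clean`
#'   (named, channels of interest), `percent_clean_channel_trials`, `passed`.
#' @export
block_quality <- function(mask, cfg = preprocess_config()) {
  stopifnot(inherits(mask, "artifact_mask"))
  coi <- cfg$channels_of_interest
  stopifnot(all(coi %in% colnames(mask$rejected)))
  clean <- !mask$rejected[, coi, drop = FALSE]
  trial_clean <- if (cfg$trial_clean_rule == "all") {
    apply(clean, 1L, all)
  } else {
    rowMeans(clean) > 0.5
  }
  structure(list(
    clean_trial_count = sum(trial_clean),
    per_channel_clean = colSums(clean),
    percent_clean_channel_trials = 100 * sum(clean) / length(clean),
    passed = sum(trial_clean) >= cfg$min_clean_trials
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d clean trials (%.1f%% of channel-trials) -> %s\n",
              x$clean_trial_count, x$percent_clean_channel_trials,
              if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

#' Average clean trials and re-reference to the posterior pool
#'
#' For each channel the mean over its own clean trials is taken; the six
#' channel-of-interest means are pooled (averaged), the two reference-channel
#' means are pooled, and the pooled reference is subtracted from the pooled
#' signal.
#'
#' Trials rejected for amplitude or range are excluded from the averages.
#' Trials flagged only as flat still enter the pool: flatness marks an
#' uninformative channel, not a contaminated one, and a flat (e.g. all-zero)
#' reference contributes its true constant level to the pooled reference,
#' whereas excluding it would make a silent, ideal recording unusable. Flat
#' trials do still count as rejected in the quality gate.
#'
#' @param epochs an [epoch_set()].
#' @param mask the matching [detect_artifacts()] mask.
#' @param cfg a [preprocess_config()].
#' @return numeric waveform (µV) on the epoch time grid, with attribute
#'   `"times"`.
#' @export
average_and_reference <- function(epochs, mask, cfg = preprocess_config()) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(mask, "artifact_mask"))
  needed <- c(cfg$channels_of_interest, cfg$reference_channels)
  ch_mean <- function(ch) {
    keep <- !mask$rejected[, ch] |
      (!is.na(mask$reason[, ch]) & mask$reason[, ch] == "flat")
    if (!any(keep)) {
      stop(sprintf("channel %s has no clean trials", ch), call. = FALSE)
    }
    m <- epochs$data[keep, ch, , drop = FALSE]
    colMeans(matrix(m, nrow = sum(keep)))
  }
  means <- lapply(needed, ch_mean)
  names(means) <- needed
  pooled_sig <- Reduce(`+`, means[cfg$channels_of_interest]) /
    length(cfg$channels_of_interest)
  pooled_ref <- Reduce(`+`, means[cfg$reference_channels]) /
    length(cfg$reference_channels)
  out <- pooled_sig - pooled_ref
  attr(out, "times") <- epochs$times
  out
}
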