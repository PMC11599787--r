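#' Synthetic infant subject profile
#'
#' Ground-truth description of a simulated subject: where in the morph space
#' their Nc response peaks, how strong and how broadly tuned that peak is, the
#' background-noise level, and how artifact contamination grows with
#' block-by-block fussiness. The Nc tuning curve is
#' \deqn{f(x) = b + A \exp(-(x - x^*)^2 / (2 w^2))}
#' in µV of Nc mean negativity, where \eqn{x^*} is the coordinate of the
#' subject's true optimum. Defaults b = 8, A = 7 put the peak response near
#' 15 µV, the scale reported for infant Nc mean negativity.
#'
#' @param subject_id identifier string.
#' @param age_days age in days (study range 158-375).
#' @param true_optimum_index 0-based index of the preferred stimulus.
#' @param nc_baseline_b µV, Nc magnitude far from the preferred stimulus.
#' @param nc_peak_gain_A µV, extra magnitude at the preferred stimulus.
#' @param tuning_width_w coordinate units, Gaussian tuning width (> 0).
#' @param noise_sd µV, per-sample pink-noise background amplitude.
#' @param trial_sd µV, trial-to-trial SD of the drawn Nc depth.
#' @param artifact_prob per trial-channel artifact probability in block 1.
#' @param fussiness_slope per-block increment of the artifact probability.
#' @param behaviour_scores named list of real covariates
#'   (interest_familiar, interest_unfamiliar, distress, similarity).
#' @return a `subject_profile` list.
#' @export
subject_profile <- function(subject_id = "S001",
                            age_days = 266L,
                            true_optimum_index = 0L,
                            nc_baseline_b = 8,
                            nc_peak_gain_A = 7,
                            tuning_width_w = 0.4,
                            noise_sd = 20,
                            trial_sd = 6,
                            artifact_prob = 0.01,
                            fussiness_slope = 0.002,
                            behaviour_scores = list(
                              interest_familiar = 1.5,
                              interest_unfamiliar = 1.3,
                              distress = 3.5,
                              similarity = 5
                            )) {
  stopifnot(nc_baseline_b >= 0, nc_peak_gain_A >= 0, tuning_width_w > 0,
            noise_sd >= 0, trial_sd >= 0,
            artifact_prob >= 0, artifact_prob <= 1, fussiness_slope >= 0)
  structure(list(
    subject_id = subject_id, age_days = as.integer(age_days),
    true_optimum_index = as.integer(true_optimum_index),
    nc_baseline_b = nc_baseline_b, nc_peak_gain_A = nc_peak_gain_A,
    tuning_width_w = tuning_width_w, noise_sd = noise_sd, trial_sd = trial_sd,
    artifact_prob = artifact_prob, fussiness_slope = fussiness_slope,
    behaviour_scores = behaviour_scores
  ), class = "subject_profile")
}

#' Expected Nc magnitude at a coordinate of the stimulus space
#'
#' The subject's ground-truth tuning curve
#' \eqn{f(x) = b + A e^{-(x-x^*)^2/(2w^2)}}, strictly maximal at the true
#' optimum's coordinate.
#'
#' @param profile a [subject_profile()].
#' @param coord coordinate(s) in the stimulus space.
#' @param space the [make_stimulus_space()] the optimum index refers to.
#' @return expected Nc mean negativity in µV (vectorised over `coord`).
#' @export
response_curve <- function(profile, coord, space = make_stimulus_space()) {
  stopifnot(inherits(profile, "subject_profile"))
  x_star <- stimulus_coordinate(space, profile$true_optimum_index)
  profile$nc_baseline_b + profile$nc_peak_gain_A *
    exp(-(coord - x_star)^2 / (2 * profile$tuning_width_w^2))
}

#' Pink (1/f) background noise
#'
#' Spectral-synthesis generator: Gaussian white noise is shaped in the
#' frequency domain with amplitude proportional to \eqn{1/\sqrt{f}} (power
#' spectral density proportional to 1/f), transformed back, and standardized
#' to zero mean and the requested SD. Uses the current R RNG state, so results
#' are reproducible under `set.seed()`.
#'
#' @param n_samples number of samples (> 1).
#' @param sd target standard deviation in µV.
#' @param sample_rate Hz (default 500).
#' @return numeric vector of length `n_samples`.
#' @export
generate_pink_noise <- function(n_samples, sd = 1, sample_rate = 500) {
  stopifnot(n_samples > 1, sd > 0)
  white <- stats::rnorm(n_samples)
  spec <- stats::fft(white)
  k <- seq_len(n_samples) - 1
  freq <- pmin(k, n_samples - k) * sample_rate / n_samples  # two-sided axis
  scale <- ifelse(freq > 0, 1 / sqrt(freq), 0)              # kill DC
  x <- Re(stats::fft(spec * scale, inverse = TRUE)) / n_samples
  sd * (x - mean(x)) / stats::sd(x)
}

# Nc mean negativity produced by a unit-depth template after the full
# (linear) preprocessing chain: converts a target block-metric value into the
# template peak depth. Cached per preprocessing configuration.
.gain_cache <- new.env(parent = emptyenv())
nc_template_gain <- function(cfg, centre = 500, width = 90) {
  key <- paste(c(cfg$segment_span, cfg$epoch_span, cfg$baseline_span,
                 cfg$band, cfg$pad_samples, cfg$sample_rate, centre, width),
               collapse = "|")
  if (!is.null(.gain_cache[[key]])) return(.gain_cache[[key]])
  t_ms <- segment_times(cfg)
  seg <- matrix(-exp(-(t_ms - centre)^2 / (2 * width^2)), nrow = 1,
                dimnames = list(cfg$channels_of_interest[1], NULL))
  ep <- preprocess_segment(seg, cfg)
  g <- nc_mean_negativity(ep[1, ], attr(ep, "times"))$mean_negativity
  .gain_cache[[key]] <- g
  g
}

#' Simulate one raw 12-trial EEG block
#'
#' Each trial is a 1500 ms, 8-channel segment around the stimulus marker:
#' pink-noise background on every channel, plus a negative Gaussian-shaped Nc
#' deflection (centre 500 ms, SD 90 ms) on the six fronto-central channels
#' only — the posterior references P7/P8 carry noise alone, so the pooled
#' reference subtraction does not cancel the signal. The per-trial deflection
#' is calibrated so that the downstream block-level Nc mean negativity matches
#' a draw from Normal(response_curve(stimulus), trial_sd). With probability
#' `artifact_prob + fussiness_slope * (block_number - 1)` per trial-channel a
#' 400 µV, 100 ms square pulse is injected at a random latency inside the
#' epoch window, guaranteed to trip the default amplitude threshold.
#'
#' @param profile a [subject_profile()].
#' @param stimulus_index 0-based stimulus to present.
#' @param block_number 1-based presented-block counter (drives fussiness).
#' @param space a [make_stimulus_space()].
#' @param cfg a [preprocess_config()] (segment span / sample rate / trial
#'   geometry).
#' @param n_trials trials per block (default 12).
#' @return a `raw_block`: list with `stimulus_index`, `trials` (list of
#'   channels x samples matrices, µV), `channel_labels`, `sample_rate`,
#'   `segment_span`.
#' @export
simulate_block <- function(profile, stimulus_index, block_number = 1L,
                           space = make_stimulus_space(),
                           cfg = preprocess_config(), n_trials = 12L) {
  stopifnot(inherits(profile, "subject_profile"), block_number >= 1)
  stimulus_index <- check_index(space, stimulus_index)
  t_ms <- segment_times(cfg)
  n <- length(t_ms)
  chans <- c(cfg$channels_of_interest, cfg$reference_channels)
  template <- exp(-(t_ms - 500)^2 / (2 * 90^2))
  gain <- nc_template_gain(cfg)
  mu <- response_curve(profile, stimulus_coordinate(space, stimulus_index),
                       space)
  p_art <- min(1, profile$artifact_prob +
                 profile$fussiness_slope * (block_number - 1))
  step <- 1000 / cfg$sample_rate

  trials <- lapply(seq_len(n_trials), function(i) {
    seg <- matrix(0, nrow = length(chans), ncol = n, dimnames = list(chans, NULL))
    if (profile$noise_sd > 0) {
      for (c in seq_along(chans)) {
        seg[c, ] <- generate_pink_noise(n, profile$noise_sd, cfg$sample_rate)
      }
    }
    depth <- if (profile$trial_sd > 0) {
      stats::rnorm(1, mu, profile$trial_sd)
    } else {
      mu
    }
    erp <- -(depth / gain) * template
    for (ch in cfg$channels_of_interest) {
      seg[ch, ] <- seg[ch, ] + erp
    }
    if (p_art > 0) {
      hit <- stats::runif(length(chans)) < p_art
      for (c in which(hit)) {
        onset <- stats::runif(1, 0, 700)  # within the epoch window
        idx <- which(t_ms >= onset & t_ms < onset + 100)
        seg[c, idx] <- seg[c, idx] + sample(c(-400, 400), 1)
      }
    }
    seg
  })
  structure(list(
    stimulus_index = stimulus_index, trials = trials, channel_labels = chans,
    sample_rate = cfg$sample_rate, segment_span = cfg$segment_span
  ), class = "raw_block")
}

#' Simulate a cohort of subject profiles
#'
#' Ages are uniform over `age_range`; true optima are drawn either from a
#' point-mass mixture (probability `p_parent` on the pure-parent extreme,
#' `p_stranger` on the pure-stranger extreme, remainder uniform over the
#' interior) or, when `planted_age_slope` is given, from a latent
#' optimum-parent distance `1.1 + slope * (age - midpoint) + noise` mapped to
#' the grid by randomized rounding (which keeps the expected distance linear
#' in age, so the planted slope is recoverable without discretisation bias).
#' Behaviour covariates are drawn from normal distributions and can be tilted
#' by the subject's optimum-parent distance through
#' `behaviour_distance_coef`.
#'
#' @param n_subjects number of profiles (>= 1).
#' @param space a [make_stimulus_space()].
#' @param age_range integer days, default 158-375.
#' @param p_parent,p_stranger mixture mass at the two extremes
#'   (defaults 20/44 and 16/44).
#' @param planted_age_slope optional distance-per-day slope planted between
#'   age and true-optimum distance (e.g. -0.004).
#' @param latent_sd SD of the latent-distance noise when planting a slope.
#' @param behaviour_distance_coef per-unit-distance shift added to each
#'   behaviour score (default 0 = uncorrelated).
#' @param ... overrides passed to every [subject_profile()] call
#'   (e.g. `noise_sd`, `trial_sd`, `artifact_prob`).
#' @return list of `subject_profile` objects.
#' @export
simulate_cohort <- function(n_subjects, space = make_stimulus_space(),
                            age_range = c(158L, 375L),
                            p_parent = 20 / 44, p_stranger = 16 / 44,
                            planted_age_slope = NULL, latent_sd = 0.15,
                            behaviour_distance_coef = 0, ...) {
  stopifnot(n_subjects >= 1, p_parent + p_stranger <= 1)
  last <- space$n_points - 1L
  ages <- as.integer(round(stats::runif(n_subjects, age_range[1], age_range[2])))
  optima <- integer(n_subjects)
  if (is.null(planted_age_slope)) {
    u <- stats::runif(n_subjects)
    for (i in seq_len(n_subjects)) {
      optima[i] <- if (u[i] < p_parent) 0L
        else if (u[i] < p_parent + p_stranger) last
        else sample(seq_len(last - 1L), 1L)
    }
  } else {
    mid <- mean(age_range)
    d_star <- 1.1 + planted_age_slope * (ages - mid) +
      stats::rnorm(n_subjects, 0, latent_sd)
    d_star <- pmin(pmax(d_star, 0), space$coordinates[space$n_points])
    lo <- floor(d_star / space$spacing)
    frac <- d_star / space$spacing - lo
    up <- stats::runif(n_subjects) < frac   # randomized rounding: E[d] = d_star
    optima <- as.integer(pmin(lo + up, last))
  }
  lapply(seq_len(n_subjects), function(i) {
    d <- optima[i] * space$spacing
    beh <- list(
      interest_familiar = stats::rnorm(1, 1.5, 0.3),
      interest_unfamiliar = stats::rnorm(1, 1.3, 0.35),
      distress = stats::rnorm(1, 3.5, 1.2),
      similarity = stats::rnorm(1, 5, 2)
    )
    if (behaviour_distance_coef != 0) {
      beh <- lapply(beh, function(v) v + behaviour_distance_coef * (d - 1.1))
    }
    subject_profile(
      subject_id = sprintf("S%03d", i), age_days = ages[i],
      true_optimum_index = optima[i], behaviour_scores = beh, ...
    )
  })
}

#' Write a simulated block as continuous CSV + events TSV
#'
#' Concatenates the trials of a [simulate_block()] result into one continuous
#' stream (with a zero-filled inter-trial gap) and writes a headered CSV of
#' channel columns plus a TSV of stimulus markers (`onset_ms`,
#' `stimulus_index`), exercising the same file-reading path used for recorded
#' data.
#'
#' @param block a `raw_block`.
#' @param csv_path,events_path output file paths.
#' @param gap_ms inter-trial gap (default 200 ms).
#' @return invisibly, the marker table.
#' @export
write_block_files <- function(block, csv_path, events_path, gap_ms = 200) {
  step <- 1000 / block$sample_rate
  gap <- matrix(0, nrow = length(block$channel_labels),
                ncol = round(gap_ms / step))
  pieces <- list()
  onsets <- numeric(length(block$trials))
  pre <- -block$segment_span[1]  # ms before marker inside each trial segment
  pos_ms <- 0
  for (i in seq_along(block$trials)) {
    onsets[i] <- pos_ms + pre
    pieces[[length(pieces) + 1L]] <- block$trials[[i]]
    pos_ms <- pos_ms + ncol(block$trials[[i]]) * step
    pieces[[length(pieces) + 1L]] <- gap
    pos_ms <- pos_ms + ncol(gap) * step
  }
  stream <- do.call(cbind, pieces)
  df <- as.data.frame(t(stream))
  names(df) <- block$channel_labels
  utils::write.csv(df, csv_path, row.names = FALSE)
  ev <- data.frame(onset_ms = onsets, stimulus_index = block$stimulus_index)
  utils::write.table(ev, events_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(ev)
}

#' Read a continuous stream written by [write_block_files()]
#'
#' @param csv_path headered CSV, one column per channel, µV.
#' @param events_path TSV with columns `onset_ms`, `stimulus_index`.
#' @return list with `continuous` (channels x samples matrix, rownames =
#'   labels) and `events` (data.frame).
#' @export
read_block_files <- function(csv_path, events_path) {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  ev <- utils::read.table(events_path, sep = "\t", header = TRUE)
  stopifnot(all(c("onset_ms", "stimulus_index") %in% names(ev)))
  cont <- t(as.matrix(df))
  rownames(cont) <- names(df)
  list(continuous = cont, events = ev)
}
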