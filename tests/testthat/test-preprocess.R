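cfg <- preprocess_config()
chan <- nbo_channels()

one_chan_segment <- function(x) {
  matrix(x, nrow = 1, dimnames = list("Fz", NULL))
}

test_that("segmentation cuts one aligned 750-sample segment per marker", {
  fs <- cfg$sample_rate
  n <- 60 * fs
  stream <- matrix(stats::rnorm(8 * n), nrow = 8, dimnames = list(chan, NULL))
  markers <- seq(2000, 46000, by = 4000)[1:12]
  segs <- segment_block(stream, markers, cfg)
  expect_length(segs, 12)
  for (s in segs) expect_identical(dim(s), c(8L, 750L))
  # segmentation preserves values: marker sample sits at t = 0
  t0 <- which(attr(segs[[1]], "times") == 0)
  m_idx <- round(markers[1] / (1000 / fs)) + 1
  expect_identical(segs[[1]][, t0], stream[, m_idx])

  expect_error(segment_block(stream, 100, cfg), "marker 1")
  const <- matrix(7, nrow = 8, ncol = n, dimnames = list(chan, NULL))
  expect_true(all(segment_block(const, markers, cfg)[[1]] == 7))
})

test_that("preprocessing removes DC and passes/stops the right frequencies", {
  t <- segment_times(cfg) / 1000
  dc <- preprocess_segment(one_chan_segment(rep(100, length(t))), cfg)
  expect_lt(max(abs(dc)), 0.5)

  interior <- 50:400
  p2p_gain <- function(freq) {
    y <- preprocess_segment(one_chan_segment(10 * sin(2 * pi * freq * t)), cfg)
    (max(y[1, interior]) - min(y[1, interior])) / 2 / 10
  }
  expect_gt(p2p_gain(10), 0.95)
  expect_lt(p2p_gain(10), 1.05)
  expect_lt(p2p_gain(35), 0.2)
})

test_that("the chain is linear and leaves a zero-mean baseline interval", {
  t <- segment_times(cfg)
  set.seed(21)
  a <- matrix(stats::rnorm(8 * length(t), sd = 30), nrow = 8,
              dimnames = list(chan, NULL))
  b <- matrix(stats::rnorm(8 * length(t), sd = 30), nrow = 8,
              dimnames = list(chan, NULL))
  lhs <- preprocess_segment(2 * a + 3 * b, cfg)
  rhs <- 2 * preprocess_segment(a, cfg) + 3 * preprocess_segment(b, cfg)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-6)

  et <- attr(lhs, "times")
  bl <- et >= -100 & et <= 0
  expect_lt(max(abs(rowMeans(preprocess_segment(a, cfg)[, bl]))), 1e-6)
})

test_that("artifact rejection flags amplitude, range and flat epochs with reasons", {
  times <- seq(-100, 800, by = 2)
  eps <- make_epochs(times = times, maker = function(t, c) {
    if (t == 1 && c == 1) {
      x <- 20 * sin(2 * pi * 5 * times / 1000); x[200] <- 300; x  # amplitude
    } else if (t == 3 && c == 3) {
      rep(0, length(times))                                       # flat
    } else {
      20 * sin(2 * pi * 5 * times / 1000)                         # clean
    }
  })
  m <- detect_artifacts(eps, cfg)
  expect_true(m$rejected[1, 1])
  expect_identical(unname(m$reason[1, 1]), "amplitude")
  expect_true(m$rejected[3, 3])
  expect_identical(unname(m$reason[3, 3]), "flat")
  expect_identical(sum(m$rejected), 2L)

  # a peak-to-peak excursion below the amplitude ceiling still trips a
  # tighter range threshold
  cfg_r <- preprocess_config(range_thresh = 150)
  eps_r <- make_epochs(n_trials = 1, times = times, maker = function(t, c) {
    90 * sin(2 * pi * 5 * times / 1000)
  })
  m_r <- detect_artifacts(eps_r, cfg_r)
  expect_true(all(m_r$rejected))
  expect_true(all(m_r$reason == "range"))
})

test_that("quality gate counts fully-clean trials against the 10-trial rule", {
  m <- clean_mask()
  q <- block_quality(m, cfg)
  expect_identical(q$clean_trial_count, 12L)
  expect_true(q$passed)
  expect_equal(q$percent_clean_channel_trials, 100)

  # 3 contaminated trials leave 9 clean: below the gate
  m2 <- clean_mask()
  m2$rejected[1:3, "Cz"] <- TRUE
  q2 <- block_quality(m2, cfg)
  expect_identical(q2$clean_trial_count, 9L)
  expect_false(q2$passed)

  # one channel rejected everywhere: no clean trials, 60/72 channel-trials
  m3 <- clean_mask()
  m3$rejected[, "Fz"] <- TRUE
  q3 <- block_quality(m3, cfg)
  expect_identical(q3$clean_trial_count, 0L)
  expect_equal(q3$percent_clean_channel_trials, 100 * 60 / 72)
  # but a majority rule would keep those trials
  cfg_maj <- preprocess_config(trial_clean_rule = "majority")
  expect_identical(block_quality(m3, cfg_maj)$clean_trial_count, 12L)

  # pass/fail is invariant to channel ordering
  perm <- sample(ncol(m2$rejected))
  m2p <- m2
  m2p$rejected <- m2$rejected[, perm]
  m2p$reason <- m2$reason[, perm]
  expect_identical(block_quality(m2p, cfg)$passed, q2$passed)
})

test_that("referenced averaging pools channels of interest minus references", {
  times <- seq(-100, 800, by = 2)
  erp <- -8 * exp(-(times - 500)^2 / (2 * 90^2))
  eps <- make_epochs(times = times, maker = function(t, c) {
    if (c <= 6) erp else rep(0, length(times))
  })
  m <- clean_mask()
  m$reason[, 7:8] <- "flat"  # refs are flat but still usable as references
  m$rejected[, 7:8] <- TRUE
  out <- average_and_reference(eps, m, cfg)
  expect_equal(as.numeric(out), erp, tolerance = 1e-12)

  # common-mode: identical signal everywhere cancels
  eps2 <- make_epochs(times = times, maker = function(t, c) erp)
  out2 <- average_and_reference(eps2, clean_mask(), cfg)
  expect_lt(max(abs(out2)), 1e-12)
})

test_that("per-channel clean subsets reproduce the nested mean on a 3-trial toy", {
  times <- seq(-100, 800, by = 2)
  set.seed(5)
  vals <- array(stats::rnorm(3 * 8 * length(times)), c(3, 8, length(times)))
  eps <- make_epochs(n_trials = 3, times = times,
                     maker = function(t, c) vals[t, c, ])
  m <- clean_mask(n_trials = 3)
  m$rejected[1, 2] <- TRUE; m$reason[1, 2] <- "amplitude"
  m$rejected[c(2, 3), 7] <- TRUE; m$reason[c(2, 3), 7] <- "range"
  out <- average_and_reference(eps, m, cfg)

  ch_means <- sapply(1:8, function(c) {
    keep <- !m$rejected[, c]
    colMeans(matrix(vals[keep, c, ], nrow = sum(keep)))
  })
  oracle <- rowMeans(ch_means[, 1:6]) - rowMeans(ch_means[, 7:8])
  expect_equal(as.numeric(out), as.numeric(oracle), tolerance = 1e-12)

  # rejecting all but one trial reproduces that trial
  m1 <- clean_mask(n_trials = 3)
  m1$rejected[1:2, ] <- TRUE; m1$reason[1:2, ] <- "amplitude"
  out1 <- average_and_reference(eps, m1, cfg)
  oracle1 <- colMeans(vals[3, 1:6, ]) - colMeans(vals[3, 7:8, ])
  expect_equal(as.numeric(out1), as.numeric(oracle1), tolerance = 1e-12)

  # a required channel contaminated in every trial is a hard error
  mbad <- clean_mask(n_trials = 3)
  mbad$rejected[, "Cz"] <- TRUE; mbad$reason[, "Cz"] <- "amplitude"
  expect_error(average_and_reference(eps, mbad, cfg), "Cz")
})
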