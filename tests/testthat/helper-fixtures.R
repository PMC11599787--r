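# Shared fixtures built in code.

# Epoch set with given per-trial/channel signals: `maker(trial, channel)`
# returns a sample vector on the default epoch grid.
make_epochs <- function(n_trials = 12, channels = nbo_channels(),
                        times = seq(-100, 800, by = 2),
                        maker = function(t, c) rep(0, length(times))) {
  arr <- array(0, dim = c(n_trials, length(channels), length(times)),
               dimnames = list(NULL, channels, NULL))
  for (t in seq_len(n_trials)) {
    for (c in seq_along(channels)) arr[t, c, ] <- maker(t, c)
  }
  structure(list(data = arr, channels = channels, times = times),
            class = "epoch_set")
}

# All-clean artifact mask for an epoch set.
clean_mask <- function(n_trials = 12, channels = nbo_channels()) {
  structure(list(
    rejected = matrix(FALSE, n_trials, length(channels),
                      dimnames = list(NULL, channels)),
    reason = matrix(NA_character_, n_trials, length(channels),
                    dimnames = list(NULL, channels))
  ), class = "artifact_mask")
}

# Outcome table encoding the reference participant flow: 61 participating,
# 9 non-completers, 8 completed without convergence, 44 converged with optima
# 20 at index 0, 16 at index 11, 8 intermediate (4 per half, giving the
# 24 / 20 side split).
reference_outcome_table <- function() {
  optima <- c(rep(0L, 20), rep(11L, 16), 1L, 2L, 3L, 5L, 6L, 8L, 9L, 10L)
  conv <- data.frame(
    subject_id = sprintf("C%02d", seq_along(optima)),
    completed = TRUE, converged = TRUE,
    optimum_index = optima,
    optimum_parent_distance = optima * 0.2,
    side = ifelse(optima <= 5, "parent", "stranger"),
    blocks_presented = pmin(6L + (seq_along(optima) %% 9L), 14L),
    stringsAsFactors = FALSE
  )
  nonconv <- data.frame(
    subject_id = sprintf("N%02d", 1:8),
    completed = TRUE, converged = FALSE,
    optimum_index = NA_integer_, optimum_parent_distance = NA_real_,
    side = NA_character_, blocks_presented = 15L,
    stringsAsFactors = FALSE
  )
  dropout <- data.frame(
    subject_id = sprintf("D%02d", 1:9),
    completed = FALSE, converged = FALSE,
    optimum_index = NA_integer_, optimum_parent_distance = NA_real_,
    side = NA_character_, blocks_presented = 4L,
    stringsAsFactors = FALSE
  )
  rbind(conv, nonconv, dropout)
}

# Independent GP-regression oracle: plain dense formulas via explicit matrix
# inversion, standardizing y the same way.
gp_oracle <- function(obs_index, obs_value, space, cfg) {
  y_mu <- mean(obs_value)
  y_sd <- stats::sd(obs_value)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  z <- (obs_value - y_mu) / y_sd
  xo <- space$coordinates[obs_index + 1]
  xg <- space$coordinates
  k <- function(a, b) {
    cfg$signal_variance *
      exp(-(outer(a, rep(1, length(b))) - outer(rep(1, length(a)), b))^2 /
            (2 * cfg$kernel_lengthscale^2))
  }
  Kinv <- solve(k(xo, xo) + (cfg$noise_variance + 1e-10) * diag(length(xo)))
  Ks <- k(xg, xo)
  list(mean = as.numeric(Ks %*% Kinv %*% z),
       sd = sqrt(pmax(cfg$signal_variance -
                        diag(Ks %*% Kinv %*% t(Ks)), 0)))
}

# First-principles sums-of-squares oracle for the 2 (within) x 2 (between)
# mixed design, balanced or not (unweighted cell means, Type-III-like for
# two-level factors).
mixed_anova_oracle <- function(parent, stranger, group) {
  g <- as.integer(factor(group))
  n_g <- tabulate(g, 2)
  subj_mean <- (parent + stranger) / 2
  d <- stranger - parent
  cell <- rbind(c(mean(parent[g == 1]), mean(stranger[g == 1])),
                c(mean(parent[g == 2]), mean(stranger[g == 2])))
  gm_g <- rowMeans(cell)           # unweighted group means
  gm_c <- colMeans(cell)           # unweighted condition means
  gm <- mean(cell)
  nh <- 2 / sum(1 / n_g)           # harmonic cell size
  ss_group <- 2 * nh * sum((gm_g - gm)^2)
  ss_cond <- 2 * nh * sum((gm_c - gm)^2)
  ss_int <- nh * sum((cell - outer(gm_g, rep(1, 2)) -
                        outer(rep(1, 2), gm_c) + gm)^2)
  ss_subj <- 2 * sum((subj_mean - gm_g[g])^2)
  ss_err <- sum((d - tapply(d, g, mean)[g])^2) / 2
  n <- length(parent)
  list(
    group = c(F = (ss_group / 1) / (ss_subj / (n - 2)), df2 = n - 2,
              ss = ss_group, ss_err = ss_subj),
    condition = c(F = (ss_cond / 1) / (ss_err / (n - 2)), df2 = n - 2,
                  ss = ss_cond, ss_err = ss_err),
    interaction = c(F = (ss_int / 1) / (ss_err / (n - 2)), df2 = n - 2,
                    ss = ss_int, ss_err = ss_err)
  )
}
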