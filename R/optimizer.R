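#' Bayesian-optimiser configuration
#'
#' Fixed hyperparameters of the Gaussian-process surrogate and acquisition
#' rule, the burn-in schedule, and the stopping rules. The four burn-in
#' stimuli are the two extremes of the space plus the two interior points
#' nearest 33% and 66% stranger on the 12-point grid (indices 4 and 7). The
#' surrogate uses a squared-exponential kernel on stimulus-space coordinates
#' with fixed hyperparameters (no marginal-likelihood optimisation), for
#' reproducibility; observations are z-standardized at every refit.
#'
#' The default acquisition is the upper confidence bound: under the
#' run-length stopping rule a session only ends early if the same stimulus is
#' proposed three times in a row, and UCB will keep proposing the incumbent
#' once its mean dominates, whereas expected improvement actively avoids
#' re-proposing an already-observed point (its improvement there collapses),
#' making three identical proposals rare under realistic noise. EI remains
#' available via `acquisition = "EI"`.
#'
#' @param burn_in_indices the four burn-in stimulus indices
#'   (default `c(0, 4, 7, 11)`; must be distinct and include both extremes).
#' @param kernel_lengthscale GP lengthscale in coordinate units (default 0.44).
#' @param signal_variance GP signal variance, standardized units^2 (default 1).
#' @param noise_variance GP noise variance, standardized units^2 (default 0.25).
#' @param acquisition `"UCB"` (upper confidence bound, default) or `"EI"`
#'   (expected improvement).
#' @param ei_xi EI exploration margin xi >= 0 (default 0.01).
#' @param ucb_kappa UCB exploration weight kappa >= 0 (default 1.5: large
#'   enough to probe unvisited regions after burn-in, small enough that a
#'   noise-free loop always settles on the argmax within the block budget —
#'   at kappa = 2 the exploration bonus can keep a neighbour of the optimum
#'   attractive indefinitely).
#' @param convergence_run_length identical consecutive proposals required to
#'   stop (default 3).
#' @param max_blocks maximum presented blocks, burn-ins and quality-repeat
#'   presentations included (default 15).
#' @param max_repetitions extra presentations allowed per block after a
#'   quality failure before the session aborts (default 2).
#' @param n_points number of grid points the burn-ins refer to (default 12).
#' @return an `optimizer_config` list.
#' @export
optimizer_config <- function(burn_in_indices = c(0L, 4L, 7L, 11L),
                             kernel_lengthscale = 0.44,
                             signal_variance = 1,
                             noise_variance = 0.25,
                             acquisition = c("UCB", "EI"),
                             ei_xi = 0.01,
                             ucb_kappa = 1.5,
                             convergence_run_length = 3L,
                             max_blocks = 15L,
                             max_repetitions = 2L,
                             n_points = 12L) {
  acquisition <- match.arg(acquisition)
  burn_in_indices <- as.integer(burn_in_indices)
  stopifnot(
    anyDuplicated(burn_in_indices) == 0L,
    0L %in% burn_in_indices, (n_points - 1L) %in% burn_in_indices,
    kernel_lengthscale > 0, signal_variance > 0, noise_variance >= 0,
    ei_xi >= 0, ucb_kappa >= 0,
    convergence_run_length >= 2, max_blocks >= length(burn_in_indices)
  )
  structure(list(
    burn_in_indices = burn_in_indices,
    kernel_lengthscale = kernel_lengthscale,
    signal_variance = signal_variance,
    noise_variance = noise_variance,
    acquisition = acquisition, ei_xi = ei_xi, ucb_kappa = ucb_kappa,
    convergence_run_length = as.integer(convergence_run_length),
    max_blocks = as.integer(max_blocks),
    max_repetitions = as.integer(max_repetitions)
  ), class = "optimizer_config")
}

#' Randomised burn-in presentation order
#'
#' A uniformly random permutation of the configured burn-in stimuli, drawn
#' from the current RNG state (deterministic under `set.seed()`).
#'
#' @param cfg an [optimizer_config()].
#' @return integer vector, a permutation of `cfg$burn_in_indices`.
#' @export
burn_in_order <- function(cfg = optimizer_config()) {
  sample(cfg$burn_in_indices)
}

#' Fresh optimiser state
#' @param cfg an [optimizer_config()].
#' @return an `optimizer_state` with empty observation and proposal history.
#' @export
new_optimizer_state <- function(cfg = optimizer_config()) {
  structure(list(
    observations = data.frame(index = integer(0), value = numeric(0)),
    proposal_history = data.frame(index = integer(0), phase = character(0),
                                  presented = logical(0),
                                  qc_failed = logical(0)),
    run = integer(0),          # consecutive-proposal bookkeeping (bo phase)
    n_burn_in_done = 0L,
    converged = FALSE,
    predicted_optimum = NULL,
    cfg = cfg
  ), class = "optimizer_state")
}

burn_ins_complete <- function(state) {
  state$n_burn_in_done >= length(state$cfg$burn_in_indices)
}

#' Fit the Gaussian-process surrogate to the observations
#'
#' Raw block metrics are z-standardized; a GP with squared-exponential kernel
#' \eqn{k(x, x') = \sigma_f^2 \exp(-(x-x')^2 / (2\ell^2))} and homoscedastic
#' noise \eqn{\sigma_n^2} is conditioned on the (possibly duplicated)
#' observed coordinates, and the posterior mean and SD are returned at every
#' grid point.
#'
#' @param observations data.frame with columns `index` (0-based) and `value`
#'   (raw metric, µV); at least 2 rows.
#' @param space a [make_stimulus_space()].
#' @param cfg an [optimizer_config()].
#' @return a `gp_posterior`: list with `mean`, `sd` (length `n_points`,
#'   standardized units), `y_best` (best standardized observation),
#'   `standardization` (mean, sd of the raw values), `observed_index`.
#' @export
fit_surrogate <- function(observations, space = make_stimulus_space(),
                          cfg = optimizer_config()) {
  if (nrow(observations) < 2L) {
    stop("at least 2 observations are required to fit the surrogate",
         call. = FALSE)
  }
  y_mu <- mean(observations$value)
  y_sd <- stats::sd(observations$value)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  z <- (observations$value - y_mu) / y_sd

  xo <- space$coordinates[observations$index + 1L]
  xg <- space$coordinates
  l2 <- cfg$kernel_lengthscale^2
  kfun <- function(a, b) {
    cfg$signal_variance * exp(-outer(a, b, `-`)^2 / (2 * l2))
  }
  K <- kfun(xo, xo) + diag(cfg$noise_variance + 1e-10, length(xo))
  Ks <- kfun(xg, xo)
  Kinv_z <- solve(K, z)
  post_mean <- as.numeric(Ks %*% Kinv_z)
  v <- solve(K, t(Ks))
  post_var <- cfg$signal_variance - rowSums(Ks * t(v))
  structure(list(
    mean = post_mean,
    sd = sqrt(pmax(post_var, 0)),
    y_best = max(z),
    standardization = c(mean = y_mu, sd = y_sd),
    observed_index = observations$index
  ), class = "gp_posterior")
}

#' Acquisition scores over the stimulus grid
#'
#' Expected improvement:
#' \eqn{EI(x) = (\mu(x) - y^+ - \xi)\Phi(z) + s(x)\phi(z)} with
#' \eqn{z = (\mu(x) - y^+ - \xi)/s(x)}, degenerating to
#' \eqn{\max(\mu(x) - y^+ - \xi, 0)} where \eqn{s(x) = 0}. Upper confidence
#' bound: \eqn{\mu(x) + \kappa s(x)}.
#'
#' @param posterior a [fit_surrogate()] result.
#' @param cfg an [optimizer_config()].
#' @return numeric score vector over the grid (EI scores are >= 0).
#' @export
acquisition_scores <- function(posterior, cfg = optimizer_config()) {
  stopifnot(inherits(posterior, "gp_posterior"))
  mu <- posterior$mean
  s <- posterior$sd
  if (cfg$acquisition == "UCB") {
    return(mu + cfg$ucb_kappa * s)
  }
  imp <- mu - posterior$y_best - cfg$ei_xi
  out <- pmax(imp, 0)
  pos <- s > 0
  z <- imp[pos] / s[pos]
  out[pos] <- imp[pos] * stats::pnorm(z) + s[pos] * stats::dnorm(z)
  out
}

#' Propose the next stimulus
#'
#' Fits the surrogate to the current observations, scores every grid point
#' with the configured acquisition function and returns the argmax, breaking
#' ties towards the lowest index. Only valid once all burn-ins are complete.
#'
#' @param state an `optimizer_state`.
#' @param space a [make_stimulus_space()].
#' @return 0-based stimulus index.
#' @export
propose_next <- function(state, space = make_stimulus_space()) {
  stopifnot(inherits(state, "optimizer_state"))
  if (!burn_ins_complete(state)) {
    stop("burn-in presentations are not complete; cannot propose yet",
         call. = FALSE)
  }
  post <- fit_surrogate(state$observations, space, state$cfg)
  scores <- acquisition_scores(post, state$cfg)
  as.integer(which.max(scores) - 1L)  # which.max takes the first (lowest) tie
}

#' Would this proposal complete the convergence run?
#'
#' TRUE when `proposed` equals the last `convergence_run_length - 1`
#' post-burn-in proposals, i.e. registering it would trigger early stopping
#' and the block need not be presented.
#'
#' @param state an `optimizer_state`.
#' @param proposed 0-based stimulus index.
#' @return logical.
#' @export
would_converge <- function(state, proposed) {
  need <- state$cfg$convergence_run_length - 1L
  length(state$run) >= need &&
    all(utils::tail(state$run, need) == proposed)
}

#' Register a proposal and its measured block metric
#'
#' Appends the proposal to the history and, when a valid metric is supplied,
#' the observation. Post-burn-in proposals extend the consecutive-proposal
#' run; when the run reaches `convergence_run_length` identical entries, the
#' state is marked converged and the repeated index becomes the predicted
#' optimum — the run-completing proposal carries no metric because it is
#' never presented. Quality-control failures (`qc_failed = TRUE`) are logged
#' but extend neither the run nor the observations: the repeated presentation
#' of the same stimulus is not a new proposal.
#'
#' @param state an `optimizer_state`.
#' @param proposed 0-based stimulus index: the most recent proposal (or the
#'   burn-in stimulus just presented).
#' @param metric block-level Nc mean negativity in µV, or NULL for an
#'   unpresented (convergence-triggering) proposal or a QC failure.
#' @param phase `"bo"` (default) or `"burn_in"`.
#' @param qc_failed logical; TRUE when the presented block failed the quality
#'   gate.
#' @return the updated `optimizer_state`.
#' @export
update_and_check <- function(state, proposed, metric = NULL,
                             phase = c("bo", "burn_in"), qc_failed = FALSE) {
  stopifnot(inherits(state, "optimizer_state"))
  phase <- match.arg(phase)
  proposed <- as.integer(proposed)
  if (phase == "burn_in" && !proposed %in% state$cfg$burn_in_indices) {
    stop("burn-in update for a non-burn-in stimulus", call. = FALSE)
  }
  if (phase == "bo" && !burn_ins_complete(state)) {
    stop("received a BO update before burn-ins were complete", call. = FALSE)
  }
  if (!is.null(metric) && (!is.numeric(metric) || length(metric) != 1L ||
                           !is.finite(metric))) {
    stop("metric must be a single finite number or NULL", call. = FALSE)
  }
  state$proposal_history <- rbind(state$proposal_history, data.frame(
    index = proposed, phase = phase,
    presented = qc_failed || !is.null(metric),
    qc_failed = qc_failed
  ))
  if (qc_failed) {
    return(state)
  }
  if (!is.null(metric)) {
    state$observations <- rbind(state$observations,
                                data.frame(index = proposed, value = metric))
    if (phase == "burn_in") state$n_burn_in_done <- state$n_burn_in_done + 1L
  }
  if (phase == "bo") {
    state$run <- c(state$run, proposed)
    k <- state$cfg$convergence_run_length
    if (length(state$run) >= k &&
        length(unique(utils::tail(state$run, k))) == 1L) {
      state$converged <- TRUE
      state$predicted_optimum <- proposed
    }
  }
  state
}

#' @export
print.optimizer_state <- function(x, ...) {
  cat(sprintf("Optimizer state: %d observations, %d proposals, %s\n",
              nrow(x$observations), nrow(x$proposal_history),
              if (x$converged) {
                sprintf("converged (optimum index %d)", x$predicted_optimum)
              } else "not converged"))
  invisible(x)
}
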