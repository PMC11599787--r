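#' Process one raw block through the preprocessing chain
#'
#' Runs every trial segment of a raw block through detrend / demean / mirror
#' pad / band-pass / crop / baseline correction, flags artifacts, applies the
#' quality gate and — when the gate passes — computes the referenced average
#' waveform and its Nc metric.
#'
#' @param block a `raw_block` (from [simulate_block()] or assembled from file
#'   input via [segment_block()]).
#' @param cfg a [preprocess_config()].
#' @return list with `qc` (a `qc_report`), `nc` (an `nc_result` or NULL when
#'   the gate fails) and `mask` (the `artifact_mask`).
#' @export
process_block <- function(block, cfg = preprocess_config()) {
  epochs <- epoch_set(lapply(block$trials, preprocess_segment, cfg = cfg))
  mask <- detect_artifacts(epochs, cfg)
  qc <- block_quality(mask, cfg)
  nc <- NULL
  if (qc$passed) {
    wf <- average_and_reference(epochs, mask, cfg)
    nc <- nc_mean_negativity(wf, attr(wf, "times"))
  }
  list(qc = qc, nc = nc, mask = mask)
}

present_with_repeats <- function(make_block, idx, blocks_presented, phase,
                                 state, pre_cfg, records) {
  # up to 1 + max_repetitions presentations of the same stimulus; returns
  # the updated bookkeeping or aborted = TRUE after persistent QC failure
  max_rep <- state$cfg$max_repetitions
  for (rep_i in 0:max_rep) {
    blocks_presented <- blocks_presented + 1L
    blk <- make_block(idx, blocks_presented)
    res <- process_block(blk, pre_cfg)
    records[[length(records) + 1L]] <- list(
      block_number = blocks_presented, stimulus_index = idx, phase = phase,
      repetition = rep_i, qc = res$qc, nc = res$nc
    )
    if (res$qc$passed) {
      state <- update_and_check(state, idx, res$nc$mean_negativity,
                                phase = phase)
      return(list(state = state, blocks_presented = blocks_presented,
                  records = records, aborted = FALSE))
    }
    state <- update_and_check(state, idx, NULL, phase = phase,
                              qc_failed = TRUE)
    if (rep_i == max_rep) {
      return(list(state = state, blocks_presented = blocks_presented,
                  records = records, aborted = TRUE))
    }
    if (blocks_presented >= state$cfg$max_blocks) break
  }
  # presented-block cap reached mid-repetition: session ends, not an abort
  list(state = state, blocks_presented = blocks_presented,
       records = records, aborted = FALSE)
}

#' Run one closed-loop session
#'
#' Presents the four burn-in stimuli in randomised order, then alternates
#' surrogate refits, acquisition-driven proposals and block presentations
#' until the optimiser proposes the same stimulus three times in a row (the
#' third, run-completing proposal is never presented), the presented-block
#' count reaches `max_blocks`, or a block fails the quality gate on its
#' initial presentation and both allowed repetitions (abort: `completed =
#' FALSE`).
#'
#' @param source a [subject_profile()] (blocks are simulated) or a function
#'   `(stimulus_index, block_number) -> raw_block` for file-fed/replayed
#'   streams.
#' @param space a [make_stimulus_space()].
#' @param pre_cfg a [preprocess_config()].
#' @param opt_cfg an [optimizer_config()].
#' @param seed optional integer seed; when given the session is fully
#'   reproducible.
#' @return a `session_result`: list with `subject_id`, `completed`,
#'   `converged`, `optimum_index`, `optimum_parent_distance`,
#'   `blocks_presented`, `block_records`, `state` (final `optimizer_state`),
#'   `nc_parent_mean` and `nc_stranger_mean` (mean block metric over valid
#'   blocks at the two extremes, burn-ins included).
#' @export
run_session <- function(source, space = make_stimulus_space(),
                        pre_cfg = preprocess_config(),
                        opt_cfg = optimizer_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  is_profile <- inherits(source, "subject_profile")
  stopifnot(is_profile || is.function(source))
  make_block <- if (is_profile) {
    function(idx, bn) simulate_block(source, idx, bn, space, pre_cfg)
  } else {
    source
  }
  state <- new_optimizer_state(opt_cfg)
  records <- list()
  blocks_presented <- 0L
  aborted <- FALSE

  for (idx in burn_in_order(opt_cfg)) {
    r <- present_with_repeats(make_block, idx, blocks_presented, "burn_in",
                              state, pre_cfg, records)
    state <- r$state; blocks_presented <- r$blocks_presented
    records <- r$records
    if (r$aborted) { aborted <- TRUE; break }
    if (blocks_presented >= opt_cfg$max_blocks) break
  }

  if (!aborted && burn_ins_complete(state)) {
    while (blocks_presented < opt_cfg$max_blocks) {
      idx <- propose_next(state, space)
      if (would_converge(state, idx)) {
        state <- update_and_check(state, idx, NULL, phase = "bo")
        break
      }
      r <- present_with_repeats(make_block, idx, blocks_presented, "bo",
                                state, pre_cfg, records)
      state <- r$state; blocks_presented <- r$blocks_presented
      records <- r$records
      if (r$aborted) { aborted <- TRUE; break }
    }
  }

  block_metric_mean <- function(index) {
    vals <- vapply(records, function(b) {
      if (!is.null(b$nc) && b$stimulus_index == index) {
        b$nc$mean_negativity
      } else NA_real_
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }

  structure(list(
    subject_id = if (is_profile) source$subject_id else "stream",
    completed = !aborted,
    converged = state$converged,
    optimum_index = state$predicted_optimum,
    optimum_parent_distance = if (state$converged) {
      optimum_parent_distance(space, state$predicted_optimum)
    } else NULL,
    blocks_presented = blocks_presented,
    block_records = records,
    state = state,
    nc_parent_mean = block_metric_mean(0L),
    nc_stranger_mean = block_metric_mean(space$n_points - 1L)
  ), class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("Session %s: %s, %s, %d blocks presented\n", x$subject_id,
              if (x$completed) "completed" else "aborted",
              if (x$converged) {
                sprintf("converged at index %d (distance %.1f)",
                        x$optimum_index, x$optimum_parent_distance)
              } else "not converged",
              x$blocks_presented))
  invisible(x)
}

#' Run the optimiser loop against a direct block-metric oracle
#'
#' Exercises burn-ins, proposals and the stopping rule with the block metric
#' drawn straight from `objective(index)` — no EEG simulation, artifact
#' rejection or quality gate. Useful for studying the optimiser's convergence
#' behaviour in isolation.
#'
#' @param objective function `(stimulus_index) -> metric` (µV); may be
#'   stochastic.
#' @param space a [make_stimulus_space()].
#' @param opt_cfg an [optimizer_config()].
#' @param seed optional integer seed.
#' @return a `session_result` with NULL block records.
#' @export
run_objective_session <- function(objective, space = make_stimulus_space(),
                                  opt_cfg = optimizer_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- new_optimizer_state(opt_cfg)
  blocks_presented <- 0L
  for (idx in burn_in_order(opt_cfg)) {
    blocks_presented <- blocks_presented + 1L
    state <- update_and_check(state, idx, objective(idx), phase = "burn_in")
  }
  while (blocks_presented < opt_cfg$max_blocks) {
    idx <- propose_next(state, space)
    if (would_converge(state, idx)) {
      state <- update_and_check(state, idx, NULL, phase = "bo")
      break
    }
    blocks_presented <- blocks_presented + 1L
    state <- update_and_check(state, idx, objective(idx), phase = "bo")
  }
  structure(list(
    subject_id = "objective", completed = TRUE, converged = state$converged,
    optimum_index = state$predicted_optimum,
    optimum_parent_distance = if (state$converged) {
      optimum_parent_distance(space, state$predicted_optimum)
    } else NULL,
    blocks_presented = blocks_presented,
    block_records = NULL, state = state,
    nc_parent_mean = NA_real_, nc_stranger_mean = NA_real_
  ), class = "session_result")
}

#' Run a cohort of closed-loop sessions
#'
#' One session per profile, each with a seed derived from the cohort seed, and
#' one outcome row per subject combining session results with the profile's
#' covariates.
#'
#' @param profiles list of [subject_profile()]s.
#' @param space a [make_stimulus_space()].
#' @param pre_cfg a [preprocess_config()].
#' @param opt_cfg an [optimizer_config()].
#' @param seed optional integer cohort seed.
#' @return an outcome table (data.frame) with columns `subject_id`,
#'   `age_days`, `completed`, `converged`, `optimum_index`,
#'   `optimum_parent_distance`, `side`, `blocks_presented`, `nc_parent_mean`,
#'   `nc_stranger_mean` and the behaviour covariates.
#' @export
run_cohort <- function(profiles, space = make_stimulus_space(),
                       pre_cfg = preprocess_config(),
                       opt_cfg = optimizer_config(), seed = NULL) {
  stopifnot(length(profiles) >= 1)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(profiles))
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    s <- run_session(p, space, pre_cfg, opt_cfg, seed = sub_seeds[i])
    data.frame(
      subject_id = p$subject_id,
      age_days = p$age_days,
      completed = s$completed,
      converged = s$converged,
      optimum_index = if (s$converged) s$optimum_index else NA_integer_,
      optimum_parent_distance = if (s$converged) {
        s$optimum_parent_distance
      } else NA_real_,
      side = if (s$converged) space_side(space, s$optimum_index)
             else NA_character_,
      blocks_presented = s$blocks_presented,
      nc_parent_mean = s$nc_parent_mean,
      nc_stranger_mean = s$nc_stranger_mean,
      interest_familiar = p$behaviour_scores$interest_familiar,
      interest_unfamiliar = p$behaviour_scores$interest_unfamiliar,
      distress = p$behaviour_scores$distress,
      similarity = p$behaviour_scores$similarity,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a session log as JSON Lines
#'
#' One header object (configs and seed), one object per block record, and a
#' footer with the session-level outcome, so a log can be replayed through
#' the analysis side without the raw EEG.
#'
#' @param session a `session_result`.
#' @param path output file.
#' @param seed the seed the session was run with (recorded in the header).
#' @return invisibly, `path`.
#' @export
write_session_log <- function(session, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(x) {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"),
               con)
  }
  emit(list(type = "header", subject_id = session$subject_id, seed = seed))
  for (b in session$block_records) {
    emit(list(
      type = "block", block_number = b$block_number,
      stimulus_index = b$stimulus_index, phase = b$phase,
      repetition = b$repetition,
      qc = list(
        clean_trial_count = b$qc$clean_trial_count,
        per_channel_clean = as.list(b$qc$per_channel_clean),
        percent_clean_channel_trials = b$qc$percent_clean_channel_trials,
        passed = b$qc$passed
      ),
      nc = if (is.null(b$nc)) NULL else list(
        mean_negativity = b$nc$mean_negativity,
        deflection_span = b$nc$deflection_span,
        peak_latency = b$nc$peak_latency,
        window_mean_amplitude = b$nc$window_mean_amplitude
      )
    ))
  }
  emit(list(type = "footer", completed = session$completed,
            converged = session$converged,
            optimum_index = session$optimum_index,
            optimum_parent_distance = session$optimum_parent_distance,
            blocks_presented = session$blocks_presented))
  invisible(path)
}
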