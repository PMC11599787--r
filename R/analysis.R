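#' Summarise cohort outcomes
#'
#' Counts and percentages of participation, completion and convergence, the
#' histogram of predicted optima, the parent/stranger side split and the
#' distribution of optimum-parent distances and blocks-to-convergence.
#' Percentages are kept at full precision; the print method rounds to two
#' decimals for report output.
#'
#' @param table an outcome table ([run_cohort()] format); required columns:
#'   `completed`, `converged`, `optimum_index`, `optimum_parent_distance`,
#'   `side`, `blocks_presented`.
#' @return an `outcome_summary` list.
#' @export
summarize_outcomes <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  required <- c("completed", "converged", "optimum_index",
                "optimum_parent_distance", "side", "blocks_presented")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("outcome table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_part <- nrow(table)
  n_comp <- sum(table$completed)
  conv <- table[which(table$converged), , drop = FALSE]
  n_conv <- nrow(conv)
  idx <- conv$optimum_index
  hist <- if (n_conv) table(factor(idx, levels = 0:max(11, idx))) else NULL
  max_idx <- if (n_conv) max(11, idx) else 11
  structure(list(
    n_participating = n_part,
    n_completed = n_comp,
    n_converged = n_conv,
    pct_completed = 100 * n_comp / n_part,
    pct_converged = if (n_comp) 100 * n_conv / n_comp else NA_real_,
    optimum_histogram = hist,
    n_parent_side = sum(conv$side == "parent"),
    n_stranger_side = sum(conv$side == "stranger"),
    pct_parent_side = if (n_conv) 100 * sum(conv$side == "parent") / n_conv
                      else NA_real_,
    pct_at_parent_extreme = if (n_conv) 100 * sum(idx == 0) / n_conv
                            else NA_real_,
    pct_at_stranger_extreme = if (n_conv) 100 * sum(idx == max_idx) / n_conv
                              else NA_real_,
    distance_mean = mean(conv$optimum_parent_distance),
    distance_sd = stats::sd(conv$optimum_parent_distance),
    distance_range = if (n_conv) range(conv$optimum_parent_distance)
                     else c(NA_real_, NA_real_),
    blocks_mean = mean(conv$blocks_presented),
    blocks_sd = stats::sd(conv$blocks_presented),
    blocks_range = if (n_conv) range(conv$blocks_presented)
                   else c(NA_real_, NA_real_)
  ), class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("Participating: %d\n", x$n_participating))
  cat(sprintf("Completed: %d (%.2f%%)\n", x$n_completed, x$pct_completed))
  cat(sprintf("Converged: %d (%.2f%% of completers)\n",
              x$n_converged, x$pct_converged))
  if (x$n_converged) {
    cat(sprintf("  at parent extreme: %.2f%%, stranger extreme: %.2f%%\n",
                x$pct_at_parent_extreme, x$pct_at_stranger_extreme))
    cat(sprintf("  parent side: %d (%.2f%%), stranger side: %d\n",
                x$n_parent_side, x$pct_parent_side, x$n_stranger_side))
    cat(sprintf("  optimum-parent distance: mean %.2f (SD %.2f, range %g-%g)\n",
                x$distance_mean, x$distance_sd,
                x$distance_range[1], x$distance_range[2]))
    cat(sprintf("  blocks to convergence: mean %.2f (SD %.2f, range %g-%g)\n",
                x$blocks_mean, x$blocks_sd,
                x$blocks_range[1], x$blocks_range[2]))
  }
  invisible(x)
}

#' Two-sample test for equality of proportions
#'
#' Pooled-proportion chi-square with optional Yates continuity correction
#' (the classic two-proportion test; with `continuity = FALSE` the statistic
#' is exactly the square of the two-proportion z statistic).
#'
#' @param x1,n1 successes and trials in sample 1.
#' @param x2,n2 successes and trials in sample 2.
#' @param continuity apply the Yates correction (default TRUE).
#' @return a `prop_test_result`: list with `statistic` (X^2), `df`, `p`.
#' @examples
#' prop_test_two_sample(24, 44, 20, 44)  # X^2 = 0.409, p = 0.522
#' @export
prop_test_two_sample <- function(x1, n1, x2, n2, continuity = TRUE) {
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2, n1 > 0, n2 > 0)
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    stop("pooled proportion is degenerate (0 or 1); test undefined",
         call. = FALSE)
  }
  ht <- stats::prop.test(c(x1, x2), c(n1, n2), correct = continuity)
  structure(list(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value
  ), class = "prop_test_result")
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat(sprintf("2-sample proportions chi-square: X^2(%d) = %.3f, p = %.3f\n",
              x$df, x$statistic, x$p))
  invisible(x)
}

# ss_scale is the total SS of the data, used to recognise numerically-zero
# effect or residual SS (perfectly constant effects, identical conditions).
anova_effect <- function(ss_effect, df_effect, ss_error, df_error, ss_scale) {
  if (ss_scale <= 0) {  # constant data: no variance to partition
    return(list(F = 0, df = c(df_effect, df_error), p = 1, pes = 0,
                zero_residual = TRUE))
  }
  eps <- 1e-10 * ss_scale
  zero_res <- ss_error <= eps
  if (ss_effect <= eps) {
    f <- 0; p <- 1
  } else if (zero_res) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_effect / df_effect) / (ss_error / df_error)
    p <- stats::pf(f, df_effect, df_error, lower.tail = FALSE)
  }
  list(
    F = f, df = c(df_effect, df_error), p = p,
    pes = if (ss_effect + ss_error > eps) ss_effect / (ss_effect + ss_error)
          else 0,
    zero_residual = zero_res
  )
}

#' Two-by-two mixed repeated-measures ANOVA
#'
#' Within-subject factor condition (parent vs stranger Nc) crossed with a
#' binary between-subject factor (e.g. age group). Fitted as a multivariate
#' linear model with Type-III sums of squares via [car::Anova()] (with a
#' balanced design all SS types coincide). Returns F, degrees of freedom, p
#' and partial eta squared for the between effect, the within (condition)
#' effect and their interaction.
#'
#' @param parent,stranger per-subject condition means (µV), equal length.
#' @param group binary between-subject factor (2 levels, >= 2 subjects each).
#' @return an `anova_result`: list of per-effect lists (`group`, `condition`,
#'   `interaction`), each with `F`, `df`, `p`, `pes`.
#' @export
mixed_anova <- function(parent, stranger, group) {
  stopifnot(length(parent) == length(stranger),
            length(group) == length(parent))
  group <- factor(group)
  if (nlevels(group) != 2L || any(table(group) < 2L)) {
    stop("between factor must have 2 levels with at least 2 subjects each",
         call. = FALSE)
  }
  y <- cbind(parent = parent, stranger = stranger)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::lm(y ~ group)
  idata <- data.frame(condition = factor(c("parent", "stranger")))
  av <- car::Anova(fit, idata = idata, idesign = ~condition, type = "III")
  # sphericity is trivially satisfied with 2 within levels; suppress car's
  # singular-SSP note on degenerate (zero-residual) inputs
  s <- suppressWarnings(summary(av, multivariate = FALSE))$univariate.tests
  ss_scale <- sum((y - mean(y))^2)
  eff <- function(row) {
    anova_effect(s[row, "Sum Sq"], s[row, "num Df"],
                 s[row, "Error SS"], s[row, "den Df"], ss_scale)
  }
  structure(list(
    group = eff("group"),
    condition = eff("condition"),
    interaction = eff("group:condition")
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  for (nm in names(x)) {
    e <- x[[nm]]
    cat(sprintf("%-12s F(%g, %g) = %.3f, p = %.3f, partial eta^2 = %.3f\n",
                nm, e$df[1], e$df[2], e$F, e$p, e$pes))
  }
  invisible(x)
}

#' Paired (one-way repeated-measures) condition test within a subgroup
#'
#' One-way repeated-measures ANOVA of parent-vs-stranger Nc within the
#' subjects who converged on the chosen half of the stimulus space, via
#' `aov` with a subject error stratum. F here is the square of the paired
#' t statistic. A zero residual SS (a perfectly constant condition effect) is
#' flagged rather than reported as an infinite F.
#'
#' @param table outcome table with columns `side`, `nc_parent_mean`,
#'   `nc_stranger_mean`, `converged`.
#' @param side `"parent"` or `"stranger"`: the subgroup to test.
#' @return an `anova_result` with a single `condition` effect.
#' @export
subgroup_condition_test <- function(table, side = c("parent", "stranger")) {
  side <- match.arg(side)
  sub <- table[which(table$converged & table$side == side &
                       is.finite(table$nc_parent_mean) &
                       is.finite(table$nc_stranger_mean)), , drop = FALSE]
  n <- nrow(sub)
  if (n < 2L) stop("subgroup has fewer than 2 usable subjects", call. = FALSE)
  d <- data.frame(
    y = c(sub$nc_parent_mean, sub$nc_stranger_mean),
    condition = factor(rep(c("parent", "stranger"), each = n)),
    subject = factor(rep(seq_len(n), 2))
  )
  fit <- stats::aov(y ~ condition + Error(subject/condition), data = d)
  s <- summary(fit)[["Error: subject:condition"]][[1L]]
  ss_c <- s["condition", "Sum Sq"]
  ss_e <- s["Residuals", "Sum Sq"]
  structure(list(
    condition = anova_effect(ss_c, 1, ss_e, n - 1, sum((d$y - mean(d$y))^2))
  ), class = "anova_result")
}

term_table <- function(coefs, stat_name) {
  data.frame(
    term = rownames(coefs),
    beta = coefs[, 1],
    se = coefs[, 2],
    statistic = coefs[, 3],
    p = coefs[, 4],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Ordinary least-squares regression
#'
#' OLS with intercept; per-term coefficient, SE, t and two-sided p.
#'
#' @param response numeric response vector.
#' @param predictors data.frame of named predictor columns.
#' @return a `regression_result`: list with `family = "linear"`, `terms`
#'   (data.frame: term, beta, se, statistic, p), `fit` (the `lm` object).
#' @export
fit_linear_model <- function(response, predictors) {
  stopifnot(is.numeric(response), is.data.frame(predictors),
            nrow(predictors) == length(response))
  dat <- cbind(data.frame(.y = response), predictors)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design: predictors are collinear", call. = FALSE)
  }
  structure(list(
    family = "linear",
    terms = term_table(summary(fit)$coefficients, "t"),
    fit = fit
  ), class = "regression_result")
}

#' Logistic regression
#'
#' Binomial GLM fitted by iteratively reweighted least squares; per-term
#' coefficient, SE, z and two-sided p. Non-convergence and (quasi-)separation
#' (fitted probabilities numerically 0 or 1) are flagged, not silently
#' accepted.
#'
#' @param outcome binary (0/1 or logical) response; both classes must be
#'   present.
#' @param predictors data.frame of named predictor columns.
#' @return a `regression_result` with `family = "logistic"` and logical flags
#'   `converged` and `separation`.
#' @export
fit_logistic_model <- function(outcome, predictors) {
  outcome <- as.numeric(outcome)
  stopifnot(all(outcome %in% c(0, 1)), is.data.frame(predictors),
            nrow(predictors) == length(outcome))
  if (length(unique(outcome)) < 2L) {
    stop("outcome has a single class; logistic model is degenerate",
         call. = FALSE)
  }
  dat <- cbind(data.frame(.y = outcome), predictors)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  eps <- 1e-8
  if (any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)) {
    separation <- TRUE
  }
  structure(list(
    family = "logistic",
    terms = term_table(summary(fit)$coefficients, "z"),
    converged = fit$converged,
    separation = separation,
    fit = fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s regression:\n", x$family))
  print(x$terms, digits = 4)
  if (identical(x$family, "logistic")) {
    if (!x$converged) cat("  WARNING: IRLS did not converge\n")
    if (x$separation) cat("  WARNING: (quasi-)separation detected\n")
  }
  invisible(x)
}
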