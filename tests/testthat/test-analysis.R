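test_that("outcome summary reproduces the reference participant-flow percentages", {
  tab <- reference_outcome_table()
  s <- summarize_outcomes(tab)
  expect_identical(s$n_participating, 61L)
  expect_identical(s$n_completed, 52L)
  expect_identical(s$n_converged, 44L)
  expect_equal(round(s$pct_completed, 2), 85.25)
  expect_equal(round(s$pct_converged, 2), 84.62)
  expect_equal(round(s$pct_at_parent_extreme, 2), 45.45)
  expect_equal(round(s$pct_at_stranger_extreme, 2), 36.36)
  expect_equal(round(s$pct_parent_side, 2), 54.55)
  expect_identical(s$n_parent_side, 24L)
  expect_identical(s$n_stranger_side, 20L)
  # extreme and intermediate percentages partition the converged group
  pct_intermediate <- 100 * sum(tab$converged &
                                  !tab$optimum_index %in% c(0, 11),
                                na.rm = TRUE) / s$n_converged
  expect_equal(s$pct_at_parent_extreme + s$pct_at_stranger_extreme +
                 pct_intermediate, 100)
  expect_error(summarize_outcomes(tab[, setdiff(names(tab), "optimum_index")]),
               "optimum_index")
})

test_that("single-row summaries behave sensibly", {
  tab <- reference_outcome_table()[1, ]
  s <- summarize_outcomes(tab)
  expect_equal(s$pct_completed, 100)
  expect_equal(s$pct_parent_side, 100)
  expect_equal(s$pct_at_parent_extreme, 100)
})

test_that("the pooled proportions chi-square matches its closed form and z identity", {
  r <- prop_test_two_sample(24, 44, 20, 44)
  expect_equal(round(r$statistic, 3), 0.409)
  expect_identical(r$df, 1)
  expect_equal(round(r$p, 3), 0.522)

  expect_equal(prop_test_two_sample(10, 20, 10, 20)$statistic, 0)

  r2 <- prop_test_two_sample(10, 10, 0, 10, continuity = FALSE)
  expect_equal(r2$statistic, 20, tolerance = 1e-12)

  # without continuity the statistic is the squared two-proportion z
  for (case in list(c(24, 44, 20, 44), c(7, 30, 15, 28), c(3, 10, 8, 12))) {
    x1 <- case[1]; n1 <- case[2]; x2 <- case[3]; n2 <- case[4]
    pb <- (x1 + x2) / (n1 + n2)
    z <- (x1 / n1 - x2 / n2) / sqrt(pb * (1 - pb) * (1 / n1 + 1 / n2))
    expect_equal(prop_test_two_sample(x1, n1, x2, n2, FALSE)$statistic, z^2,
                 tolerance = 1e-12)
  }
  expect_error(prop_test_two_sample(0, 10, 0, 12), "degenerate")
})

test_that("mixed ANOVA agrees with the first-principles SS oracle", {
  # balanced toy with integer values
  parent <- c(10, 12, 14, 9, 11, 13)
  stranger <- c(11, 15, 12, 10, 14, 12)
  group <- rep(c("young", "old"), each = 3)
  r <- mixed_anova(parent, stranger, group)
  o <- mixed_anova_oracle(parent, stranger, group)
  for (e in c("group", "condition", "interaction")) {
    expect_equal(r[[e]]$F, unname(o[[e]]["F"]), tolerance = 1e-10)
    expect_equal(r[[e]]$df[2], unname(o[[e]]["df2"]))
    expect_equal(r[[e]]$pes,
                 unname(o[[e]]["ss"] / (o[[e]]["ss"] + o[[e]]["ss_err"])),
                 tolerance = 1e-10)
  }

  # unbalanced groups are accepted and produce well-formed results
  parent2 <- c(parent, 8, 15)
  stranger2 <- c(stranger, 12, 13)
  group2 <- c(group, "old", "old")
  r2 <- mixed_anova(parent2, stranger2, group2)
  for (e in c("group", "condition", "interaction")) {
    expect_true(is.finite(r2[[e]]$F) && r2[[e]]$F >= 0)
    expect_true(r2[[e]]$p >= 0 && r2[[e]]$p <= 1)
    expect_identical(r2[[e]]$df[2], length(parent2) - 2)
  }

  # all-equal data: no effects anywhere
  r0 <- mixed_anova(rep(5, 6), rep(5, 6), group)
  for (e in c("group", "condition", "interaction")) {
    expect_true(r0[[e]]$F == 0 || r0[[e]]$zero_residual)
  }
})

test_that("a pure constant condition shift gives zero interaction and its exact SS", {
  set.seed(31)
  parent <- stats::rnorm(8, 12, 3)
  delta <- 5
  stranger <- parent + delta
  group <- rep(c("a", "b"), each = 4)
  r <- mixed_anova(parent, stranger, group)
  o <- mixed_anova_oracle(parent, stranger, group)
  expect_equal(unname(o$interaction["ss"]), 0, tolerance = 1e-9)
  expect_equal(unname(o$condition["ss"]), length(parent) * delta^2 / 2,
               tolerance = 1e-9)
  # zero within-subject residual: flagged, partial eta^2 -> 1
  expect_true(r$condition$zero_residual)
  expect_equal(r$condition$pes, 1, tolerance = 1e-9)
  expect_equal(r$interaction$F, 0, tolerance = 1e-9)
})

test_that("subgroup paired ANOVA equals the squared paired t statistic", {
  set.seed(32)
  n <- 10
  tab <- data.frame(
    converged = TRUE, side = "parent",
    nc_parent_mean = stats::rnorm(n, 14, 4),
    nc_stranger_mean = stats::rnorm(n, 12, 4)
  )
  r <- subgroup_condition_test(tab, "parent")
  tt <- stats::t.test(tab$nc_parent_mean, tab$nc_stranger_mean, paired = TRUE)
  expect_equal(r$condition$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(r$condition$df, c(1, n - 1))
  expect_equal(r$condition$p, tt$p.value, tolerance = 1e-9)

  # identical condition values: F = 0
  tab0 <- data.frame(converged = TRUE, side = "stranger",
                     nc_parent_mean = 1:5, nc_stranger_mean = 1:5)
  expect_equal(subgroup_condition_test(tab0, "stranger")$condition$F, 0)
  expect_error(subgroup_condition_test(tab0[1, ], "stranger"), "fewer than 2")
})

test_that("a planted parent-side preference is detected in most replicates", {
  set.seed(33)
  hits <- replicate(60, {
    n <- 24
    parent <- stats::rnorm(n, 15, 4)
    tab <- data.frame(
      converged = TRUE, side = "parent",
      nc_parent_mean = parent,
      nc_stranger_mean = parent - 5 + stats::rnorm(n, 0, 4)
    )
    subgroup_condition_test(tab, "parent")$condition$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("linear models recover exact and planted coefficients", {
  x <- 1:10
  r <- suppressWarnings(fit_linear_model(2 * x, data.frame(x = x)))
  expect_equal(r$terms$beta[r$terms$term == "x"], 2, tolerance = 1e-12)
  expect_lt(sum(stats::residuals(r$fit)^2), 1e-20)

  r0 <- fit_linear_model(c(4, 6, 8), data.frame(z = c(0, 0, 0))[0])
  expect_equal(r0$terms$beta[1], 6)

  expect_error(fit_linear_model(rnorm(5), data.frame(a = 1:5, b = 2 * (1:5))),
               "singular")
})

test_that("logistic models flag separation and recover generative coefficients", {
  # perfectly separable toy
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  r <- fit_logistic_model(y, data.frame(x = x))
  expect_true(r$separation)

  expect_error(fit_logistic_model(rep(1, 10), data.frame(x = rnorm(10))),
               "single class")

  set.seed(34)
  x2 <- stats::rnorm(2000)
  p <- stats::plogis(-1 + 0.8 * x2)
  y2 <- stats::rbinom(2000, 1, p)
  r2 <- fit_logistic_model(y2, data.frame(x = x2))
  b <- r2$terms
  expect_lt(abs(b$beta[b$term == "(Intercept)"] + 1),
            3 * b$se[b$term == "(Intercept)"])
  expect_lt(abs(b$beta[b$term == "x"] - 0.8), 3 * b$se[b$term == "x"])
  expect_false(r2$separation)

  # null predictor: slope within 3 SE of zero
  y3 <- stats::rbinom(1000, 1, 0.4)
  r3 <- fit_logistic_model(y3, data.frame(x = stats::rnorm(1000)))
  b3 <- r3$terms
  expect_lt(abs(b3$beta[b3$term == "x"]), 3 * b3$se[b3$term == "x"])
})
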