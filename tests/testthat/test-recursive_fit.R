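test_that("logit fit on a 2x2 table equals the closed-form log odds ratio", {
  d <- tiny_logit_diagram()
  dat <- tiny_2x2_data(30, 10, 20, 40)
  fit <- fit_equation(dat, d, "y")
  # oracle: slope = ln(ad/bc), intercept = ln(c/d)
  expect_equal(unname(fit$coefficients["y|x|yes"]),
               log(30 * 40 / (10 * 20)), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["y|(Intercept)|"]), log(20 / 40),
               tolerance = 1e-8)
  expect_identical(fit$n_used, 100L)
  expect_true(fit$converged)

  # invariance to row order
  perm <- dat[sample.int(nrow(dat)), ]
  fit2 <- fit_equation(perm, d, "y")
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-10)
})

test_that("the gaussian equation interpolates noise-free linear data exactly", {
  d <- path_diagram(
    list(variable_spec("x", "exogenous", NULL, "binary", c("no", "yes")),
         variable_spec("k", "endogenous", "gaussian", "continuous")),
    data.frame(parent = "x", child = "k"), outcome = "k")
  dat <- data.frame(x = factor(rep(c("no", "yes"), 25),
                               levels = c("no", "yes")))
  dat$k <- 1 + 2 * (dat$x == "yes")
  fit <- fit_equation(dat, d, "k")
  expect_equal(unname(fit$coefficients["k|x|yes"]), 2, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["k|(Intercept)|"]), 1,
               tolerance = 1e-12)
})

test_that("degenerate inputs raise named errors", {
  d <- tiny_logit_diagram()
  # perfect separation: x = yes always seeks, x = no never does
  sep <- tiny_2x2_data(40, 0, 0, 40)
  expect_error(suppressWarnings(fit_equation(sep, d, "y")), "separation")
  # empty factor level
  onelevel <- tiny_2x2_data(30, 10, 0, 0)
  expect_error(fit_equation(onelevel, d, "y"), "no observations at level")
})

test_that("sandwich covariance equals the brute-force score oracle", {
  set.seed(42)
  d <- tiny_logit_diagram()
  dat <- tiny_2x2_data(35, 22, 18, 40)
  fit <- fit_equation(dat, d, "y")
  g <- fit$glm
  # brute force: explicit per-observation score loop
  X <- model.matrix(g)
  n <- nrow(X); k <- ncol(X)
  B <- matrix(0, k, k)
  for (i in seq_len(n)) {
    s_i <- (g$y[i] - g$fitted.values[i]) * X[i, ]
    B <- B + s_i %o% s_i
  }
  Ainv <- summary(g)$cov.unscaled
  V_oracle <- Ainv %*% B %*% Ainv * n / (n - k)
  expect_equal(unname(fit$vcov), unname(V_oracle), tolerance = 1e-10)
  # the established implementation agrees up to IRLS bookkeeping (its
  # estfun is evaluated at the last stored working weights, ours at the
  # final coefficients)
  expect_equal(unname(fit$vcov),
               unname(sandwich::vcovHC(g, type = "HC1")),
               tolerance = 1e-4)
})

test_that("cluster-robust covariance degrades to HC with one unit per cluster", {
  d <- tiny_logit_diagram()
  dat <- tiny_2x2_data(35, 22, 18, 40)
  fit <- fit_equation(dat, d, "y")
  g <- fit$glm
  n <- 115; k <- 2
  V_cl <- sandwich_covariance(g, cluster = seq_len(n))
  V_hc <- sandwich_covariance(g)
  ratio <- (n / (n - 1) * (n - 1) / (n - k)) / (n / (n - k))
  expect_equal(unname(V_cl), unname(V_hc) * ratio, tolerance = 1e-12)
})

test_that("robust and classical SEs agree on homoskedastic gaussian data", {
  set.seed(7)
  n <- 10000
  d <- path_diagram(
    list(variable_spec("x", "exogenous", NULL, "binary", c("no", "yes")),
         variable_spec("k", "endogenous", "gaussian", "continuous")),
    data.frame(parent = "x", child = "k"), outcome = "k")
  dat <- data.frame(x = factor(sample(c("no", "yes"), n, TRUE),
                               levels = c("no", "yes")))
  dat$k <- 0.5 + 1.5 * (dat$x == "yes") + rnorm(n)
  fit <- fit_equation(dat, d, "k")
  se_rob <- sqrt(diag(fit$vcov))
  se_cls <- sqrt(diag(vcov(fit$glm)))
  expect_true(all(abs(se_rob / se_cls - 1) < 0.10))
})

test_that("the system fit restricts each equation to its subpopulation", {
  fit <- tt_fit()
  n_sick <- sum(tt_pop()$sick_neonate)
  n_comp <- sum(tt_pop()$sick_neonate & tt_pop()$had_complication)
  for (eq in c("anc4", "facility_delivery", "pnc", "knowledge",
               "neo_careseek")) {
    expect_identical(fit$fits[[eq]]$n_used, n_sick)
  }
  expect_identical(fit$fits$mat_careseek$n_used, n_comp)
  # outcome equation keeps its full subpopulation despite the structurally
  # missing complication predictor (reference-level recoding)
  expect_gt(fit$fits$neo_careseek$n_used, 8000L)
})

test_that("joint covariance modes behave as declared", {
  fit <- tt_fit()
  terms_of <- function(eq) names(fit$fits[[eq]]$coefficients)
  # block-diagonal: all cross-equation entries exactly zero
  cross <- fit$vcov[terms_of("anc4"), terms_of("neo_careseek")]
  expect_true(all(cross == 0))
  expect_identical(fit$vcov, t(fit$vcov))

  # stacked mode on two equations over disjoint subpopulations: zero block
  d <- path_diagram(
    list(variable_spec("x", "exogenous", NULL, "binary", c("no", "yes")),
         variable_spec("y1", "endogenous", "binomial", "binary",
                       c("no", "yes")),
         variable_spec("y2", "endogenous", "binomial", "binary",
                       c("no", "yes"))),
    data.frame(parent = c("x", "x"), child = c("y1", "y2")),
    outcome = "y2",
    subpopulations = list(y1 = "gA", y2 = "gB"))
  set.seed(11)
  n <- 600
  dat <- data.frame(
    x = factor(sample(c("no", "yes"), n, TRUE), levels = c("no", "yes")),
    gA = rep(c(TRUE, FALSE), each = n / 2),
    cluster = "c1")
  dat$gB <- !dat$gA
  dat$y1 <- factor(ifelse(dat$gA, sample(c("no", "yes"), n, TRUE), NA),
                   levels = c("no", "yes"))
  dat$y2 <- factor(ifelse(dat$gB, sample(c("no", "yes"), n, TRUE), NA),
                   levels = c("no", "yes"))
  sf <- fit_system(dat, d, joint = "stacked_sandwich")
  blk <- sf$vcov[names(sf$fits$y1$coefficients),
                 names(sf$fits$y2$coefficients)]
  expect_true(all(blk == 0))
})

test_that("fitted synthetic coefficients are presented like the source table", {
  fit <- tt_fit()
  ct <- coef_terms(fit, "facility_delivery", "anc4")
  # truth within the fit's own Wald interval
  expect_lt(abs(ct$estimate - log(2.53)), 1.959964 * ct$se * 1.5)
  tab <- system_table(fit)
  row <- tab[tab$equation == "facility_delivery" & tab$predictor == "anc4", ]
  expect_equal(row$estimate, exp(ct$estimate))
  expect_equal(row$ci_low, exp(ct$estimate - 1.959964 * ct$se))
  expect_equal(row$ci_high, exp(ct$estimate + 1.959964 * ct$se))
  f <- tempfile(fileext = ".json")
  system_to_json(fit, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "")))
  unlink(f)
})

test_that("significance stars follow the two-sided Wald thresholds", {
  expect_identical(significance_label(1, 1), "")
  expect_identical(significance_label(2, 1), "*")
  expect_identical(significance_label(3, 1), "**")
  expect_identical(significance_label(c(-3, 0.5), c(1, 1)), c("**", ""))
  expect_error(significance_label(1, 0), "positive")
})
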