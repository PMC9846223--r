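test_that("path enumeration matches an exhaustive igraph oracle on random DAGs", {
  for (seed in 1:20) {
    d <- random_dag(n_nodes = sample(4:8, 1, FALSE), seed = seed)
    g <- igraph::graph_from_data_frame(d$edges, directed = TRUE,
                                       vertices = names(d$variables))
    oracle <- igraph::all_simple_paths(g, from = "v1", to = d$outcome,
                                       mode = "out")
    oracle <- Filter(function(p) length(p) >= 3, oracle)
    oracle_keys <- sort(vapply(oracle, function(p)
      paste(names(p), collapse = ">"), ""))
    got <- enumerate_paths(d, "v1", max_mediators = length(d$variables))
    got_keys <- sort(vapply(got, function(p)
      paste(c(p$exposure, p$mediators, p$outcome), collapse = ">"), ""))
    expect_identical(got_keys, oracle_keys)
  }
})

test_that("the care-seeking diagram yields the published mediator sets", {
  d <- tt_diagram()
  anc <- enumerate_paths(d, "anc4")
  expect_length(anc, 3)
  expect_setequal(vapply(anc, function(p) p$mediators, ""),
                  c("facility_delivery", "pnc", "knowledge"))
  # the complication-care-seeking mediator is defined on a strictly
  # narrower subpopulation and excluded by default, not by the DAG
  anc_all <- enumerate_paths(d, "anc4", exclude_restricted = FALSE)
  expect_length(anc_all, 4)
  expect_length(enumerate_paths(d, "facility_delivery"), 2)
  expect_length(enumerate_paths(d, "knowledge"), 0)
  expect_error(enumerate_paths(d, "nonesuch"), "unknown exposure")
  # longer chains appear once max_mediators is raised
  anc3 <- enumerate_paths(d, "anc4", max_mediators = 3)
  keys <- vapply(anc3, format, "")
  expect_true("anc4 -> facility_delivery -> pnc -> neo_careseek" %in% keys)
  expect_true(all(vapply(anc, format, "") %in% keys))
})

test_that("average relative effects follow the significance rules", {
  src <- reference_coefficients()
  # binary passthrough
  e <- exposure_effect(src, "neo_careseek", "facility_delivery")
  expect_equal(e$value, log(1.30))
  # mean of the two starred gaussian age terms
  e <- exposure_effect(src, "knowledge", "mother_age")
  expect_equal(e$value, mean(c(0.21, 0.22)))
  expect_setequal(e$levels, c("20-34", "35-49"))
  # mean of the logs of the starred education odds ratios
  e <- exposure_effect(src, "anc4", "education")
  expect_equal(e$value, mean(log(c(1.36, 1.73, 2.62))), tolerance = 1e-12)
  # all-levels mode includes the unstarred level
  e_all <- exposure_effect(src, "anc4", "education", mode = "all_levels")
  expect_equal(e_all$value, mean(log(c(1.18, 1.36, 1.73, 2.62))),
               tolerance = 1e-12)
  # no significant level: undefined, rendered as a dash
  e <- exposure_effect(src, "neo_careseek", "education")
  expect_false(e$defined)
  expect_match(format(e), "-$")
})

test_that("indirect effects multiply link-scale coefficients along the path", {
  src <- reference_coefficients()
  via_fd <- indirect_effect(
    mediated_path("anc4", "facility_delivery", "neo_careseek"), src)
  expect_equal(via_fd$value, log(2.53) * log(1.30), tolerance = 1e-12)
  expect_equal(round_half_away(via_fd$value), 0.24)
  via_pnc <- indirect_effect(mediated_path("anc4", "pnc", "neo_careseek"),
                             src)
  expect_equal(round_half_away(via_pnc$value), 0.06)
  # a zero leg annihilates the product exactly
  zsrc <- tiny_coef_source(data.frame(
    equation = c("m", "y"), predictor = c("x", "m"),
    level = c("yes", "yes"), est_link = c(0, 0.7), se = c(0.1, 0.1),
    significant = TRUE, stringsAsFactors = FALSE))
  z <- indirect_effect(mediated_path("x", "m", "y"), zsrc)
  expect_identical(z$value, 0)
  # sign propagation over every published-diagram path
  d <- tt_diagram()
  for (expo in c("anc4", "education", "living_children", "distance")) {
    for (p in enumerate_paths(d, expo)) {
      eff <- indirect_effect(p, src)
      if (!eff$defined) next
      leg1 <- exposure_effect(src, p$mediators[1], expo, kind = "leg")
      leg2 <- coef_terms(src, "neo_careseek", p$mediators[1])
      leg2 <- if (nrow(leg2) > 1) leg2$estimate[leg2$level == "5+"]
              else leg2$estimate
      expect_identical(sign(eff$value), sign(leg1$value) * sign(leg2))
    }
  }
})

test_that("delta-method SEs have the two-coefficient closed form", {
  sig <- diag(c(0.2, 0.3)^2)
  dimnames(sig) <- list(c("a", "b"), c("a", "b"))
  b1 <- 1.4; b2 <- -0.6
  g <- c(a = b2, b = b1)  # gradient of b1*b2
  expect_equal(delta_method_se(g, sig),
               sqrt(b2^2 * 0.2^2 + b1^2 * 0.3^2), tolerance = 1e-12)
  # algebraic limit at b1 = 0: SE = |b2| * sigma1
  g0 <- c(a = b2, b = 0)
  expect_equal(delta_method_se(g0, sig), abs(b2) * 0.2, tolerance = 1e-12)
  expect_error(delta_method_se(c(zz = 1), sig), "missing")
})

test_that("delta-method intervals match the published path and a simulation oracle", {
  src <- reference_coefficients()
  eff <- indirect_effect(
    mediated_path("anc4", "facility_delivery", "neo_careseek"), src)
  # printed interval is (0.12, 0.39); independent-normal recomputation
  # lands within 0.02 of it at the printed precision
  expect_lte(abs(round_half_away(eff$ci[1]) - 0.12), 0.02 + 1e-12)
  expect_lte(abs(round_half_away(eff$ci[2]) - 0.39), 0.02 + 1e-12)
  # oracle: 10,000-draw parametric simulation of the product
  set.seed(88)
  b1 <- rnorm(10000, log(2.53), ci_se <- (log(2.83) - log(2.27)) / 3.919928)
  b2 <- rnorm(10000, log(1.30), (log(1.48) - log(1.14)) / 3.919928)
  expect_equal(eff$se, sd(b1 * b2), tolerance = 0.05)
})

test_that("decomposition identities hold exactly for any coefficient source", {
  d <- tt_diagram()
  for (src in list(reference_coefficients(), tt_fit())) {
    for (expo in c("anc4", "facility_delivery", "pnc", "education",
                   "wealth", "distance", "living_children", "sex")) {
      row <- decompose(expo, src, d)
      ti <- if (is.null(row$total_indirect)) 0 else row$total_indirect$value
      dir <- if (is.null(row$direct)) 0 else row$direct$value
      expect_identical(row$total$value, dir + ti)
      if (!is.null(row$total_indirect)) {
        expect_identical(row$total_indirect$value,
                         sum(vapply(row$paths, `[[`, 0, "value")))
      }
      if (!is.na(row$mediation_proportion)) {
        expect_equal(row$mediation_proportion,
                     100 * ti / row$total$value, tolerance = 1e-12)
      }
    }
  }
})

test_that("decomposition rows reproduce the published special cases", {
  src <- reference_coefficients()
  d <- tt_diagram()
  # no mediated paths: total = direct = ln 1.20
  sex <- decompose("sex", src, d)
  expect_length(sex$paths, 0)
  expect_equal(sex$total$value, log(1.20))
  expect_equal(sex$direct$value, log(1.20))
  # no significant direct term: direct absent, total = total indirect
  edu <- decompose("education", src, d)
  expect_null(edu$direct)
  expect_identical(edu$total$value, edu$total_indirect$value)
  expect_true(is.na(edu$mediation_proportion))
  expect_error(decompose("neo_careseek", src, d), "outcome")
})

test_that("decomposition tables render, round and round-trip", {
  src <- reference_coefficients()
  d <- tt_diagram()
  empty <- decomposition_table(character(0), src, d)
  expect_null(as.data.frame(empty))
  tab <- decomposition_table(c("distance", "sex"), src, d)
  df <- as.data.frame(tab)
  expect_true(all(c("path_indirect", "total_indirect", "direct", "total",
                    "mediation_proportion") %in%
                    df$quantity[df$exposure == "distance"]))
  f <- tempfile(fileext = ".csv")
  write_decomposition(tab, f)
  back <- utils::read.csv(f)
  expect_equal(back$value[back$exposure == "distance" &
                            back$quantity == "total"], 0.20)
  expect_equal(back$value[back$exposure == "distance" &
                            back$quantity == "mediation_proportion"], 40.0,
               tolerance = 0.11)
  unlink(f)
  # a failing exposure is flagged, not fatal
  tab2 <- decomposition_table(c("neo_careseek", "sex"), src, d)
  expect_s3_class(tab2$rows$neo_careseek, "gsem_decomp_error")
  expect_s3_class(tab2$rows$sex, "gsem_decomp_row")
})
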