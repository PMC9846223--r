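#' Describe the two-stage cluster-survey design to emulate
#'
#' Nested district/cluster labels with roughly equal cluster takes, an
#' illness indicator defining the sick-neonate subpopulation, and a
#' maternal-complication indicator whose prevalence differs between mothers
#' of sick and healthy neonates (the published subpopulation counts imply
#' the association: 2993/8765 among sick vs 1720/8486 among healthy,
#' totalling the published 4713 complications).
#'
#' @param n_districts Number of districts (default 14).
#' @param clusters_per_district Clusters per district (default 120).
#' @param records_per_cluster Records per cluster (default 10, the design
#'   take of the emulated survey).
#' @param n_total Optional total record count; when given it overrides
#'   `records_per_cluster` and is spread as evenly as possible over the
#'   clusters (the survey's realized sample, 17,251, is not a multiple of
#'   the cluster count).
#' @param illness_prevalence P(sick neonate).
#' @param complication_prev_sick,complication_prev_healthy P(maternal
#'   complication) given a sick / healthy neonate.
#' @param cluster_effect_sd Optional SD of a link-scale cluster-level
#'   intercept perturbation (0 = none; the reference analysis models no
#'   cluster effect).
#' @param seed Integer seed; the generator is a pure function of
#'   (diagram, params, design).
#' @return An object of class `gsem_design`.
#' @export
population_design <- function(n_districts = 14, clusters_per_district = 120,
                              records_per_cluster = 10, n_total = NULL,
                              illness_prevalence = 8765 / 17251,
                              complication_prev_sick = 2993 / 8765,
                              complication_prev_healthy = 1720 / 8486,
                              cluster_effect_sd = 0, seed = 1) {
  stopifnot(n_districts >= 1, clusters_per_district >= 1,
            records_per_cluster >= 1,
            illness_prevalence >= 0, illness_prevalence <= 1,
            complication_prev_sick >= 0, complication_prev_sick <= 1,
            complication_prev_healthy >= 0, complication_prev_healthy <= 1,
            cluster_effect_sd >= 0)
  structure(
    list(n_districts = n_districts,
         clusters_per_district = clusters_per_district,
         records_per_cluster = records_per_cluster, n_total = n_total,
         illness_prevalence = illness_prevalence,
         complication_prev_sick = complication_prev_sick,
         complication_prev_healthy = complication_prev_healthy,
         cluster_effect_sd = cluster_effect_sd, seed = as.integer(seed)),
    class = "gsem_design"
  )
}

# Exogenous category probabilities, defaulting to the published overall
# counts (recomputed from the printed n's, not the rounded percentages).
exogenous_marginals_default <- function(diagram) {
  marg <- reference_marginals()
  exo <- names(Filter(function(v) v$role == "exogenous", diagram$variables))
  out <- list()
  for (v in exo) {
    rows <- marg[marg$variable == v, , drop = FALSE]
    if (nrow(rows) == 0) {
      stop_gsem("no default marginal for exogenous variable '", v, "'")
    }
    lev <- diagram$variables[[v]]$levels
    p <- rows$overall_n[match(lev, rows$level)]
    out[[v]] <- stats::setNames(p / sum(p), lev)
  }
  out
}

# Cluster frame of the design: district/cluster labels, one row per record.
design_frame <- function(design) {
  ncl <- design$n_districts * design$clusters_per_district
  take <- if (is.null(design$n_total)) {
    rep(design$records_per_cluster, ncl)
  } else {
    base <- design$n_total %/% ncl
    rem <- design$n_total %% ncl
    rep(base, ncl) + c(rep(1L, rem), rep(0L, ncl - rem))
  }
  district <- rep(rep(seq_len(design$n_districts),
                      each = design$clusters_per_district), times = take)
  cluster_in_d <- rep(rep(seq_len(design$clusters_per_district),
                          times = design$n_districts), times = take)
  data.frame(
    district = sprintf("d%02d", district),
    cluster = sprintf("d%02d_c%03d", district, cluster_in_d),
    stringsAsFactors = FALSE
  )
}

draw_exogenous <- function(n, marginals, diagram) {
  out <- list()
  for (v in names(marginals)) {
    p <- marginals[[v]]
    out[[v]] <- factor(sample(names(p), n, replace = TRUE, prob = p),
                       levels = diagram$variables[[v]]$levels)
  }
  out
}

# Linear predictor of one equation minus its intercept. NA parent cells
# contribute nothing, i.e. they are read as the reference level; for
# structurally missing parents (narrower subpopulation) this is the
# "no event" coding the reference analysis must have used to reach its
# printed equation sample sizes.
linear_predictor <- function(df, diagram, params, equation) {
  eta <- numeric(nrow(df))
  coefs <- params_for(params, equation)
  for (i in seq_len(nrow(coefs))) {
    col <- predictor_column(diagram, coefs$predictor[i])
    x <- df[[col]]
    ind <- !is.na(x) & x == coefs$level[i]
    eta <- eta + coefs$value[i] * ind
  }
  eta
}

# Rows on which a variable is defined in the generated data: the outcome
# needs its subpopulation (care-seeking presupposes an illness); any other
# restricted equation is defined on its own filters net of the global
# analysis restriction.
generation_support <- function(df, diagram, variable) {
  own <- subpopulation_of(diagram, variable)
  flags <- if (variable == diagram$outcome) {
    own
  } else {
    setdiff(own, subpopulation_of(diagram, diagram$outcome))
  }
  sup <- rep(TRUE, nrow(df))
  for (f in flags) sup <- sup & df[[f]]
  sup
}

band_knowledge <- function(k, levels = c("0", "1-4", "5+")) {
  factor(ifelse(is.na(k), NA,
                ifelse(k == 0, levels[1],
                       ifelse(k <= 4, levels[2], levels[3]))),
         levels = levels)
}

draw_endogenous <- function(df, diagram, params, equation, design,
                            cluster_shift = NULL) {
  v <- diagram$variables[[equation]]
  eta <- params$intercepts[[equation]] +
    linear_predictor(df, diagram, params, equation)
  if (!is.null(cluster_shift)) {
    eta <- eta + cluster_shift[df$cluster]
  }
  sup <- generation_support(df, diagram, equation)
  n <- nrow(df)
  if (v$family == "binomial") {
    y <- rep(NA_character_, n)
    draw <- stats::rbinom(n, 1, stats::plogis(eta))
    y[sup] <- v$levels[draw[sup] + 1L]
    factor(y, levels = v$levels)
  } else {
    y <- rep(NA_real_, n)
    draw <- round(stats::rnorm(n, eta, params$sigma))
    y[sup] <- pmin(pmax(draw[sup], 0), 22)
  }
}

#' Generate a synthetic survey population
#'
#' Draws exogenous covariates independently from their configured category
#' marginals (defaults: the published overall distribution), then the
#' endogenous variables in topological order through the diagram --
#' binomial variables as Bernoulli(inverse-logit(linear predictor)), the
#' knowledge score as a rounded gaussian clipped to 0-22 (with its banded
#' companion column `knowledge_cat`). Records carry district/cluster labels
#' and the `sick_neonate` / `had_complication` flags; maternal-complication
#' care-seeking is only defined where a complication occurred and the
#' outcome only for sick neonates. Identical inputs give identical output;
#' the caller's RNG state is left untouched.
#'
#' @param diagram A [path_diagram()].
#' @param params A `gsem_params` truth, e.g. [reference_params()] after
#'   [calibrate_intercepts()].
#' @param design A [population_design()].
#' @param marginals Optional named list of exogenous category probability
#'   vectors.
#' @return A data frame with one row per mother-newborn record.
#' @export
generate_population <- function(diagram, params, design,
                                marginals = NULL) {
  stopifnot(inherits(diagram, "gsem_diagram"),
            inherits(params, "gsem_params"),
            inherits(design, "gsem_design"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed)

  if (is.null(marginals)) marginals <- exogenous_marginals_default(diagram)
  df <- design_frame(design)
  n <- nrow(df)
  df <- cbind(df, draw_exogenous(n, marginals, diagram))
  df$sick_neonate <- stats::runif(n) < design$illness_prevalence
  p_comp <- ifelse(df$sick_neonate, design$complication_prev_sick,
                   design$complication_prev_healthy)
  df$had_complication <- stats::runif(n) < p_comp

  order <- topological_order(diagram)
  for (eq in order) {
    shift <- NULL
    if (design$cluster_effect_sd > 0) {
      cl <- unique(df$cluster)
      shift <- stats::setNames(
        stats::rnorm(length(cl), 0, design$cluster_effect_sd), cl)
    }
    df[[eq]] <- draw_endogenous(df, diagram, params, eq, design, shift)
    v <- diagram$variables[[eq]]
    if (v$measurement == "count" && v$predictor_encoding == "as_levels") {
      df[[paste0(eq, "_cat")]] <- band_knowledge(df[[eq]], v$levels)
    }
  }
  df
}

#' Calibrate equation intercepts to target marginals
#'
#' Walks the endogenous variables in topological order over one large
#' simulated population: for each binomial equation the intercept is found
#' by monotone root-finding so that the simulated marginal (on the
#' equation's defined subpopulation) hits the target prevalence; the
#' gaussian intercept has the closed form target mean minus the mean linear
#' predictor. After each equation is calibrated the variable is drawn so
#' downstream equations see calibrated parents. Deterministic given the
#' design seed.
#'
#' @param params A `gsem_params` with placeholder intercepts.
#' @param targets Named targets (probability for binomial equations, mean
#'   for the gaussian one); default [reference_targets()].
#' @param design A [population_design()]; only its probability fields and
#'   seed are used.
#' @param n_sim Size of the calibration population (default 200,000).
#' @param tol Acceptable |simulated marginal - target| (default 0.005).
#' @param marginals Optional exogenous marginals, as in
#'   [generate_population()].
#' @param diagram A [path_diagram()].
#' @return `params` with calibrated intercepts.
#' @export
calibrate_intercepts <- function(params, targets = reference_targets(),
                                 design = population_design(),
                                 diagram = careseeking_diagram(),
                                 n_sim = 200000, tol = 0.005,
                                 marginals = NULL) {
  binom_eqs <- names(Filter(
    function(v) v$role == "endogenous" && v$family == "binomial",
    diagram$variables))
  bad <- binom_eqs[!(targets[binom_eqs] > 0 & targets[binom_eqs] < 1)]
  if (length(bad) > 0) {
    stop_gsem("binomial targets must lie in (0,1): ",
              paste(bad, collapse = ", "))
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed)

  if (is.null(marginals)) marginals <- exogenous_marginals_default(diagram)
  df <- data.frame(district = "d01", cluster = "d01_c001",
                   stringsAsFactors = FALSE)[rep(1, n_sim), , drop = FALSE]
  rownames(df) <- NULL
  df <- cbind(df, draw_exogenous(n_sim, marginals, diagram))
  df$sick_neonate <- stats::runif(n_sim) < design$illness_prevalence
  p_comp <- ifelse(df$sick_neonate, design$complication_prev_sick,
                   design$complication_prev_healthy)
  df$had_complication <- stats::runif(n_sim) < p_comp

  for (eq in topological_order(diagram)) {
    target <- targets[[eq]]
    if (is.null(target) || is.na(target)) {
      stop_gsem("no calibration target for equation '", eq, "'")
    }
    eta <- linear_predictor(df, diagram, params, eq)
    sup <- generation_support(df, diagram, eq)
    v <- diagram$variables[[eq]]
    if (v$family == "gaussian") {
      params$intercepts[[eq]] <- target - mean(eta[sup])
    } else {
      f <- function(c0) mean(stats::plogis(c0 + eta[sup])) - target
      root <- stats::uniroot(f, c(-25, 25), tol = 1e-10)
      params$intercepts[[eq]] <- root$root
      achieved <- target + f(root$root)
      if (abs(achieved - target) > tol) {
        stop_gsem("calibration of '", eq, "' did not converge: achieved ",
                  signif(achieved, 4), " for target ", signif(target, 4))
      }
    }
    df[[eq]] <- draw_endogenous(df, diagram, params, eq, design)
    if (v$measurement == "count" && v$predictor_encoding == "as_levels") {
      df[[paste0(eq, "_cat")]] <- band_knowledge(df[[eq]], v$levels)
    }
  }
  params
}
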