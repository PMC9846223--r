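# Packaged transcriptions of the reference study's published tables, and the
# coefficient-source interface the mediation calculus works against.
#
# A "coefficient source" is anything that can answer two questions:
#   coef_terms(source, equation, predictor) -> one row per non-reference
#     level: link-scale estimate, SE, significance flag, term id
#   coef_sigma(source, term_ids) -> joint covariance over those terms
# Both the published coefficient table (SEs backed out of the printed CIs,
# cross-covariances zero) and a fitted system (full robust covariance)
# implement it.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "gsempath")
  if (!nzchar(p)) stop_gsem("packaged fixture '", file, "' not found")
  p
}

read_fixture <- function(file, required) {
  df <- utils::read.csv(fixture_path(file), stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_gsem("fixture '", file, "' is corrupted: missing column(s) ",
              paste(missing, collapse = ", "))
  }
  df
}

term_id <- function(equation, predictor, level) {
  paste(equation, predictor, level, sep = "|")
}

#' Published adjusted coefficients of the six-equation system
#'
#' The transcribed adjusted odds ratios (binomial equations) and adjusted
#' linear-regression coefficients (knowledge equation) of the reference
#' study, one row per non-reference level, with their printed 95% CIs and
#' significance stars. Link-scale values (`est_link`: log odds or raw beta)
#' and standard errors backed out of the CI width are added on load.
#'
#' @return A data frame of class `gsem_coef_table`.
#' @export
reference_coefficients <- function() {
  df <- read_fixture("reference_coefficients.csv",
                     c("equation", "predictor", "level", "scale",
                       "estimate", "ci_low", "ci_high", "stars"))
  if (!is.numeric(df$estimate) || anyNA(df$estimate)) {
    stop_gsem("fixture 'reference_coefficients.csv' is corrupted: ",
              "non-numeric estimates")
  }
  df$stars[is.na(df$stars)] <- ""
  df$est_link <- df$estimate
  df$est_link[df$scale == "or"] <- log(df$estimate[df$scale == "or"])
  df$se <- ci_to_se(df$ci_low, df$ci_high, df$scale)
  df$significant <- df$stars != ""
  df$term <- term_id(df$equation, df$predictor, df$level)
  class(df) <- c("gsem_coef_table", "data.frame")
  df
}

#' Published effect decomposition of the reference study
#'
#' The transcribed mediation table: per-mediator indirect effects, total
#' indirect, direct and total effects (log odds with 95% CI and stars) and
#' mediation proportions, one quantity per row. The `curated` flag marks
#' cells that are arithmetically recoverable from the published coefficients
#' at 2-dp rounding; excluded cells carry a `note` explaining the source
#' inconsistency (see the package vignette).
#'
#' @return A data frame of class `gsem_decomp_fixture`.
#' @export
reference_decomposition_published <- function() {
  df <- read_fixture("reference_decomposition.csv",
                     c("exposure", "mediator", "quantity", "value",
                       "ci_low", "ci_high", "stars", "curated", "note"))
  df$stars[is.na(df$stars)] <- ""
  df$mediator[is.na(df$mediator) | df$mediator == ""] <- NA_character_
  class(df) <- c("gsem_decomp_fixture", "data.frame")
  df
}

#' Published descriptive marginals
#'
#' The transcribed background-characteristics table: counts and column
#' percentages per variable level, overall and split by healthy/sick
#' neonate. Printed cells are kept verbatim; internally inconsistent rows
#' (the maternal-complication care-seeking block) are flagged in `note`.
#'
#' @return A data frame of class `gsem_marginals`.
#' @export
reference_marginals <- function() {
  df <- read_fixture("reference_marginals.csv",
                     c("variable", "level", "overall_n", "overall_pct",
                       "healthy_n", "healthy_pct", "sick_n", "sick_pct",
                       "note"))
  class(df) <- c("gsem_marginals", "data.frame")
  df
}

#' @rdname coef_terms
#' @export
coef_terms <- function(source, equation, predictor) UseMethod("coef_terms")

#' Look up the link-scale terms of a predictor in one equation
#'
#' @param source A coefficient source: `gsem_coef_table`
#'   ([reference_coefficients()]) or `gsem_system_fit` ([fit_system()]).
#' @param equation Equation (endogenous variable) name.
#' @param predictor Parent variable name.
#' @return Data frame with one row per non-reference level: `term`, `level`,
#'   `estimate` (link scale), `se`, `significant`.
#' @export
coef_terms.gsem_coef_table <- function(source, equation, predictor) {
  rows <- source[source$equation == equation & source$predictor == predictor,
                 , drop = FALSE]
  if (nrow(rows) == 0) {
    stop_gsem("no coefficient for predictor '", predictor,
              "' in equation '", equation, "'")
  }
  data.frame(term = rows$term, level = rows$level, estimate = rows$est_link,
             se = rows$se, significant = rows$significant,
             stringsAsFactors = FALSE)
}

#' @rdname coef_sigma
#' @export
coef_sigma <- function(source, terms) UseMethod("coef_sigma")

#' Joint covariance of selected terms
#'
#' For the published coefficient table the covariance is diagonal (squared
#' SEs backed out of the printed CIs; cross-covariances are not published).
#' For a fitted system it is the corresponding block of the assembled joint
#' covariance.
#'
#' @param source A coefficient source.
#' @param terms Character vector of term ids.
#' @return Covariance matrix with `terms` as dimnames.
#' @export
coef_sigma.gsem_coef_table <- function(source, terms) {
  idx <- match(terms, source$term)
  if (anyNA(idx)) {
    stop_gsem("unknown term(s): ", paste(terms[is.na(idx)], collapse = ", "))
  }
  diag(source$se[idx]^2, nrow = length(terms), ncol = length(terms)) |>
    `dimnames<-`(list(terms, terms))
}
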