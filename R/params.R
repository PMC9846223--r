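#' Construct a link-scale parameter set for a diagram
#'
#' A parameter set is the generating truth of the simulator: one intercept
#' per equation, one link-scale coefficient per (equation, parent,
#' non-reference level) edge term, and the residual SD of the gaussian
#' knowledge equation. Reference-level coefficients are implicitly zero.
#'
#' @param diagram A [path_diagram()].
#' @param coefficients Data frame with columns `equation`, `predictor`,
#'   `level`, `value` (link scale: log odds for binomial equations, raw
#'   slope for the gaussian one).
#' @param intercepts Named numeric, one per endogenous variable (default all
#'   zero, pending [calibrate_intercepts()]).
#' @param sigma Residual SD of the gaussian equation.
#' @return An object of class `gsem_params`.
#' @export
param_set <- function(diagram, coefficients, intercepts = NULL, sigma = 1.5) {
  endo <- endogenous_vars(diagram)
  if (is.null(intercepts)) {
    intercepts <- stats::setNames(numeric(length(endo)), endo)
  }
  stopifnot(all(endo %in% names(intercepts)))
  # every coefficient must correspond to a diagram edge, and every edge must
  # carry at least one coefficient
  key <- paste(coefficients$equation, coefficients$predictor)
  edge_key <- paste(diagram$edges$child, diagram$edges$parent)
  extra <- setdiff(key, edge_key)
  if (length(extra) > 0) {
    stop_gsem("coefficient without a matching edge: ",
              paste(unique(extra), collapse = "; "))
  }
  missing <- setdiff(edge_key, key)
  if (length(missing) > 0) {
    stop_gsem("edge without a coefficient: ",
              paste(unique(missing), collapse = "; "))
  }
  structure(
    list(coefficients = coefficients[, c("equation", "predictor", "level",
                                         "value")],
         intercepts = intercepts[endo], sigma = sigma),
    class = "gsem_params"
  )
}

#' Generating truth from the published coefficients
#'
#' Converts the packaged coefficient table to a link-scale parameter set:
#' every non-reference coefficient is the log of the printed adjusted OR
#' (binomial equations) or the printed adjusted beta (knowledge equation).
#' Intercepts are zero placeholders until [calibrate_intercepts()] pins them
#' to the published marginals.
#'
#' @param diagram A [path_diagram()]; defaults to [careseeking_diagram()].
#' @param sigma Residual SD for the knowledge equation (default 1.5).
#' @return A `gsem_params` object.
#' @export
reference_params <- function(diagram = careseeking_diagram(), sigma = 1.5) {
  tab <- reference_coefficients()
  coefs <- data.frame(equation = tab$equation, predictor = tab$predictor,
                      level = tab$level, value = tab$est_link,
                      stringsAsFactors = FALSE)
  param_set(diagram, coefs, sigma = sigma)
}

# Coefficient rows of one equation.
params_for <- function(params, equation) {
  params$coefficients[params$coefficients$equation == equation, ,
                      drop = FALSE]
}

#' Marginal targets matching the published descriptive table
#'
#' Targets for [calibrate_intercepts()]: the published prevalence of each
#' binomial endogenous variable (computed from the printed counts;
#' care-seeking targets are conditional on their subpopulation) and a target
#' mean for the knowledge score. The knowledge mean is not published; 3.2 is
#' chosen so that with residual SD 1.5 the banded shares at 0 and 5+ sit
#' near the printed 3.3% and 20.3%.
#'
#' @param knowledge_mean Target mean of the 0-22 knowledge score.
#' @return Named numeric vector of targets.
#' @export
reference_targets <- function(knowledge_mean = 3.2) {
  c(anc4 = 4711 / 17251,
    facility_delivery = 8997 / 17251,
    pnc = 7486 / 17251,
    mat_careseek = 3063 / 4713,
    knowledge = knowledge_mean,
    neo_careseek = 3198 / 8765)
}
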