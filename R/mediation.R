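# The mediation calculus: enumerate exposure -> mediator(s) -> outcome
# paths over the diagram, form each path's indirect effect as the product of
# link-scale coefficients (with the average relative effect summarizing
# multi-categorical exposures), and decompose every exposure's effect into
# direct, path-specific indirect, total indirect and total, all in log odds
# with delta-method Wald intervals.

#' A mediated path
#'
#' @param exposure Exposure variable name.
#' @param mediators Character vector of intermediate endogenous variables,
#'   in causal order.
#' @param outcome Outcome variable name.
#' @return An object of class `gsem_path`.
#' @export
mediated_path <- function(exposure, mediators, outcome) {
  stopifnot(length(mediators) >= 1, !anyDuplicated(mediators),
            !(exposure %in% mediators), !(outcome %in% mediators))
  structure(list(exposure = exposure, mediators = mediators,
                 outcome = outcome), class = "gsem_path")
}

#' @export
format.gsem_path <- function(x, ...) {
  paste(c(x$exposure, x$mediators, x$outcome), collapse = " -> ")
}

#' @export
print.gsem_path <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Enumerate mediated paths from an exposure to the outcome
#'
#' Depth-first enumeration of all simple directed paths
#' exposure -> mediator(s) -> outcome with between 1 and `max_mediators`
#' intermediates, in deterministic order (fewest mediators first, then by
#' topological position). Mediators whose equation subpopulation is strictly
#' narrower than the outcome's (here: care-seeking for a maternal
#' complication, defined only for mothers who had one) are excluded by
#' default: a product of coefficients through a variable undefined on most
#' of the outcome population has no population-level reading.
#'
#' @param diagram A [path_diagram()].
#' @param exposure Exposure variable name.
#' @param max_mediators Maximum number of intermediates (default 1, the
#'   single-mediator decomposition of the reference analysis).
#' @param exclude_restricted Drop subpopulation-restricted mediators
#'   (default `TRUE`).
#' @return List of [mediated_path()] objects (possibly empty).
#' @export
enumerate_paths <- function(diagram, exposure, max_mediators = 1,
                            exclude_restricted = TRUE) {
  if (!(exposure %in% names(diagram$variables))) {
    stop_gsem("unknown exposure '", exposure, "'")
  }
  outcome <- diagram$outcome
  out_sub <- subpopulation_of(diagram, outcome)
  topo <- c(setdiff(names(diagram$variables), topological_order(diagram)),
            topological_order(diagram))
  usable <- function(m) {
    !exclude_restricted ||
      length(setdiff(subpopulation_of(diagram, m), out_sub)) == 0
  }
  paths <- list()
  walk <- function(node, mediators) {
    for (ch in sort_by_topo(children_of(diagram, node), topo)) {
      if (ch == outcome) {
        if (length(mediators) >= 1) {
          paths[[length(paths) + 1]] <<-
            mediated_path(exposure, mediators, outcome)
        }
      } else if (length(mediators) < max_mediators &&
                 !(ch %in% c(mediators, exposure)) && usable(ch)) {
        walk(ch, c(mediators, ch))
      }
    }
  }
  walk(exposure, character(0))
  ord <- order(lengths(lapply(paths, `[[`, "mediators")),
               vapply(paths, function(p)
                 paste(sprintf("%03d", match(p$mediators, topo)),
                       collapse = ""), ""))
  paths[ord]
}

sort_by_topo <- function(nodes, topo) nodes[order(match(nodes, topo))]

# An effect in the delta-method calculus: a value plus its gradient with
# respect to the link-scale coefficients it references (named by term id).
make_effect <- function(value, grad, kind, levels = NULL, defined = TRUE) {
  structure(list(value = value, grad = grad, kind = kind, levels = levels,
                 defined = defined, se = NA_real_, ci = c(NA_real_, NA_real_)),
            class = "gsem_effect")
}

undefined_effect <- function(kind) {
  make_effect(NA_real_, numeric(0), kind, defined = FALSE)
}

add_grads <- function(a, b) {
  terms <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(terms)), terms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

# Attach the delta-method SE and Wald CI from the source's covariance.
finalize_effect <- function(eff, source) {
  if (!eff$defined) return(eff)
  eff$se <- delta_method_se(eff$grad, coef_sigma(source, names(eff$grad)))
  eff$ci <- c(eff$value - Z975 * eff$se, eff$value + Z975 * eff$se)
  eff
}

#' @export
format.gsem_effect <- function(x, ...) {
  if (!x$defined) return(paste0(x$kind, ": -"))
  sprintf("%s: %.2f (%.2f, %.2f)%s", x$kind,
          round_half_away(x$value), round_half_away(x$ci[1]),
          round_half_away(x$ci[2]), significance_label(x$value, x$se))
}

#' @export
print.gsem_effect <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Delta-method standard error of a smooth combination
#'
#' `sqrt(g' Sigma g)` for gradient `g`; for a product of coefficients
#' `theta = prod(beta_i)` the gradient entries are the products of the other
#' coefficients, sums of products add gradients, and K-level averages weight
#' by 1/K.
#'
#' @param grad Named gradient vector over term ids.
#' @param sigma Covariance matrix over (at least) those terms.
#' @return The standard error.
#' @export
delta_method_se <- function(grad, sigma) {
  terms <- names(grad)
  missing <- setdiff(terms, rownames(sigma))
  if (length(missing) > 0) {
    stop_gsem("covariance entries missing for: ",
              paste(missing, collapse = ", "))
  }
  s <- sigma[terms, terms, drop = FALSE]
  sqrt(drop(t(grad) %*% s %*% grad))
}

#' Scalar effect of an exposure in one equation
#'
#' Binary exposures contribute their lone link-scale coefficient.
#' Multi-categorical exposures are summarized by the average relative
#' effect: the arithmetic mean of per-level link-scale coefficients over the
#' statistically significant levels (two-sided Wald p < 0.05; the printed
#' stars when the source is the published table), or over all non-reference
#' levels in `"all_levels"` mode. With no significant level the effect is
#' undefined (rendered as a dash in tables).
#'
#' @param source A coefficient source ([reference_coefficients()] or
#'   [fit_system()]).
#' @param equation Equation in which the exposure appears.
#' @param exposure Exposure variable name.
#' @param mode `"significant_levels"` (default) or `"all_levels"`.
#' @param kind Effect kind label.
#' @return A `gsem_effect` with the contributing levels attached.
#' @export
exposure_effect <- function(source, equation, exposure,
                            mode = c("significant_levels", "all_levels"),
                            kind = "direct") {
  mode <- match.arg(mode)
  tt <- coef_terms(source, equation, exposure)
  if (mode == "significant_levels") tt <- tt[tt$significant, , drop = FALSE]
  if (nrow(tt) == 0) return(undefined_effect(kind))
  k <- nrow(tt)
  make_effect(mean(tt$estimate),
              stats::setNames(rep(1 / k, k), tt$term), kind,
              levels = tt$level)
}

# Link-scale coefficient a mediator contributes to a downstream equation.
# Dual-coded knowledge contributes the coefficient of one chosen band
# (default the 5+-vs-0 contrast); binary mediators their lone term.
mediator_coefficient <- function(source, equation, mediator,
                                 knowledge_level = "5+") {
  tt <- coef_terms(source, equation, mediator)
  if (nrow(tt) > 1) {
    tt <- tt[tt$level == knowledge_level, , drop = FALSE]
    if (nrow(tt) == 0) {
      stop_gsem("mediator '", mediator, "' has no level '",
                knowledge_level, "' in equation '", equation, "'")
    }
  }
  make_effect(tt$estimate, stats::setNames(1, tt$term), "leg",
              levels = tt$level)
}

#' Indirect effect of one mediated path
#'
#' The product of link-scale coefficients along the path: the exposure's
#' (average relative) effect on the first mediator, times each subsequent
#' mediator's coefficient in the next equation, ending in the outcome
#' equation. SE by the delta method over the source's joint covariance.
#'
#' @param path A [mediated_path()].
#' @param source A coefficient source.
#' @inheritParams exposure_effect
#' @param knowledge_level Band contrast used when dual-coded knowledge is a
#'   mediator (default `"5+"`).
#' @return A `gsem_effect` of kind `path_indirect`; undefined when the
#'   first-leg effect is undefined under `significant_levels` mode.
#' @export
indirect_effect <- function(path, source,
                            mode = c("significant_levels", "all_levels"),
                            knowledge_level = "5+") {
  mode <- match.arg(mode)
  chain <- c(path$exposure, path$mediators, path$outcome)
  legs <- vector("list", length(chain) - 1)
  legs[[1]] <- exposure_effect(source, chain[2], path$exposure, mode,
                               kind = "leg")
  if (!legs[[1]]$defined) return(undefined_effect("path_indirect"))
  for (i in seq.int(2, length(chain) - 1)) {
    legs[[i]] <- mediator_coefficient(source, chain[i + 1], chain[i],
                                      knowledge_level)
  }
  vals <- vapply(legs, `[[`, 0, "value")
  grad <- numeric(0)
  for (i in seq_along(legs)) {
    grad <- add_grads(grad, legs[[i]]$grad * prod(vals[-i]))
  }
  eff <- make_effect(prod(vals), grad, "path_indirect",
                     levels = legs[[1]]$levels)
  finalize_effect(eff, source)
}

#' Decompose one exposure's effect on the outcome
#'
#' Computes the direct effect (the exposure's average relative effect in the
#' outcome equation; absent when the exposure is not a parent of the outcome
#' or, in `significant_levels` mode, has no significant level there), the
#' per-path indirect effects, their exact sum (total indirect), the total
#' effect (direct + total indirect, exact by construction) and the mediation
#' proportion 100 x total indirect / total (only when both direct and
#' indirect parts exist and the total is non-zero).
#'
#' @param exposure Exposure variable name.
#' @param source A coefficient source.
#' @param diagram A [path_diagram()].
#' @inheritParams indirect_effect
#' @param max_mediators Passed to [enumerate_paths()] when `paths` is NULL.
#' @param paths Optional explicit list of [mediated_path()]s (e.g. the
#'   published row layout); default enumerates all.
#' @return An object of class `gsem_decomp_row`.
#' @export
decompose <- function(exposure, source, diagram = careseeking_diagram(),
                      mode = c("significant_levels", "all_levels"),
                      max_mediators = 1, paths = NULL,
                      knowledge_level = "5+") {
  mode <- match.arg(mode)
  if (exposure == diagram$outcome) {
    stop_gsem("exposure must differ from the outcome")
  }
  if (is.null(paths)) {
    paths <- enumerate_paths(diagram, exposure, max_mediators)
  }
  path_effects <- lapply(paths, indirect_effect, source = source,
                         mode = mode, knowledge_level = knowledge_level)
  defined <- vapply(path_effects, `[[`, TRUE, "defined")
  kept <- path_effects[defined]
  names(kept) <- vapply(paths[defined], function(p)
    paste(p$mediators, collapse = "+"), "")
  dropped <- vapply(paths[!defined], format, "")

  total_indirect <- NULL
  if (length(kept) > 0) {
    grad <- Reduce(add_grads, lapply(kept, `[[`, "grad"))
    total_indirect <- finalize_effect(
      make_effect(sum(vapply(kept, `[[`, 0, "value")), grad,
                  "total_indirect"), source)
  }
  direct <- NULL
  if (exposure %in% parents_of(diagram, diagram$outcome)) {
    d <- exposure_effect(source, diagram$outcome, exposure, mode, "direct")
    if (d$defined) direct <- finalize_effect(d, source)
  }
  parts <- c(if (!is.null(direct)) list(direct),
             if (!is.null(total_indirect)) list(total_indirect))
  if (length(parts) == 0) {
    stop_gsem("exposure '", exposure, "' has neither a defined direct ",
              "effect nor any mediated path")
  }
  total <- finalize_effect(
    make_effect(sum(vapply(parts, `[[`, 0, "value")),
                Reduce(add_grads, lapply(parts, `[[`, "grad")), "total"),
    source)
  proportion <- if (!is.null(direct) && !is.null(total_indirect) &&
                    total$value != 0) {
    100 * total_indirect$value / total$value
  } else {
    NA_real_
  }
  structure(
    list(exposure = exposure, paths = kept, dropped_paths = dropped,
         total_indirect = total_indirect, direct = direct, total = total,
         mediation_proportion = proportion),
    class = "gsem_decomp_row"
  )
}

#' @export
print.gsem_decomp_row <- function(x, ...) {
  cat("Decomposition for exposure '", x$exposure, "':\n", sep = "")
  for (m in names(x$paths)) {
    cat("  via ", m, "  ", format(x$paths[[m]]), "\n", sep = "")
  }
  for (part in c("total_indirect", "direct", "total")) {
    if (!is.null(x[[part]])) cat("  ", format(x[[part]]), "\n", sep = "")
  }
  cat("  mediation proportion: ",
      if (is.na(x$mediation_proportion)) "-"
      else paste0(sprintf("%.1f", x$mediation_proportion), "%"), "\n",
      sep = "")
  invisible(x)
}

#' Decomposition table over several exposures
#'
#' One [decompose()] row per exposure; a failing row is flagged and carried
#' as an error message rather than aborting the table.
#'
#' @param exposures Character vector of exposures.
#' @inheritParams decompose
#' @param path_sets Optional named list (by exposure) of explicit path
#'   lists.
#' @return An object of class `gsem_decomp_table`.
#' @export
decomposition_table <- function(exposures, source,
                                diagram = careseeking_diagram(),
                                mode = c("significant_levels", "all_levels"),
                                max_mediators = 1, path_sets = NULL,
                                knowledge_level = "5+") {
  mode <- match.arg(mode)
  rows <- lapply(exposures, function(e) {
    tryCatch(
      decompose(e, source, diagram, mode, max_mediators,
                paths = path_sets[[e]], knowledge_level = knowledge_level),
      error = function(err) {
        structure(list(exposure = e, error = conditionMessage(err)),
                  class = "gsem_decomp_error")
      })
  })
  names(rows) <- exposures
  structure(list(rows = rows), class = "gsem_decomp_table")
}

effect_df_row <- function(exposure, mediator, quantity, eff) {
  data.frame(exposure = exposure, mediator = mediator, quantity = quantity,
             value = eff$value, se = eff$se, ci_low = eff$ci[1],
             ci_high = eff$ci[2],
             stars = if (is.na(eff$se)) "" else
               significance_label(eff$value, eff$se),
             stringsAsFactors = FALSE)
}

#' @export
as.data.frame.gsem_decomp_table <- function(x, ...) {
  out <- list()
  for (row in x$rows) {
    if (inherits(row, "gsem_decomp_error")) next
    for (m in names(row$paths)) {
      out[[length(out) + 1]] <-
        effect_df_row(row$exposure, m, "path_indirect", row$paths[[m]])
    }
    if (!is.null(row$total_indirect)) {
      out[[length(out) + 1]] <- effect_df_row(row$exposure, NA_character_,
                                              "total_indirect",
                                              row$total_indirect)
    }
    if (!is.null(row$direct)) {
      out[[length(out) + 1]] <- effect_df_row(row$exposure, NA_character_,
                                              "direct", row$direct)
    }
    out[[length(out) + 1]] <- effect_df_row(row$exposure, NA_character_,
                                            "total", row$total)
    if (!is.na(row$mediation_proportion)) {
      out[[length(out) + 1]] <- data.frame(
        exposure = row$exposure, mediator = NA_character_,
        quantity = "mediation_proportion", value = row$mediation_proportion,
        se = NA_real_, ci_low = NA_real_, ci_high = NA_real_, stars = "",
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' @export
print.gsem_decomp_table <- function(x, ...) {
  for (row in x$rows) {
    if (inherits(row, "gsem_decomp_error")) {
      cat("Decomposition for exposure '", row$exposure, "' failed: ",
          row$error, "\n", sep = "")
    } else {
      print(row)
    }
  }
  invisible(x)
}

#' Write a decomposition table to CSV
#'
#' Effects are rounded to 2 decimal places (half away from zero) and
#' mediation proportions to 1, matching the presentation convention;
#' internal arithmetic is never rounded.
#'
#' @param table A `gsem_decomp_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(table, path) {
  df <- as.data.frame(table)
  prop <- df$quantity == "mediation_proportion"
  for (col in c("value", "ci_low", "ci_high")) {
    df[[col]] <- ifelse(prop, round_half_away(df[[col]], 1),
                        round_half_away(df[[col]], 2))
  }
  df$se <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
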