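# Fitting the recursive system: one GLM per endogenous variable on its
# declared subpopulation, robust (sandwich) covariance per equation, and an
# assembled joint covariance across equations for the delta-method calculus.

# Model frame of one equation: response plus one factor column per parent,
# restricted to the equation's subpopulation, complete cases only. Parents
# whose own subpopulation is strictly narrower than the equation's (the
# maternal-complication care-seeking predictor in the outcome equation) have
# NA recoded to the reference level, matching the reference analysis's
# printed equation sample sizes.
equation_frame <- function(data, diagram, equation) {
  flags <- subpopulation_of(diagram, equation)
  keep <- rep(TRUE, nrow(data))
  for (f in flags) {
    if (is.null(data[[f]])) stop_gsem("missing subpopulation flag '", f, "'")
    keep <- keep & !is.na(data[[f]]) & data[[f]]
  }
  df <- data[keep, , drop = FALSE]
  v <- diagram$variables[[equation]]
  y <- if (v$family == "binomial") {
    as.integer(df[[equation]] == v$levels[2])
  } else {
    as.numeric(df[[equation]])
  }
  mf <- data.frame(.y = y)
  rows_in_data <- which(keep)
  for (p in parents_of(diagram, equation)) {
    col <- predictor_column(diagram, p)
    if (is.null(df[[col]])) {
      stop_gsem("equation '", equation, "': predictor column '", col,
                "' not in data")
    }
    pv <- diagram$variables[[p]]
    x <- factor(df[[col]], levels = pv$levels)
    if (length(setdiff(subpopulation_of(diagram, p), flags)) > 0) {
      x[is.na(x)] <- pv$reference_level
    }
    mf[[col]] <- x
  }
  cc <- stats::complete.cases(mf)
  list(frame = mf[cc, , drop = FALSE], rows = rows_in_data[cc],
       family = v$family)
}

# Term metadata: glm coefficient name -> (term id, predictor, level).
equation_terms <- function(diagram, equation) {
  out <- data.frame(coef_name = "(Intercept)",
                    term = term_id(equation, "(Intercept)", ""),
                    predictor = "(Intercept)", level = "",
                    stringsAsFactors = FALSE)
  for (p in parents_of(diagram, equation)) {
    col <- predictor_column(diagram, p)
    lev <- predictor_levels(diagram, p)
    out <- rbind(out, data.frame(
      coef_name = paste0(col, lev),
      term = term_id(equation, p, lev),
      predictor = p, level = lev, stringsAsFactors = FALSE))
  }
  out
}

#' Fit one equation of the system
#'
#' Binomial equations are fitted by logit maximum likelihood (IRLS,
#' coefficient tolerance 1e-10, at most 100 iterations); the gaussian
#' equation by ordinary least squares. Categorical parents expand to
#' indicator terms against their reference level. Perfect separation,
#' rank deficiency, empty factor levels and non-convergence are errors
#' naming the offending term.
#'
#' @param data Record-level data frame (e.g. [generate_population()]).
#' @param diagram A [path_diagram()].
#' @param equation Endogenous variable to fit.
#' @param covariance `"HC1"` (observation-level robust, default) or
#'   `"cluster"` (cluster-robust over `cluster_col`).
#' @param cluster_col Column holding the cluster id (default `"cluster"`).
#' @return An object of class `gsem_equation_fit`: link-scale coefficients
#'   and robust covariance named by term id, `n_used`, log-likelihood and
#'   convergence diagnostics.
#' @export
fit_equation <- function(data, diagram, equation,
                         covariance = c("HC1", "cluster"),
                         cluster_col = "cluster") {
  covariance <- match.arg(covariance)
  ef <- equation_frame(data, diagram, equation)
  mf <- ef$frame
  for (col in setdiff(names(mf), ".y")) {
    counts <- table(mf[[col]])
    if (any(counts == 0)) {
      stop_gsem("equation '", equation, "': no observations at level(s) ",
                paste(names(counts)[counts == 0], collapse = ", "),
                " of '", col, "'")
    }
  }
  fam <- if (ef$family == "binomial") stats::binomial() else stats::gaussian()
  fit <- stats::glm(.y ~ ., data = mf, family = fam,
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  if (!fit$converged) {
    stop_gsem("equation '", equation, "' did not converge in ",
              fit$iter, " IRLS iterations")
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop_gsem("equation '", equation, "' is rank deficient; collinear ",
              "term(s): ", paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  if (ef$family == "binomial" && max(abs(cf[-1])) > 12) {
    worst <- names(cf[-1])[which.max(abs(cf[-1]))]
    stop_gsem("apparent perfect separation in equation '", equation,
              "' on term '", worst, "'")
  }
  terms <- equation_terms(diagram, equation)
  idx <- match(names(cf), terms$coef_name)
  if (anyNA(idx)) {
    stop_gsem("equation '", equation, "': unmapped coefficient(s) ",
              paste(names(cf)[is.na(idx)], collapse = ", "))
  }
  names(cf) <- terms$term[idx]
  cluster <- if (covariance == "cluster") {
    if (is.null(data[[cluster_col]])) {
      stop_gsem("cluster column '", cluster_col, "' not in data")
    }
    data[[cluster_col]][ef$rows]
  }
  V <- sandwich_covariance(fit, cluster = cluster)
  dimnames(V) <- list(names(cf), names(cf))
  structure(
    list(equation = equation, coefficients = cf, vcov = V,
         n_used = nrow(mf), loglik = as.numeric(stats::logLik(fit)),
         converged = fit$converged, iterations = fit$iter,
         family = ef$family, terms = terms[idx, , drop = FALSE],
         rows = ef$rows, glm = fit),
    class = "gsem_equation_fit"
  )
}

# Per-observation scores of a fitted canonical-link GLM: (y - mu) x for the
# logit fit, r x for OLS (the sigma^2-free parameterization whose bread is
# X'WX resp. X'X).
equation_scores <- function(fit) {
  X <- stats::model.matrix(fit)
  r <- fit$y - fit$fitted.values
  X * r
}

#' Robust sandwich covariance of a fitted equation
#'
#' Computes A^-1 B A^-1 with bread A the observed information (binomial) or
#' X'X (gaussian) and meat B the sum of per-unit score outer products. Units
#' are observations with the HC1 small-sample factor n/(n-k), or clusters
#' (scores summed within cluster) with factor G/(G-1) * (n-1)/(n-k).
#'
#' @param fit A fitted [stats::glm()] (canonical link) or the `glm` element
#'   of a `gsem_equation_fit`.
#' @param cluster Optional vector of cluster ids, one per used observation.
#' @return Covariance matrix over the equation's coefficients.
#' @export
sandwich_covariance <- function(fit, cluster = NULL) {
  if (inherits(fit, "gsem_equation_fit")) fit <- fit$glm
  s <- equation_scores(fit)
  n <- nrow(s)
  k <- ncol(s)
  Ainv <- summary(fit)$cov.unscaled
  if (is.null(cluster)) {
    B <- crossprod(s)
    adj <- n / (n - k)
  } else {
    stopifnot(length(cluster) == n)
    S <- rowsum(s, group = as.character(cluster))
    B <- crossprod(S)
    G <- nrow(S)
    adj <- G / (G - 1) * (n - 1) / (n - k)
  }
  V <- Ainv %*% B %*% Ainv * adj
  (V + t(V)) / 2
}

#' Fit the full recursive system
#'
#' Fits every equation in topological order on its declared subpopulation
#' and assembles the joint covariance over all equations' terms. In
#' `block_diagonal` mode (default) cross-equation blocks are exactly zero --
#' the likelihood of a recursive system with distinct parameters factorizes,
#' so per-equation covariances are sufficient for the published-style CIs.
#' `stacked_sandwich` additionally fills cross-equation meat blocks from
#' score cross-products over observations shared by both equations (bread
#' stays block-diagonal), for sensitivity analysis.
#'
#' @inheritParams fit_equation
#' @param joint `"block_diagonal"` or `"stacked_sandwich"`.
#' @return An object of class `gsem_system_fit`: per-equation fits, joint
#'   covariance, and the diagram.
#' @export
fit_system <- function(data, diagram, covariance = c("HC1", "cluster"),
                       cluster_col = "cluster",
                       joint = c("block_diagonal", "stacked_sandwich")) {
  covariance <- match.arg(covariance)
  joint <- match.arg(joint)
  order <- topological_order(diagram)
  fits <- list()
  for (eq in order) {
    fits[[eq]] <- tryCatch(
      fit_equation(data, diagram, eq, covariance, cluster_col),
      error = function(e) {
        stop_gsem("equation '", eq, "': ", conditionMessage(e))
      })
  }
  all_terms <- unlist(lapply(fits, function(f) names(f$coefficients)),
                      use.names = FALSE)
  V <- matrix(0, length(all_terms), length(all_terms),
              dimnames = list(all_terms, all_terms))
  for (f in fits) {
    V[names(f$coefficients), names(f$coefficients)] <- f$vcov
  }
  if (joint == "stacked_sandwich") {
    for (i in seq_along(fits)) {
      for (j in seq_along(fits)) {
        if (i >= j) next
        fi <- fits[[i]]; fj <- fits[[j]]
        shared <- intersect(fi$rows, fj$rows)
        if (length(shared) == 0) next
        si <- equation_scores(fi$glm)[match(shared, fi$rows), , drop = FALSE]
        sj <- equation_scores(fj$glm)[match(shared, fj$rows), , drop = FALSE]
        Ai <- summary(fi$glm)$cov.unscaled
        Aj <- summary(fj$glm)$cov.unscaled
        blk <- Ai %*% crossprod(si, sj) %*% Aj
        V[names(fi$coefficients), names(fj$coefficients)] <- blk
        V[names(fj$coefficients), names(fi$coefficients)] <- t(blk)
      }
    }
  }
  structure(
    list(fits = fits, vcov = V, joint = joint, covariance = covariance,
         diagram = diagram),
    class = "gsem_system_fit"
  )
}

#' @export
print.gsem_system_fit <- function(x, ...) {
  cat("Recursive system fit (", x$covariance, " covariance, ", x$joint,
      " joint mode)\n", sep = "")
  for (f in x$fits) {
    cat(sprintf("  %-18s n = %6d  logLik = %10.1f  (%d terms)\n",
                f$equation, f$n_used, f$loglik, length(f$coefficients)))
  }
  invisible(x)
}

#' Significance stars for a Wald test
#'
#' Two-sided Wald p-value from the standard normal: `"**"` for p < 0.01,
#' `"*"` for p < 0.05, `""` otherwise.
#'
#' @param estimate Link-scale estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return Character vector of labels.
#' @export
significance_label <- function(estimate, se) {
  if (any(se <= 0)) stop_gsem("standard errors must be positive")
  p <- 2 * stats::pnorm(-abs(estimate / se))
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' @export
coef_terms.gsem_system_fit <- function(source, equation, predictor) {
  f <- source$fits[[equation]]
  if (is.null(f)) stop_gsem("no fitted equation '", equation, "'")
  rows <- f$terms[f$terms$predictor == predictor, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop_gsem("no coefficient for predictor '", predictor,
              "' in equation '", equation, "'")
  }
  est <- f$coefficients[rows$term]
  se <- sqrt(diag(f$vcov)[rows$term])
  data.frame(term = rows$term, level = rows$level, estimate = unname(est),
             se = unname(se),
             significant = significance_label(est, se) != "",
             stringsAsFactors = FALSE)
}

#' @export
coef_sigma.gsem_system_fit <- function(source, terms) {
  missing <- setdiff(terms, rownames(source$vcov))
  if (length(missing) > 0) {
    stop_gsem("terms not in joint covariance: ",
              paste(missing, collapse = ", "))
  }
  source$vcov[terms, terms, drop = FALSE]
}

#' Presentation table of a fitted system
#'
#' One row per coefficient in the published style: exponentiated estimates
#' with Wald 95% CIs for binomial equations, raw estimates for the gaussian
#' one, significance stars, and the equation sample size.
#'
#' @param system A `gsem_system_fit`.
#' @return A data frame.
#' @export
system_table <- function(system) {
  out <- do.call(rbind, lapply(system$fits, function(f) {
    keep <- f$terms$predictor != "(Intercept)"
    est <- f$coefficients[f$terms$term[keep]]
    se <- sqrt(diag(f$vcov)[f$terms$term[keep]])
    scale_or <- f$family == "binomial"
    tf <- if (scale_or) exp else identity
    data.frame(
      equation = f$equation, predictor = f$terms$predictor[keep],
      level = f$terms$level[keep],
      scale = if (scale_or) "or" else "beta",
      estimate = tf(unname(est)),
      ci_low = tf(unname(est - Z975 * se)),
      ci_high = tf(unname(est + Z975 * se)),
      stars = significance_label(est, se),
      n = f$n_used, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Serialize a fitted system to JSON
#'
#' @param system A `gsem_system_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
system_to_json <- function(system, path) {
  lst <- list(
    covariance = system$covariance, joint = system$joint,
    equations = lapply(system$fits, function(f) {
      list(equation = f$equation, n_used = f$n_used, loglik = f$loglik,
           converged = f$converged, iterations = f$iterations,
           coefficients = as.list(f$coefficients),
           vcov = f$vcov)
    })
  )
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
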