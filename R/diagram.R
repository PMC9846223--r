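#' Declare a variable of the structural diagram
#'
#' A variable specification records how a survey variable behaves inside the
#' recursive equation system: whether it is modeled (`endogenous`) or only a
#' predictor (`exogenous`), the GLM family used when it is modeled, its
#' measurement type and category levels, and how it enters equations where it
#' is a parent.
#'
#' Count variables with `predictor_encoding = "as_levels"` are dual-coded:
#' the raw count is the dependent variable of their own (gaussian) equation,
#' while a banded categorical version (the `levels`) is used wherever the
#' variable is a parent. The fitting and simulation layers expect that banded
#' version in a companion column named `<name>_cat`.
#'
#' @param name Variable (column) name.
#' @param role `"exogenous"` or `"endogenous"`.
#' @param family GLM family, `"binomial"` or `"gaussian"`; required for
#'   endogenous variables and forbidden for exogenous ones.
#' @param measurement `"binary"`, `"categorical"`, `"count"` or
#'   `"continuous"`.
#' @param levels Ordered character vector of category labels; the first is
#'   the reference. Required for binary/categorical variables (and for count
#'   variables entering as levels).
#' @param reference_level Reference category; defaults to `levels[1]`.
#' @param predictor_encoding `"as_levels"` (indicator terms against the
#'   reference) or `"as_continuous"`.
#' @return An object of class `gsem_variable`.
#' @export
variable_spec <- function(name, role = c("exogenous", "endogenous"),
                          family = NULL,
                          measurement = c("binary", "categorical", "count",
                                          "continuous"),
                          levels = NULL, reference_level = NULL,
                          predictor_encoding = c("as_levels",
                                                 "as_continuous")) {
  role <- match.arg(role)
  measurement <- match.arg(measurement)
  predictor_encoding <- match.arg(predictor_encoding)
  if (!is.null(family)) {
    family <- match.arg(family, c("binomial", "gaussian"))
  }
  if (!is.null(levels) && is.null(reference_level)) {
    reference_level <- levels[1]
  }
  structure(
    list(name = name, role = role, family = family,
         measurement = measurement, levels = levels,
         reference_level = reference_level,
         predictor_encoding = predictor_encoding),
    class = "gsem_variable"
  )
}

#' Assemble a path diagram
#'
#' A path diagram is the DAG of the recursive system: the variable
#' declarations, the directed edges (one per adjusted coefficient of the
#' corresponding equation), the single outcome, and the subpopulation each
#' equation is fitted on, given as named flag columns of the dataset.
#'
#' @param variables List of [variable_spec()] objects.
#' @param edges Data frame with columns `parent`, `child`; each child must be
#'   endogenous.
#' @param outcome Name of the outcome variable (endogenous, no outgoing
#'   edges).
#' @param subpopulations Named list mapping an endogenous variable to the
#'   character vector of logical flag columns its equation is restricted to.
#' @return An object of class `gsem_diagram`.
#' @seealso [careseeking_diagram()], [validate_diagram()], [load_diagram()]
#' @export
path_diagram <- function(variables, edges, outcome, subpopulations = list()) {
  names(variables) <- vapply(variables, `[[`, "", "name")
  edges <- data.frame(parent = as.character(edges$parent),
                      child = as.character(edges$child),
                      stringsAsFactors = FALSE)
  structure(
    list(variables = variables, edges = edges, outcome = outcome,
         subpopulations = subpopulations),
    class = "gsem_diagram"
  )
}

#' @export
print.gsem_diagram <- function(x, ...) {
  endo <- endogenous_vars(x)
  cat("Recursive path diagram:", length(x$variables), "variables,",
      nrow(x$edges), "edges\n")
  cat("Endogenous (fitting order):", paste(topological_order(x),
                                           collapse = " -> "), "\n")
  cat("Outcome:", x$outcome, "\n")
  invisible(x)
}

endogenous_vars <- function(diagram) {
  names(Filter(function(v) v$role == "endogenous", diagram$variables))
}

parents_of <- function(diagram, child) {
  diagram$edges$parent[diagram$edges$child == child]
}

children_of <- function(diagram, parent) {
  diagram$edges$child[diagram$edges$parent == parent]
}

# Column holding the predictor-side coding of a variable (the banded
# companion column for dual-coded counts).
predictor_column <- function(diagram, name) {
  v <- diagram$variables[[name]]
  if (!is.null(v) && v$measurement == "count" &&
      v$predictor_encoding == "as_levels") {
    paste0(name, "_cat")
  } else {
    name
  }
}

# Non-reference levels a parent contributes to an equation's design.
predictor_levels <- function(diagram, name) {
  v <- diagram$variables[[name]]
  if (is.null(v$levels)) return(NULL)
  setdiff(v$levels, v$reference_level)
}

subpopulation_of <- function(diagram, name) {
  as.character(diagram$subpopulations[[name]] %||% character())
}

#' Topological fitting order of the endogenous variables
#'
#' Kahn's algorithm over the diagram's edges. Errors if the edge set is
#' cyclic; use [validate_diagram()] for a non-throwing check.
#'
#' @param diagram A [path_diagram()].
#' @return Character vector of endogenous variable names in an order where
#'   every equation's endogenous parents precede it.
#' @export
topological_order <- function(diagram) {
  nodes <- names(diagram$variables)
  edges <- diagram$edges
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges$child)
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  ready <- nodes[indeg == 0]
  while (length(ready) > 0) {
    n <- ready[1]
    ready <- ready[-1]
    order <- c(order, n)
    for (ch in children_of(diagram, n)) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order) < length(nodes)) {
    stop_gsem("diagram contains a cycle involving: ",
              paste(setdiff(nodes, order), collapse = ", "))
  }
  intersect(order, endogenous_vars(diagram))
}

#' Validate a path diagram
#'
#' Checks every structural invariant of the diagram and reports all
#' violations found; violations are data, not errors.
#'
#' @param diagram A [path_diagram()].
#' @return Character vector of violation messages; `character(0)` for a valid
#'   diagram.
#' @export
validate_diagram <- function(diagram) {
  v <- character(0)
  vars <- diagram$variables
  nm <- names(vars)
  if (anyDuplicated(nm)) {
    v <- c(v, paste0("duplicated variable names: ",
                     paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  for (x in vars) {
    if (x$role == "endogenous" && is.null(x$family)) {
      v <- c(v, paste0("endogenous variable '", x$name, "' has no family"))
    }
    if (x$role == "exogenous" && !is.null(x$family)) {
      v <- c(v, paste0("exogenous variable '", x$name,
                       "' must not declare a family"))
    }
    if (x$measurement == "binary" && length(x$levels) != 2) {
      v <- c(v, paste0("binary variable '", x$name,
                       "' must have exactly two levels"))
    }
    if (!is.null(x$levels) && !identical(x$reference_level, x$levels[1])) {
      v <- c(v, paste0("reference level of '", x$name,
                       "' is not the first listed level"))
    }
  }
  e <- diagram$edges
  unknown <- setdiff(unique(c(e$parent, e$child)), nm)
  if (length(unknown) > 0) {
    v <- c(v, paste0("edges reference unknown variables: ",
                     paste(unknown, collapse = ", ")))
  }
  self <- e$parent == e$child
  if (any(self)) {
    v <- c(v, paste0("self-edge on '", paste(unique(e$parent[self]),
                                             collapse = "', '"), "'"))
  }
  endo <- endogenous_vars(diagram)
  bad_child <- setdiff(intersect(e$child, nm), endo)
  if (length(bad_child) > 0) {
    v <- c(v, paste0("edge child must be endogenous: ",
                     paste(unique(bad_child), collapse = ", ")))
  }
  for (y in endo) {
    if (length(parents_of(diagram, y)) == 0) {
      v <- c(v, paste0("endogenous variable '", y, "' has an empty parent set"))
    }
  }
  if (!(diagram$outcome %in% endo)) {
    v <- c(v, paste0("outcome '", diagram$outcome, "' is not endogenous"))
  } else if (length(children_of(diagram, diagram$outcome)) > 0) {
    v <- c(v, paste0("outcome '", diagram$outcome, "' has outgoing edges"))
  }
  # acyclicity via Kahn on the edge subgraph (ignore earlier structural issues)
  cyc <- tryCatch({
    topo_ok <- TRUE
    nodes <- unique(c(e$parent, e$child))
    indeg <- stats::setNames(integer(length(nodes)), nodes)
    tab <- table(e$child[!self])
    indeg[names(tab)] <- as.integer(tab)
    ready <- nodes[indeg == 0]
    seen <- character(0)
    ee <- e[!self, , drop = FALSE]
    while (length(ready) > 0) {
      n <- ready[1]; ready <- ready[-1]; seen <- c(seen, n)
      ch <- ee$child[ee$parent == n]
      for (c0 in ch) {
        indeg[c0] <- indeg[c0] - 1L
        if (indeg[c0] == 0L) ready <- c(ready, c0)
      }
    }
    setdiff(nodes, seen)
  }, error = function(e) character(0))
  if (length(cyc) > 0) {
    v <- c(v, paste0("cycle involving: ", paste(cyc, collapse = ", ")))
  }
  unknown_sub <- setdiff(names(diagram$subpopulations), endo)
  if (length(unknown_sub) > 0) {
    v <- c(v, paste0("subpopulation filter on non-endogenous variable: ",
                     paste(unknown_sub, collapse = ", ")))
  }
  v
}

#' The built-in six-equation care-seeking diagram
#'
#' The recursive system for qualified care-seeking for sick newborns:
#' equations for 4+ qualified ANC visits, facility delivery, qualified PNC,
#' care-seeking for the last maternal complication (restricted to mothers who
#' had one), danger-sign knowledge (gaussian count), and the outcome,
#' qualified care-seeking for the sick neonate. Parent sets follow the
#' adjusted-coefficient structure of the reference study: a predictor is a
#' parent exactly when its adjusted coefficient is reported for that
#' equation. All equations are fitted on the sick-neonate subpopulation.
#'
#' The knowledge score is dual-coded: the equation models the 0-22 count,
#' while as a predictor it enters as the banded factor 0 / 1-4 / 5+ through
#' the companion column `knowledge_cat`.
#'
#' @return A validated [path_diagram()].
#' @export
careseeking_diagram <- function() {
  bin <- function(name, role = "exogenous", family = NULL)
    variable_spec(name, role, family, "binary", c("no", "yes"))
  vars <- list(
    variable_spec("mother_age", "exogenous", NULL, "categorical",
                  c("<20", "20-34", "35-49")),
    variable_spec("education", "exogenous", NULL, "categorical",
                  c("no_education", "primary_incomplete", "primary_complete",
                    "secondary_incomplete", "secondary_complete_plus")),
    variable_spec("wealth", "exogenous", NULL, "categorical",
                  c("lowest", "second", "middle", "fourth", "highest")),
    variable_spec("living_children", "exogenous", NULL, "categorical",
                  c("1", "2-3", "4+")),
    bin("child_death"),
    variable_spec("sex", "exogenous", NULL, "binary", c("female", "male")),
    variable_spec("distance", "exogenous", NULL, "binary",
                  c("5+km", "<=5km")),
    bin("chw_visit"),
    bin("ds_counseling"),
    bin("anc4", "endogenous", "binomial"),
    bin("facility_delivery", "endogenous", "binomial"),
    bin("pnc", "endogenous", "binomial"),
    bin("mat_careseek", "endogenous", "binomial"),
    variable_spec("knowledge", "endogenous", "gaussian", "count",
                  c("0", "1-4", "5+")),
    bin("neo_careseek", "endogenous", "binomial")
  )
  seven <- c("mother_age", "education", "wealth", "living_children",
             "child_death", "distance", "chw_visit")
  eq <- list(
    anc4 = seven,
    facility_delivery = c("anc4", seven),
    pnc = c("facility_delivery", "anc4", seven),
    mat_careseek = c("pnc", "facility_delivery", "anc4", seven),
    knowledge = c("pnc", "facility_delivery", "anc4", setdiff(seven, "distance"),
                  "ds_counseling"),
    neo_careseek = c("knowledge", "mat_careseek", "pnc", "facility_delivery",
                     "anc4", "mother_age", "education", "wealth",
                     "living_children", "child_death", "sex", "distance",
                     "chw_visit", "ds_counseling")
  )
  edges <- do.call(rbind, lapply(names(eq), function(child)
    data.frame(parent = eq[[child]], child = child,
               stringsAsFactors = FALSE)))
  d <- path_diagram(
    variables = vars, edges = edges, outcome = "neo_careseek",
    subpopulations = list(
      anc4 = "sick_neonate", facility_delivery = "sick_neonate",
      pnc = "sick_neonate",
      mat_careseek = c("sick_neonate", "had_complication"),
      knowledge = "sick_neonate", neo_careseek = "sick_neonate"
    )
  )
  viol <- validate_diagram(d)
  stopifnot(length(viol) == 0)
  d
}
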