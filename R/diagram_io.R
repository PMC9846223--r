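# Serialization of path diagrams to/from JSON and YAML configuration files.
#
# Schema: top-level keys `variables` (list of {name, role, family,
# measurement, levels, reference_level, predictor_encoding}), `edges`
# (list of {parent, child}), `outcome`, `subpopulations` (map from
# endogenous variable to flag column(s)).

diagram_to_list <- function(diagram) {
  list(
    variables = lapply(unname(diagram$variables), function(v) {
      out <- list(name = v$name, role = v$role,
                  measurement = v$measurement,
                  predictor_encoding = v$predictor_encoding)
      if (!is.null(v$family)) out$family <- v$family
      if (!is.null(v$levels)) {
        out$levels <- as.list(v$levels)
        out$reference_level <- v$reference_level
      }
      out
    }),
    edges = lapply(seq_len(nrow(diagram$edges)), function(i)
      list(parent = diagram$edges$parent[i], child = diagram$edges$child[i])),
    outcome = diagram$outcome,
    subpopulations = lapply(diagram$subpopulations, as.list)
  )
}

#' Serialize a path diagram to a config file
#'
#' @param diagram A [path_diagram()].
#' @param path Output file; format chosen by extension (`.json`, `.yaml` /
#'   `.yml`).
#' @return `path`, invisibly.
#' @export
save_diagram <- function(diagram, path) {
  lst <- diagram_to_list(diagram)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

parse_error <- function(field, msg) {
  stop_gsem("diagram config: field '", field, "': ", msg)
}

#' Read a path diagram from a config file or string
#'
#' Parses the JSON/YAML schema, checks required fields and enumerations, and
#' validates the resulting diagram; an invalid diagram is an error listing
#' every violation.
#'
#' @param config A file path, or a literal JSON/YAML string.
#' @return A validated [path_diagram()].
#' @export
load_diagram <- function(config) {
  if (length(config) == 1 && !grepl("[\n{:]", config) && file.exists(config)) {
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    is_json <- grepl("\\.json$", config)
  } else {
    txt <- paste(config, collapse = "\n")
    is_json <- grepl("^\\s*\\{", txt)
  }
  lst <- if (is_json) jsonlite::fromJSON(txt, simplifyVector = FALSE)
         else yaml::yaml.load(txt)
  for (field in c("variables", "edges", "outcome")) {
    if (is.null(lst[[field]])) parse_error(field, "missing")
  }
  fams <- c("binomial", "gaussian")
  vars <- lapply(lst$variables, function(v) {
    if (is.null(v$name)) parse_error("variables.name", "missing")
    if (is.null(v$role)) parse_error("variables.role", "missing")
    if (!is.null(v$family) && !(v$family %in% fams)) {
      parse_error("variables.family",
                  paste0("'", v$family, "' not one of: ",
                         paste(fams, collapse = ", ")))
    }
    variable_spec(
      name = v$name, role = v$role, family = v$family,
      measurement = v$measurement %||% "binary",
      levels = if (!is.null(v$levels)) unlist(v$levels),
      reference_level = v$reference_level,
      predictor_encoding = v$predictor_encoding %||% "as_levels"
    )
  })
  edges <- do.call(rbind, lapply(lst$edges, function(e) {
    if (is.null(e$parent) || is.null(e$child)) {
      parse_error("edges", "each edge needs 'parent' and 'child'")
    }
    data.frame(parent = e$parent, child = e$child, stringsAsFactors = FALSE)
  }))
  d <- path_diagram(vars, edges, lst$outcome,
                    lapply(lst$subpopulations %||% list(), unlist))
  viol <- validate_diagram(d)
  if (length(viol) > 0) {
    stop_gsem("invalid diagram:\n  ", paste(viol, collapse = "\n  "))
  }
  d
}
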