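# Shared fixtures, built in code and memoized across test files.

.tt_cache <- new.env(parent = emptyenv())

tt_memo <- function(key, expr) {
  if (!exists(key, .tt_cache)) assign(key, force(expr), .tt_cache)
  get(key, .tt_cache)
}

tt_diagram <- function() tt_memo("diagram", careseeking_diagram())

# Truth calibrated to the published marginals; seed fixed up front.
tt_params <- function() tt_memo("params", {
  calibrate_intercepts(reference_params(tt_diagram()),
                       design = population_design(seed = 20251),
                       diagram = tt_diagram(), n_sim = 100000)
})

tt_design <- function(seed = 101) population_design(n_total = 17251,
                                                    seed = seed)

tt_pop <- function() tt_memo("pop", {
  generate_population(tt_diagram(), tt_params(), tt_design())
})

tt_fit <- function() tt_memo("fit", {
  fit_system(tt_pop(), tt_diagram())
})

# A one-equation binary diagram (x -> y), for closed-form GLM oracles.
tiny_logit_diagram <- function() {
  path_diagram(
    variables = list(
      variable_spec("x", "exogenous", NULL, "binary", c("no", "yes")),
      variable_spec("y", "endogenous", "binomial", "binary", c("no", "yes"))
    ),
    edges = data.frame(parent = "x", child = "y"),
    outcome = "y"
  )
}

# 2x2 table as records: counts (x=yes,y=yes), (yes,no), (no,yes), (no,no).
tiny_2x2_data <- function(a, b, c, d) {
  data.frame(
    x = factor(rep(c("yes", "yes", "no", "no"), c(a, b, c, d)),
               levels = c("no", "yes")),
    y = factor(rep(c("yes", "no", "yes", "no"), c(a, b, c, d)),
               levels = c("no", "yes")),
    cluster = "c1", stringsAsFactors = FALSE
  )
}

# Random small recursive DAG (node 1 exogenous, the rest endogenous, the
# last node the outcome), for path-enumeration property tests.
random_dag <- function(n_nodes, seed) {
  set.seed(seed)
  nm <- paste0("v", seq_len(n_nodes))
  edges <- list()
  for (j in 2:n_nodes) {
    parents <- which(stats::runif(j - 1) < 0.4)
    if (length(parents) == 0) parents <- sample.int(j - 1, 1)
    edges[[j]] <- data.frame(parent = nm[parents], child = nm[j],
                             stringsAsFactors = FALSE)
  }
  vars <- c(
    list(variable_spec(nm[1], "exogenous", NULL, "binary", c("no", "yes"))),
    lapply(nm[-1], function(v)
      variable_spec(v, "endogenous", "binomial", "binary", c("no", "yes")))
  )
  path_diagram(vars, do.call(rbind, edges), outcome = nm[n_nodes])
}

# Minimal hand-built coefficient source (class gsem_coef_table) from a
# data.frame of equation/predictor/level/est_link/se/significant.
tiny_coef_source <- function(df) {
  df$term <- paste(df$equation, df$predictor, df$level, sep = "|")
  class(df) <- c("gsem_coef_table", "data.frame")
  df
}
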