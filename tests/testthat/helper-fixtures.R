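# shared fixtures and small independent utilities for the suite

toy_ext <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- extend_model(make_toy_model())
    cache
  }
})

# independent boolean evaluation of a GPR string: translate to an R logical
# expression and eval under an assignment (never touches the package parser)
eval_gpr_text <- function(text, active, genes) {
  expr <- text
  for (g in genes) {
    val <- if (g %in% active) "TRUE" else "FALSE"
    expr <- gsub(paste0("\\b", g, "\\b"), val, expr)
  }
  expr <- gsub("\\band\\b", "&&", expr)
  expr <- gsub("\\bor\\b", "||", expr)
  eval(parse(text = expr))
}

# random well-formed GPR string over genes g1..gk
random_gpr_string <- function(n_genes) {
  genes <- paste0("g", seq_len(n_genes))
  grow <- function(depth) {
    if (depth <= 0 || stats::runif(1) < 0.4) return(sample(genes, 1))
    op <- sample(c("and", "or"), 1)
    lhs <- grow(depth - 1); rhs <- grow(depth - 1)
    if (stats::runif(1) < 0.5) sprintf("(%s %s %s)", lhs, op, rhs)
    else sprintf("%s %s %s", lhs, op, rhs)
  }
  grow(3)
}

# a noiseless simulated instance of the default scenario
noiseless_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_condition_pair(toy_scenario(seed = 7, sigma = 0, sigma_expr = 0))
    cache
  }
})
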