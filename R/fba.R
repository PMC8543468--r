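# dense column-space row from reaction-level weights
reaction_row <- function(ext, weights) {
  row <- numeric(ncol(ext$S_ext))
  for (rid in names(weights)) {
    rm <- ext$reaction_map[[rid]]
    if (is.null(rm)) stop(sprintf("unknown reaction: %s", rid))
    row[rm$idx] <- row[rm$idx] + weights[[rid]] * rm$sign
  }
  row
}

# base LP pieces shared by fba() and marge(): steady state + aggregate
# reaction bounds, over the extended columns
base_lp_rows <- function(ext) {
  n <- ncol(ext$S_ext)
  A_ub <- NULL; b_ub <- NULL
  for (a in ext$agg) {
    row <- numeric(n); row[a$idx] <- a$sign
    A_ub <- rbind(A_ub, row, -row)
    b_ub <- c(b_ub, a$ub, -a$lb)
  }
  list(A_eq = ext$S_ext, b_eq = numeric(nrow(ext$S_ext)), A_ub = A_ub, b_ub = b_ub)
}

#' Flux balance analysis on an extended model
#'
#' Optimizes a reaction flux subject to steady state (`S_ext x = 0`),
#' column bounds and reaction-level aggregate bounds.
#'
#' @param ext an `extended_model`.
#' @param objective reaction id to optimize, or a named numeric vector of
#'   reaction weights for a general linear objective.
#' @param sense `"max"` or `"min"`.
#' @param extra_constraints optional list of constraints, each a list with
#'   `weights` (named numeric over reaction ids) or `row` (numeric over
#'   columns), `dir` (`"<="`, `">="` or `"=="`) and `rhs`.
#' @return object of class `flux_state`: `flux` (named reaction fluxes),
#'   `usage` (named usage-variable values), `objective`, `status`.
#' @export
fba <- function(ext, objective, sense = c("max", "min"), extra_constraints = NULL) {
  sense <- match.arg(sense)
  stopifnot(inherits(ext, "extended_model"))
  w <- if (is.character(objective)) stats::setNames(1, objective) else objective
  obj <- reaction_row(ext, as.list(w))

  rows <- base_lp_rows(ext)
  A_ub <- rows$A_ub; b_ub <- rows$b_ub
  A_eq <- rows$A_eq; b_eq <- rows$b_eq
  for (ct in extra_constraints %||% list()) {
    row <- if (!is.null(ct$row)) ct$row else reaction_row(ext, as.list(ct$weights))
    if (ct$dir == "==") { A_eq <- rbind(A_eq, row); b_eq <- c(b_eq, ct$rhs) }
    else if (ct$dir == "<=") { A_ub <- rbind(A_ub, row); b_ub <- c(b_ub, ct$rhs) }
    else { A_ub <- rbind(A_ub, -row); b_ub <- c(b_ub, -ct$rhs) }
  }

  sol <- solve_lp(obj, A_eq = A_eq, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub,
                  lb = ext$vars$lb, ub = ext$vars$ub, maximize = (sense == "max"))
  flux_state_from_solution(ext, sol)
}

flux_state_from_solution <- function(ext, sol) {
  if (sol$status != "optimal")
    return(structure(list(flux = NULL, usage = NULL, objective = NA_real_,
                          status = if (sol$status == "maxiter") "infeasible" else sol$status),
                     class = "flux_state"))
  x <- stats::setNames(sol$x, ext$vars$name)
  structure(list(flux = reconstruct_fluxes(ext, sol$x),
                 usage = x[ext$vars$kind == "usage"],
                 objective = sol$objective,
                 status = "optimal"),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("<flux_state> status=%s objective=%s\n", x$status,
              format(x$objective)))
  invisible(x)
}

#' Maximum feasible uptake magnitude of an exchange reaction
#'
#' Single flux-variability-style optimization: minimizes the exchange flux
#' under the model's current bounds and returns the uptake magnitude
#' (uptake being negative exchange flux), floored at zero.
#'
#' @param ext an `extended_model`.
#' @param exchange_id an exchange reaction id of the base model.
#' @return nonnegative scalar uptake rate.
#' @export
max_uptake_rate <- function(ext, exchange_id) {
  if (!exchange_id %in% ext$base$exchange_ids)
    stop(sprintf("%s is not an exchange reaction", exchange_id))
  fs <- fba(ext, exchange_id, sense = "min")
  if (fs$status != "optimal")
    stop(sprintf("model infeasible while computing max uptake of %s", exchange_id))
  max(0, -fs$objective)
}

#' Mass-balance residual of a flux state
#'
#' @param ext an `extended_model`.
#' @param fs a `flux_state` with status `"optimal"`.
#' @return max absolute residual of `S v` over metabolites.
#' @export
mass_balance_residual <- function(ext, fs) {
  S <- stoichiometric_matrix(ext$base)
  max(abs(S %*% fs$flux[colnames(S)]))
}
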