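#' Parameters of the two-step relative-expression flux fit
#'
#' @param u_min flux activation threshold: minimum total usage imposed on
#'   every enzyme group with measured relative expression, in each
#'   condition (default 0.001 flux units).
#' @param step2_tol relaxation `eps` of the second step: the returned
#'   solution's expression-agreement value may exceed the Step-1 optimum
#'   by at most this fraction (default 0.1).
#' @param growth_frac_a,growth_frac_b optional biomass floors as fractions
#'   of each condition's own FBA maximum (default 0.8; `NULL` disables).
#' @param total_flux_budget optional constant total enzyme usage imposed
#'   on each condition (`sum(u) = budget`), implementing a constant total
#'   metabolic flux assumption. `NULL` (default) disables.
#' @param activation logical; apply the `u >= u_min` activation
#'   constraints (default TRUE).
#' @return object of class `marge_params`.
#' @export
marge_params <- function(u_min = 0.001, step2_tol = 0.1,
                         growth_frac_a = 0.8, growth_frac_b = 0.8,
                         total_flux_budget = NULL, activation = TRUE) {
  stopifnot(u_min > 0, step2_tol >= 0)
  for (gf in list(growth_frac_a, growth_frac_b))
    if (!is.null(gf)) stopifnot(gf >= 0, gf <= 1)
  structure(list(u_min = u_min, step2_tol = step2_tol,
                 growth_frac_a = growth_frac_a, growth_frac_b = growth_frac_b,
                 total_flux_budget = total_flux_budget,
                 activation = isTRUE(activation)),
            class = "marge_params")
}

#' Aggregate gene-level relative expression to enzyme-usage groups
#'
#' Genes are filtered to significant differential expression
#' (`qvalue < q_max`, the usual q < 0.1 convention) and their log2 fold
#' changes (condition b versus a) are mapped to each enzyme group (one
#' isozyme of one reaction). The group ratio `r = e_b/e_a` on the linear
#' scale is the geometric mean of `2^lfc` over the group's member genes
#' present in the input — equivalently `2^mean(lfc)` — or, under the
#' `"min"` rule, the smallest member fold change (the complex is limited
#' by its least-expressed subunit). Groups with no measured member gene
#' are absent from the result and therefore do not enter the Step-1
#' objective.
#'
#' @param expression data.frame with columns `gene_id`, `log2fc` and
#'   optionally `qvalue` (if absent, all genes are used).
#' @param ext an `extended_model`.
#' @param q_max significance cutoff on `qvalue`.
#' @param aggregation `"geomean"` (default) or `"min"`.
#' @return named numeric vector: enzyme group id -> ratio (> 0).
#' @export
enzyme_ratios <- function(expression, ext, q_max = 0.1,
                          aggregation = c("geomean", "min")) {
  aggregation <- match.arg(aggregation)
  stopifnot(all(c("gene_id", "log2fc") %in% names(expression)))
  if (!all(is.finite(expression$log2fc))) stop("non-finite log2 fold changes")
  if ("qvalue" %in% names(expression))
    expression <- expression[expression$qvalue < q_max, , drop = FALSE]
  lfc <- stats::setNames(expression$log2fc, expression$gene_id)

  out <- numeric(0)
  for (gid in names(ext$groups)) {
    members <- intersect(ext$groups[[gid]], names(lfc))
    if (!length(members)) next
    out[gid] <- switch(aggregation,
                       geomean = 2^mean(lfc[members]),
                       min = 2^min(lfc[members]))
  }
  out
}

#' Two-step linear fit of flux redistribution to relative expression
#'
#' Couples two steady-state flux distributions (conditions a and b) of
#' the enzyme-usage extended model through relative expression. Step 1
#' minimizes the expression-agreement objective
#' \deqn{obj_1 = \sum_{i \in E} | u^b_i - r_i u^a_i |}
#' over enzyme usage variables whose group has a measured expression
#' ratio `r_i = e_b/e_a`, subject to steady state in both conditions,
#' flux bounds, the exchange constraint set (direction calls, magnitude
#' floors, between-condition ratio intervals), optional biomass floors
#' and an optional total-usage budget, plus activation constraints
#' `sum(u_group) >= u_min` for measured groups (the conceptual strict
#' inequality "expressed implies active" implemented as `>=`, the
#' LP-representable form). Step 2
#' applies a parsimonious enzyme usage criterion: it minimizes total
#' usage `sum(u^a) + sum(u^b)` over all usage variables subject to all
#' Step-1 constraints and the relaxed agreement cap
#' `sum_i |u^b_i - r_i u^a_i| <= obj_1 (1 + eps)`.
#'
#' Absolute values are linearized with nonnegative deviation variables
#' `d_i >= +/-(u^b_i - r_i u^a_i)`. If Step 1 is infeasible the
#' activation constraints are dropped first (logged); if the program is
#' still infeasible, the constraint group restoring feasibility is
#' reported in the error.
#'
#' @param ext an `extended_model`.
#' @param ratios named numeric vector from [enzyme_ratios()] (group id ->
#'   ratio); may be empty, in which case Step 1 is trivially 0.
#' @param constraints an `exchange_constraint_set` or `NULL`.
#' @param params a [marge_params()] object.
#' @return object of class `marge_solution`: `flux_a`, `flux_b`
#'   (`flux_state` objects), `obj1`, `obj2` (total usage), `agreement`
#'   (agreement value of the returned solution), `status`, `log`.
#' @export
marge <- function(ext, ratios, constraints = NULL, params = marge_params()) {
  stopifnot(inherits(ext, "extended_model"), inherits(params, "marge_params"))
  if (length(ratios) && any(ratios <= 0)) stop("enzyme ratios must be positive")
  bad <- setdiff(names(ratios), names(ext$groups))
  if (length(bad)) stop(sprintf("unknown enzyme groups in ratios: %s", paste(bad, collapse = ", ")))

  n <- ncol(ext$S_ext)
  vars <- ext$vars
  usage_idx <- which(vars$kind == "usage")
  # deviation variables: one per usage column whose group has a ratio
  dev_idx <- which(vars$kind == "usage" & vars$group %in% names(ratios))
  nd <- length(dev_idx)
  N <- 2L * n + nd
  log <- character(0)

  lb <- c(vars$lb, vars$lb, rep(0, nd))
  dmax <- if (nd) vars$ub[dev_idx] + ratios[vars$group[dev_idx]] * vars$ub[dev_idx] + 1 else numeric(0)
  ub <- c(vars$ub, vars$ub, dmax)

  pad <- function(row, cond) {
    out <- numeric(N)
    out[seq_len(n) + (cond == "b") * n] <- row
    out
  }

  base <- base_lp_rows(ext)
  A_eq <- rbind(cbind(base$A_eq, matrix(0, nrow(base$A_eq), N - n)),
                cbind(matrix(0, nrow(base$A_eq), n), base$A_eq,
                      matrix(0, nrow(base$A_eq), nd)))
  b_eq <- c(base$b_eq, base$b_eq)
  A_ub <- NULL; b_ub <- NULL
  add_ub <- function(row, rhs) { A_ub <<- rbind(A_ub, row); b_ub <<- c(b_ub, rhs) }

  if (!is.null(base$A_ub))
    for (cond in c("a", "b"))
      for (k in seq_len(nrow(base$A_ub)))
        add_ub(pad(base$A_ub[k, ], cond), base$b_ub[k])

  # exchange direction/floor rows
  for (cond in c("a", "b"))
    for (ct in exchange_condition_constraints(constraints, ext, cond)) {
      row <- reaction_row(ext, as.list(ct$weights))
      if (ct$dir == "<=") add_ub(pad(row, cond), ct$rhs) else add_ub(-pad(row, cond), -ct$rhs)
    }

  # between-condition magnitude-ratio rows
  if (!is.null(constraints) && nrow(constraints)) {
    for (i in seq_len(nrow(constraints))) {
      if (is.na(constraints$ratio_low[i])) next
      s <- if (constraints$direction_a[i] == "secretion") 1 else -1
      row <- s * reaction_row(ext, stats::setNames(list(1), constraints$exchange_id[i]))
      # m_b <= high * m_a ; m_b >= low * m_a
      add_ub(pad(row, "b") - constraints$ratio_high[i] * pad(row, "a"), 0)
      add_ub(constraints$ratio_low[i] * pad(row, "a") - pad(row, "b"), 0)
    }
  }

  # biomass floors: fraction of each condition's own constrained FBA maximum
  if (!is.null(ext$base$biomass_id)) {
    for (cond in c("a", "b")) {
      gf <- params[[paste0("growth_frac_", cond)]]
      if (is.null(gf)) next
      fmax <- fba(ext, ext$base$biomass_id, "max",
                  extra_constraints = exchange_condition_constraints(constraints, ext, cond))
      if (fmax$status != "optimal")
        stop(errorCondition(
          sprintf("condition %s infeasible under its exchange constraints alone", cond),
          class = c("marge_infeasible", "error")))
      row <- reaction_row(ext, stats::setNames(list(1), ext$base$biomass_id))
      add_ub(-pad(row, cond), -gf * fmax$objective)
      log <- c(log, sprintf("biomass floor %s: %.6g (%.0f%% of constrained max %.6g)",
                            cond, gf * fmax$objective, 100 * gf, fmax$objective))
    }
  }

  # total-usage budget (constant total metabolic flux) per condition
  if (!is.null(params$total_flux_budget)) {
    for (cond in c("a", "b")) {
      row <- numeric(N)
      row[usage_idx + (cond == "b") * n] <- 1
      A_eq <- rbind(A_eq, row); b_eq <- c(b_eq, params$total_flux_budget)
    }
  }

  # activation rows: total usage of each measured group >= u_min, both sides
  activation_rows <- NULL; activation_rhs <- NULL
  if (params$activation && length(ratios)) {
    for (gid in names(ratios)) {
      gi <- which(vars$group %in% gid)
      for (cond in c("a", "b")) {
        row <- numeric(N); row[gi + (cond == "b") * n] <- -1
        activation_rows <- rbind(activation_rows, row)
        activation_rhs <- c(activation_rhs, -params$u_min)
      }
    }
  }

  # deviation linearization rows
  if (nd) {
    for (k in seq_len(nd)) {
      i <- dev_idx[k]; r <- unname(ratios[vars$group[i]])
      row1 <- numeric(N); row1[n + i] <- 1; row1[i] <- -r; row1[2L * n + k] <- -1
      add_ub(row1, 0)
      row2 <- numeric(N); row2[n + i] <- -1; row2[i] <- r; row2[2L * n + k] <- -1
      add_ub(row2, 0)
    }
  }

  obj1_coef <- numeric(N); if (nd) obj1_coef[2L * n + seq_len(nd)] <- 1

  solve_step1 <- function(with_activation) {
    Au <- A_ub; bu <- b_ub
    if (with_activation && !is.null(activation_rows)) {
      Au <- rbind(Au, activation_rows); bu <- c(bu, activation_rhs)
    }
    list(sol = solve_lp(obj1_coef, A_eq = A_eq, b_eq = b_eq, A_ub = Au, b_ub = bu,
                        lb = lb, ub = ub),
         A_ub = Au, b_ub = bu)
  }

  s1 <- solve_step1(TRUE)
  if (s1$sol$status != "optimal" && params$activation && !is.null(activation_rows)) {
    log <- c(log, "Step 1 infeasible with activation constraints; retrying without them")
    s1 <- solve_step1(FALSE)
  }
  if (s1$sol$status != "optimal") {
    group <- diagnose_infeasibility(ext, constraints, A_eq, b_eq, obj1_coef, lb, ub, N, n)
    stop(errorCondition(
      sprintf("MARGE Step 1 infeasible (violated constraint group: %s)", group),
      class = c("marge_infeasible", "error")))
  }
  obj1 <- s1$sol$objective

  # Step 2: parsimonious usage under relaxed agreement cap
  cap_row <- obj1_coef
  A2 <- rbind(s1$A_ub, cap_row)
  b2 <- c(s1$b_ub, obj1 * (1 + params$step2_tol) + 1e-9)
  obj2_coef <- numeric(N)
  obj2_coef[usage_idx] <- 1; obj2_coef[usage_idx + n] <- 1
  s2 <- solve_lp(obj2_coef, A_eq = A_eq, b_eq = b_eq, A_ub = A2, b_ub = b2,
                 lb = lb, ub = ub)
  if (s2$status != "optimal")
    stop(errorCondition("MARGE Step 2 infeasible (numerical)", class = c("marge_infeasible", "error")))

  x <- s2$x
  xa <- x[seq_len(n)]; xb <- x[n + seq_len(n)]
  agreement <- if (nd) sum(abs(xb[dev_idx] - ratios[vars$group[dev_idx]] * xa[dev_idx])) else 0

  mk_state <- function(xc) {
    xv <- stats::setNames(xc, vars$name)
    structure(list(flux = reconstruct_fluxes(ext, xc),
                   usage = xv[usage_idx], objective = NA_real_, status = "optimal"),
              class = "flux_state")
  }
  structure(list(flux_a = mk_state(xa), flux_b = mk_state(xb),
                 obj1 = obj1, obj2 = s2$objective, agreement = agreement,
                 ratios = ratios, params = params, status = "optimal", log = log),
            class = "marge_solution")
}

# locate which constraint family breaks feasibility (best-effort diagnosis)
diagnose_infeasibility <- function(ext, constraints, A_eq, b_eq, obj, lb, ub, N, n) {
  base <- base_lp_rows(ext)
  try_rows <- function(extra) {
    A_ub <- NULL; b_ub <- NULL
    if (!is.null(base$A_ub))
      for (cond in c(0L, n))
        for (k in seq_len(nrow(base$A_ub))) {
          row <- numeric(N); row[seq_len(n) + cond] <- base$A_ub[k, ]
          A_ub <- rbind(A_ub, row); b_ub <- c(b_ub, base$b_ub[k])
        }
    for (e in extra) { A_ub <- rbind(A_ub, e$row); b_ub <- c(b_ub, e$rhs) }
    solve_lp(obj, A_eq = A_eq, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub,
             lb = lb, ub = ub)$status == "optimal"
  }
  if (try_rows(list())) "exchange constraints (floors/directions/ratios) or growth floors"
  else "model structure (steady state and bounds)"
}

#' @export
print.marge_solution <- function(x, ...) {
  cat(sprintf("<marge_solution> status=%s obj1=%.6g obj2=%.6g agreement=%.6g\n",
              x$status, x$obj1, x$obj2, x$agreement))
  invisible(x)
}

#' Per-pathway share of total absolute flux, per condition
#'
#' Summarizes a two-condition solution as each pathway's share of the
#' summed absolute flux over mapped reactions, and the change in share
#' between conditions — the flux redistribution readout.
#'
#' @param sol a `marge_solution`.
#' @param pathway_map named character vector: reaction id -> pathway label.
#' @return data.frame with `pathway`, `share_a`, `share_b`, `delta`
#'   (`share_b - share_a`); shares sum to 1 per condition over mapped
#'   reactions.
#' @export
pathway_flux_summary <- function(sol, pathway_map) {
  stopifnot(inherits(sol, "marge_solution"))
  if (!length(pathway_map)) stop("empty pathway map")
  rxns <- intersect(names(pathway_map), names(sol$flux_a$flux))
  if (!length(rxns)) stop("pathway map covers no model reactions")
  tot_a <- sum(abs(sol$flux_a$flux[rxns]))
  tot_b <- sum(abs(sol$flux_b$flux[rxns]))
  if (tot_a <= 0 || tot_b <= 0) stop("zero total flux over mapped reactions")
  paths <- unique(unname(pathway_map[rxns]))
  out <- do.call(rbind, lapply(paths, function(p) {
    pr <- rxns[pathway_map[rxns] == p]
    data.frame(pathway = p,
               share_a = sum(abs(sol$flux_a$flux[pr])) / tot_a,
               share_b = sum(abs(sol$flux_b$flux[pr])) / tot_b,
               stringsAsFactors = FALSE)
  }))
  out$delta <- out$share_b - out$share_a
  out
}
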