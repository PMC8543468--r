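# Independent LP oracle used by cross-check tests.
#
# Problems are solved by scipy's HiGHS interior-point/simplex through the
# system python - a different solver from the package's simplex backend -
# and the optimization programs are re-encoded from scratch here with a
# different variable layout (free reaction-flux variables linked to usage
# variables by equality rows; split plus/minus deviation variables instead
# of a single deviation bounded by two inequalities).

oracle_python_script <- function() {
  path <- file.path(tempdir(), "lp_oracle.py")
  if (!file.exists(path)) writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "probs = json.load(open(sys.argv[1]))",
    "out = []",
    "for p in probs:",
    "    n = len(p['c'])",
    "    c = np.array(p['c'], float)",
    "    if p.get('maximize'): c = -c",
    "    kw = {}",
    "    if p.get('Aeq'): kw['A_eq'] = np.array(p['Aeq'], float).reshape(-1, n); kw['b_eq'] = p['beq']",
    "    if p.get('Aub'): kw['A_ub'] = np.array(p['Aub'], float).reshape(-1, n); kw['b_ub'] = p['bub']",
    "    res = linprog(c, bounds=list(zip(p['lb'], p['ub'])), method='highs', **kw)",
    "    obj = None",
    "    if res.status == 0:",
    "        obj = float(res.fun) * (-1 if p.get('maximize') else 1)",
    "    out.append({'status': int(res.status), 'objective': obj,",
    "                'x': (list(map(float, res.x)) if res.x is not None else None)})",
    "json.dump(out, open(sys.argv[2], 'w'))"), path)
  path
}

# batch-solve a list of LPs; each problem: list(c, Aeq, beq, Aub, bub, lb,
# ub, maximize). Matrices are flattened row-major for transport.
oracle_solve_lps <- function(problems) {
  enc <- lapply(problems, function(p) {
    list(c = as.numeric(p$c),
         Aeq = if (!is.null(p$Aeq) && nrow(p$Aeq)) as.numeric(t(p$Aeq)) else NULL,
         beq = if (!is.null(p$beq)) as.numeric(p$beq) else NULL,
         Aub = if (!is.null(p$Aub) && nrow(p$Aub)) as.numeric(t(p$Aub)) else NULL,
         bub = if (!is.null(p$bub)) as.numeric(p$bub) else NULL,
         lb = as.numeric(p$lb), ub = as.numeric(p$ub),
         maximize = isTRUE(p$maximize))
  })
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  jsonlite::write_json(enc, fin, auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2("python", c(oracle_python_script(), fin, fout),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout))
    stop("oracle python call failed: ", paste(status, collapse = "\n"))
  jsonlite::read_json(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

oracle_solve_lp <- function(p) oracle_solve_lps(list(p))[[1]]

# FBA on the UNextended model: free reaction-flux variables v within their
# bounds, S v = 0 - structurally different from the usage-column encoding.
oracle_fba_raw <- function(model, weights, maximize = TRUE, extra = list()) {
  S <- stoichiometric_matrix(model)
  rxns <- colnames(S)
  cvec <- numeric(length(rxns)); names(cvec) <- rxns
  for (r in names(weights)) cvec[r] <- weights[[r]]
  Aub <- NULL; bub <- NULL; Aeq <- S; beq <- numeric(nrow(S))
  for (ct in extra) {
    row <- numeric(length(rxns)); names(row) <- rxns
    for (r in names(ct$weights)) row[r] <- ct$weights[[r]]
    if (ct$dir == "==") { Aeq <- rbind(Aeq, row); beq <- c(beq, ct$rhs) }
    else if (ct$dir == "<=") { Aub <- rbind(Aub, row); bub <- c(bub, ct$rhs) }
    else { Aub <- rbind(Aub, -row); bub <- c(bub, -ct$rhs) }
  }
  oracle_solve_lp(list(c = cvec, Aeq = Aeq, beq = beq, Aub = Aub, bub = bub,
                       lb = vapply(model$reactions, `[[`, 0, "lb")[rxns],
                       ub = vapply(model$reactions, `[[`, 0, "ub")[rxns],
                       maximize = maximize))
}

# Independent re-encoding of the two-step program.
# Variables: [v_a (nr) | u_a (nu) | v_b (nr) | u_b (nu) | dplus | dminus]
# with v free in reaction bounds, v_j = sum(sign * u_ji) link equalities for
# GPR reactions, and u_b - r u_a = dplus - dminus.
oracle_marge <- function(ext, ratios, constraints, params) {
  model <- ext$base
  S <- stoichiometric_matrix(model)
  rxns <- colnames(S); nr <- length(rxns)
  uvars <- which(ext$vars$kind == "usage"); nu <- length(uvars)
  dev <- which(ext$vars$kind == "usage" & ext$vars$group %in% names(ratios))
  nd <- length(dev)
  N <- 2 * (nr + nu) + 2 * nd
  iv <- function(cond) (cond == "b") * (nr + nu) + seq_len(nr)
  iu <- function(cond) (cond == "b") * (nr + nu) + nr + seq_len(nu)
  idp <- 2 * (nr + nu) + seq_len(nd)
  idm <- 2 * (nr + nu) + nd + seq_len(nd)

  rlb <- vapply(model$reactions, `[[`, 0, "lb")[rxns]
  rub <- vapply(model$reactions, `[[`, 0, "ub")[rxns]
  ulb <- rep(0, nu); uub <- ext$vars$ub[uvars]
  big <- 1e7
  lb <- c(rlb, ulb, rlb, ulb, rep(0, 2 * nd))
  ub <- c(rub, uub, rub, uub, rep(big, 2 * nd))

  Aeq <- NULL; beq <- NULL; Aub <- NULL; bub <- NULL
  addeq <- function(row, rhs) { Aeq <<- rbind(Aeq, row); beq <<- c(beq, rhs) }
  addub <- function(row, rhs) { Aub <<- rbind(Aub, row); bub <<- c(bub, rhs) }

  for (cond in c("a", "b")) {
    # steady state over reaction fluxes
    for (k in seq_len(nrow(S))) {
      row <- numeric(N); row[iv(cond)] <- S[k, ]; addeq(row, 0)
    }
    # link v_j to its usage variables for GPR reactions
    for (rid in rxns) {
      rm <- ext$reaction_map[[rid]]
      if (all(ext$vars$kind[rm$idx] == "usage")) {
        row <- numeric(N)
        row[iv(cond)[match(rid, rxns)]] <- 1
        row[iu(cond)[match(rm$idx, uvars)]] <- -rm$sign
        addeq(row, 0)
      }
    }
  }

  # exchange constraints
  if (!is.null(constraints) && nrow(constraints)) {
    for (i in seq_len(nrow(constraints))) {
      ex <- constraints$exchange_id[i]; j <- match(ex, rxns)
      for (cond in c("a", "b")) {
        dir <- constraints[[paste0("direction_", cond)]][i]
        fl <- constraints[[paste0("abs_floor_", cond)]][i]
        if (dir == "uptake") { row <- numeric(N); row[iv(cond)[j]] <- 1; addub(row, -fl) }
        else if (dir == "secretion") { row <- numeric(N); row[iv(cond)[j]] <- -1; addub(row, -fl) }
      }
      if (!is.na(constraints$ratio_low[i])) {
        s <- if (constraints$direction_a[i] == "secretion") 1 else -1
        row <- numeric(N); row[iv("b")[j]] <- s; row[iv("a")[j]] <- -s * constraints$ratio_high[i]
        addub(row, 0)
        row <- numeric(N); row[iv("a")[j]] <- s * constraints$ratio_low[i]; row[iv("b")[j]] <- -s
        addub(row, 0)
      }
    }
  }

  # growth floors from the oracle's own constrained FBA maxima
  if (!is.null(model$biomass_id)) {
    for (cond in c("a", "b")) {
      gf <- params[[paste0("growth_frac_", cond)]]
      if (is.null(gf)) next
      extra <- list()
      if (!is.null(constraints) && nrow(constraints))
        for (i in seq_len(nrow(constraints))) {
          dir <- constraints[[paste0("direction_", cond)]][i]
          fl <- constraints[[paste0("abs_floor_", cond)]][i]
          ex <- constraints$exchange_id[i]
          if (dir == "uptake")
            extra <- c(extra, list(list(weights = stats::setNames(list(1), ex), dir = "<=", rhs = -fl)))
          else if (dir == "secretion")
            extra <- c(extra, list(list(weights = stats::setNames(list(1), ex), dir = ">=", rhs = fl)))
        }
      fmax <- oracle_fba_raw(model, stats::setNames(list(1), model$biomass_id),
                             maximize = TRUE, extra = extra)
      stopifnot(fmax$status == 0)
      row <- numeric(N); row[iv(cond)[match(model$biomass_id, rxns)]] <- -1
      addub(row, -gf * fmax$objective)
    }
  }

  # budget
  if (!is.null(params$total_flux_budget)) {
    for (cond in c("a", "b")) {
      row <- numeric(N); row[iu(cond)] <- 1
      addeq(row, params$total_flux_budget)
    }
  }

  # activation
  if (isTRUE(params$activation)) {
    for (gid in names(ratios)) {
      gi <- which(ext$vars$group[uvars] %in% gid)
      for (cond in c("a", "b")) {
        row <- numeric(N); row[iu(cond)[gi]] <- -1
        addub(row, -params$u_min)
      }
    }
  }

  # u_b - r u_a = dplus - dminus
  if (nd) for (k in seq_len(nd)) {
    i <- match(dev[k], uvars)
    r <- unname(ratios[ext$vars$group[dev[k]]])
    row <- numeric(N)
    row[iu("b")[i]] <- 1; row[iu("a")[i]] <- -r
    row[idp[k]] <- -1; row[idm[k]] <- 1
    addeq(row, 0)
  }

  c1 <- numeric(N); if (nd) c1[c(idp, idm)] <- 1
  s1 <- oracle_solve_lp(list(c = c1, Aeq = Aeq, beq = beq, Aub = Aub, bub = bub,
                             lb = lb, ub = ub))
  if (s1$status != 0) return(list(status = "infeasible"))
  obj1 <- s1$objective

  c2 <- numeric(N); c2[c(iu("a"), iu("b"))] <- 1
  Aub2 <- rbind(Aub, c1); bub2 <- c(bub, obj1 * (1 + params$step2_tol) + 1e-9)
  s2 <- oracle_solve_lp(list(c = c2, Aeq = Aeq, beq = beq, Aub = Aub2, bub = bub2,
                             lb = lb, ub = ub))
  if (s2$status != 0) return(list(status = "infeasible"))
  list(status = "optimal", obj1 = obj1, obj2 = s2$objective, x = s2$x)
}
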