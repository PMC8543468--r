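#' Expand GPR rules into an enzyme-usage extended system
#'
#' Builds the extended stoichiometric system in which every GPR-bearing
#' reaction is replaced by one nonnegative usage variable per (isozyme,
#' direction). A usage column carries the reaction's stoichiometry
#' (negated for the backward direction), so the reaction flux is the
#' signed sum of its usages and mass balance is preserved. Reactions
#' without a GPR — including all exchange reactions — keep a single
#' ordinary flux column with the original bounds.
#'
#' Per-usage bounds are `[0, |corresponding reaction bound|]`; in
#' addition the reaction-level aggregate `lb <= sum(forward) -
#' sum(backward) <= ub` is recorded and enforced in every solve, so any
#' reconstructed flux vector is feasible in the unextended model.
#'
#' A GPR attached to an exchange reaction is ignored with a warning: a
#' boundary pseudo-reaction has no enzyme.
#'
#' @param model a `metabolic_model`.
#' @return object of class `extended_model` with fields `base`, `vars`
#'   (one row per LP column: name, reaction, kind, isozyme, direction,
#'   group, lb, ub), `S_ext` (metabolites x columns), `reaction_map`
#'   (reaction id -> list(idx, sign)), `groups` (usage-group id -> gene
#'   set), `agg` (aggregate bound rows for GPR reactions).
#' @export
extend_model <- function(model) {
  validate_model(model)
  met_ids <- model$metabolites$id
  vars <- list(); cols <- list()
  reaction_map <- list()
  groups <- list()

  for (r in model$reactions) {
    has_gpr <- !is.na(r$gpr)
    if (has_gpr && r$id %in% model$exchange_ids) {
      warning(sprintf("GPR on exchange reaction %s ignored (treated as non-enzymatic)", r$id))
      has_gpr <- FALSE
    }
    if (!has_gpr) {
      vars[[length(vars) + 1L]] <- data.frame(
        name = r$id, reaction = r$id, kind = "flux", isozyme = NA_integer_,
        direction = NA_character_, group = NA_character_, lb = r$lb, ub = r$ub,
        stringsAsFactors = FALSE)
      cols[[length(cols) + 1L]] <- r$stoich
      reaction_map[[r$id]] <- list(idx = length(vars), sign = 1)
      next
    }
    rule <- parse_gpr(r$gpr)
    # deterministic isozyme order: sort by member gene list
    dnf <- rule$dnf[order(vapply(rule$dnf, paste, "", collapse = "+"))]
    idx <- integer(0); sgn <- numeric(0)
    for (i in seq_along(dnf)) {
      gid <- sprintf("%s@%d", r$id, i)
      groups[[gid]] <- dnf[[i]]
      dirs <- "forward"
      if (r$lb < 0) dirs <- c(dirs, "backward")
      for (d in dirs) {
        ub <- if (d == "forward") max(r$ub, 0) else -r$lb
        vars[[length(vars) + 1L]] <- data.frame(
          name = sprintf("%s@%d:%s", r$id, i, substr(d, 1, 1)),
          reaction = r$id, kind = "usage", isozyme = i, direction = d,
          group = gid, lb = 0, ub = ub, stringsAsFactors = FALSE)
        cols[[length(cols) + 1L]] <- if (d == "forward") r$stoich else -r$stoich
        idx <- c(idx, length(vars)); sgn <- c(sgn, if (d == "forward") 1 else -1)
      }
    }
    reaction_map[[r$id]] <- list(idx = idx, sign = sgn)
  }

  vars <- do.call(rbind, vars)
  S_ext <- matrix(0, length(met_ids), nrow(vars),
                  dimnames = list(met_ids, vars$name))
  for (j in seq_along(cols)) S_ext[names(cols[[j]]), j] <- cols[[j]]

  # aggregate reaction-level bound rows for GPR-expanded reactions: the
  # per-usage bounds do not cap the isozyme SUM, nor enforce a positive lb
  agg <- list()
  for (rid in names(reaction_map)) {
    rm <- reaction_map[[rid]]
    if (all(vars$kind[rm$idx] == "usage"))
      agg[[rid]] <- list(reaction = rid, idx = rm$idx, sign = rm$sign,
                         lb = model$reactions[[rid]]$lb,
                         ub = model$reactions[[rid]]$ub)
  }

  structure(list(base = model, vars = vars, S_ext = S_ext,
                 reaction_map = reaction_map, groups = groups, agg = agg),
            class = "extended_model")
}

#' @export
print.extended_model <- function(x, ...) {
  cat(sprintf("<extended_model> %s: %d metabolites x %d columns (%d usage variables, %d enzyme groups)\n",
              x$base$id, nrow(x$S_ext), ncol(x$S_ext),
              sum(x$vars$kind == "usage"), length(x$groups)))
  invisible(x)
}

#' Reconstruct reaction fluxes from an extended-model column vector
#'
#' @param ext an `extended_model`.
#' @param x numeric vector over the extended columns.
#' @return named numeric vector of reaction fluxes.
#' @export
reconstruct_fluxes <- function(ext, x) {
  vapply(ext$reaction_map, function(rm) sum(rm$sign * x[rm$idx]), 0)
}
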