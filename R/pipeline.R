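pipeline_defaults <- function() {
  list(version = 1L,
       model = NULL, expression = NULL, exomet = NULL,
       pathways = NULL, out_dir = ".", verbosity = 1L,
       marge = list(u_min = 0.001, step2_tol = 0.1,
                    growth_frac_a = 0.8, growth_frac_b = 0.8,
                    total_flux_budget = NULL),
       exo = list(tau = 0.5, phi = 0.01),
       reporter = list(n_perm = 10000L, seed = 1L))
}

#' Read a pipeline run configuration
#'
#' YAML file with a versioned schema mirroring the analysis parameters:
#' top-level `model`, `expression`, `exomet`, optional `pathways`
#' (reaction -> pathway TSV), `out_dir`, `verbosity`, and blocks `marge`
#' (`u_min` 0.001, `step2_tol` 0.1, `growth_frac_a`/`_b` 0.8,
#' `total_flux_budget`), `exo` (`tau` 0.5, `phi` 0.01) and `reporter`
#' (`n_perm` 10000, `seed`). Unknown keys are errors, protecting against
#' silently ignored typos; every default can be overridden.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("config file not found: %s", path),
                        class = c("input_error", "error")))
  raw <- yaml::read_yaml(path)
  merge_block <- function(def, got, where) {
    unknown <- setdiff(names(got), names(def))
    if (length(unknown))
      stop(errorCondition(
        sprintf("unknown config key%s in %s: %s", if (length(unknown) > 1) "s" else "",
                where, paste(unknown, collapse = ", ")),
        class = c("input_error", "error")))
    for (k in names(got)) def[k] <- list(got[[k]])  # keep explicit NULLs
    def
  }
  def <- pipeline_defaults()
  for (blk in c("marge", "exo", "reporter"))
    if (!is.null(raw[[blk]])) {
      def[[blk]] <- merge_block(def[[blk]], raw[[blk]], blk)
      raw[[blk]] <- NULL
    }
  cfg <- merge_block(def, raw, "top level")
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' Serialization is the inverse of [read_run_config()]:
#' serialize-parse-serialize is idempotent.
#'
#' @param config a `run_config` (or plain list with the same shape).
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full two-condition analysis pipeline
#'
#' Reads the model, expression and exometabolome tables named in the
#' config; derives exchange constraints; aggregates expression to enzyme
#' ratios; solves the two-step program; and, with gene q-values as
#' gene-level statistics, runs the reporter-metabolite analysis over
#' GPR-derived metabolite gene sets. Artifacts written to `out_dir`:
#' `solution.json`, `constraints.json`, `pathway_summary.tsv` (when a
#' pathway map is configured), `reporter_*.tsv` and `run.log`.
#'
#' @param config a `run_config` from [read_run_config()], or a path to a
#'   YAML config.
#' @return invisibly, a list with `solution`, `constraints`, `reporter`,
#'   `artifacts` (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  log <- c(sprintf("run started %s", format(Sys.time())),
           paste0("config: ", yaml::as.yaml(unclass(config))))
  say <- function(...) if (isTRUE(config$verbosity >= 1L)) message(sprintf(...))

  for (f in c("model", "expression", "exomet")) {
    if (is.null(config[[f]]))
      stop(errorCondition(sprintf("config field '%s' is required", f),
                          class = c("input_error", "error")))
    if (!file.exists(config[[f]]))
      stop(errorCondition(sprintf("%s file not found: %s", f, config[[f]]),
                          class = c("input_error", "error")))
  }

  model <- read_model(config$model)
  ext <- extend_model(model)
  expression <- utils::read.delim(config$expression, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "log2fc") %in% names(expression)))
    stop(errorCondition("expression table needs columns gene_id, log2fc[, qvalue]",
                        class = c("input_error", "error")))
  exomet <- read_exomet_tsv(config$exomet)

  say("building exchange constraints (tau=%g, phi=%g)", config$exo$tau, config$exo$phi)
  constraints <- build_exchange_constraints(exomet, ext,
                                            tau = config$exo$tau, phi = config$exo$phi)
  log <- c(log, attr(constraints, "log"))

  ratios <- enzyme_ratios(expression, ext)
  say("%d enzyme groups with measured relative expression", length(ratios))

  params <- marge_params(u_min = config$marge$u_min,
                         step2_tol = config$marge$step2_tol,
                         growth_frac_a = config$marge$growth_frac_a,
                         growth_frac_b = config$marge$growth_frac_b,
                         total_flux_budget = config$marge$total_flux_budget)
  sol <- marge(ext, ratios, constraints, params)
  log <- c(log, sol$log,
           sprintf("solver status: %s; obj1=%.8g; obj2=%.8g; agreement=%.8g",
                   sol$status, sol$obj1, sol$obj2, sol$agreement))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  f_sol <- file.path(config$out_dir, "solution.json")
  write_solution_json(sol, f_sol)
  artifacts <- c(artifacts, f_sol)
  f_con <- file.path(config$out_dir, "constraints.json")
  write_constraints_json(constraints, f_con)
  artifacts <- c(artifacts, f_con)

  if (!is.null(config$pathways)) {
    pm <- utils::read.delim(config$pathways, stringsAsFactors = FALSE)
    pmap <- stats::setNames(pm$pathway, pm$reaction_id)
    ps <- pathway_flux_summary(sol, pmap)
    f_ps <- file.path(config$out_dir, "pathway_summary.tsv")
    utils::write.table(ps, f_ps, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, f_ps)
  }

  rep_res <- NULL
  if ("qvalue" %in% names(expression)) {
    gstats <- data.frame(gene_id = expression$gene_id,
                         pvalue = expression$qvalue,
                         log2fc = expression$log2fc)
    sets <- metabolite_gene_sets(model)
    if (length(sets)) {
      say("reporter analysis over %d metabolite gene sets (%d permutations)",
          length(sets), config$reporter$n_perm)
      rep_res <- reporter_analysis(gstats, sets,
                                   n_perm = config$reporter$n_perm,
                                   seed = config$reporter$seed)
      artifacts <- c(artifacts, write_reporter_tsv(rep_res, config$out_dir))
    }
  }

  f_log <- file.path(config$out_dir, "run.log")
  writeLines(log, f_log)
  artifacts <- c(artifacts, f_log)
  say("wrote %d artifacts to %s", length(artifacts), config$out_dir)
  invisible(list(solution = sol, constraints = constraints,
                 reporter = rep_res, artifacts = artifacts))
}

#' Write a two-condition solution to JSON
#'
#' @param sol a `marge_solution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_solution_json <- function(sol, path) {
  obj <- list(status = sol$status,
              objectives = list(step1 = sol$obj1, step2 = sol$obj2,
                                agreement = sol$agreement),
              params = unclass(sol$params),
              ratios = as.list(sol$ratios),
              flux = lapply(names(sol$flux_a$flux), function(r)
                list(reaction = r, flux_a = unname(sol$flux_a$flux[[r]]),
                     flux_b = unname(sol$flux_b$flux[[r]]))),
              usage = lapply(names(sol$flux_a$usage), function(u)
                list(variable = u, usage_a = unname(sol$flux_a$usage[[u]]),
                     usage_b = unname(sol$flux_b$usage[[u]]))),
              log = as.list(sol$log))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write fluxes of a solution as TSV
#'
#' @param sol a `marge_solution`.
#' @param path output TSV with columns `reaction_id`, `flux_a`, `flux_b`.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(sol, path) {
  df <- data.frame(reaction_id = names(sol$flux_a$flux),
                   flux_a = unname(sol$flux_a$flux),
                   flux_b = unname(sol$flux_b$flux))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
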