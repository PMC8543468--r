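#' Deterministic branched toy metabolic network
#'
#' A fixed 12-reaction, 10-metabolite network used throughout the test
#' suite: glucose uptake feeding glycolysis (a two-gene enzyme complex),
#' a fermentative branch secreting lactate (an isozyme pair), an
#' oxidative branch consuming oxygen with a high ATP yield, a reversible
#' glutamine transporter (two isozymes), and a biomass sink consuming
#' pyruvate, ATP and glutamine. Four reactions carry GPR rules; the
#' transporter is the reversible one.
#'
#' The network is glutamine-limited at full glucose uptake, so its FBA
#' optimum engages both branches — flux can shift between fermentation
#' and respiration without changing the optimum structure, which is the
#' regime the relative-expression fit is designed to probe.
#'
#' @return a `metabolic_model`.
#' @export
make_toy_model <- function() {
  mets <- data.frame(
    id = c("glc_e", "glc_c", "pyr_c", "lac_c", "lac_e",
           "atp_c", "o2_c", "o2_e", "gln_c", "gln_e"),
    name = c("glucose (extracellular)", "glucose", "pyruvate", "lactate",
             "lactate (extracellular)", "ATP", "oxygen", "oxygen (extracellular)",
             "glutamine", "glutamine (extracellular)"),
    compartment = c("e", "c", "c", "c", "e", "c", "c", "e", "c", "e"),
    stringsAsFactors = FALSE)
  rx <- function(id, stoich, lb, ub, gpr = NA_character_)
    list(id = id, stoich = stoich, lb = lb, ub = ub, gpr = gpr)
  reactions <- list(
    rx("EX_glc", c(glc_e = -1), -10, 0),
    rx("GLCt",   c(glc_e = -1, glc_c = 1), 0, 1000),
    rx("GLYC",   c(glc_c = -1, pyr_c = 2, atp_c = 2), 0, 1000, "glyA and glyB"),
    rx("LDH",    c(pyr_c = -1, lac_c = 1), 0, 1000, "ldhA or ldhB"),
    rx("LACt",   c(lac_c = -1, lac_e = 1), 0, 1000),
    rx("EX_lac", c(lac_e = -1), 0, 1000),
    rx("OXP",    c(pyr_c = -1, o2_c = -3, atp_c = 15), 0, 1000, "oxp1"),
    rx("O2t",    c(o2_e = -1, o2_c = 1), 0, 1000),
    rx("EX_o2",  c(o2_e = -1), -1000, 0),
    rx("GLNt",   c(gln_e = -1, gln_c = 1), -1000, 1000, "glnT1 or glnT2"),
    rx("EX_gln", c(gln_e = -1), -5, 1000),
    rx("BIOMASS", c(pyr_c = -1, atp_c = -10, gln_c = -0.5), 0, 1000))
  metabolic_model(id = "toy_branched",
                  metabolites = mets, reactions = reactions,
                  exchange_ids = c("EX_glc", "EX_lac", "EX_o2", "EX_gln"),
                  biomass_id = "BIOMASS")
}

#' Pathway labels for the toy network
#'
#' @return named character vector: reaction id -> pathway label.
#' @export
toy_pathways <- function() {
  c(GLYC = "glycolysis",
    LDH = "fermentative", LACt = "fermentative", EX_lac = "fermentative",
    OXP = "oxidative", O2t = "oxidative", EX_o2 = "oxidative")
}

# genes of each regulable branch of the toy network
toy_branch_genes <- function() {
  list(fermentative = c("ldhA", "ldhB"),
       oxidative = "oxp1",
       glycolysis = c("glyA", "glyB"))
}

# exchange reaction metabolite mapping and pure-medium composition
toy_medium <- function() {
  data.frame(metabolite_id = c("glc", "lac", "gln"),
             exchange_id = c("EX_glc", "EX_lac", "EX_gln"),
             media = c(25, 0, 12), stringsAsFactors = FALSE)
}

#' Define a paired-condition simulation scenario on the toy network
#'
#' Condition a is the reference state; condition b carries the planted
#' perturbation: per-branch expression fold changes and per-exchange
#' magnitude ratios. The defaults plant a 2x upregulated fermentative
#' branch with a matching doubling of lactate secretion — the
#' qualitative template of a glycolytic shift between two cell states.
#'
#' @param seed RNG seed for the noise draws.
#' @param regulation named numeric: branch -> planted log2 fold change
#'   (b vs a) applied to the branch's genes.
#' @param exchange_shifts named list: exchange id -> list(direction,
#'   ratio), the planted magnitude ratio of condition b versus a.
#' @param sigma log-normal noise sigma on simulated abundances
#'   (default 0.1).
#' @param sigma_expr Gaussian noise sd on simulated log2 fold changes
#'   (default 0.1).
#' @param substrate_uptake fixed glucose uptake of the ground-truth flux
#'   pair (default 10, the exchange bound).
#' @return object of class `toy_scenario`.
#' @export
toy_scenario <- function(seed = 1L,
                         regulation = c(fermentative = 1),
                         exchange_shifts = list(EX_lac = list(direction = "secretion", ratio = 2)),
                         sigma = 0.1, sigma_expr = 0.1,
                         substrate_uptake = 10) {
  stopifnot(sigma >= 0, sigma_expr >= 0, substrate_uptake > 0)
  bad <- setdiff(names(regulation), names(toy_branch_genes()))
  if (length(bad)) stop(sprintf("unknown branches: %s", paste(bad, collapse = ", ")))
  structure(list(seed = as.integer(seed), regulation = regulation,
                 exchange_shifts = exchange_shifts, sigma = sigma,
                 sigma_expr = sigma_expr, substrate_uptake = substrate_uptake,
                 model = make_toy_model()),
            class = "toy_scenario")
}

# parsimonious reference solve: maximize biomass under extra constraints,
# then minimize total usage at the fixed optimum
pfba_reference <- function(ext, extra = list()) {
  top <- fba(ext, ext$base$biomass_id, "max", extra_constraints = extra)
  if (top$status != "optimal") return(NULL)
  # hold biomass at the optimum with a hair of slack: an exact equality at
  # the LP optimum is numerically brittle for the simplex
  fix <- c(extra, list(list(weights = stats::setNames(list(1), ext$base$biomass_id),
                            dir = ">=", rhs = top$objective - 1e-9)))
  # minimize the sum of usage columns at the fixed biomass optimum
  rows <- base_lp_rows(ext)
  n <- ncol(ext$S_ext)
  obj <- ifelse(ext$vars$kind == "usage", 1, 0)
  A_eq <- rows$A_eq; b_eq <- rows$b_eq; A_ub <- rows$A_ub; b_ub <- rows$b_ub
  for (ct in fix) {
    row <- if (!is.null(ct$row)) ct$row else reaction_row(ext, as.list(ct$weights))
    if (ct$dir == "==") { A_eq <- rbind(A_eq, row); b_eq <- c(b_eq, ct$rhs) }
    else if (ct$dir == "<=") { A_ub <- rbind(A_ub, row); b_ub <- c(b_ub, ct$rhs) }
    else { A_ub <- rbind(A_ub, -row); b_ub <- c(b_ub, -ct$rhs) }
  }
  sol <- solve_lp(obj, A_eq = A_eq, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub,
                  lb = ext$vars$lb, ub = ext$vars$ub)
  if (sol$status != "optimal") return(NULL)
  flux_state_from_solution(ext, list(status = "optimal", x = sol$x,
                                     objective = top$objective))
}

#' Simulate a paired-condition expression and exometabolome data set
#'
#' Solves the scenario's ground-truth flux pair (parsimonious FBA for
#' condition a at fixed substrate uptake; condition b re-solved with the
#' planted exchange ratios imposed), verifies the planted shifts are
#' realizable, and emits noisy observations: gene log2 fold changes
#' (planted regulation plus Gaussian noise, with rank-based synthetic
#' q-values under which exactly the planted genes pass q < 0.1) and
#' spent-medium abundances (`media + flux x 1 time unit`, log-normal
#' multiplicative noise, significance flags from the noise model).
#'
#' @param scenario a [toy_scenario()].
#' @param out_dir optional directory; when given, writes `model.xml`,
#'   `model.json`, `expression.tsv`, `exomet.tsv` and `truth.json`.
#' @return list with `expression`, `exomet` (data.frames), `truth`
#'   (flux/usage vectors per condition plus objective), `scenario`.
#' @export
simulate_condition_pair <- function(scenario, out_dir = NULL) {
  stopifnot(inherits(scenario, "toy_scenario"))
  model <- scenario$model
  ext <- extend_model(model)

  fix_glc <- list(list(weights = list(EX_glc = 1), dir = "==",
                       rhs = -scenario$substrate_uptake))
  truth_a <- pfba_reference(ext, fix_glc)
  if (is.null(truth_a)) stop("scenario infeasible: no reference flux state")

  extra_b <- fix_glc
  for (ex in names(scenario$exchange_shifts)) {
    sh <- scenario$exchange_shifts[[ex]]
    extra_b <- c(extra_b, list(list(weights = stats::setNames(list(1), ex),
                                    dir = "==", rhs = sh$ratio * truth_a$flux[[ex]])))
  }
  truth_b <- pfba_reference(ext, extra_b)
  if (is.null(truth_b))
    stop("planted exchange shifts are not realizable in the toy network")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(scenario$seed)

  # expression table: planted branch genes + null genes, rank-based q-values
  branch_genes <- toy_branch_genes()
  genes <- sort(unique(unlist(lapply(model$reactions, function(r)
    if (!is.na(r$gpr)) gpr_genes(parse_gpr(r$gpr))))))
  lfc <- stats::setNames(stats::rnorm(length(genes), 0, scenario$sigma_expr), genes)
  planted <- character(0)
  for (br in names(scenario$regulation)) {
    g <- branch_genes[[br]]
    lfc[g] <- lfc[g] + scenario$regulation[[br]]
    planted <- c(planted, g)
  }
  qv <- stats::setNames(numeric(length(genes)), genes)
  pl <- names(qv) %in% planted
  if (any(pl))
    qv[pl] <- 0.001 + 0.05 * (rank(-abs(lfc[pl])) - 1) / max(1, sum(pl))
  if (any(!pl))
    qv[!pl] <- 0.2 + 0.7 * (rank(-abs(lfc[!pl])) - 1) / max(1, sum(!pl))
  expression <- data.frame(gene_id = genes, log2fc = unname(lfc[genes]),
                           qvalue = unname(qv[genes]), stringsAsFactors = FALSE)

  # exometabolome: concentrations after one time unit of the truth fluxes
  med <- toy_medium()
  noisy <- function(x) if (scenario$sigma > 0)
    x * exp(stats::rnorm(length(x), 0, scenario$sigma)) else x
  ab_a <- noisy(med$media + vapply(med$exchange_id, function(e) truth_a$flux[[e]], 0))
  ab_b <- noisy(med$media + vapply(med$exchange_id, function(e) truth_b$flux[[e]], 0))
  ab_m <- noisy(med$media)
  thr <- function(x, y) 3 * scenario$sigma * pmax(x, y, 1)
  exomet <- data.frame(
    metabolite_id = med$metabolite_id, exchange_id = med$exchange_id,
    abundance_a = ab_a, abundance_b = ab_b, abundance_media = ab_m,
    sig_vs_media_a = abs(ab_a - ab_m) > thr(ab_a, ab_m),
    sig_vs_media_b = abs(ab_b - ab_m) > thr(ab_b, ab_m),
    sig_between = abs(ab_b - ab_a) > thr(ab_a, ab_b),
    stringsAsFactors = FALSE)

  truth <- list(flux_a = truth_a$flux, flux_b = truth_b$flux,
                usage_a = truth_a$usage, usage_b = truth_b$usage,
                biomass_a = truth_a$objective, biomass_b = truth_b$objective)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_model_sbml(model, file.path(out_dir, "model.xml"))
    write_model_json(model, file.path(out_dir, "model.json"))
    utils::write.table(expression, file.path(out_dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(exomet, file.path(out_dir, "exomet.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(lapply(truth, as.list), file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(expression = expression, exomet = exomet, truth = truth, scenario = scenario)
}

#' Deterministically perturbed variant of the toy network
#'
#' Rescales exchange bounds, the oxidative ATP yield and the biomass
#' composition by seed-determined factors while keeping the network
#' structure (and GPR rules) fixed. Used to exercise the solvers on a
#' family of related small instances.
#'
#' @param seed integer seed selecting the variant; `0` returns the
#'   unperturbed toy network.
#' @return a `metabolic_model`.
#' @export
toy_model_variant <- function(seed) {
  model <- make_toy_model()
  if (seed == 0L) return(model)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  model$reactions$EX_glc$lb <- -stats::runif(1, 6, 12)
  model$reactions$EX_gln$lb <- -stats::runif(1, 3, 7)
  model$reactions$OXP$stoich[["atp_c"]] <- stats::runif(1, 12, 18)
  model$reactions$BIOMASS$stoich[["atp_c"]] <- -stats::runif(1, 8, 12)
  model$reactions$BIOMASS$stoich[["gln_c"]] <- -stats::runif(1, 0.3, 0.7)
  validate_model(model)
  model
}

#' Randomized feasible MARGE instance on a toy-network variant
#'
#' Builds a model variant, derives exchange constraints from the
#' variant's own noiseless simulated exometabolome (so the constraint set
#' is satisfied by the variant's ground-truth flux pair), and draws
#' random enzyme ratios for a random subset of enzyme groups. Because a
#' rescaled variant does not always accommodate the default planted
#' lactate doubling together with the biomass floors, the planted ratio
#' backs off along a fixed ladder (2, 1.5, 1.2, 1) until the instance is
#' solvable; the ladder is part of the generator's definition, keeping
#' every emitted instance feasible by construction. The result feeds
#' solver cross-checks and property tests.
#'
#' @param seed integer seed.
#' @return list with `ext`, `ratios`, `constraints`, `params`,
#'   `planted_ratio`.
#' @export
random_marge_instance <- function(seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)

  model <- toy_model_variant(seed)
  ext <- extend_model(model)
  set.seed(seed + 1000L)
  groups <- names(ext$groups)
  k <- sample(seq_along(groups), 1L)
  chosen <- sample(groups, k)
  ratios <- stats::setNames(2^stats::runif(k, -2, 2), chosen)
  params <- marge_params()

  for (planted in c(2, 1.5, 1.2, 1)) {
    sc <- toy_scenario(seed = seed, sigma = 0, sigma_expr = 0,
                       exchange_shifts = list(EX_lac = list(direction = "secretion",
                                                            ratio = planted)),
                       substrate_uptake = -model$reactions$EX_glc$lb)
    sc$model <- model
    sim <- tryCatch(simulate_condition_pair(sc), error = function(e) NULL)
    if (is.null(sim)) next
    constraints <- build_exchange_constraints(sim$exomet, ext)
    ok <- tryCatch({
      marge(ext, ratios, constraints, params)
      TRUE
    }, marge_infeasible = function(e) FALSE)
    if (ok)
      return(list(ext = ext, ratios = ratios, constraints = constraints,
                  params = params, planted_ratio = planted))
  }
  stop("no feasible instance found for this seed")  # ratio 1 should always work
}
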