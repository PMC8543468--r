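test_that("enzyme ratios aggregate member genes geometrically", {
  ext <- toy_ext()
  # single-gene isozyme: r = 2^lfc
  ex1 <- data.frame(gene_id = "oxp1", log2fc = 1, qvalue = 0.01)
  r <- enzyme_ratios(ex1, ext)
  expect_equal(unname(r[["OXP@1"]]), 2.0)
  # two-gene complex: geometric mean of 4 and 1
  ex2 <- data.frame(gene_id = c("glyA", "glyB"), log2fc = c(2, 0), qvalue = 0.01)
  r2 <- enzyme_ratios(ex2, ext)
  expect_equal(unname(r2[["GLYC@1"]]), 2.0)
  # min rule: limited by the weakest subunit
  r2m <- enzyme_ratios(ex2, ext, aggregation = "min")
  expect_equal(unname(r2m[["GLYC@1"]]), 1.0)
  # unmeasured groups are absent
  expect_false("LDH@1" %in% names(r2))
  # q-value gate
  ex3 <- data.frame(gene_id = "oxp1", log2fc = 1, qvalue = 0.5)
  expect_length(enzyme_ratios(ex3, ext), 0L)
})

all_one_ratios <- function(ext) setNames(rep(1, length(ext$groups)), names(ext$groups))

test_that("symmetric program: all ratios one gives obj1 = 0 and u_a = u_b", {
  ext <- toy_ext()
  sol <- marge(ext, all_one_ratios(ext), constraints = NULL)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$obj1, 0, tolerance = 1e-9)
  expect_lt(max(abs(sol$flux_a$usage - sol$flux_b$usage)), 1e-6)
})

test_that("a doubled branch ratio moves the branch flux ratio toward 2", {
  sim <- noiseless_sim()
  ext <- toy_ext()
  cs <- build_exchange_constraints(sim$exomet, ext)
  ratios <- enzyme_ratios(sim$expression, ext)
  expect_setequal(names(ratios), c("LDH@1", "LDH@2"))
  sol <- marge(ext, ratios, cs)
  expect_equal(sol$status, "optimal")
  ldh_a <- sol$flux_a$flux[["LDH"]]; ldh_b <- sol$flux_b$flux[["LDH"]]
  expect_gt(ldh_a, 0)
  expect_equal(ldh_b / ldh_a, 2, tolerance = 1e-3)
  ps <- pathway_flux_summary(sol, c(LDH = "fermentative", OXP = "oxidative"))
  expect_gt(ps$delta[ps$pathway == "fermentative"], 0)
})

test_that("the returned solution respects the step-2 agreement cap", {
  sim <- noiseless_sim()
  ext <- toy_ext()
  cs <- build_exchange_constraints(sim$exomet, ext)
  ratios <- enzyme_ratios(sim$expression, ext)
  sol <- marge(ext, ratios, cs, marge_params(step2_tol = 0.1))
  expect_lte(sol$agreement, sol$obj1 * 1.1 + 1e-6)
})

test_that("obj1 is non-decreasing as enzymes enter the objective on a fixed feasible set", {
  ext <- toy_ext()
  params <- marge_params(activation = FALSE)  # keep the feasible set fixed
  sim <- noiseless_sim()
  cs <- build_exchange_constraints(sim$exomet, ext)
  set.seed(5)
  full <- setNames(2^runif(length(ext$groups), -1.5, 1.5), names(ext$groups))
  ord <- sample(names(full))
  prev <- -Inf
  for (k in 1:4) {
    sol <- marge(ext, full[ord[seq_len(k)]], cs, params)
    expect_gte(sol$obj1, prev - 1e-7)
    prev <- sol$obj1
  }
})

test_that("scaling bounds, floors and thresholds by k scales the solution by k", {
  k <- 3
  m1 <- make_toy_model()
  m2 <- m1
  for (r in names(m2$reactions)) {
    m2$reactions[[r]]$lb <- m2$reactions[[r]]$lb * k
    m2$reactions[[r]]$ub <- m2$reactions[[r]]$ub * k
  }
  e1 <- extend_model(m1); e2 <- extend_model(m2)
  sim <- noiseless_sim()
  ratios <- enzyme_ratios(sim$expression, e1)
  cs1 <- build_exchange_constraints(sim$exomet, e1)
  cs2 <- cs1
  cs2$abs_floor_a <- cs2$abs_floor_a * k
  cs2$abs_floor_b <- cs2$abs_floor_b * k
  s1 <- marge(e1, ratios, cs1, marge_params(u_min = 0.001))
  s2 <- marge(e2, ratios, cs2, marge_params(u_min = 0.001 * k))
  expect_equal(s2$obj1, k * s1$obj1, tolerance = 1e-6)
  expect_equal(s2$obj2, k * s1$obj2, tolerance = 1e-6)
  expect_equal(unname(s2$flux_a$flux["BIOMASS"]), k * unname(s1$flux_a$flux["BIOMASS"]),
               tolerance = 1e-6)
})

test_that("infeasible activation constraints are dropped with a log entry", {
  m <- make_toy_model()
  m$reactions$EX_lac$ub <- 0  # lactate cannot leave: LDH cannot run
  ext <- extend_model(m)
  ratios <- c("LDH@1" = 2, "LDH@2" = 2)
  sol <- marge(ext, ratios, NULL, marge_params())
  expect_equal(sol$status, "optimal")
  expect_match(paste(sol$log, collapse = " "), "without")
  expect_lt(sol$flux_a$flux[["LDH"]], 1e-9)
})

test_that("a structurally infeasible program raises a typed condition", {
  m <- make_toy_model()
  m$reactions$EX_glc$ub <- -20  # demands more uptake than the lb allows
  m$reactions$EX_glc$lb <- -21
  m$reactions$GLCt$ub <- 1      # but the transporter cannot carry it
  expect_error(marge(extend_model(m), c("OXP@1" = 1), NULL),
               class = "marge_infeasible")
})

test_that("total-usage budget mode pins the summed usage in both conditions", {
  ext <- toy_ext()
  sol <- marge(ext, all_one_ratios(ext), NULL,
               marge_params(growth_frac_a = NULL, growth_frac_b = NULL,
                            total_flux_budget = 30))
  expect_equal(sum(sol$flux_a$usage), 30, tolerance = 1e-6)
  expect_equal(sum(sol$flux_b$usage), 30, tolerance = 1e-6)
})

test_that("pathway shares sum to one and behave on degenerate maps", {
  sim <- noiseless_sim()
  ext <- toy_ext()
  sol <- marge(ext, enzyme_ratios(sim$expression, ext),
               build_exchange_constraints(sim$exomet, ext))
  one <- pathway_flux_summary(sol, c(BIOMASS = "all"))
  expect_equal(one$share_a, 1); expect_equal(one$share_b, 1)
  expect_equal(one$delta, 0)
  # two reactions carrying identical flux by stoichiometry split 50/50
  two <- pathway_flux_summary(sol, c(GLCt = "p1", GLYC = "p2"))
  expect_equal(two$share_a, c(0.5, 0.5), tolerance = 1e-9)
  full <- pathway_flux_summary(sol, toy_pathways())
  expect_equal(sum(full$share_a), 1, tolerance = 1e-9)
  expect_equal(sum(full$share_b), 1, tolerance = 1e-9)
  expect_error(pathway_flux_summary(sol, c()), "empty")
})
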