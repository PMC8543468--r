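test_that("the toy network matches its versioned manifest", {
  m <- make_toy_model()
  expect_equal(length(m$reactions), 12L)
  expect_equal(nrow(m$metabolites), 10L)
  expect_setequal(m$exchange_ids, c("EX_glc", "EX_lac", "EX_o2", "EX_gln"))
  expect_equal(m$biomass_id, "BIOMASS")
  gprs <- Filter(Negate(is.na), lapply(m$reactions, `[[`, "gpr"))
  expect_length(gprs, 4L)
  # one two-gene complex, one isozyme pair, one reversible two-isozyme carrier
  expect_equal(parse_gpr(m$reactions$GLYC$gpr)$dnf, list(c("glyA", "glyB")))
  expect_length(parse_gpr(m$reactions$LDH$gpr)$dnf, 2L)
  expect_true(m$reactions$GLNt$reversible)
  expect_length(parse_gpr(m$reactions$GLNt$gpr)$dnf, 2L)
})

test_that("biomass is achievable with open uptakes and zero without substrate", {
  m <- make_toy_model()
  expect_gt(fba(extend_model(m), "BIOMASS", "max")$objective, 0)
  m$reactions$EX_glc$lb <- 0
  expect_equal(fba(extend_model(m), "BIOMASS", "max")$objective, 0, tolerance = 1e-9)
})

test_that("noiseless simulation reproduces the planted exchange ratio exactly", {
  sim <- noiseless_sim()
  lac <- sim$exomet[sim$exomet$exchange_id == "EX_lac", ]
  fc <- (lac$abundance_b - lac$abundance_media) / (lac$abundance_a - lac$abundance_media)
  expect_equal(fc, 2, tolerance = 1e-12)
  expect_equal(sim$truth$flux_b[["EX_lac"]] / sim$truth$flux_a[["EX_lac"]], 2,
               tolerance = 1e-9)
  # abundances are medium plus one time unit of the true exchange flux
  glc <- sim$exomet[sim$exomet$exchange_id == "EX_glc", ]
  expect_equal(glc$abundance_a, glc$abundance_media + sim$truth$flux_a[["EX_glc"]])
})

test_that("planted genes pass the q < 0.1 convention and null genes do not", {
  sim <- noiseless_sim()
  ex <- sim$expression
  planted <- ex$gene_id %in% c("ldhA", "ldhB")
  expect_true(all(ex$qvalue[planted] < 0.1))
  expect_true(all(ex$qvalue[!planted] >= 0.1))
  expect_equal(ex$log2fc[planted], c(1, 1))
})

test_that("the same seed reproduces the simulation byte for byte", {
  s1 <- simulate_condition_pair(toy_scenario(seed = 13))
  s2 <- simulate_condition_pair(toy_scenario(seed = 13))
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$exomet, s2$exomet)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_condition_pair(toy_scenario(seed = 13), out_dir = d1)
  simulate_condition_pair(toy_scenario(seed = 13), out_dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  s3 <- simulate_condition_pair(toy_scenario(seed = 14))
  expect_false(identical(s1$exomet, s3$exomet))
})

test_that("unrealizable planted shifts error at generation time", {
  sc <- toy_scenario(exchange_shifts = list(EX_lac = list(direction = "secretion",
                                                          ratio = 1000)))
  expect_error(simulate_condition_pair(sc), "not realizable")
})

test_that("model variants stay valid and deterministic", {
  v1 <- toy_model_variant(4); v2 <- toy_model_variant(4)
  expect_identical(v1, v2)
  expect_equal(length(v1$reactions), 12L)
  expect_gt(fba(extend_model(v1), "BIOMASS", "max")$objective, 0)
  expect_false(identical(toy_model_variant(5)$reactions$EX_glc$lb,
                         v1$reactions$EX_glc$lb))
})

test_that("end-to-end: the planted fermentative shift is recovered from one draw", {
  sim <- simulate_condition_pair(toy_scenario(seed = 3))
  ext <- toy_ext()
  sol <- marge(ext, enzyme_ratios(sim$expression, ext),
               build_exchange_constraints(sim$exomet, ext))
  ps <- pathway_flux_summary(sol, c(LDH = "fermentative", OXP = "oxidative"))
  expect_gt(ps$delta[ps$pathway == "fermentative"], 0)
})
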