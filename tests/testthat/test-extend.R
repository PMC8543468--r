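mini_model <- function(rev_lb = 0, gpr = "e1 or e2") {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c")
  metabolic_model("mini", mets, list(
    list(id = "EX_A", stoich = c(A = -1), lb = -10, ub = 0),
    list(id = "R1", stoich = c(A = -1, B = 1), lb = rev_lb, ub = 10, gpr = gpr),
    list(id = "EX_B", stoich = c(B = -1), lb = if (rev_lb < 0) -10 else 0, ub = 10)),
    exchange_ids = c("EX_A", "EX_B"))
}

test_that("an irreversible reaction with two isozymes yields two forward columns", {
  ext <- extend_model(mini_model())
  u <- ext$vars[ext$vars$reaction == "R1", ]
  expect_equal(nrow(u), 2L)
  expect_true(all(u$direction == "forward"))
  expect_true(all(u$lb == 0 & u$ub == 10))
  # reaction flux is u1 + u2
  rm <- ext$reaction_map$R1
  expect_equal(rm$sign, c(1, 1))
  x <- numeric(ncol(ext$S_ext)); x[rm$idx] <- c(2, 3)
  expect_equal(unname(reconstruct_fluxes(ext, x)[["R1"]]), 5)
})

test_that("a reversible single-isozyme reaction yields forward and backward columns", {
  ext <- extend_model(mini_model(rev_lb = -10, gpr = "e1"))
  u <- ext$vars[ext$vars$reaction == "R1", ]
  expect_equal(u$direction, c("forward", "backward"))
  expect_true(all(u$lb == 0))
  rm <- ext$reaction_map$R1
  x <- numeric(ncol(ext$S_ext)); x[rm$idx] <- c(4, 1)
  expect_equal(unname(reconstruct_fluxes(ext, x)[["R1"]]), 3)
  # backward column carries negated stoichiometry
  expect_equal(unname(ext$S_ext[, rm$idx[2]]), -unname(ext$S_ext[, rm$idx[1]]))
})

test_that("toy fixture usage-column count matches isozyme x direction enumeration", {
  m <- make_toy_model()
  ext <- extend_model(m)
  # independent enumeration from the GPR table
  expected <- 0L
  for (r in m$reactions) {
    if (is.na(r$gpr) || r$id %in% m$exchange_ids) next
    n_iso <- length(parse_gpr(r$gpr)$dnf)
    n_dir <- if (r$lb < 0) 2L else 1L
    expected <- expected + n_iso * n_dir
  }
  expect_equal(sum(ext$vars$kind == "usage"), expected)
  expect_equal(expected, 8L)  # versioned manifest of the fixture
  # non-GPR reactions keep a single ordinary column
  expect_equal(sum(ext$vars$kind == "flux"), 8L)
})

test_that("a GPR on an exchange reaction is ignored with a warning", {
  mets <- data.frame(id = "A", name = "A", compartment = "c")
  m <- metabolic_model("m", mets, list(
    list(id = "EX_A", stoich = c(A = -1), lb = -5, ub = 5, gpr = "g1"),
    list(id = "SINK", stoich = c(A = -1), lb = 0, ub = 5)))
  m$exchange_ids <- "EX_A"
  expect_warning(ext <- extend_model(m), "non-enzymatic")
  expect_equal(ext$vars$kind[ext$vars$reaction == "EX_A"], "flux")
})

test_that("reconstructed fluxes of extended solutions are feasible in the raw model", {
  ext <- toy_ext()
  m <- ext$base
  S <- stoichiometric_matrix(m)
  set.seed(11)
  for (i in 1:10) {
    w <- setNames(runif(3, -1, 1), sample(names(m$reactions), 3))
    fs <- fba(ext, w, sense = "max")
    expect_equal(fs$status, "optimal")
    v <- fs$flux[colnames(S)]
    expect_lt(max(abs(S %*% v)), 1e-6)
    for (r in names(m$reactions)) {
      expect_gte(v[[r]], m$reactions[[r]]$lb - 1e-6)
      expect_lte(v[[r]], m$reactions[[r]]$ub + 1e-6)
    }
  }
})

test_that("extended and unextended FBA optima agree for random objectives", {
  ext <- toy_ext()
  m <- ext$base
  set.seed(23)
  for (i in 1:8) {
    w <- as.list(setNames(runif(4, -1, 1), sample(names(m$reactions), 4)))
    fs <- fba(ext, unlist(w), sense = "max")
    raw <- oracle_fba_raw(m, w, maximize = TRUE)
    expect_equal(fs$objective, raw$objective, tolerance = 1e-6)
  }
})
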