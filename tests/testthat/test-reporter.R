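test_that("raw Z has its closed-form values", {
  expect_equal(reporter_z(0.5), 0, tolerance = 1e-12)
  expect_equal(reporter_z(c(0.05, 0.05)), 2 * qnorm(0.95) / sqrt(2), tolerance = 1e-10)
  expect_equal(reporter_z(0.95), qnorm(0.05), tolerance = 1e-10)
  expect_error(reporter_z(numeric(0)), "empty")
})

test_that("decreasing a member p-value never decreases the raw Z", {
  set.seed(3)
  for (i in 1:20) {
    p <- runif(5)
    z0 <- reporter_z(p)
    j <- sample(5, 1)
    p[j] <- p[j] * runif(1)
    expect_gte(reporter_z(p), z0 - 1e-12)
  }
})

test_that("metabolite gene sets come from GPRs of adjacent reactions", {
  sets <- metabolite_gene_sets(make_toy_model())
  expect_setequal(sets$pyr_c, c("glyA", "glyB", "ldhA", "ldhB", "oxp1"))
  expect_setequal(sets$gln_e, c("glnT1", "glnT2"))
  expect_false("glc_e" %in% names(sets))  # only GPR-free neighbors
})

null_stats <- function(n, seed) {
  set.seed(seed)
  data.frame(gene_id = sprintf("g%03d", 1:n), pvalue = runif(n),
             log2fc = rnorm(n))
}

random_sets <- function(genes, n_sets, seed) {
  set.seed(seed)
  sets <- lapply(1:n_sets, function(i) sample(genes, sample(1:5, 1)))
  names(sets) <- sprintf("met%03d", 1:n_sets)
  sets
}

test_that("background-corrected Z is standardized within set-size strata", {
  stats <- null_stats(200, 31)
  sets <- random_sets(stats$gene_id, 60, 32)
  res <- reporter_analysis(stats, sets, n_perm = 2000, seed = 9)
  nd <- res[res$class == "non-directional", ]
  # metabolite sets are themselves draws from the null here, so their
  # corrected Z should be approximately standard normal
  expect_lt(abs(mean(nd$z_corrected)), 0.2)
  expect_lt(abs(sd(nd$z_corrected) - 1), 0.3)
})

test_that("a coherently significant set ranks first in the non-directional class", {
  stats <- null_stats(100, 41)
  stats$pvalue[stats$gene_id %in% c("g001", "g002", "g003")] <- 1e-4
  sets <- random_sets(stats$gene_id[4:100], 30, 42)
  sets$hit <- c("g001", "g002", "g003")
  res <- reporter_analysis(stats, sets, n_perm = 1000, seed = 5)
  nd <- res[res$class == "non-directional", ]
  expect_equal(nd$metabolite[which.max(nd$z_corrected)], "hit")
  expect_equal(nd$metabolite[which.min(nd$pvalue)], "hit")
})

test_that("directional classes orient by fold-change sign", {
  stats <- data.frame(gene_id = c("u1", "u2", "d1", "d2"),
                      pvalue = c(0.01, 0.02, 0.01, 0.02),
                      log2fc = c(1, 2, -1, -2))
  sets <- list(up_met = c("u1", "u2"), dn_met = c("d1", "d2"))
  res <- reporter_analysis(stats, sets, n_perm = 200, seed = 2)
  dd <- res[res$class == "distinct-directional", ]
  expect_gt(dd$z_raw[dd$metabolite == "up_met"], 0)
  expect_lt(dd$z_raw[dd$metabolite == "dn_met"], 0)
  mu <- res[res$class == "mixed-directional up", ]
  expect_equal(mu$k[mu$metabolite == "up_met"], 2L)
  expect_equal(mu$k[mu$metabolite == "dn_met"], 0L)  # no up-genes in the set
  expect_true(is.na(mu$z_raw[mu$metabolite == "dn_met"]))
})

test_that("significance is capped at the top 5% of tested metabolites", {
  stats <- null_stats(300, 51)
  stats$pvalue[1:150] <- 1e-6  # half the genome strongly regulated
  sets <- random_sets(stats$gene_id[1:150], 100, 52)
  res <- reporter_analysis(stats, sets, n_perm = 300, seed = 3)
  for (cls in unique(res$class)) {
    n_sig <- sum(res$significant[res$class == cls])
    expect_lte(n_sig, 5L)  # floor(0.05 * 100)
  }
})

test_that("identical seed and inputs reproduce the result exactly", {
  stats <- null_stats(80, 61)
  sets <- random_sets(stats$gene_id, 25, 62)
  r1 <- reporter_analysis(stats, sets, n_perm = 500, seed = 77)
  r2 <- reporter_analysis(stats, sets, n_perm = 500, seed = 77)
  expect_identical(r1, r2)
})

test_that("metabolites with no measured member genes are dropped and recorded", {
  stats <- null_stats(20, 71)
  sets <- list(ok = stats$gene_id[1:3], ghost = c("nope1", "nope2"))
  res <- reporter_analysis(stats, sets, n_perm = 200, seed = 1)
  expect_false("ghost" %in% res$metabolite)
  expect_equal(attr(res, "dropped"), "ghost")
})
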