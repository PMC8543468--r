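meas_row <- function(met = "m", ex = "EX_glc", a, b, media, sa = TRUE, sb = TRUE,
                     sab = TRUE) {
  data.frame(metabolite_id = met, exchange_id = ex, abundance_a = a,
             abundance_b = b, abundance_media = media, sig_vs_media_a = sa,
             sig_vs_media_b = sb, sig_between = sab, stringsAsFactors = FALSE)
}

test_that("direction calls follow sign of the baseline-subtracted change", {
  expect_equal(call_direction(6, 10, TRUE), "uptake")
  expect_equal(call_direction(5, 0, TRUE), "secretion")
  expect_equal(call_direction(9.5, 10, FALSE), "unconstrained")
  expect_equal(call_direction(10, 10, TRUE), "unconstrained")
})

test_that("worked uptake example: interval [1, 3] and 1% floors", {
  ext <- toy_ext()
  cs <- build_exchange_constraints(meas_row(a = 8, b = 6, media = 10), ext,
                                   tau = 0.5, phi = 0.01)
  expect_equal(cs$direction_a, "uptake")
  expect_equal(cs$direction_b, "uptake")
  # FC = (10-6)/(10-8) = 2; interval [2*0.5, 2*1.5]
  expect_equal(cs$ratio_low, 1.0)
  expect_equal(cs$ratio_high, 3.0)
  expect_equal(cs$abs_floor_a, 0.01 * max_uptake_rate(ext, "EX_glc"))
  expect_equal(cs$abs_floor_a, 0.1)
})

test_that("secretion-side fold change uses the same rule", {
  ext <- toy_ext()
  cs <- build_exchange_constraints(meas_row(ex = "EX_lac", a = 5, b = 10, media = 0),
                                   ext, tau = 0.5)
  expect_equal(cs$direction_a, "secretion")
  expect_equal(cs$direction_b, "secretion")
  expect_equal(cs$ratio_low, 1.0)
  expect_equal(cs$ratio_high, 3.0)
})

test_that("insignificant measurements yield neither floor nor direction", {
  ext <- toy_ext()
  cs <- build_exchange_constraints(meas_row(a = 8, b = 6, media = 10, sa = FALSE,
                                            sb = FALSE, sab = FALSE), ext)
  expect_equal(cs$direction_a, "unconstrained")
  expect_equal(cs$abs_floor_a, 0)
  expect_true(is.na(cs$ratio_low))
})

test_that("opposite directions and zero denominators skip the ratio with a log entry", {
  ext <- toy_ext()
  cs <- build_exchange_constraints(meas_row(a = 8, b = 12, media = 10), ext)
  expect_true(is.na(cs$ratio_low))
  expect_match(paste(attr(cs, "log"), collapse = " "), "opposite direction")
  # floors are kept
  expect_gt(cs$abs_floor_a, 0)

  cs2 <- build_exchange_constraints(meas_row(a = 10, b = 6, media = 10, sa = TRUE),
                                    ext)
  expect_true(is.na(cs2$ratio_low))

  cs3 <- suppressWarnings(
    build_exchange_constraints(meas_row(ex = "EX_gln", a = 12 - 1e-12, b = 6, media = 12),
                               ext))
  expect_true(is.na(cs3$ratio_low) || cs3$ratio_high < Inf)
})

test_that("unknown exchanges are skipped and logged", {
  ext <- toy_ext()
  cs <- build_exchange_constraints(meas_row(ex = "EX_missing", a = 8, b = 6, media = 10),
                                   ext)
  expect_equal(nrow(cs), 0L)
  expect_match(attr(cs, "log"), "no exchange reaction")
})

test_that("widening tau never shrinks a ratio interval", {
  ext <- toy_ext()
  taus <- c(0, 0.25, 0.5, 0.9)
  rows <- lapply(taus, function(tt)
    build_exchange_constraints(meas_row(a = 8, b = 6, media = 10), ext, tau = tt))
  for (i in seq_along(taus)[-1]) {
    expect_lte(rows[[i]]$ratio_low, rows[[i - 1]]$ratio_low)
    expect_gte(rows[[i]]$ratio_high, rows[[i - 1]]$ratio_high)
  }
})

test_that("noiseless generator output recovers the planted directions exactly", {
  sim <- noiseless_sim()
  ext <- toy_ext()
  cs <- build_exchange_constraints(sim$exomet, ext)
  cs <- cs[order(cs$exchange_id), ]
  expect_equal(cs$direction_a[cs$exchange_id == "EX_glc"], "uptake")
  expect_equal(cs$direction_b[cs$exchange_id == "EX_glc"], "uptake")
  expect_equal(cs$direction_a[cs$exchange_id == "EX_lac"], "secretion")
  expect_equal(cs$direction_b[cs$exchange_id == "EX_lac"], "secretion")
  expect_equal(cs$direction_a[cs$exchange_id == "EX_gln"], "uptake")
  # planted lactate ratio 2 with tau = 0.5 gives [1, 3]
  expect_equal(cs$ratio_low[cs$exchange_id == "EX_lac"], 1.0, tolerance = 1e-9)
  expect_equal(cs$ratio_high[cs$exchange_id == "EX_lac"], 3.0, tolerance = 1e-9)
})

test_that("the ground-truth flux pair satisfies the derived constraint set", {
  sim <- noiseless_sim()
  ext <- toy_ext()
  cs <- build_exchange_constraints(sim$exomet, ext)
  for (i in seq_len(nrow(cs))) {
    ex <- cs$exchange_id[i]
    va <- sim$truth$flux_a[[ex]]; vb <- sim$truth$flux_b[[ex]]
    for (cond in c("a", "b")) {
      v <- if (cond == "a") va else vb
      dir <- cs[[paste0("direction_", cond)]][i]
      fl <- cs[[paste0("abs_floor_", cond)]][i]
      if (dir == "uptake") expect_lte(v, -fl + 1e-9)
      if (dir == "secretion") expect_gte(v, fl - 1e-9)
    }
    if (!is.na(cs$ratio_low[i])) {
      s <- if (cs$direction_a[i] == "secretion") 1 else -1
      expect_gte(s * vb, cs$ratio_low[i] * s * va - 1e-9)
      expect_lte(s * vb, cs$ratio_high[i] * s * va + 1e-9)
    }
  }
})
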