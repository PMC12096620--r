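test_that("ER/PR and HER2 binning match the category edge conventions", {
  er <- bin_cells(
    tibble::tibble(ER_norm = c(0, 3, 7, 12, 12.5)), "ER", bin_scheme_er_pr()
  )
  expect_equal(
    as.character(er$ER_bin),
    c("negative", "1+", "2+", "2+", "3+")
  )
  her2 <- bin_cells(
    tibble::tibble(HER2_norm = c(0, 5, 7, 13, 15)), "HER2", bin_scheme_her2()
  )
  expect_equal(as.character(her2$HER2_bin), c("0", "0", "1+", "3+", "3+"))

  top <- bin_cells(tibble::tibble(ER_norm = rep(15, 4)), "ER", bin_scheme_er_pr())
  expect_true(all(top$ER_bin == "3+"))

  expect_error(
    bin_cells(tibble::tibble(ER_norm = 16), "ER", bin_scheme_er_pr()),
    class = "mxifhet_validation_error"
  )
})

test_that("binning assigns exactly one category to every cell", {
  withr::with_seed(8, {
    v <- c(0, 15, runif(500, 0, 15))
  })
  for (scheme in list(bin_scheme_er_pr(), bin_scheme_her2())) {
    out <- bin_cells(tibble::tibble(M_norm = v), "M", scheme)
    expect_false(anyNA(out$M_bin))
    expect_true(all(as.character(out$M_bin) %in% scheme$category))
  }
})

test_that("histoscore evaluates the published formula and its bounds", {
  lv <- c("negative", "1+", "2+", "3+")
  mk <- function(bins) {
    tibble::tibble(core_id = "c1", ER_bin = factor(bins, levels = lv))
  }
  # 50% 3+, 30% 2+, 20% 1+ -> 3*50 + 2*30 + 20 = 230
  h <- histoscore(mk(rep(c("3+", "2+", "1+"), c(5, 3, 2))), "ER")
  expect_equal(h$H, 230)
  expect_equal(
    h$`pct_negative` + h$`pct_1+` + h$`pct_2+` + h$`pct_3+`, 100,
    tolerance = 1e-9
  )
  expect_equal(histoscore(mk(rep("3+", 7)), "ER")$H, 300)
  expect_equal(histoscore(mk(rep("negative", 7)), "ER")$H, 0)
  expect_error(histoscore(mk(character(0)), "ER"),
    class = "mxifhet_validation_error"
  )
})

test_that("pooled-core histoscore equals the brute-force recount", {
  lv <- c("negative", "1+", "2+", "3+")
  withr::with_seed(21, {
    sub1 <- sample(lv, 40, replace = TRUE, prob = c(.1, .3, .4, .2))
    sub2 <- sample(lv, 70, replace = TRUE, prob = c(.4, .2, .2, .2))
  })
  pooled <- tibble::tibble(
    core_id = "pool", ER_bin = factor(c(sub1, sub2), levels = lv)
  )
  h <- histoscore(pooled, "ER")$H
  # independent recount straight from category tallies
  tab <- table(factor(c(sub1, sub2), levels = lv))
  h_brute <- as.numeric(
    100 * (3 * tab[["3+"]] + 2 * tab[["2+"]] + tab[["1+"]]) / sum(tab)
  )
  expect_equal(h, h_brute, tolerance = 1e-12)
})

test_that("Ki67 positivity counts any normalized signal above zero", {
  x <- tibble::tibble(core_id = "c1", Ki67_norm = c(0, 0.01, 14))
  expect_equal(ki67_positivity(x)$ki67_pct, 100 * 2 / 3)
  expect_equal(
    ki67_positivity(tibble::tibble(core_id = "c", Ki67_norm = rep(0, 5)))$ki67_pct,
    0
  )
  expect_equal(
    ki67_positivity(tibble::tibble(core_id = "c", Ki67_norm = rep(3, 5)))$ki67_pct,
    100
  )
  expect_error(ki67_positivity(tibble::tibble(core_id = character(), Ki67_norm = numeric())),
    class = "mxifhet_validation_error"
  )
})

test_that("valley thresholds recover the known mixture midpoint", {
  ctl <- simulate_tonsil_control(
    seed = 9, n_cells = 2000,
    mixing_fraction = 0.5, separation = 4, neg_mean = 6
  )
  thr <- estimate_thresholds(ctl, c("CD3", "CD68", "PDL1"))
  expect_true(all(abs(thr - 8) < 0.5)) # true midpoint 6 + 4/2

  # manual overrides pass through verbatim
  thr2 <- estimate_thresholds(ctl, c("CD3", "CD68"), manual = c(CD3 = 1.23))
  expect_equal(thr2[["CD3"]], 1.23)

  expect_error(estimate_thresholds(ctl, "NotAMarker"),
    class = "mxifhet_schema_error"
  )

  # unimodal control: warning then fallback (error when none configured)
  uni <- withr::with_seed(4, tibble::tibble(M = 2^rnorm(800, 7, 0.5)))
  expect_warning(
    thr3 <- estimate_thresholds(uni, "M", fallback = 9),
    "unimodal"
  )
  expect_equal(thr3[["M"]], 9)
  expect_error(
    suppressWarnings(estimate_thresholds(uni, "M")),
    class = "mxifhet_validation_error"
  )
})

test_that("gating follows the most-specific-first phenotype rules", {
  thr <- setNames(rep(0, 7), c("CK", "CD3", "CD8", "CD68", "CD163", "PD1", "PDL1"))
  cfg <- gating_config(thr)
  mknorm <- function(...) {
    vals <- list(...)
    base <- tibble::tibble(
      CK_norm = -1, CD3_norm = -1, CD8_norm = -1, CD68_norm = -1,
      CD163_norm = -1, PD1_norm = -1, PDL1_norm = -1
    )
    for (nm in names(vals)) base[[paste0(nm, "_norm")]] <- vals[[nm]]
    base
  }
  expect_equal(
    gate_immune(mknorm(CD3 = 2, PD1 = 2), cfg)$phenotype, "CD3+/CD8-/PD1+"
  )
  expect_equal(
    gate_immune(mknorm(CD68 = 2, CD163 = 2), cfg)$phenotype, "CD68+/CD163+"
  )
  expect_equal(
    gate_immune(mknorm(CD3 = 2, CD8 = 2, PD1 = 2), cfg)$phenotype,
    "CD3+/CD8+/PD1+"
  )
  expect_equal(gate_immune(mknorm(CK = 2), cfg)$phenotype, "CK+")
  expect_equal(gate_immune(mknorm(), cfg)$phenotype, "other")

  # contradictory gate definition
  expect_error(
    gating_config(thr, gates = list(list(label = "bad", pos = "CD3", neg = "CD3"))),
    class = "mxifhet_config_error"
  )
})

test_that("gating recovers simulated gate classes with >= 99% accuracy", {
  cells <- simulate_archetype_cells(
    3000,
    archetypes = default_archetypes("Immune"), seed = 14
  )
  norm <- normalize_markers(cells, panel_markers("Immune"), mode = "zscore")
  gate_markers <- c("CK", "CD3", "CD8", "CD68", "CD163", "PD1", "PDL1")
  thr <- estimate_thresholds(norm, gate_markers, transform = "norm")
  gated <- gate_immune(norm, gating_config(thr))
  expect_gte(mean(gated$phenotype == gated$archetype), 0.99)
  # partition: exactly one label per cell, all from the closed label set
  expect_true(all(gated$phenotype %in% c(patch_features(), "other")))
})
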