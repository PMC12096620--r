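mk_cells <- function(x, y, phen, core = "c1") {
  tibble::tibble(core_id = core, x = x, y = y, phenotype = phen)
}

test_that("cells map to half-open 150-px grid cells anchored per core", {
  cells <- mk_cells(
    x = c(0, 149, 150, 10), y = c(0, 149, 0, 160),
    phen = rep("CK+", 4)
  )
  p <- assign_patches(cells)
  key <- paste(p$i, p$j)
  # (0,0) and (149,149) share patch (0,0); (150,0) -> (1,0); (10,160) -> (0,1)
  expect_setequal(key, c("0 0", "1 0", "0 1"))
  expect_equal(p$n_cells[p$i == 0 & p$j == 0], 2)
  # physical patch side at defaults: 150 px * 0.325 um/px = 48.75 um
  expect_identical(attr(p, "patch_side_um"), 48.75)
})

test_that("patch composition uses the configured denominator", {
  cells <- mk_cells(
    x = rep(1, 10), y = rep(1, 10),
    phen = c(rep("CK+", 6), rep("CD3+/CD8-", 2), rep("other", 2))
  )
  p <- assign_patches(cells)
  expect_equal(p$`frac_CK+`, 0.6)
  expect_equal(p$`frac_CD3+/CD8-`, 0.2)
  p2 <- assign_patches(cells, denominator = "classified")
  expect_equal(p2$`frac_CK+`, 0.75)
  expect_equal(p2$`frac_CD3+/CD8-`, 0.25)
  # empty input -> empty patch table
  expect_equal(nrow(assign_patches(mk_cells(
    numeric(), numeric(),
    character()
  ))), 0)
  expect_error(assign_patches(tibble::tibble(core_id = "c", x = 1, y = 1)),
    class = "mxifhet_schema_error"
  )
})

test_that("patch counts are conserved before filtering", {
  coh <- simulate_cohort(
    cohort_spec(
      n_cases = 2, regions_per_case = c(2, 2),
      cells_per_core = c(300, 400), seed = 4
    ),
    core_radius_px = 500
  )
  gated <- coh$cells$immune
  gated$phenotype <- coh$truth$immune$gate_class[
    match(gated$cell_id, coh$truth$immune$cell_id)
  ]
  p <- assign_patches(gated)
  expect_equal(sum(p$n_cells), nrow(gated))
  sums <- rowSums(p[, paste0("frac_", patch_features())])
  expect_true(all(sums <= 1 + 1e-9))
})

test_that("sparse patches and poorly covered cores are filtered", {
  p <- tibble::tibble(
    core_id = c(rep("a", 12), rep("b", 10)),
    i = 1:22, j = 0,
    n_cells = c(4, 5, 6, rep(20, 9), rep(c(4, 20), 5))
  )
  f <- filter_patches(p, quiet = TRUE)
  # counts {4,5,6}: the 4-cell patch drops, boundary 5 stays
  expect_equal(sort(f$n_cells[f$core_id == "a"][1:2]), c(5, 6))
  expect_equal(sum(f$core_id == "a"), 11)
  # core b drops to 5 surviving patches -> whole core removed
  expect_equal(sum(f$core_id == "b"), 0)
  # boundary: exactly 10 surviving patches keeps the core
  p10 <- tibble::tibble(
    core_id = "c", i = 1:10, j = 0, n_cells = rep(5, 10)
  )
  expect_equal(nrow(filter_patches(p10, quiet = TRUE)), 10)
  # monotonicity: raising min_cells never increases survivors
  for (mc in c(1, 5, 10, 25)) {
    expect_lte(
      nrow(filter_patches(p, min_cells = mc + 5, quiet = TRUE)),
      nrow(filter_patches(p, min_cells = mc, quiet = TRUE))
    )
  }
})

test_that("per-core phenotype fractions sum to one", {
  p <- tibble::tibble(
    core_id = rep(c("a", "b"), c(10, 4)),
    phenotype = c(rep("Immune rich", 4), rep("cancer only", 6), rep("CD3++", 4))
  )
  fr <- phenotype_fractions(p)
  expect_equal(
    fr$fraction[fr$core_id == "a" & fr$phenotype == "Immune rich"], 0.4
  )
  expect_equal(
    fr$fraction[fr$core_id == "b" & fr$phenotype == "CD3++"], 1.0
  )
  sums <- tapply(fr$fraction, fr$core_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # cores share the full phenotype space (absent phenotypes at 0)
  expect_equal(nrow(fr), 2 * 3)
})

test_that("phenotype_patches validates the patch count against K", {
  p <- tibble::tibble(core_id = "a", i = 1:5, j = 0, n_cells = 10)
  for (f in patch_features()) p[[paste0("frac_", f)]] <- 0.1
  expect_error(phenotype_patches(p, k = 30),
    "smaller K",
    class = "mxifhet_validation_error"
  )
})

test_that("LumA cores show more CD3-rich patches than LumB cores", {
  coh <- simulate_cohort(
    cohort_spec(
      n_cases = 8, regions_per_case = c(2, 2),
      cells_per_core = c(1500, 2000),
      subtype_weights = c(LumA = .5, LumB = .5, HER2E = 0, Basal = 0),
      polytypic_fraction = 0, seed = 18
    )
  )
  tonsil <- simulate_tonsil_control(seed = 19)
  res <- run_immune_pipeline(coh$cells$immune, coh$metadata,
    tonsil = tonsil, seed = 2
  )
  # identify the CD3-dominant phenotype group from its mean composition
  # (auto-names are descriptive, not guaranteed to contain "CD3")
  cd3_cols <- c("frac_CD3+/CD8-", "frac_CD3+/CD8+")
  by_phen <- res$patches |>
    dplyr::group_by(phenotype) |>
    dplyr::summarise(cd3 = mean(rowSums(dplyr::pick(dplyr::all_of(cd3_cols)))))
  cd3_phen <- by_phen$phenotype[which.max(by_phen$cd3)]
  d <- dplyr::inner_join(
    res$fractions[res$fractions$phenotype == cd3_phen, ],
    coh$metadata[, c("core_id", "subtype")],
    by = "core_id"
  )
  means <- tapply(d$fraction, d$subtype, mean)
  expect_gt(means[["LumA"]], means[["LumB"]])
})
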