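#' Analysis parameters for the end-to-end pipelines
#'
#' Collects every tunable stage parameter with its conventional default:
#' DAPI QC cutoff 1000, log2 offset 1, K = 300 for IHC4 cell clustering and
#' K = 30 for patch clustering, 150-pixel patches at 0.325 um/pixel, the
#' >= 5 cells/patch and >= 10 patches/core filters, and 8 merged immune
#' phenotypes. `k_ihc4` (and `k_patches`) are capped at `n - 1` at run time;
#' supply `k_scan` to select K by modularity maximization instead.
#'
#' @param dapi_min QC cutoff on raw DAPI intensity.
#' @param log_offset Added before log2 in normalization.
#' @param k_ihc4 Neighbour count for IHC4 single-cell clustering.
#' @param k_scan Optional candidate K vector; when given, K is chosen by
#'   modularity maximization over the scan.
#' @param k_patches Neighbour count for patch-composition clustering.
#' @param n_phenotypes Merged phenotype group count.
#' @param patch_px Patch side (pixels).
#' @param pixel_size_um Micrometres per pixel for the immune panel.
#' @param min_cells_per_patch,min_patches_per_core Patch/core filters.
#' @param ck_fallback_threshold Fallback CK threshold (0-15 scale) used to
#'   call cancer cells when the CK distribution is not clearly bimodal.
#' @param immune_fallback_threshold Fallback gating threshold (Z-score
#'   units) for immune markers with a unimodal control distribution.
#' @return A named list of class `pipeline_params`.
#' @export
pipeline_params <- function(dapi_min = 1000,
                            log_offset = 1,
                            k_ihc4 = 300,
                            k_scan = NULL,
                            k_patches = 30,
                            n_phenotypes = 8,
                            patch_px = 150,
                            pixel_size_um = 0.325,
                            min_cells_per_patch = 5,
                            min_patches_per_core = 10,
                            ck_fallback_threshold = 7.5,
                            immune_fallback_threshold = 1) {
  structure(
    list(
      dapi_min = dapi_min, log_offset = log_offset,
      k_ihc4 = k_ihc4, k_scan = k_scan, k_patches = k_patches,
      n_phenotypes = n_phenotypes, patch_px = patch_px,
      pixel_size_um = pixel_size_um,
      min_cells_per_patch = min_cells_per_patch,
      min_patches_per_core = min_patches_per_core,
      ck_fallback_threshold = ck_fallback_threshold,
      immune_fallback_threshold = immune_fallback_threshold
    ),
    class = "pipeline_params"
  )
}

#' Run the IHC4 heterogeneity pipeline
#'
#' QC filter, log2 + 0-15 range normalization, CK-based cancer-cell calling,
#' ER/PR/HER2 binning and per-core histoscores, Ki67 positivity,
#' PhenoGraph-style clustering of all QC-passed cells on the five
#' normalized markers, per-case alpha/beta diversity of cluster
#' compositions, and ANOVA comparisons of ER/PR histoscores and Ki67
#' positivity across core subtypes.
#'
#' @param cells IHC4 cell tibble (see [validate_cell_table()]).
#' @param metadata Per-core metadata with `core_id`, `subtype`.
#' @param params A [pipeline_params()] list.
#' @param seed Integer seed.
#' @return List with `cells` (normalized, clustered), `scores`,
#'   `ki67`, `clustering` (`phenograph_clust`), `diversity`, `comparisons`,
#'   `ck_threshold`, `n_qc_removed`.
#' @export
run_ihc4_pipeline <- function(cells, metadata, params = pipeline_params(),
                              seed = 1L) {
  cells <- validate_cell_table(cells, "IHC4")
  markers <- panel_markers("IHC4")
  qc <- qc_filter(cells, dapi_min = params$dapi_min, quiet = TRUE)
  n_removed <- attr(qc, "n_removed")
  norm <- normalize_markers(qc,
    markers = markers, mode = "range_0_15",
    log_offset = params$log_offset
  )
  ck_thr <- tryCatch(
    suppressWarnings(estimate_thresholds(
      norm, "CK",
      transform = "norm",
      fallback = params$ck_fallback_threshold
    )[["CK"]]),
    error = function(e) params$ck_fallback_threshold
  )
  cancer <- filter(norm, .data$CK_norm > ck_thr)
  binned <- cancer |>
    bin_cells("ER", bin_scheme_er_pr()) |>
    bin_cells("PR", bin_scheme_er_pr()) |>
    bin_cells("HER2", bin_scheme_her2())
  scores <- bind_rows(
    histoscore(binned, "ER"),
    histoscore(binned, "PR"),
    histoscore(binned, "HER2")
  )
  ki67 <- ki67_positivity(cancer)

  feats <- as.matrix(norm[, paste0(markers, "_norm")])
  cl <- if (!is.null(params$k_scan)) {
    select_k(feats, k_scan = params$k_scan, seed = seed)
  } else {
    phenograph(feats, k = min(params$k_ihc4, nrow(feats) - 1), seed = seed)
  }
  norm$cluster <- cl$labels

  div <- cohort_diversity(norm, cluster = "cluster")

  per_core <- scores |>
    select("core_id", "marker", "H") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "H") |>
    left_join(ki67, by = "core_id") |>
    left_join(select(metadata, "core_id", "subtype"), by = "core_id")
  comparisons <- bind_rows(purrr::map(
    c(ER = "ER", PR = "PR", Ki67 = "ki67_pct"),
    function(colnm) {
      d <- per_core[!is.na(per_core[[colnm]]), ]
      if (dplyr::n_distinct(d$subtype) < 2) {
        return(tibble())
      }
      compare_groups(d, colnm, "subtype", test = "anova")
    }
  ), .id = "feature")

  list(
    cells = norm, scores = scores, ki67 = ki67, clustering = cl,
    diversity = div, comparisons = comparisons,
    ck_threshold = ck_thr, n_qc_removed = n_removed
  )
}

#' Run the immune spatial-phenotyping pipeline
#'
#' QC filter, log2 + Z-score normalization (jointly with the on-slide
#' tonsil control when supplied), valley-method threshold estimation on the
#' control, binary gating into CK+/immune phenotypes, 150-px patch
#' construction and filtering, patch-composition clustering with merge into
#' immune niche phenotypes, per-core phenotype fractions, and ANOVA
#' comparison of each phenotype's patch fraction across core subtypes.
#'
#' @param cells Immune-panel cell tibble.
#' @param metadata Per-core metadata with `core_id`, `subtype`.
#' @param tonsil Optional tonsil control cell tibble
#'   ([simulate_tonsil_control()]); when given it is normalized together
#'   with the cohort and thresholds are estimated on it, otherwise
#'   thresholds are estimated on the cohort cells themselves.
#' @param params A [pipeline_params()] list.
#' @param seed Integer seed.
#' @return List with `cells` (gated), `thresholds`, `patches` (phenotyped),
#'   `fractions`, `comparisons`, `n_qc_removed`.
#' @export
run_immune_pipeline <- function(cells, metadata, tonsil = NULL,
                                params = pipeline_params(), seed = 1L) {
  cells <- validate_cell_table(cells, "Immune")
  markers <- panel_markers("Immune")
  gate_markers <- c("CK", "CD3", "CD8", "CD68", "CD163", "PD1", "PDL1")
  qc <- qc_filter(cells, dapi_min = params$dapi_min, quiet = TRUE)
  n_removed <- attr(qc, "n_removed")
  pool <- if (!is.null(tonsil)) {
    bind_rows(qc, qc_filter(as_tibble(tonsil), params$dapi_min, quiet = TRUE))
  } else {
    qc
  }
  norm <- normalize_markers(pool,
    markers = markers, mode = "zscore",
    log_offset = params$log_offset
  )
  thr_source <- if (!is.null(tonsil)) {
    filter(norm, .data$core_id == "tonsil")
  } else {
    norm
  }
  thresholds <- suppressWarnings(estimate_thresholds(
    thr_source, gate_markers,
    transform = "norm",
    fallback = params$immune_fallback_threshold
  ))
  gated <- gate_immune(norm, gating_config(thresholds)) |>
    filter(.data$core_id != "tonsil")

  patches <- assign_patches(gated,
    patch_px = params$patch_px,
    pixel_size_um = params$pixel_size_um
  )
  patches <- filter_patches(patches,
    min_cells = params$min_cells_per_patch,
    min_patches = params$min_patches_per_core, quiet = TRUE
  )
  patches <- phenotype_patches(patches,
    k = min(params$k_patches, nrow(patches) - 1),
    n_phenotypes = params$n_phenotypes, seed = seed
  )
  fractions <- phenotype_fractions(patches)

  frac_meta <- left_join(
    fractions, select(metadata, "core_id", "subtype"),
    by = "core_id"
  )
  comparisons <- frac_meta |>
    filter(!is.na(.data$subtype)) |>
    group_by(feature = .data$phenotype) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$subtype) < 2) {
        return(tibble())
      }
      compare_groups(d, "fraction", "subtype", test = "anova")
    }) |>
    ungroup()

  list(
    cells = gated, thresholds = thresholds, patches = patches,
    fractions = fractions, comparisons = comparisons,
    n_qc_removed = n_removed
  )
}

#' Run both analysis pipelines and persist every output
#'
#' Executes the IHC4 heterogeneity pipeline and the immune
#' spatial-phenotyping pipeline on a cohort and writes every intermediate
#' and result table to `out_dir` as provenance-stamped CSV, together with a
#' deterministic `run.log` (stage record, filter counts, seed, config hash)
#' and a serialized copy of the configuration. Refuses to write into an
#' existing non-empty directory unless `overwrite = TRUE`.
#'
#' @param cells_ihc4,cells_immune Panel cell tibbles.
#' @param metadata Per-core metadata.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param tonsil Optional tonsil control table.
#' @param params [pipeline_params()].
#' @param seed Integer seed used by every stochastic stage.
#' @param overwrite Allow reuse of a non-empty `out_dir`.
#' @return Invisibly, a list with `ihc4` and `immune` pipeline results and
#'   `out_dir`.
#' @export
run_pipeline <- function(cells_ihc4, cells_immune, metadata,
                         out_dir = NULL, tonsil = NULL,
                         params = pipeline_params(), seed = 1L,
                         overwrite = FALSE) {
  cfg_hash <- rlang::hash(list(params = unclass(params), seed = seed))
  if (!is.null(out_dir)) ensure_out_dir(out_dir, overwrite)

  stage <- "ihc4"
  res_ihc4 <- tryCatch(
    run_ihc4_pipeline(cells_ihc4, metadata, params = params, seed = seed),
    error = function(e) {
      abort(paste0("Pipeline failed at stage '", stage, "': ",
        conditionMessage(e)), class = "mxifhet_pipeline_error")
    }
  )
  stage <- "immune"
  res_imm <- tryCatch(
    run_immune_pipeline(cells_immune, metadata,
      tonsil = tonsil,
      params = params, seed = seed
    ),
    error = function(e) {
      abort(paste0("Pipeline failed at stage '", stage, "': ",
        conditionMessage(e)), class = "mxifhet_pipeline_error")
    }
  )

  if (!is.null(out_dir)) {
    wp <- function(x, nm) {
      write_provenance_csv(x, file.path(out_dir, nm),
        seed = seed, config_hash = cfg_hash
      )
    }
    wp(res_ihc4$cells, "ihc4_cells.csv")
    wp(res_ihc4$scores, "ihc4_histoscores.csv")
    wp(res_ihc4$ki67, "ihc4_ki67.csv")
    wp(res_ihc4$clustering$centroids, "ihc4_cluster_centroids.csv")
    wp(res_ihc4$diversity, "ihc4_diversity_cases.csv")
    wp(attr(res_ihc4$diversity, "cores"), "ihc4_diversity_cores.csv")
    wp(res_ihc4$comparisons, "ihc4_comparisons.csv")
    wp(res_imm$cells, "immune_cells.csv")
    wp(res_imm$patches, "immune_patches.csv")
    wp(res_imm$fractions, "immune_phenotype_fractions.csv")
    wp(res_imm$comparisons, "immune_comparisons.csv")
    wp(
      tibble(marker = names(res_imm$thresholds),
        threshold = unname(res_imm$thresholds)),
      "immune_thresholds.csv"
    )
    writeLines(
      c(
        paste0("mxifhet run, package version ",
          as.character(utils::packageVersion("mxifhet"))),
        paste0("seed: ", seed),
        paste0("config_hash: ", cfg_hash),
        paste0("ihc4: qc removed ", res_ihc4$n_qc_removed, " cells; ",
          res_ihc4$clustering$n_clusters, " clusters (K = ",
          res_ihc4$clustering$k, ", Q = ",
          format(res_ihc4$clustering$modularity, digits = 10), ")"),
        paste0("ihc4: CK threshold ",
          format(res_ihc4$ck_threshold, digits = 10)),
        paste0("immune: qc removed ", res_imm$n_qc_removed, " cells; ",
          nrow(res_imm$patches), " patches retained")
      ),
      file.path(out_dir, "run.log")
    )
    dput(
      list(params = unclass(params), seed = seed),
      file.path(out_dir, "config.R")
    )
  }

  invisible(list(ihc4 = res_ihc4, immune = res_imm, out_dir = out_dir))
}
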