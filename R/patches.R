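#' Assign cells to a square image-patch grid and compute compositions
#'
#' Divides each core into square patches of `patch_px` x `patch_px` pixels
#' (48.75 um at the 150 px / 0.325 um-per-pixel defaults), anchored at the
#' per-core bounding-box minimum with half-open intervals: a cell at
#' `(x, y)` falls in patch `(floor((x - x0)/patch_px),
#' floor((y - y0)/patch_px))`. For every patch the cell count and the
#' fractions of the ten cell-type features of [patch_features()] are
#' computed. By default the denominator is all cells in the patch including
#' `"other"`, so the ten fractions sum to at most 1;
#' `denominator = "classified"` restricts it to gated cells.
#'
#' @param cells Gated cell tibble with `core_id`, `x`, `y` and a
#'   `phenotype` column (see [gate_immune()]).
#' @param patch_px Patch side length in pixels.
#' @param pixel_size_um Micrometres per pixel (metadata only; recorded as an
#'   attribute `patch_side_um`).
#' @param denominator `"all"` (default) or `"classified"`.
#' @return A tibble with one row per non-empty patch: `core_id`, `i`, `j`,
#'   `n_cells`, and one `frac_<feature>` column per feature.
#' @examples
#' cells <- tibble::tibble(
#'   core_id = "c1", x = c(0, 149, 150), y = 0,
#'   phenotype = c("CK+", "CK+", "other")
#' )
#' assign_patches(cells)[, c("i", "j", "n_cells")]
#' @export
assign_patches <- function(cells, patch_px = 150, pixel_size_um = 0.325,
                           denominator = c("all", "classified")) {
  denominator <- match.arg(denominator)
  stopifnot(patch_px >= 1)
  if (!"phenotype" %in% names(cells)) {
    abort("Cell table has no 'phenotype' column; run gate_immune() first",
      class = "mxifhet_schema_error"
    )
  }
  feat <- patch_features()
  if (nrow(cells) == 0) {
    out <- tibble(
      core_id = character(), i = numeric(), j = numeric(),
      n_cells = integer()
    )
    for (f in feat) out[[paste0("frac_", f)]] <- numeric()
    attr(out, "patch_side_um") <- patch_px * pixel_size_um
    attr(out, "patch_px") <- patch_px
    return(out)
  }
  out <- cells |>
    group_by(.data$core_id) |>
    mutate(
      i = floor((.data$x - min(.data$x)) / patch_px),
      j = floor((.data$y - min(.data$y)) / patch_px)
    ) |>
    group_by(.data$core_id, .data$i, .data$j) |>
    summarise(
      n_cells = dplyr::n(),
      n_classified = sum(.data$phenotype %in% feat),
      !!!setNames(
        purrr::map(feat, function(f) rlang::quo(sum(.data$phenotype == !!f))),
        paste0("count_", feat)
      ),
      .groups = "drop"
    )
  denom <- if (denominator == "all") out$n_cells else pmax(out$n_classified, 1)
  for (f in feat) {
    out[[paste0("frac_", f)]] <- out[[paste0("count_", f)]] / denom
    out[[paste0("count_", f)]] <- NULL
  }
  out <- select(out, -"n_classified")
  attr(out, "patch_side_um") <- patch_px * pixel_size_um
  attr(out, "patch_px") <- patch_px
  out
}

#' Filter sparse patches and poorly covered cores
#'
#' Drops patches with fewer than `min_cells` cells, then drops every core
#' left with fewer than `min_patches` surviving patches (tissue damage or
#' poor cellularity). Drop counts are reported.
#'
#' @param patches Patch tibble from [assign_patches()].
#' @param min_cells Minimum cells per patch (default 5).
#' @param min_patches Minimum surviving patches per core (default 10).
#' @param quiet Suppress the drop report.
#' @return The filtered patch tibble.
#' @export
filter_patches <- function(patches, min_cells = 5, min_patches = 10,
                           quiet = FALSE) {
  kept <- filter(patches, .data$n_cells >= min_cells)
  core_sizes <- count(kept, .data$core_id)
  good_cores <- core_sizes$core_id[core_sizes$n >= min_patches]
  out <- filter(kept, .data$core_id %in% good_cores)
  if (!quiet) {
    inform(sprintf(
      "filter_patches: dropped %d sparse patch(es) and %d core(s)",
      nrow(patches) - nrow(kept),
      dplyr::n_distinct(patches$core_id) - length(good_cores)
    ))
  }
  out
}

# Name a merged phenotype group from its mean composition vector.
name_phenotype <- function(comp) {
  feat <- patch_features()
  ck <- comp[["frac_CK+"]]
  immune <- comp[paste0("frac_", setdiff(feat, "CK+"))]
  imm_total <- sum(immune)
  pdl1 <- sum(comp[c("frac_CD68+/PDL1+", "frac_CD163+/PDL1+")])
  top <- names(immune)[which.max(immune)]
  top_name <- sub("^frac_", "", top)
  if (imm_total < 0.12) {
    return("cancer only")
  }
  if (imm_total >= 0.35) {
    if (pdl1 >= 0.5 * imm_total) {
      return("PDL1-macrophage")
    }
    if (max(immune) >= 0.5 * imm_total) {
      return(paste0(sub("\\+.*$", "", top_name), "++"))
    }
    return("Immune rich")
  }
  paste0("cancer with ", sub("\\+.*$", "", top_name))
}

#' Cluster patch compositions and assign immune niche phenotypes
#'
#' Clusters the 10-way composition vectors of the filtered patches with
#' [phenograph()] (K = 30 by default), aggregates the resulting fine
#' clusters into `n_phenotypes` groups with [merge_clusters()], and names
#' each group from its dominant composition features (e.g. "cancer only",
#' "CD3++", "Immune rich", "PDL1-macrophage"). Duplicate auto-names are
#' disambiguated with a numeric suffix.
#'
#' @param patches Filtered patch tibble ([filter_patches()]).
#' @param k Neighbour count for patch clustering.
#' @param n_phenotypes Number of merged phenotype groups (default 8).
#' @param seed Integer seed.
#' @return `patches` with `patch_cluster` and `phenotype` columns appended.
#'   Attributes: `clustering` (the `phenograph_clust`), `merge` (the
#'   `cluster_merge`), `phenotype_names` (group -> name map).
#' @export
phenotype_patches <- function(patches, k = 30, n_phenotypes = 8, seed = 1L) {
  feat_cols <- paste0("frac_", patch_features())
  missing <- setdiff(feat_cols, names(patches))
  if (length(missing) > 0) {
    abort(paste0("Patch table is missing composition column(s): ",
      paste(missing, collapse = ", ")), class = "mxifhet_schema_error")
  }
  if (nrow(patches) <= k) {
    abort(paste0("Only ", nrow(patches), " patches for K = ", k,
      "; use a smaller K"), class = "mxifhet_validation_error")
  }
  x <- as.matrix(patches[, feat_cols])
  cl <- phenograph(x, k = k, seed = seed)
  n_groups <- min(n_phenotypes, cl$n_clusters)
  mg <- merge_clusters(cl, n_groups)
  group_of <- setNames(mg$map$group, mg$map$cluster)
  grp <- unname(group_of[as.character(cl$labels)])
  # name each group from the mean composition of its member patches
  nm <- vapply(seq_len(n_groups), function(g) {
    name_phenotype(colMeans(x[grp == g, , drop = FALSE]))
  }, character(1))
  dup <- duplicated(nm)
  if (any(dup)) nm[dup] <- paste0(nm[dup], " (", which(dup), ")")
  out <- as_tibble(patches)
  out$patch_cluster <- cl$labels
  out$phenotype <- nm[grp]
  attr(out, "clustering") <- cl
  attr(out, "merge") <- mg
  attr(out, "phenotype_names") <- setNames(nm, seq_len(n_groups))
  out
}

#' Per-core fractions of patches by phenotype
#'
#' For every core, the fraction of its surviving patches assigned to each
#' phenotype; fractions sum to 1 per core. Phenotypes absent from a core
#' appear with fraction 0 so cores share a common feature space.
#'
#' @param patches Phenotyped patch tibble ([phenotype_patches()]).
#' @return Tibble `core_id`, `phenotype`, `n_patches`, `fraction`.
#' @export
phenotype_fractions <- function(patches) {
  if (!"phenotype" %in% names(patches)) {
    abort("Patch table has no 'phenotype' column",
      class = "mxifhet_schema_error"
    )
  }
  patches |>
    mutate(phenotype = factor(.data$phenotype)) |>
    count(.data$core_id, .data$phenotype, .drop = FALSE, name = "n_patches") |>
    group_by(.data$core_id) |>
    mutate(fraction = .data$n_patches / sum(.data$n_patches)) |>
    ungroup() |>
    mutate(phenotype = as.character(.data$phenotype))
}
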