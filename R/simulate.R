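#' Specify a synthetic lumpectomy cohort
#'
#' Describes the sampling design of a simulated multi-region breast-cancer
#' cohort: how many cases, how many TMA cores (sampled regions) per case,
#' cellularity per core, the molecular-subtype mix, and the fraction of
#' cases carrying more than one subtype among their regions ("polytypic").
#'
#' Defaults mirror the study design the package targets: 2-9 regions per
#' case, a subtype mix proportional to 10 LumA : 7 LumB : 2 HER2E : 6 Basal
#' monotypic cases, and a polytypic fraction of 13/38.
#'
#' @param n_cases Number of lumpectomy cases.
#' @param regions_per_case Inclusive integer range of cores per case,
#'   within `[2, 9]`.
#' @param cells_per_core Inclusive integer range of cells per core (per
#'   panel section).
#' @param subtype_weights Named probability vector over
#'   `c("LumA","LumB","HER2E","Basal")`; must sum to 1.
#' @param polytypic_fraction Probability that a case carries at least two
#'   distinct subtype calls among its cores.
#' @param seed Integer seed; fully determines the simulated cohort.
#' @return A list of class `cohort_spec`.
#' @examples
#' cohort_spec(n_cases = 4, seed = 1)
#' @export
cohort_spec <- function(n_cases = 10,
                        regions_per_case = c(2L, 9L),
                        cells_per_core = c(2000L, 3500L),
                        subtype_weights = c(
                          LumA = 10, LumB = 7, HER2E = 2, Basal = 6
                        ) / 25,
                        polytypic_fraction = 13 / 38,
                        seed = 1L) {
  stopifnot(length(n_cases) == 1, n_cases >= 1)
  regions_per_case <- as.integer(regions_per_case)
  if (length(regions_per_case) != 2 ||
    regions_per_case[1] > regions_per_case[2] ||
    regions_per_case[1] < 2 || regions_per_case[2] > 9) {
    abort("'regions_per_case' must be an increasing pair within [2, 9]",
      class = "mxifhet_validation_error"
    )
  }
  cells_per_core <- as.integer(cells_per_core)
  stopifnot(length(cells_per_core) == 2, cells_per_core[1] >= 1,
    cells_per_core[1] <= cells_per_core[2])
  if (!identical(sort(names(subtype_weights)), sort(subtype_levels()))) {
    abort("'subtype_weights' must be named over LumA, LumB, HER2E, Basal",
      class = "mxifhet_validation_error"
    )
  }
  check_prob_vector(subtype_weights, "subtype_weights")
  if (!is.finite(polytypic_fraction) || polytypic_fraction < 0 ||
    polytypic_fraction > 1) {
    abort("'polytypic_fraction' must lie in [0, 1]",
      class = "mxifhet_validation_error"
    )
  }
  structure(
    list(
      n_cases = as.integer(n_cases),
      regions_per_case = regions_per_case,
      cells_per_core = cells_per_core,
      subtype_weights = subtype_weights[subtype_levels()],
      polytypic_fraction = polytypic_fraction,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Default cell archetypes for a panel
#'
#' Archetypes stand in for the latent cell populations behind observed
#' marker co-expression clusters. Each archetype draws raw intensities
#' log-normally: `2^rnorm(mean, sd)` per marker, clipped to the 16-bit range
#' `[0, 65535]`. For the IHC4 panel the archetypes are five biologically
#' motivated populations (hormone-receptor-positive quiescent and
#' proliferative luminal cells, HER2-amplified cells, basal-like cells, and
#' CK-negative stroma) whose prevalence depends on the core's molecular
#' subtype. For the immune panel each archetype corresponds to one gate
#' label of [patch_features()] plus an `"other"` (all-negative) population,
#' with positive markers centred 5 log2 units above negative ones so the
#' true gate is recoverable.
#'
#' @param panel `"IHC4"` or `"Immune"`.
#' @return A tibble with columns `name`, `mean_<marker>`, `sd_<marker>` and,
#'   for IHC4, `prev_<subtype>` mixture weights.
#' @export
default_archetypes <- function(panel = c("IHC4", "Immune")) {
  panel <- match.arg(panel)
  if (panel == "IHC4") {
    a <- tibble::tribble(
      ~name,                ~ER, ~PR, ~HER2, ~Ki67, ~CK,
      "lum_quiescent",       11,  11,     7,     5,  11,
      "lum_proliferative",   11,   7,     7,    10,  11,
      "her2_amplified",       7,   6,    12,     9,  11,
      "basal_like",           5,   5,     6,    10,  11,
      "stromal",              5,   5,     6,     6,   5
    )
    prev <- tibble::tribble(
      ~name,                ~prev_LumA, ~prev_LumB, ~prev_HER2E, ~prev_Basal,
      "lum_quiescent",             .60,        .15,         .05,         .02,
      "lum_proliferative",         .07,        .50,         .05,         .02,
      "her2_amplified",            .03,        .05,         .60,         .03,
      "basal_like",                .02,        .02,         .02,         .60,
      "stromal",                   .28,        .28,         .28,         .33
    )
    markers <- panel_markers("IHC4")
    out <- a
    names(out)[match(markers, names(out))] <- paste0("mean_", markers)
    for (m in markers) out[[paste0("sd_", m)]] <- 0.7
    return(left_join(out, prev, by = "name"))
  }
  markers <- panel_markers("Immune")
  classes <- c(patch_features(), "other")
  pos_sets <- list(
    "CK+" = "CK",
    "CD3+/CD8-" = "CD3",
    "CD3+/CD8+" = c("CD3", "CD8"),
    "CD68+" = "CD68",
    "CD163+" = "CD163",
    "CD68+/CD163+" = c("CD68", "CD163"),
    "CD68+/PDL1+" = c("CD68", "PDL1"),
    "CD163+/PDL1+" = c("CD163", "PDL1"),
    "CD3+/CD8+/PD1+" = c("CD3", "CD8", "PD1"),
    "CD3+/CD8-/PD1+" = c("CD3", "PD1"),
    "other" = character()
  )
  out <- tibble(name = classes)
  for (m in markers) {
    base <- if (m %in% c("FoxP3", "Ki67")) 7 else 6
    out[[paste0("mean_", m)]] <- vapply(
      classes,
      function(cl) if (m %in% pos_sets[[cl]]) 11 else base,
      numeric(1)
    )
    out[[paste0("sd_", m)]] <- if (m %in% c("FoxP3", "Ki67")) 1.0 else 0.7
  }
  out
}

#' Default immune niche archetypes
#'
#' Eight recurring local immune microenvironment patterns, each defined by a
#' 10-way cell-type composition over [patch_features()] and a spatial blob
#' radius. They range from immune-cold ("cancer only") to immune-hot
#' ("Immune rich", "CD3++") phenotypes, plus a PDL1-expressing macrophage
#' niche.
#'
#' @param blob_radius_um Standard deviation of the isotropic Gaussian blob a
#'   niche occupies, in micrometres.
#' @return Tibble with columns `niche`, `blob_radius_um`, and one
#'   composition column per feature of [patch_features()]; compositions each
#'   sum to 1.
#' @export
default_niches <- function(blob_radius_um = 50) {
  f <- patch_features()
  comp <- rbind(
    "cancer only"      = c(.97, 0, 0, .015, .015, 0, 0, 0, 0, 0),
    "cancer with CD68" = c(.65, 0, 0, .30, 0, .05, 0, 0, 0, 0),
    "cancer with CD163" = c(.65, 0, 0, 0, .30, .05, 0, 0, 0, 0),
    "CD3++"            = c(.08, .42, .34, 0, 0, 0, 0, 0, .08, .08),
    "CD68++"           = c(.08, 0, 0, .62, .04, .18, .08, 0, 0, 0),
    "CD163++"          = c(.08, 0, 0, .04, .62, .18, 0, .08, 0, 0),
    "Immune rich"      = c(.10, .10, .10, .10, .10, .10, .10, .10, .10, .10),
    "PDL1-macrophage"  = c(.10, 0, 0, .07, .07, 0, .38, .38, 0, 0)
  )
  colnames(comp) <- f
  out <- as_tibble(comp)
  out$niche <- rownames(comp)
  out$blob_radius_um <- blob_radius_um
  relocate(out, "niche", "blob_radius_um")
}

#' Default niche mixture weights by molecular subtype
#'
#' Probability of each niche archetype per core subtype. Luminal A cores are
#' given a higher weight on the T-lymphocyte-rich (`CD3++`) and immune-rich
#' niches than Luminal B cores, so end-to-end tests can check the expected
#' direction of the subtype contrast in CD3-rich patch fractions.
#'
#' @return Matrix (subtype x niche) of probabilities; rows sum to 1.
#' @export
default_niche_weights <- function() {
  n <- default_niches()$niche
  w <- rbind(
    LumA  = c(.18, .10, .10, .22, .08, .08, .16, .08),
    LumB  = c(.30, .14, .14, .06, .10, .10, .08, .08),
    HER2E = c(.22, .12, .12, .10, .12, .12, .10, .10),
    Basal = c(.20, .10, .10, .12, .10, .10, .18, .10)
  )
  colnames(w) <- n
  w
}

# sample() that never falls into the scalar-x gotcha.
resample <- function(x, ...) x[sample.int(length(x), ...)]

# Draw raw intensities for one marker: log-normal, clipped to 16-bit range.
draw_intensity <- function(n, log2_mean, log2_sd) {
  pmin(65535, pmax(0, 2^rnorm(n, log2_mean, log2_sd)))
}

# Draw DAPI with a controlled sub-threshold fraction (uniform below 1000 for
# "damaged" cells, log-normal >= 1000 otherwise).
draw_dapi <- function(n, low_fraction) {
  low <- runif(n) < low_fraction
  out <- numeric(n)
  out[low] <- runif(sum(low), 100, 999)
  out[!low] <- pmin(65535, pmax(1000, 2^rnorm(sum(!low), 12, 0.5)))
  out
}

# Sample blob centres inside a disk with a soft minimum-separation rule.
sample_blob_centres <- function(n_blobs, radius, min_sep) {
  centres <- matrix(NA_real_, n_blobs, 2)
  for (b in seq_len(n_blobs)) {
    for (try in 1:50) {
      r <- radius * 0.85 * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      cand <- c(radius + r * cos(th), radius + r * sin(th))
      if (b == 1) break
      d <- sqrt(rowSums((centres[seq_len(b - 1), , drop = FALSE] -
        matrix(cand, b - 1, 2, byrow = TRUE))^2))
      if (all(d >= min_sep)) break
    }
    centres[b, ] <- cand
  }
  centres
}

# Clip points to the circular core footprint by radial scaling.
clip_to_disk <- function(xy, radius) {
  centre <- c(radius, radius)
  d <- sqrt((xy[, 1] - centre[1])^2 + (xy[, 2] - centre[2])^2)
  out <- d > radius * 0.995
  if (any(out)) {
    sc <- (radius * 0.995) / d[out]
    xy[out, 1] <- centre[1] + (xy[out, 1] - centre[1]) * sc
    xy[out, 2] <- centre[2] + (xy[out, 2] - centre[2]) * sc
  }
  xy
}

# Build an intensity tibble for cells of known archetype.
intensities_for <- function(arch_names, archetypes, markers) {
  idx <- match(arch_names, archetypes$name)
  out <- lapply(markers, function(m) {
    draw_intensity(
      length(idx),
      archetypes[[paste0("mean_", m)]][idx],
      archetypes[[paste0("sd_", m)]][idx]
    )
  })
  names(out) <- markers
  as_tibble(out)
}

#' Simulate a multi-region MxIF cohort with full ground truth
#'
#' Generates per-cell tables for both staining panels, per-core metadata,
#' and ground-truth labels for every simulated cell. Each case receives
#' between 2 and 9 circular TMA cores. Polytypic cases (drawn with
#' probability `spec$polytypic_fraction`) carry at least two distinct
#' subtype calls among their cores. IHC4-panel cells are drawn as a
#' subtype-dependent mixture of marker archetypes placed uniformly in the
#' core; immune-panel cells are placed in Gaussian niche blobs whose niche
#' identity is drawn from subtype-dependent weights, and their gate class is
#' drawn from the niche's composition (with an `other_fraction` of
#' unclassifiable cells). A configurable fraction of cells receives DAPI
#' below 1000 to exercise the QC filter.
#'
#' @param spec A [cohort_spec()].
#' @param archetypes_ihc4,archetypes_immune Archetype tibbles; see
#'   [default_archetypes()].
#' @param niches Niche tibble; see [default_niches()].
#' @param niche_weights Subtype-by-niche probability matrix; see
#'   [default_niche_weights()].
#' @param dapi_low_fraction Fraction of cells simulated with DAPI < 1000.
#' @param other_fraction Fraction of immune-panel cells assigned no gate
#'   class ("other").
#' @param core_radius_px Core footprint radius in pixels.
#' @param pixel_size_um Micrometres per pixel (used to convert niche blob
#'   radii to pixels).
#' @param blobs_per_core Poisson mean of the number of niche blobs per core
#'   (floored at 3).
#' @return A list of class `mxif_cohort` with elements `cells` (list of
#'   tibbles `ihc4`, `immune`), `metadata` (one row per core), `truth`
#'   (per-cell ground-truth tibbles per panel) and `truth_composition`
#'   (per-core true 10-way gate-class fractions among classified immune
#'   cells).
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_cases = 2, regions_per_case = c(2, 2),
#'   cells_per_core = c(100, 150), seed = 7))
#' names(coh)
#' @export
simulate_cohort <- function(spec,
                            archetypes_ihc4 = default_archetypes("IHC4"),
                            archetypes_immune = default_archetypes("Immune"),
                            niches = default_niches(),
                            niche_weights = default_niche_weights(),
                            dapi_low_fraction = 0.1,
                            other_fraction = 0.1,
                            core_radius_px = 1500,
                            pixel_size_um = 0.325,
                            blobs_per_core = 8) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (nrow(archetypes_ihc4) < 2 || nrow(archetypes_immune) < 2) {
    abort("at least 2 archetypes are required per panel",
      class = "mxifhet_validation_error"
    )
  }
  if (nrow(niches) < 1) {
    abort("at least 1 niche is required", class = "mxifhet_validation_error")
  }
  feat <- patch_features()
  for (i in seq_len(nrow(niches))) {
    check_prob_vector(unlist(niches[i, feat]),
      paste0("niches$composition[", niches$niche[i], "]"))
  }
  for (s in rownames(niche_weights)) {
    check_prob_vector(niche_weights[s, ], paste0("niche_weights[", s, "]"))
  }

  withr::local_seed(spec$seed)

  subtypes <- sample(subtype_levels(), spec$n_cases,
    replace = TRUE, prob = spec$subtype_weights
  )
  polytypic <- runif(spec$n_cases) < spec$polytypic_fraction
  n_regions <- resample(
    seq(spec$regions_per_case[1], spec$regions_per_case[2]),
    spec$n_cases,
    replace = TRUE
  )

  meta <- vector("list", spec$n_cases)
  ihc4 <- vector("list", spec$n_cases)
  immune <- vector("list", spec$n_cases)
  truth_ihc4 <- vector("list", spec$n_cases)
  truth_immune <- vector("list", spec$n_cases)

  ihc4_markers <- panel_markers("IHC4")
  imm_markers <- panel_markers("Immune")
  blob_sd_px <- niches$blob_radius_um / pixel_size_um

  for (i in seq_len(spec$n_cases)) {
    case_id <- sprintf("L%02d", i)
    nr <- n_regions[i]
    core_subtypes <- rep(subtypes[i], nr)
    if (polytypic[i]) {
      others <- setdiff(subtype_levels(), subtypes[i])
      w <- spec$subtype_weights[others]
      second <- sample(others, 1, prob = if (sum(w) > 0) w else NULL)
      n_switch <- resample(seq_len(nr - 1), 1)
      core_subtypes[sample(nr, n_switch)] <- second
    }
    core_ids <- sprintf("%s_r%d", case_id, seq_len(nr))
    meta[[i]] <- tibble(
      case_id = case_id, core_id = core_ids, focus = seq_len(nr),
      subtype = core_subtypes
    )

    ih <- im <- ti <- tm <- vector("list", nr)
    for (r in seq_len(nr)) {
      st <- core_subtypes[r]

      # --- IHC4 section: subtype-weighted archetype mixture, uniform in disk
      n1 <- resample(seq(spec$cells_per_core[1], spec$cells_per_core[2]), 1)
      prev <- vapply(
        archetypes_ihc4[[paste0("prev_", st)]], identity, numeric(1)
      )
      arch <- sample(archetypes_ihc4$name, n1, replace = TRUE, prob = prev)
      rr <- core_radius_px * sqrt(runif(n1))
      th <- runif(n1, 0, 2 * pi)
      cells1 <- tibble(
        cell_id = sprintf("%s_I%05d", core_ids[r], seq_len(n1)),
        case_id = case_id, core_id = core_ids[r],
        x = core_radius_px + rr * cos(th),
        y = core_radius_px + rr * sin(th),
        area = runif(n1, 60, 220),
        DAPI = draw_dapi(n1, dapi_low_fraction)
      )
      cells1 <- dplyr::bind_cols(
        cells1, intensities_for(arch, archetypes_ihc4, ihc4_markers)
      )
      ih[[r]] <- cells1
      ti[[r]] <- tibble(
        cell_id = cells1$cell_id, core_id = core_ids[r],
        case_id = case_id, archetype = arch
      )

      # --- Immune section: niche blobs inside the disk
      n2 <- resample(seq(spec$cells_per_core[1], spec$cells_per_core[2]), 1)
      n_blobs <- max(3L, rpois(1, blobs_per_core))
      blob_niche <- sample(niches$niche, n_blobs,
        replace = TRUE, prob = niche_weights[st, niches$niche]
      )
      sds <- blob_sd_px[match(blob_niche, niches$niche)]
      centres <- sample_blob_centres(
        n_blobs, core_radius_px, 3.5 * mean(sds)
      )
      blob_of <- sample(n_blobs, n2, replace = TRUE)
      dx <- rnorm(n2, 0, sds[blob_of])
      dy <- rnorm(n2, 0, sds[blob_of])
      # truncate blob tails at 2 SD so niches stay locally coherent
      rr2 <- sqrt(dx^2 + dy^2)
      over <- rr2 > 2 * sds[blob_of]
      if (any(over)) {
        sc <- (2 * sds[blob_of][over]) / rr2[over]
        dx[over] <- dx[over] * sc
        dy[over] <- dy[over] * sc
      }
      xy <- clip_to_disk(
        cbind(centres[blob_of, 1] + dx, centres[blob_of, 2] + dy),
        core_radius_px
      )
      # The niche map is spatial: a cell expresses the niche of the nearest
      # blob centre, so overlapping blobs still yield locally coherent
      # neighbourhoods (mixing only along territory boundaries).
      d2 <- outer(xy[, 1], centres[, 1], `-`)^2 +
        outer(xy[, 2], centres[, 2], `-`)^2
      nearest <- max.col(-d2, ties.method = "first")
      cell_niche <- blob_niche[nearest]
      cls <- character(n2)
      is_other <- runif(n2) < other_fraction
      cls[is_other] <- "other"
      for (b in seq_len(n_blobs)) {
        idx <- which(nearest == b & !is_other)
        if (length(idx) == 0) next
        comp <- unlist(niches[niches$niche == blob_niche[b], feat])
        cls[idx] <- sample(feat, length(idx), replace = TRUE, prob = comp)
      }
      cells2 <- tibble(
        cell_id = sprintf("%s_M%05d", core_ids[r], seq_len(n2)),
        case_id = case_id, core_id = core_ids[r],
        x = xy[, 1], y = xy[, 2],
        area = runif(n2, 60, 220),
        DAPI = draw_dapi(n2, dapi_low_fraction)
      )
      cells2 <- dplyr::bind_cols(
        cells2, intensities_for(cls, archetypes_immune, imm_markers)
      )
      im[[r]] <- cells2
      tm[[r]] <- tibble(
        cell_id = cells2$cell_id, core_id = core_ids[r],
        case_id = case_id, gate_class = cls,
        niche = cell_niche, blob = nearest
      )
    }
    ihc4[[i]] <- bind_rows(ih)
    immune[[i]] <- bind_rows(im)
    truth_ihc4[[i]] <- bind_rows(ti)
    truth_immune[[i]] <- bind_rows(tm)
  }

  truth_immune <- bind_rows(truth_immune)
  truth_comp <- truth_immune |>
    filter(.data$gate_class != "other") |>
    count(.data$core_id, .data$gate_class) |>
    group_by(.data$core_id) |>
    mutate(true_fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    select("core_id", feature = "gate_class", "true_fraction")

  structure(
    list(
      cells = list(ihc4 = bind_rows(ihc4), immune = bind_rows(immune)),
      metadata = bind_rows(meta),
      truth = list(ihc4 = bind_rows(truth_ihc4), immune = truth_immune),
      truth_composition = truth_comp,
      params = list(
        spec = spec, dapi_low_fraction = dapi_low_fraction,
        other_fraction = other_fraction, core_radius_px = core_radius_px,
        pixel_size_um = pixel_size_um
      )
    ),
    class = "mxif_cohort"
  )
}

#' Simulate a flat archetype mixture (no spatial structure)
#'
#' Convenience generator for clustering validation: `n` cells drawn from a
#' mixture of marker archetypes with known labels, without cores or niches.
#'
#' @param n Number of cells.
#' @param archetypes Archetype tibble (see [default_archetypes()]).
#' @param weights Mixture weights over archetypes (default equal).
#' @param seed Integer seed.
#' @param dapi_low_fraction Fraction of cells with DAPI < 1000.
#' @return A cell tibble with an `archetype` ground-truth column.
#' @export
simulate_archetype_cells <- function(n, archetypes = default_archetypes("IHC4"),
                                     weights = NULL, seed = 1L,
                                     dapi_low_fraction = 0) {
  stopifnot(n >= 1)
  withr::local_seed(seed)
  weights <- weights %||% rep(1 / nrow(archetypes), nrow(archetypes))
  check_prob_vector(weights, "weights")
  markers <- sub(
    "^mean_", "", grep("^mean_", names(archetypes), value = TRUE)
  )
  arch <- sample(archetypes$name, n, replace = TRUE, prob = weights)
  out <- tibble(
    cell_id = sprintf("SIM_c%06d", seq_len(n)),
    case_id = "SIM", core_id = "SIM_r1",
    x = runif(n, 0, 1000), y = runif(n, 0, 1000),
    area = runif(n, 60, 220),
    DAPI = draw_dapi(n, dapi_low_fraction)
  )
  dplyr::bind_cols(
    out, intensities_for(arch, archetypes, markers),
    tibble(archetype = arch)
  )
}

#' Simulate a tonsil positive-control cell table
#'
#' Tonsil tissue carries abundant positive and negative cells for each
#' immune marker, so its per-marker intensity distribution is bimodal. This
#' generator draws, for each marker, a two-component log-normal mixture with
#' known mixing fraction and mode separation, enabling validation of
#' valley-based threshold estimation against the true midpoint.
#'
#' @param seed Integer seed.
#' @param n_cells Number of control cells (>= 100).
#' @param markers Markers to simulate bimodally (default: the gating markers
#'   of the immune panel).
#' @param mixing_fraction Fraction of positive cells per marker.
#' @param separation Distance between negative and positive modes, in log2
#'   raw-intensity units.
#' @param neg_mean Log2 mean of the negative mode.
#' @param sd Log2 SD of each mode.
#' @return A cell tibble (`core_id = "tonsil"`). The attribute
#'   `true_thresholds` carries the per-marker true mode midpoint on the log2
#'   scale.
#' @export
simulate_tonsil_control <- function(seed = 1L, n_cells = 2000,
                                    markers = c(
                                      "CK", "CD3", "CD8", "CD68",
                                      "CD163", "PD1", "PDL1"
                                    ),
                                    mixing_fraction = 0.5,
                                    separation = 4,
                                    neg_mean = 6,
                                    sd = 0.7) {
  if (n_cells < 100) {
    abort("'n_cells' must be at least 100",
      class = "mxifhet_validation_error"
    )
  }
  withr::local_seed(seed)
  out <- tibble(
    cell_id = sprintf("tonsil_c%05d", seq_len(n_cells)),
    case_id = "tonsil", core_id = "tonsil",
    x = runif(n_cells, 0, 1200), y = runif(n_cells, 0, 1200),
    area = runif(n_cells, 60, 220),
    DAPI = pmin(65535, pmax(1000, 2^rnorm(n_cells, 12, 0.5)))
  )
  all_markers <- panel_markers("Immune")
  mids <- setNames(rep(NA_real_, length(all_markers)), all_markers)
  for (m in all_markers) {
    if (m %in% markers) {
      pos <- runif(n_cells) < mixing_fraction
      mu <- ifelse(pos, neg_mean + separation, neg_mean)
      out[[m]] <- draw_intensity(n_cells, mu, sd)
      mids[m] <- neg_mean + separation / 2
    } else {
      out[[m]] <- draw_intensity(n_cells, 7, 1)
    }
  }
  attr(out, "true_thresholds") <- mids[markers]
  out
}

#' Deterministic example cohort metadata reproducing published marginals
#'
#' A synthetic per-core metadata table for 38 multi-focal cases constructed
#' (without randomness) so that its case-level marginals match the cohort
#' summary the package's statistics reproduce: 13/38 polytypic cases, 27/38
#' clinically HR+/HER2- cases, 23/38 grade I or II, and a monotypic subtype
#' split of 10 LumA, 7 LumB, 2 HER2E and 6 Basal. Region counts cycle
#' through 2-9. The table is synthetic: individual rows do not correspond to
#' real study cases.
#'
#' @return A tibble with one row per core: `case_id`, `core_id`, `focus`,
#'   `subtype`, `ihc_class`, `grade`.
#' @examples
#' classify_typy(example_cohort_metadata())
#' @export
example_cohort_metadata <- function() {
  mono <- c(rep("LumA", 10), rep("LumB", 7), rep("HER2E", 2), rep("Basal", 6))
  # Polytypic mixes: 10 LumA/LumB (clinically HR+/HER2-), 1 involving HER2E
  # (clinically HER2+), 2 involving Basal (clinically TNBC).
  poly <- c(
    rep(list(c("LumA", "LumB")), 10),
    list(c("LumB", "HER2E")),
    list(c("Basal", "LumB")),
    list(c("Basal", "HER2E"))
  )
  ihc <- c(
    rep("HR+/HER2-", 17), # monotypic LumA + LumB
    rep("HER2+", 2), # monotypic HER2E
    rep("TNBC", 6), # monotypic Basal
    rep("HR+/HER2-", 10), # polytypic LumA/LumB
    "HER2+", "TNBC", "TNBC"
  )
  grade <- c(rep(c("I", "II"), length.out = 23), rep("III", 15))
  n_regions <- rep(2:9, length.out = 38)
  rows <- purrr::map(seq_len(38), function(i) {
    case_id <- sprintf("L%02d", i)
    nr <- n_regions[i]
    if (i <= 25) {
      st <- rep(mono[i], nr)
    } else {
      mix <- poly[[i - 25]]
      st <- rep(mix[1], nr)
      st[seq(2, nr, by = 2)] <- mix[2]
    }
    tibble(
      case_id = case_id,
      core_id = sprintf("%s_r%d", case_id, seq_len(nr)),
      focus = seq_len(nr),
      subtype = st,
      ihc_class = ihc[i],
      grade = grade[i]
    )
  })
  bind_rows(rows)
}

#' @export
print.mxif_cohort <- function(x, ...) {
  cat("<mxif_cohort>\n")
  cat("  cases:", length(unique(x$metadata$case_id)),
    " cores:", nrow(x$metadata), "\n")
  cat("  IHC4 cells:", nrow(x$cells$ihc4),
    " immune cells:", nrow(x$cells$immune), "\n")
  invisible(x)
}
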