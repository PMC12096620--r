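#' Intensity bin schemes for clinical-style marker categories
#'
#' Category edges on the 0-15 range-normalized scale. For ER and PR:
#' `negative` at exactly 0, `1+` on (0, 7), `2+` on \[7, 12\], `3+` on
#' (12, 15\]. For HER2: `0` on \[0, 5\], `1+` on (5, 10\], `2+` on (10, 13),
#' `3+` on \[13, 15\] — the printed `2+`/`3+` edges overlap at 13, which is
#' resolved in favour of `3+` as a documented convention.
#'
#' @return A tibble with columns `category`, `lower`, `upper`, `lower_inc`,
#'   `upper_inc`, evaluated in row order (first match wins).
#' @examples
#' bin_scheme_er_pr()
#' @export
bin_scheme_er_pr <- function() {
  tibble::tribble(
    ~category,  ~lower, ~upper, ~lower_inc, ~upper_inc,
    "negative",      0,      0, TRUE,       TRUE,
    "1+",            0,      7, FALSE,      FALSE,
    "2+",            7,     12, TRUE,       TRUE,
    "3+",           12,     15, FALSE,      TRUE
  )
}

#' @rdname bin_scheme_er_pr
#' @export
bin_scheme_her2 <- function() {
  tibble::tribble(
    ~category, ~lower, ~upper, ~lower_inc, ~upper_inc,
    "3+",          13,     15, TRUE,       TRUE,
    "2+",          10,     13, FALSE,      FALSE,
    "1+",           5,     10, FALSE,      TRUE,
    "0",            0,      5, TRUE,       TRUE
  )
}

# Order in which histoscore weights apply; categories not listed weigh 0.
hscore_weights <- c("1+" = 1, "2+" = 2, "3+" = 3)

#' Bin normalized marker values into staining categories
#'
#' Assigns each cell exactly one category of `scheme` from its
#' `<marker>_norm` value on the 0-15 scale; the result is appended as
#' `<marker>_bin`. Values outside \[0, 15\] violate the normalization
#' contract and raise an error.
#'
#' @param cells Cell tibble carrying `<marker>_norm`.
#' @param marker Marker name (e.g. `"ER"`).
#' @param scheme A bin scheme tibble; see [bin_scheme_er_pr()].
#' @return `cells` with a `<marker>_bin` factor column appended.
#' @examples
#' x <- tibble::tibble(ER_norm = c(0, 3, 7, 12, 12.5))
#' bin_cells(x, "ER", bin_scheme_er_pr())$ER_bin
#' @export
bin_cells <- function(cells, marker, scheme) {
  col <- paste0(marker, "_norm")
  if (!col %in% names(cells)) {
    abort(paste0("Column '", col, "' not found; normalize first"),
      class = "mxifhet_schema_error"
    )
  }
  v <- cells[[col]]
  if (any(v < 0 | v > 15, na.rm = TRUE)) {
    abort(paste0("'", col, "' has values outside [0, 15]; ",
      "normalization contract violated"), class = "mxifhet_validation_error")
  }
  lab <- rep(NA_character_, length(v))
  for (i in seq_len(nrow(scheme))) {
    lo_ok <- if (scheme$lower_inc[i]) v >= scheme$lower[i] else v > scheme$lower[i]
    hi_ok <- if (scheme$upper_inc[i]) v <= scheme$upper[i] else v < scheme$upper[i]
    hit <- is.na(lab) & lo_ok & hi_ok
    lab[hit] <- scheme$category[i]
  }
  if (anyNA(lab[!is.na(v)])) {
    abort("Bin scheme does not cover all values in [0, 15]",
      class = "mxifhet_validation_error"
    )
  }
  out <- as_tibble(cells)
  out[[paste0(marker, "_bin")]] <- factor(lab, levels = unique(scheme$category))
  out
}

#' Per-core histoscore (H-score)
#'
#' Summarizes staining-intensity categories of the scored cells in each core
#' as `H = 3 * (% 3+) + 2 * (% 2+) + (% 1+)`, ranging 0-300. Cells supplied
#' should already be restricted to the population being scored (typically
#' CK8/18-positive cancer cells) and binned with [bin_cells()].
#'
#' @param cells Binned cell tibble carrying `<marker>_bin` and `core_id`.
#' @param marker Marker name.
#' @return A tibble with one row per core: `core_id`, `marker`, `n_cells`,
#'   `H`, and one `pct_<category>` column per category (summing to 100).
#' @examples
#' x <- tibble::tibble(
#'   core_id = "c1",
#'   ER_bin = factor(rep(c("3+", "2+", "1+"), c(5, 3, 2)),
#'     levels = c("negative", "1+", "2+", "3+"))
#' )
#' histoscore(x, "ER")$H # 230
#' @export
histoscore <- function(cells, marker) {
  col <- paste0(marker, "_bin")
  if (!col %in% names(cells)) {
    abort(paste0("Column '", col, "' not found; run bin_cells() first"),
      class = "mxifhet_schema_error"
    )
  }
  if (nrow(cells) == 0) {
    abort("No scored cells supplied", class = "mxifhet_validation_error")
  }
  pct <- cells |>
    count(.data$core_id, category = .data[[col]], .drop = FALSE) |>
    group_by(.data$core_id) |>
    mutate(
      n_cells = sum(.data$n),
      pct = 100 * .data$n / .data$n_cells
    ) |>
    ungroup()
  h <- pct |>
    mutate(w = dplyr::coalesce(
      hscore_weights[as.character(.data$category)], 0
    )) |>
    group_by(.data$core_id) |>
    summarise(
      n_cells = .data$n_cells[1],
      H = sum(.data$w * .data$pct),
      .groups = "drop"
    )
  wide <- pct |>
    select("core_id", "category", "pct") |>
    tidyr::pivot_wider(
      names_from = "category", values_from = "pct", names_prefix = "pct_"
    )
  h |>
    mutate(marker = marker) |>
    left_join(wide, by = "core_id") |>
    relocate("core_id", "marker", "n_cells", "H")
}

#' Per-core Ki67 positivity
#'
#' Percentage of cancer cells whose range-normalized Ki67 exceeds 0 — any
#' measurable normalized signal counts as positive, mirroring clinical
#' scoring where any nuclear staining is positive. Supply cancer
#' (CK-positive) cells only.
#'
#' @param cells Cancer-cell tibble with `Ki67_norm` and `core_id`.
#' @return Tibble with `core_id`, `n_cancer`, `ki67_pct`.
#' @examples
#' x <- tibble::tibble(core_id = "c1", Ki67_norm = c(0, 0.01, 14))
#' ki67_positivity(x)$ki67_pct # 66.67
#' @export
ki67_positivity <- function(cells) {
  if (!"Ki67_norm" %in% names(cells)) {
    abort("Column 'Ki67_norm' not found", class = "mxifhet_schema_error")
  }
  if (nrow(cells) == 0) {
    abort("No cancer cells supplied", class = "mxifhet_validation_error")
  }
  cells |>
    group_by(.data$core_id) |>
    summarise(
      n_cancer = dplyr::n(),
      ki67_pct = 100 * mean(.data$Ki67_norm > 0),
      .groups = "drop"
    )
}

#' Estimate gating thresholds from a bimodal control tissue
#'
#' For each marker, locates the two dominant modes of the control-cell
#' intensity distribution via kernel density estimation and returns the
#' value at the density minimum (valley) between them. Tonsil tissue, which
#' carries both positive and negative cells for every immune marker, is the
#' intended control. If a marker's distribution is effectively unimodal, a
#' warning is raised and the configured `fallback` threshold is used (an
#' error if none is provided). Entries of `manual` override estimation
#' verbatim.
#'
#' @param control Control cell tibble.
#' @param markers Marker names to threshold.
#' @param transform How to read values: a function applied to the raw marker
#'   column (default `log2(x + 1)`), or the string `"norm"` to use
#'   pre-computed `<marker>_norm` columns.
#' @param manual Optional named numeric vector of manual thresholds returned
#'   verbatim for those markers.
#' @param fallback Optional single fallback threshold for unimodal markers.
#' @param min_peak_frac Local maxima below this fraction of the tallest peak
#'   are ignored when deciding bimodality.
#' @return Named numeric vector of thresholds (units of `transform`).
#' @export
estimate_thresholds <- function(control, markers,
                                transform = function(x) log2(x + 1),
                                manual = NULL, fallback = NULL,
                                min_peak_frac = 0.05) {
  out <- setNames(numeric(length(markers)), markers)
  for (m in markers) {
    if (!is.null(manual) && m %in% names(manual)) {
      out[m] <- manual[[m]]
      next
    }
    v <- if (identical(transform, "norm")) {
      col <- paste0(m, "_norm")
      if (!col %in% names(control)) {
        abort(paste0("Column '", col, "' not found in control table"),
          class = "mxifhet_schema_error"
        )
      }
      control[[col]]
    } else {
      if (!m %in% names(control)) {
        abort(paste0("Marker '", m, "' not found in control table"),
          class = "mxifhet_schema_error"
        )
      }
      transform(control[[m]])
    }
    d <- density(v, n = 1024)
    y <- d$y
    is_max <- which(diff(sign(diff(y))) == -2) + 1
    is_max <- is_max[y[is_max] >= min_peak_frac * max(y)]
    if (length(is_max) < 2) {
      warn(paste0("Marker '", m, "' control distribution looks unimodal; ",
        "using fallback threshold"))
      if (is.null(fallback)) {
        abort(paste0("No fallback threshold configured for marker '", m, "'"),
          class = "mxifhet_validation_error"
        )
      }
      out[m] <- fallback
      next
    }
    peaks <- is_max[order(y[is_max], decreasing = TRUE)][1:2]
    lo <- min(peaks); hi <- max(peaks)
    valley <- lo + which.min(y[lo:hi]) - 1
    out[m] <- d$x[valley]
  }
  out
}

#' Gating configuration for immune phenotyping
#'
#' Binds per-marker positivity thresholds (in the units of the normalized
#' columns, Z-scores by default) to an ordered list of gate definitions.
#' Gates are evaluated most-specific-first: sorted by the number of
#' constrained markers, descending, with ties broken by listed order, so
#' e.g. `CD3+/CD8+/PD1+` wins over `CD3+/CD8+`. Cells satisfying no gate are
#' labelled `"other"`.
#'
#' @param thresholds Named numeric vector of per-marker thresholds; a cell
#'   is positive for a marker when `<marker>_norm > threshold`.
#' @param gates List of gates, each `list(label =, pos =, neg =)`. Defaults
#'   to [default_gates()].
#' @return A list of class `gating_config` with gates already sorted into
#'   evaluation order.
#' @export
gating_config <- function(thresholds, gates = default_gates()) {
  needed <- unique(unlist(purrr::map(gates, function(g) c(g$pos, g$neg))))
  missing <- setdiff(needed, names(thresholds))
  if (length(missing) > 0) {
    abort(paste0("No threshold for marker(s): ",
      paste(missing, collapse = ", ")), class = "mxifhet_config_error")
  }
  for (g in gates) {
    if (length(intersect(g$pos, g$neg)) > 0) {
      abort(paste0("Gate '", g$label,
        "' requires a marker both positive and negative"),
      class = "mxifhet_config_error")
    }
  }
  n_constr <- vapply(gates, function(g) length(g$pos) + length(g$neg), 1L)
  ord <- order(-n_constr, seq_along(gates))
  structure(
    list(thresholds = thresholds, gates = gates[ord]),
    class = "gating_config"
  )
}

#' @rdname gating_config
#' @export
default_gates <- function() {
  list(
    list(label = "CD3+/CD8+/PD1+", pos = c("CD3", "CD8", "PD1"), neg = character()),
    list(label = "CD3+/CD8-/PD1+", pos = c("CD3", "PD1"), neg = "CD8"),
    list(label = "CD68+/CD163+", pos = c("CD68", "CD163"), neg = character()),
    list(label = "CD68+/PDL1+", pos = c("CD68", "PDL1"), neg = character()),
    list(label = "CD163+/PDL1+", pos = c("CD163", "PDL1"), neg = character()),
    list(label = "CD3+/CD8+", pos = c("CD3", "CD8"), neg = character()),
    list(label = "CD3+/CD8-", pos = "CD3", neg = "CD8"),
    list(label = "CD68+", pos = "CD68", neg = character()),
    list(label = "CD163+", pos = "CD163", neg = character()),
    list(label = "CK+", pos = "CK", neg = character())
  )
}

#' Assign immune/cancer phenotypes by binary gating
#'
#' Thresholds each gating marker's normalized intensity and assigns every
#' cell exactly one phenotype label: the first gate (in most-specific-first
#' order, see [gating_config()]) whose positive markers all exceed their
#' thresholds and whose negative markers do not. Ungated cells get
#' `"other"`.
#'
#' @param cells Cell tibble with `<marker>_norm` columns for every gated
#'   marker.
#' @param config A [gating_config()].
#' @return `cells` with a `phenotype` character column appended.
#' @export
gate_immune <- function(cells, config) {
  stopifnot(inherits(config, "gating_config"))
  thr <- config$thresholds
  needed <- unique(unlist(purrr::map(config$gates, function(g) c(g$pos, g$neg))))
  cols <- paste0(needed, "_norm")
  missing <- setdiff(cols, names(cells))
  if (length(missing) > 0) {
    abort(paste0("Missing normalized column(s): ",
      paste(missing, collapse = ", ")), class = "mxifhet_schema_error")
  }
  pos <- purrr::map(needed, function(m) cells[[paste0(m, "_norm")]] > thr[[m]])
  names(pos) <- needed
  lab <- rep(NA_character_, nrow(cells))
  for (g in config$gates) {
    ok <- rep(TRUE, nrow(cells))
    for (m in g$pos) ok <- ok & pos[[m]]
    for (m in g$neg) ok <- ok & !pos[[m]]
    hit <- is.na(lab) & ok
    lab[hit] <- g$label
  }
  lab[is.na(lab)] <- "other"
  out <- as_tibble(cells)
  out$phenotype <- lab
  out
}
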