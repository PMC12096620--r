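#' Quality-control filter on DAPI signal
#'
#' Removes cells whose nuclear DAPI intensity falls below `dapi_min`,
#' restricting analysis to undamaged, well-segmented cells. The boundary is
#' retained: cells with DAPI exactly equal to `dapi_min` pass (strictly
#' "less than" is excluded).
#'
#' @param cells Cell tibble with a numeric `DAPI` column.
#' @param dapi_min Minimum raw DAPI intensity (default 1000).
#' @param quiet If `FALSE` (default), report the number of cells removed.
#' @return The filtered tibble. The attribute `n_removed` records how many
#'   rows were dropped.
#' @examples
#' qc_filter(tibble::tibble(DAPI = c(999, 1000, 1001)))
#' @export
qc_filter <- function(cells, dapi_min = 1000, quiet = FALSE) {
  if (!"DAPI" %in% names(cells)) {
    abort("Cell table has no 'DAPI' column", class = "mxifhet_schema_error")
  }
  if (any(cells$DAPI < 0, na.rm = TRUE)) {
    abort("'DAPI' must be non-negative", class = "mxifhet_schema_error")
  }
  keep <- cells$DAPI >= dapi_min
  out <- as_tibble(cells)[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (!quiet) {
    inform(sprintf(
      "qc_filter: removed %d of %d cells (DAPI < %g)",
      n_removed, length(keep), dapi_min
    ))
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Log2-transform and normalize marker intensities
#'
#' Applies `x -> log2(x + log_offset)` to each raw marker column, then
#' rescales per marker across all cells in the table: either min-max to the
#' 0-15 range used for the IHC4 panel (`mode = "range_0_15"`) or
#' standardization to mean 0, SD 1 used for the immune panel
#' (`mode = "zscore"`). Normalized values are added as `<marker>_norm`
#' columns alongside the raw columns.
#'
#' Normalization is global per marker over the supplied table; callers who
#' want per-core scaling should group beforehand. Optional percentile
#' clipping (`clip_quantiles`) winsorizes the log2 values before min-max
#' scaling for robustness against single extreme cells.
#'
#' @param cells Cell tibble after [qc_filter()].
#' @param markers Marker columns to normalize (default: all panel markers
#'   present in the table).
#' @param mode `"range_0_15"` (IHC4 convention) or `"zscore"` (immune
#'   convention).
#' @param log_offset Value added before log2 (default 1, so raw zeros map to
#'   log2 value 0).
#' @param clip_quantiles Optional length-2 probability pair; log2 values are
#'   winsorized to these quantiles before range scaling. `NULL` (default)
#'   disables clipping.
#' @return `cells` with `<marker>_norm` columns appended.
#' @examples
#' x <- tibble::tibble(ER = c(1, 3, 7))
#' normalize_markers(x, "ER", mode = "range_0_15")$ER_norm
#' @export
normalize_markers <- function(cells,
                              markers = intersect(
                                union(panel_markers("IHC4"),
                                  panel_markers("Immune")),
                                names(cells)
                              ),
                              mode = c("range_0_15", "zscore"),
                              log_offset = 1,
                              clip_quantiles = NULL) {
  mode <- match.arg(mode)
  stopifnot(log_offset >= 0)
  missing <- setdiff(markers, names(cells))
  if (length(missing) > 0) {
    abort(paste0("Missing marker column(s): ", paste(missing, collapse = ", ")),
      class = "mxifhet_schema_error"
    )
  }
  out <- as_tibble(cells)
  for (m in markers) {
    raw <- out[[m]]
    if (any(raw < 0, na.rm = TRUE)) {
      abort(paste0("Marker '", m, "' has negative raw intensities"),
        class = "mxifhet_schema_error"
      )
    }
    v <- log2(raw + log_offset)
    if (mode == "range_0_15") {
      if (!is.null(clip_quantiles)) {
        q <- stats::quantile(v, clip_quantiles, na.rm = TRUE)
        v <- pmin(pmax(v, q[1]), q[2])
      }
      rng <- range(v)
      if (rng[1] == rng[2]) {
        warn(paste0("Marker '", m, "' is constant; normalized values set to 0"))
        norm <- rep(0, length(v))
      } else {
        # clamp: rounding in the division can overshoot the bounds by an ulp
        norm <- pmin(15, pmax(0, 15 * (v - rng[1]) / (rng[2] - rng[1])))
      }
    } else {
      s <- sd(v)
      if (!is.finite(s) || s == 0) {
        abort(paste0("Marker '", m, "' is constant; Z-score is undefined"),
          class = "mxifhet_validation_error"
        )
      }
      norm <- (v - mean(v)) / s
    }
    out[[paste0(m, "_norm")]] <- norm
  }
  out
}
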