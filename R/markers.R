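#' Marker panels
#'
#' The two staining panels handled by the package. The IHC4 panel carries the
#' clinical breast-cancer biomarkers (ER, PR, HER2, Ki67) plus cytokeratin
#' 8/18 (`CK`) as the epithelial mask; the immune panel carries T-cell and
#' macrophage lineage markers plus checkpoint proteins. `DAPI` is present in
#' every cell table as the nuclear counterstain used for quality control but
#' is not part of either analytic panel.
#'
#' @param panel `"IHC4"` or `"Immune"`.
#' @return Character vector of marker column names.
#' @examples
#' panel_markers("IHC4")
#' @export
panel_markers <- function(panel = c("IHC4", "Immune")) {
  panel <- match.arg(panel)
  switch(panel,
    IHC4 = c("ER", "PR", "HER2", "Ki67", "CK"),
    Immune = c("CK", "CD3", "CD8", "CD68", "CD163", "FoxP3", "PD1", "PDL1", "Ki67")
  )
}

#' Cell phenotype labels used in patch composition vectors
#'
#' The ten cell-type features used to describe each image patch: the cancer
#' epithelial fraction (`CK+`) and nine immune lineage phenotypes derived by
#' binary gating. Cells matching no gate are labelled `"other"`; they count
#' toward patch cell totals but not toward any of the ten features.
#'
#' @return Character vector of length 10.
#' @examples
#' patch_features()
#' @export
patch_features <- function() {
  c(
    "CK+",
    "CD3+/CD8-", "CD3+/CD8+",
    "CD68+", "CD163+", "CD68+/CD163+",
    "CD68+/PDL1+", "CD163+/PDL1+",
    "CD3+/CD8+/PD1+", "CD3+/CD8-/PD1+"
  )
}

#' Molecular subtype labels
#' @return Character vector of the four PAM50-style subtype labels.
#' @keywords internal
subtype_levels <- function() c("LumA", "LumB", "HER2E", "Basal")

# Required identifier columns for any cell table.
cell_id_cols <- function() c("cell_id", "case_id", "core_id", "x", "y")

#' Validate a cell table against the panel schema
#'
#' Checks that the identifier columns, `DAPI`, and every marker of the panel
#' are present, and that intensity columns are numeric. Unknown columns are
#' allowed and preserved by all pipeline stages.
#'
#' @param cells A data frame of single cells.
#' @param panel `"IHC4"` or `"Immune"`.
#' @return `cells` as a tibble, invisibly validated.
#' @export
validate_cell_table <- function(cells, panel = c("IHC4", "Immune")) {
  panel <- match.arg(panel)
  cells <- as_tibble(cells)
  required <- c(cell_id_cols(), "DAPI", panel_markers(panel))
  missing <- setdiff(required, names(cells))
  if (length(missing) > 0) {
    abort(paste0(
      "Cell table is missing required column(s): ",
      paste(missing, collapse = ", ")
    ), class = "mxifhet_schema_error")
  }
  numeric_cols <- c("x", "y", "DAPI", panel_markers(panel))
  for (col in numeric_cols) {
    if (!is.numeric(cells[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(cells[[col]]))))
      abort(paste0(
        "Column '", col, "' must be numeric; first offending row: ",
        if (length(bad)) bad[1] else "(type mismatch)"
      ), class = "mxifhet_schema_error")
    }
  }
  cells
}

# Validate a probability vector; `what` names the offending field in errors.
check_prob_vector <- function(p, what, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0)) {
    abort(paste0("'", what, "' must be a non-negative probability vector"),
      class = "mxifhet_validation_error"
    )
  }
  if (abs(sum(p) - 1) > tol) {
    abort(paste0("'", what, "' must sum to 1 (got ", format(sum(p)), ")"),
      class = "mxifhet_validation_error"
    )
  }
  invisible(p)
}
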