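#' Read a single-cell table from CSV or TSV
#'
#' The delimiter is sniffed from the first non-comment line (tab wins over
#' comma when both appear). Lines starting with `#` (provenance headers
#' written by [write_provenance_csv()]) are skipped. The table is validated
#' against the panel schema: identifier columns, `DAPI`, and every panel
#' marker must be present and numeric; unknown columns are preserved.
#'
#' @param path File path.
#' @param panel `"IHC4"` or `"Immune"`.
#' @return A validated cell tibble.
#' @export
read_cell_table <- function(path, panel = c("IHC4", "Immune")) {
  panel <- match.arg(panel)
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "mxifhet_io_error")
  }
  lines <- readr::read_lines(path, n_max = 50)
  first <- lines[!startsWith(lines, "#")][1]
  delim <- if (grepl("\t", first)) "\t" else ","
  tab <- readr::read_delim(
    path,
    delim = delim, comment = "#", show_col_types = FALSE,
    progress = FALSE
  )
  validate_cell_table(tab, panel)
}

#' Write a table as CSV with a provenance header
#'
#' Prepends a comment line recording the seed and configuration hash of the
#' run that produced the table, so every output file is traceable.
#' [read_cell_table()] and `readr::read_csv(comment = "#")` skip it.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param seed Integer seed of the producing run (or `NA`).
#' @param config_hash Hash string of the run configuration (or `NA`).
#' @return `path`, invisibly.
#' @export
write_provenance_csv <- function(x, path, seed = NA, config_hash = NA) {
  header <- sprintf(
    "# mxifhet v%s seed=%s config=%s",
    as.character(utils::packageVersion("mxifhet")),
    as.character(seed), as.character(config_hash)
  )
  readr::write_lines(header, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a simulated cohort to a directory of CSV files
#'
#' Emits `cells_ihc4.csv`, `cells_immune.csv`, `metadata.csv`,
#' `truth_ihc4.csv`, `truth_immune.csv` and `truth_composition.csv`, each
#' with a provenance header carrying the simulation seed.
#'
#' @param cohort An `mxif_cohort` from [simulate_cohort()].
#' @param dir Output directory.
#' @param overwrite Refuse to write into an existing non-empty directory
#'   unless `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "mxif_cohort"))
  ensure_out_dir(dir, overwrite)
  seed <- cohort$params$spec$seed
  h <- rlang::hash(cohort$params)
  tabs <- list(
    cells_ihc4 = cohort$cells$ihc4,
    cells_immune = cohort$cells$immune,
    metadata = cohort$metadata,
    truth_ihc4 = cohort$truth$ihc4,
    truth_immune = cohort$truth$immune,
    truth_composition = cohort$truth_composition
  )
  for (nm in names(tabs)) {
    write_provenance_csv(
      tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
      seed = seed, config_hash = h
    )
  }
  invisible(dir)
}

# Create (or validate emptiness of) an output directory.
ensure_out_dir <- function(dir, overwrite) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite) {
    abort(paste0(
      "Output directory '", dir,
      "' exists and is not empty; pass overwrite = TRUE to reuse it"
    ), class = "mxifhet_io_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  invisible(dir)
}
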