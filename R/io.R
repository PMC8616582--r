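# Readers and writers for the plain-text interchange formats. Delimiter
# follows the file extension: .csv is comma-separated, anything else tab.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop_config(sprintf("%s file not found: %s", what, path))
  }
  x <- readr::read_delim(path, delim = delim_for(path),
                         show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop_config(sprintf("%s file %s lacks column(s): %s", what, path,
                        paste(missing, collapse = ", ")))
  }
  x
}

#' Read a spectral-count table
#'
#' First column `protein_id`, remaining columns one per sample.
#' @param path TSV (or CSV) file.
#' @return A tibble.
#' @export
read_counts <- function(path) {
  x <- read_table_checked(path, "protein_id", "Counts")
  if (names(x)[1] != "protein_id") {
    stop_config("`protein_id` must be the first column of the counts table.")
  }
  x
}

#' Read a sample sheet (`sample_id`, `group`, optional `replicate`)
#' @param path TSV/CSV file.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  read_table_checked(path, c("sample_id", "group"), "Sample sheet")
}

#' Read curated reference sets (`protein_id`, `granule`)
#' @param path TSV/CSV file.
#' @return A tibble.
#' @export
read_reference_sets <- function(path) {
  read_table_checked(path, c("protein_id", "granule"), "Reference")
}

#' Read an identifier alias table (`alias`, `canonical`)
#' @param path TSV/CSV file.
#' @return A tibble.
#' @export
read_alias_map <- function(path) {
  read_table_checked(path, c("alias", "canonical"), "Alias")
}

#' Read long-format per-residue disorder scores
#'
#' Columns `protein_id`, `position`, `score`; an optional predictor mode
#' label (e.g. `"long"`, `"short"`) is recorded as attribute `"mode"`.
#' @param path TSV/CSV file.
#' @param mode Optional predictor mode metadata.
#' @return A tibble with attribute `"mode"`.
#' @export
read_residue_scores <- function(path, mode = NULL) {
  x <- read_table_checked(path, c("protein_id", "position", "score"),
                          "Residue score")
  attr(x, "mode") <- mode
  x
}

#' Read a per-protein disorder summary (`protein_id`, `length`, `total`,
#' `mean`)
#' @param path TSV/CSV file.
#' @return A tibble.
#' @export
read_disorder_summary <- function(path) {
  read_table_checked(path, c("protein_id", "mean"), "Disorder summary")
}

#' Read ROI mean-intensity measurements
#'
#' Columns `animal_id`, `genotype`, `rachis`, `edge1`, `edge2`,
#' `background`.
#' @param path CSV/TSV file.
#' @return A tibble.
#' @export
read_roi_measurements <- function(path) {
  read_table_checked(
    path, c("animal_id", "rachis", "edge1", "edge2", "background"), "ROI"
  )
}

#' Write an enrichment table as TSV
#' @param x An `"enrichment_tbl"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
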