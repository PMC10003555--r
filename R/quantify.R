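BAND_COLS <- c("lane", "condition", "replicate", "band", "intensity")

validate_band_table <- function(tbl) {
  missing <- setdiff(BAND_COLS, names(tbl))
  if (length(missing)) {
    abort(sprintf("missing column: %s", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(tbl$band), c("T", "FL"))
  if (length(bad)) {
    abort(sprintf("`band` must be T or FL; found: %s", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(tbl$intensity)) || any(tbl$intensity < 0)) {
    abort("negative or non-finite intensity")
  }
  if (any(tbl$replicate < 1 | tbl$replicate != floor(tbl$replicate))) {
    abort("`replicate` must be integers >= 1")
  }
  dup <- tbl |>
    dplyr::count(.data$condition, .data$replicate, .data$band) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf(
      "duplicate band rows for (condition, replicate, band): %s",
      paste(sprintf("(%s, %d, %s)", dup$condition, dup$replicate, dup$band),
            collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(tbl)
  class(out) <- c("plor_band_table", class(out))
  out
}

#' Read a band-intensity table
#'
#' Ingests a densitometry export (one row per gel band) as delimited text.
#' Comma or tab is auto-detected from the header line. Required columns:
#' `lane`, `condition`, `replicate`, `band` (values `T` or `FL`),
#' `intensity`; an optional `length_nt` column enables
#' [molar_correct()] in `per_length` mode, and any other columns are
#' preserved as metadata.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @return A validated `plor_band_table` tibble.
#' @examples
#' tbl <- read_band_table(system.file("extdata", "example_bands.csv", package = "plor"))
#' @export
read_band_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_band_table(tbl)
}

#' Construct a band table from data in memory
#'
#' @param tbl A data frame with the columns described in [read_band_table()].
#' @return A validated `plor_band_table` tibble.
#' @export
band_table <- function(tbl) validate_band_table(tbl)

#' Molar correction of band intensities
#'
#' Stain-based signal (e.g. intercalating dyes under UV) scales with RNA mass,
#' so a longer band over-reports its molecule count relative to a shorter one;
#' single-fluorophore labeling scales with molecule count directly. Mode
#' `"per_length"` divides each intensity by its `length_nt` to convert
#' mass-proportional signal to molecule-proportional; `"none"` (the default
#' everywhere in this package) leaves the table untouched.
#'
#' @param tbl A `plor_band_table`.
#' @param mode `"none"` or `"per_length"`.
#' @return The corrected `plor_band_table`.
#' @export
molar_correct <- function(tbl, mode = c("none", "per_length")) {
  mode <- match.arg(mode)
  tbl <- validate_band_table(tbl)
  if (mode == "none") return(tbl)
  if (!"length_nt" %in% names(tbl)) abort("per_length correction requires a `length_nt` column")
  bad <- which(!is.finite(tbl$length_nt) | tbl$length_nt <= 0)
  if (length(bad)) {
    abort(sprintf("per_length correction: missing or invalid length_nt on row(s) %s",
                  paste(bad, collapse = ", ")))
  }
  dplyr::mutate(tbl, intensity = .data$intensity / .data$length_nt)
}

#' Per-condition termination statistics with replicate aggregation
#'
#' Computes the termination efficiency `T/(T+FL)` and read-through ratio
#' `FL/T` per replicate, then aggregates per condition as mean and sample
#' (n-1) standard deviation. Averaging per-replicate efficiencies (rather
#' than pooling intensities) keeps replicates with different exposures
#' weighted equally; the statistics are invariant under per-replicate
#' rescaling of intensities. Replicate pairs missing one band are excluded
#' and counted in the `n_dropped` attribute (with a warning).
#'
#' @param tbl A `plor_band_table`.
#' @return A tibble of class `plor_quant`, one row per condition:
#'   `condition`, `n_replicates`, `mean_efficiency`, `sd_efficiency`,
#'   `mean_ratio_FL_T`, `sd_ratio_FL_T` (sds `NA` when a single replicate;
#'   ratio statistics computed over replicates with `T > 0`).
#' @examples
#' tbl <- read_band_table(system.file("extdata", "example_bands.csv", package = "plor"))
#' summarize_bands(tbl)
#' @export
summarize_bands <- function(tbl) {
  tbl <- validate_band_table(tbl)
  wide <- tbl |>
    dplyr::select("condition", "replicate", "band", "intensity") |>
    tidyr::pivot_wider(names_from = "band", values_from = "intensity")
  if (!"T" %in% names(wide)) wide$T <- NA_real_
  if (!"FL" %in% names(wide)) wide$FL <- NA_real_
  incomplete <- is.na(wide$T) | is.na(wide$FL) | (wide$T + wide$FL == 0)
  n_dropped <- sum(incomplete)
  if (n_dropped > 0L) {
    warn(sprintf("%d replicate pair(s) missing a band or without signal; excluded",
                 n_dropped))
  }
  usable <- wide[!incomplete, , drop = FALSE]
  if (nrow(usable) == 0L) {
    warn("no usable replicate pairs")
    out <- tibble(condition = character(), n_replicates = integer(),
                  mean_efficiency = numeric(), sd_efficiency = numeric(),
                  mean_ratio_FL_T = numeric(), sd_ratio_FL_T = numeric())
  } else {
    out <- usable |>
      dplyr::mutate(
        efficiency = .data$T / (.data$T + .data$FL),
        ratio = ifelse(.data$T > 0, .data$FL / .data$T, NA_real_)
      ) |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(
        n_replicates = dplyr::n(),
        mean_efficiency = mean(.data$efficiency),
        sd_efficiency = if (dplyr::n() > 1L) sd(.data$efficiency) else NA_real_,
        mean_ratio_FL_T = mean(.data$ratio, na.rm = TRUE),
        sd_ratio_FL_T = if (sum(!is.na(.data$ratio)) > 1L) {
          sd(.data$ratio, na.rm = TRUE)
        } else NA_real_,
        .groups = "drop"
      )
  }
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("plor_quant", class(out))
  out
}
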