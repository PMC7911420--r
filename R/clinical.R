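# Clinical workflow table: per-subject scan delays, pain scores and binary
# feature strings, with the median summary the study reports.

#' Read a clinical workflow table
#'
#' Expects a TSV with one row per subject and (at least) the numeric columns
#' `prodrome_delay_min`, `full_blown_delay_min`, `recovery_delay_min`,
#' `nrs_full_blown`, `nrs_recovery`, plus optional binary feature-string
#' columns. A copy of the published per-subject workflow ships with the
#' package (`system.file("extdata", "ntg_clinical_workflow.tsv",
#' package = "dynfc")`).
#'
#' @param path TSV file with a header row.
#' @return a `clinical_table` data.frame.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  clinical_table(df)
}

#' Validate a clinical workflow table
#'
#' @param df data.frame with the columns described in
#'   [read_clinical_table()].
#' @return a `clinical_table` data.frame.
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("prodrome_delay_min", "full_blown_delay_min",
            "recovery_delay_min", "nrs_full_blown", "nrs_recovery")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_mod("clinical", "missing columns: %s",
             paste(missing, collapse = ", "))
  if (nrow(df) < 1) stop_mod("clinical", "need at least one row")
  for (col in need) {
    v <- df[[col]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad))
      stop_mod("clinical", "non-numeric value in column '%s', row %d", col,
               bad[1])
    df[[col]] <- as.numeric(v)
  }
  nrs <- c(df$nrs_full_blown, df$nrs_recovery)
  if (any(nrs < 0 | nrs > 10 | nrs != round(nrs)))
    stop_mod("clinical", "NRS values must be integers in [0, 10]")
  delays <- c(df$prodrome_delay_min, df$full_blown_delay_min,
              df$recovery_delay_min)
  if (any(delays <= 0))
    stop_mod("clinical", "scan delays must be positive")
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Map an NRS pain score to its severity band
#'
#' Mild 1-3, moderate 4-6, severe 7-10; 0 = no pain.
#'
#' @param nrs integer vector of 0-10 pain scores.
#' @return character vector of band labels.
#' @export
nrs_severity_band <- function(nrs) {
  cut(nrs, breaks = c(-0.5, 0.5, 3.5, 6.5, 10.5),
      labels = c("none", "mild", "moderate", "severe")) |> as.character()
}

#' Median summary of the clinical workflow
#'
#' Medians of every numeric column (even-count median = mean of the two
#' middle values, the [stats::median()] convention); NRS medians are
#' reported together with their severity band.
#'
#' @param table a `clinical_table` (or a data.frame accepted by
#'   [clinical_table()]).
#' @return a `clinical_summary` list: `medians` (named numeric) and
#'   `nrs_bands` (named character).
#' @export
summarize_clinical <- function(table) {
  table <- clinical_table(table)
  num <- vapply(table, is.numeric, logical(1))
  med <- vapply(table[num], median, numeric(1))
  bands <- c(
    nrs_full_blown = nrs_severity_band(med[["nrs_full_blown"]]),
    nrs_recovery = nrs_severity_band(med[["nrs_recovery"]]))
  structure(list(medians = med, nrs_bands = bands, n_subjects = nrow(table)),
            class = "clinical_summary")
}

#' @export
print.clinical_summary <- function(x, ...) {
  cat(sprintf("<clinical_summary> %d subjects\n", x$n_subjects))
  for (nm in names(x$medians)) {
    extra <- if (nm %in% names(x$nrs_bands))
      sprintf(" (%s)", x$nrs_bands[[nm]]) else ""
    cat(sprintf("  median %s = %g%s\n", nm, x$medians[[nm]], extra))
  }
  invisible(x)
}
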