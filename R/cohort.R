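#' Required cohort columns
#'
#' Column names every cohort table must provide; `diagnosis` is optional.
#' @return Character vector of required column names.
#' @export
cohort_columns <- function() {
  c("subject_id", "age", "sex", "education", "ticv", "wmh",
    "abeta_ratio", "ptau", "ttau", "hippocampal_volume")
}

#' Build a validated cohort table from a data frame
#'
#' One row per participant: CSF Abeta42/40 ratio (unitless), phospho-tau181
#' and total tau (pg/ml), hippocampal volume (ul), covariates age (years),
#' sex (0 = male, 1 = female), education (years), TICV (ml), WMH (ml), and
#' an optional clinical diagnosis (NC/SCD/MCI/DAT). Missing biomarker values
#' are kept as `NA` and flagged, never imputed.
#'
#' @param df Data frame with the columns of [cohort_columns()].
#' @param source Provenance string recorded on the object.
#' @param hv_units Units of the `hippocampal_volume` column as supplied:
#'   "ul" (default) or "ml" (converted to ul on construction).
#' @return A `cohort_table` (data frame subclass).
#' @export
cohort_table <- function(df, source = "in-memory", hv_units = c("ul", "ml")) {
  hv_units <- match.arg(hv_units)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols)) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    dup <- unique(df$subject_id[duplicated(df$subject_id)])
    stop("duplicate subject_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(cohort_columns(), "subject_id")
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  if (hv_units == "ml") {
    df$hippocampal_volume <- df$hippocampal_volume * 1000
  }
  check_pos <- function(col, strict) {
    v <- df[[col]]
    bad <- if (strict) !is.na(v) & v <= 0 else !is.na(v) & v < 0
    if (any(bad)) {
      stop("invalid ", col, " for subject(s) ",
           paste(df$subject_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  check_pos("age", strict = TRUE)
  check_pos("ticv", strict = TRUE)
  for (cl in c("wmh", "abeta_ratio", "ptau", "ttau", "hippocampal_volume")) {
    check_pos(cl, strict = FALSE)
  }
  if ("diagnosis" %in% names(df)) {
    known <- c("NC", "SCD", "MCI", "DAT")
    bad <- !is.na(df$diagnosis) & !df$diagnosis %in% known
    if (any(bad)) {
      stop("unknown diagnosis label(s): ",
           paste(unique(df$diagnosis[bad]), collapse = ", "), call. = FALSE)
    }
  }
  structure(df, class = c("cohort_table", "data.frame"),
            source = source, hv_units = "ul")
}

#' Read a cohort table from delimited text
#'
#' Reads a CSV or TSV file (delimiter chosen by extension, ".tsv"/".txt"
#' mean tab) with a header naming the columns of [cohort_columns()].
#'
#' @param path File path.
#' @param hv_units Units of the hippocampal volume column; see
#'   [cohort_table()].
#' @return A validated [cohort_table()].
#' @export
read_cohort_table <- function(path, hv_units = c("ul", "ml")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), fileEncoding = "UTF-8")
  cohort_table(df, source = path, hv_units = match.arg(hv_units))
}

#' Write a cohort table to delimited text
#'
#' @param cohort A [cohort_table()].
#' @param path Output path; ".tsv"/".txt" write tab-separated, else comma.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(cohort), path, sep = sep,
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Subjects with complete classification markers
#'
#' @param cohort A [cohort_table()].
#' @param n_marker "ahv" or "ttau"; decides which N marker must be present.
#' @return Logical vector, `TRUE` where all required markers are non-missing.
#' @export
complete_markers <- function(cohort, n_marker = c("ahv", "ttau")) {
  n_marker <- match.arg(n_marker)
  need <- c("abeta_ratio", "ptau",
            if (n_marker == "ahv") "hippocampal_volume" else "ttau")
  stats::complete.cases(as.data.frame(cohort)[, need, drop = FALSE])
}

#' Published DELCODE sample characteristics by ATN group
#'
#' Per-group sample sizes and marker/covariate means and standard
#' deviations of the DELCODE baseline sample (n = 437), as printed in its
#' descriptive characteristics table. Used as the default parameterization
#' of the synthetic-cohort generator and for consistency checks. Volumes:
#' `ahv_*` in ml (adjusted hippocampal volume), `wmh_*` in ml; CSF markers
#' in pg/ml except the unitless `abeta_*` ratio.
#'
#' @return Data frame with one row per ATN group (Table-order:
#'   A-T-N-, A-T-N+, A-T+N-, A-T+N+, A+T-N-, A+T-N+, A+T+N-, A+T+N+).
#' @export
delcode_reference <- function() {
  data.frame(
    group = c("A-T-N-", "A-T-N+", "A-T+N-", "A-T+N+",
              "A+T-N-", "A+T-N+", "A+T+N-", "A+T+N+"),
    n = c(143L, 41L, 29L, 14L, 45L, 23L, 61L, 81L),
    age_mean = c(69.64, 68.10, 70.20, 70.86, 69.97, 70.91, 73.20, 73.46),
    age_sd = c(5.50, 5.85, 4.56, 5.90, 5.12, 7.10, 5.30, 5.84),
    pct_female = c(48.25, 48.78, 72.41, 28.57, 42.22, 39.13, 47.54, 55.56),
    education_mean = c(14.65, 14.71, 13.79, 16.57, 14.07, 14.43, 13.67, 13.75),
    education_sd = c(2.92, 2.87, 2.02, 2.53, 2.53, 3.19, 3.33, 2.98),
    abeta_mean = c(0.110, 0.108, 0.112, 0.118, 0.074, 0.064, 0.053, 0.050),
    abeta_sd = c(0.011, 0.011, 0.013, 0.014, 0.012, 0.015, 0.011, 0.013),
    ptau_mean = c(41.02, 39.85, 68.02, 74.68, 41.88, 44.49, 93.26, 95.06),
    ptau_sd = c(8.81, 11.84, 10.88, 19.41, 9.99, 9.40, 50.38, 31.09),
    ttau_mean = c(288.18, 291.24, 465.98, 544.38,
                  321.41, 312.96, 677.41, 778.43),
    ttau_sd = c(89.16, 131.09, 115.59, 167.71,
                104.50, 94.48, 335.83, 287.03),
    ahv_mean_ml = c(3.14, 2.64, 3.18, 2.63, 3.12, 2.60, 3.12, 2.56),
    ahv_sd_ml = c(0.21, 0.15, 0.24, 0.11, 0.21, 0.21, 0.23, 0.22),
    wmh_mean = c(3.29, 3.27, 1.42, 2.09, 3.19, 4.66, 6.99, 6.34),
    wmh_sd = c(5.31, 6.07, 1.70, 2.83, 3.61, 6.05, 11.61, 7.96),
    stringsAsFactors = FALSE
  )
}
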