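#' Default analysis cutoffs
#'
#' Published fixed cutoffs for the DELCODE operationalization: amyloid
#' positivity below an Abeta42/40 ratio of 0.09, tau positivity above 57
#' pg/ml phospho-tau, neurodegeneration below 2821.1 ul adjusted
#' hippocampal volume or above 470 pg/ml total tau.
#'
#' @return Named list of cutoff values.
#' @export
default_cutoffs <- function() {
  list(abeta = 0.09, ptau = 57, ahv = 2821.1, ttau = 470)
}

#' Validate an analysis configuration
#'
#' Fills defaults for any field not supplied: N marker "ahv"; fixed
#' published cutoffs (each may instead be the directive "gmm" or "youden"
#' to estimate from data); covariates age, sex, education, TICV, WMH;
#' sequence set "permutations24"; gray-matter absolute threshold 0.05;
#' FDR q 0.05; minimum 3 subjects per sequence position; seed 1.
#'
#' @param raw Named list (possibly empty), e.g. parsed from YAML/JSON.
#' @return An `analysis_config` list with all fields populated.
#' @export
#' @examples
#' validate_config(list())$gm_threshold
#' validate_config(list(n_marker = "ttau"))$n_marker
validate_config <- function(raw = list()) {
  if (!is.list(raw)) stop("config must be a named list", call. = FALSE)
  known <- c("n_marker", "cutoffs", "covariates", "sequences",
             "gm_threshold", "fdr_q", "seed", "min_group_n",
             "adjust_on", "hv_units")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- list(
    n_marker = "ahv",
    cutoffs = default_cutoffs(),
    covariates = c("age", "sex", "education", "ticv", "wmh"),
    sequences = "permutations24",
    gm_threshold = 0.05,
    fdr_q = 0.05,
    seed = 1L,
    min_group_n = 3L,
    adjust_on = "all",   # or "atn_negative": restrict adjustment fit
    hv_units = "ul"
  )
  for (nm in names(raw)) if (!is.null(raw[[nm]])) cfg[[nm]] <- raw[[nm]]
  cfg$n_marker <- tolower(as.character(cfg$n_marker))
  if (cfg$n_marker == "ahv" || cfg$n_marker == "hv") cfg$n_marker <- "ahv"
  if (!cfg$n_marker %in% c("ahv", "ttau")) {
    stop("unsupported N marker '", cfg$n_marker,
         "' (supported: \"ahv\", \"ttau\")", call. = FALSE)
  }
  defaults <- default_cutoffs()
  if (!is.list(cfg$cutoffs)) stop("cutoffs must be a list", call. = FALSE)
  for (nm in names(cfg$cutoffs)) {
    if (!nm %in% names(defaults)) {
      stop("unknown cutoff name '", nm, "'", call. = FALSE)
    }
    v <- cfg$cutoffs[[nm]]
    ok_directive <- is.character(v) && length(v) == 1L &&
      v %in% c("gmm", "youden")
    ok_number <- is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0
    if (!ok_directive && !ok_number) {
      stop("cutoff '", nm,
           "' must be a positive number or \"gmm\"/\"youden\"",
           call. = FALSE)
    }
  }
  cfg$cutoffs <- utils::modifyList(defaults, cfg$cutoffs)
  bad_cov <- setdiff(cfg$covariates, setdiff(cohort_columns(), "subject_id"))
  if (length(bad_cov)) {
    stop("covariate(s) not cohort fields: ", paste(bad_cov, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(cfg$gm_threshold) || cfg$gm_threshold < 0 ||
      cfg$gm_threshold >= 1) {
    stop("gm_threshold must be in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(cfg$fdr_q) || cfg$fdr_q <= 0 || cfg$fdr_q >= 1) {
    stop("fdr_q must be in (0, 1)", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$min_group_n <- as.integer(cfg$min_group_n)
  if (cfg$min_group_n < 1L) stop("min_group_n must be >= 1", call. = FALSE)
  if (!cfg$adjust_on %in% c("all", "atn_negative")) {
    stop("adjust_on must be \"all\" or \"atn_negative\"", call. = FALSE)
  }
  if (!cfg$hv_units %in% c("ul", "ml")) {
    stop("hv_units must be \"ul\" or \"ml\"", call. = FALSE)
  }
  if (!is.character(cfg$sequences) && !inherits(cfg$sequences, "sequence_set")) {
    stop("sequences must be a set name or a sequence_set", call. = FALSE)
  }
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path File path ending in .yaml/.yml or .json.
#' @return A validated `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$covariates)) raw$covariates <- unlist(raw$covariates)
  validate_config(raw)
}
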