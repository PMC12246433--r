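#' Sample sheet
#'
#' Per-sample experimental metadata driving every grouping in the pipeline.
#' Compartments follow the study design: washed cell pellets (`cell`),
#' cell-free conditioned culture medium (`conditioned_medium`), unconditioned
#' `blank_medium` processed identically as background, blood `serum` and
#' `plasma`, white-blood-cell pellets (`wbc`) and their conditioned medium
#' (`wbc_medium`).
#'
#' @param df data.frame with at least `sample_id` and `compartment`; optional
#'   columns `donor`, `culture_medium`, `time_min`, `input_ng`, `replicate`,
#'   `dilution_member`. Missing optional columns are created; empty cells map
#'   to "absent" (`NA`; `culture_medium` defaults to `"none"`, `replicate`
#'   to 1, `dilution_member` to `FALSE`).
#' @return a validated `sample_sheet` data.frame.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "compartment")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop_input("sample sheet missing mandatory column(s): ",
                               paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$compartment <- as.character(df$compartment)
  if (anyDuplicated(df$sample_id)) {
    stop_input("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1L])
  }
  bad <- setdiff(unique(df$compartment), COMPARTMENTS)
  if (length(bad)) {
    stop_input("unknown compartment '", bad[1L], "'; allowed: ",
               paste(COMPARTMENTS, collapse = ", "))
  }
  if (is.null(df$donor)) df$donor <- NA_character_
  df$donor <- as.character(df$donor)
  if (is.null(df$culture_medium)) df$culture_medium <- "none"
  df$culture_medium <- as.character(df$culture_medium)
  df$culture_medium[is.na(df$culture_medium) | df$culture_medium == ""] <- "none"
  bad_med <- setdiff(unique(df$culture_medium), CULTURE_MEDIA)
  if (length(bad_med)) {
    stop_input("unknown culture_medium '", bad_med[1L], "'; allowed: ",
               paste(CULTURE_MEDIA, collapse = ", "))
  }
  if (is.null(df$time_min)) df$time_min <- NA_real_
  df$time_min <- as.numeric(df$time_min)
  if (any(df$time_min < 0, na.rm = TRUE)) stop_input("time_min must be >= 0")
  if (is.null(df$input_ng)) df$input_ng <- NA_real_
  df$input_ng <- as.numeric(df$input_ng)
  if (any(df$input_ng <= 0, na.rm = TRUE)) stop_input("input_ng must be > 0")
  if (is.null(df$replicate)) df$replicate <- 1L
  df$replicate[is.na(df$replicate)] <- 1L
  df$replicate <- as.integer(df$replicate)
  if (any(df$replicate < 1L)) stop_input("replicate must be >= 1")
  if (is.null(df$dilution_member)) df$dilution_member <- FALSE
  df$dilution_member <- parse_logical(df$dilution_member)
  df$dilution_member[is.na(df$dilution_member)] <- FALSE
  if (any(df$dilution_member & is.na(df$input_ng))) {
    bad <- df$sample_id[df$dilution_member & is.na(df$input_ng)][1L]
    stop_input("dilution_member sample '", bad, "' requires input_ng")
  }
  df <- df[, c("sample_id", "compartment", "donor", "culture_medium",
               "time_min", "input_ng", "replicate", "dilution_member")]
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read a sample sheet from TSV
#'
#' @param path tab-separated file with mandatory columns `sample_id`,
#'   `compartment` and the optional columns of [sample_sheet()]; empty cells
#'   mean "absent".
#' @return a `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  sample_sheet(df)
}

#' Write a sample sheet to TSV
#' @param sheet a `sample_sheet`.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Analysis configuration
#'
#' @param alpha significance level for all hypothesis tests (default 0.05).
#' @param detection_threshold numeric intensity (linear scale) above which a
#'   probe is called present, or `"derive"` to derive it from a dilution
#'   series via [derive_detection_threshold()].
#' @param min_detect_samples minimum number of samples a miRNA must be
#'   detected in to enter an averaged signature.
#' @param correlation_subset_policy `"union"` (zero-fill miRNAs absent from
#'   one profile) or `"intersection"`.
#' @param endothelial_reference reference set for blood-origin classification:
#'   `"cells"` (intracellular union), `"media"` (secretory union) or `"both"`.
#' @param seed integer RNG seed recorded in run manifests.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(alpha = 0.05,
                            detection_threshold = "derive",
                            min_detect_samples = 1L,
                            correlation_subset_policy = c("union", "intersection"),
                            endothelial_reference = c("cells", "media", "both"),
                            seed = 1L) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_input("alpha must be in (0, 1)")
  }
  if (!identical(detection_threshold, "derive")) {
    if (!is_scalar_number(detection_threshold) || detection_threshold <= 0) {
      stop_input("detection_threshold must be > 0 when numeric, or \"derive\"")
    }
  }
  min_detect_samples <- as.integer(min_detect_samples)
  if (is.na(min_detect_samples) || min_detect_samples < 1L) {
    stop_input("min_detect_samples must be an integer >= 1")
  }
  structure(list(
    alpha = alpha,
    detection_threshold = detection_threshold,
    min_detect_samples = min_detect_samples,
    correlation_subset_policy = match.arg(correlation_subset_policy),
    endothelial_reference = match.arg(endothelial_reference),
    seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Field names mirror [analysis_config()]; unspecified fields keep their
#' defaults.
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(analysis_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop_input("unknown config field(s): ", paste(extra, collapse = ", "))
  do.call(analysis_config, vals)
}
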