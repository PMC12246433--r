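#' Probe-level intensity matrix
#'
#' Lightweight container for a probes x samples intensity table. Values are
#' fluorescence intensities in arbitrary units; `scale_tag` records whether
#' they are on the linear or log2 scale. The whole pipeline operates on
#' linear-scale signal, because both the detection threshold and the
#' fraction-of-total normalisation are defined on signal magnitude.
#'
#' @param values numeric matrix with unique, non-empty rownames (probe ids)
#'   and colnames (sample ids). `NA` cells are allowed and mean "not measured
#'   on this array" (distinct from an intensity of 0).
#' @param scale_tag `"linear"` (default) or `"log2"`.
#' @return a `probe_matrix`: the numeric matrix carrying a `scale_tag`
#'   attribute.
#' @export
probe_matrix <- function(values, scale_tag = c("linear", "log2")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid)) {
    stop_input("probe_matrix requires rownames (probe ids) and colnames (sample ids)")
  }
  if (anyDuplicated(pid)) {
    stop_input("duplicate probe id: ", pid[duplicated(pid)][1L])
  }
  if (anyDuplicated(sid)) {
    stop_input("duplicate sample id: ", sid[duplicated(sid)][1L])
  }
  if (scale_tag == "linear" && any(values < 0, na.rm = TRUE)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop_input("negative intensity at probe '", pid[idx[1L]],
               "', sample '", sid[idx[2L]], "' with scale_tag = linear")
  }
  structure(values, scale_tag = scale_tag, class = c("probe_matrix", "matrix", "array"))
}

scale_tag <- function(x) attr(x, "scale_tag") %||% "linear"

# Re-wrap a plain matrix derived from `template` as a probe_matrix.
pm_like <- function(values, template) {
  probe_matrix(values, scale_tag = scale_tag(template))
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes x %d samples (%s scale)\n",
              nrow(x), ncol(x), scale_tag(x)))
  if (anyNA(x)) cat(sprintf("  %d missing cells\n", sum(is.na(x))))
  invisible(x)
}

#' Read a probe intensity matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample identifiers and a
#' first column of probe identifiers (header name arbitrary, conventionally
#' `probe_id`). Tab separator, `.` decimal point, UTF-8, no quoting. A log2
#' input is exponentiated on load (with a warning) so that downstream
#' thresholding and normalisation always see linear signal.
#'
#' @param path file path.
#' @param scale_tag scale of the stored values, `"linear"` or `"log2"`.
#' @return a [probe_matrix()] on the linear scale.
#' @export
read_intensity_matrix <- function(path, scale_tag = c("linear", "log2")) {
  scale_tag <- match.arg(scale_tag)
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop_input("intensity matrix needs a probe column plus >= 1 sample column: ", path)
  pid <- df[[1L]]
  if (anyDuplicated(pid)) stop_input("duplicate probe id: ", pid[duplicated(pid)][1L])
  sid <- colnames(df)[-1L]
  if (anyDuplicated(sid)) stop_input("duplicate sample id: ", sid[duplicated(sid)][1L])
  vals <- matrix(NA_real_, nrow = length(pid), ncol = length(sid),
                 dimnames = list(pid, sid))
  for (j in seq_along(sid)) {
    raw <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad)) {
      stop_input("non-numeric value '", raw[bad[1L]], "' at probe '",
                 pid[bad[1L]], "', sample '", sid[j], "'")
    }
    vals[, j] <- num
  }
  if (scale_tag == "log2") {
    warning("log2-scale input exponentiated to linear scale on load")
    vals <- 2^vals
    scale_tag <- "linear"
  }
  probe_matrix(vals, scale_tag = scale_tag)
}

#' Write a probe intensity matrix to TSV
#'
#' Inverse of [read_intensity_matrix()]: round-trips are value- and
#' order-identical.
#'
#' @param x a [probe_matrix()] (or plain named matrix).
#' @param path output file path.
#' @export
write_intensity_matrix <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read simplified Agilent Feature Extraction text exports
#'
#' Minimal reader for the tab-delimited per-array text files produced by the
#' Agilent Feature Extraction software: one file per array, a header line of
#' named columns, one row per feature. Only the probe-name column, the chosen
#' signal column and (optionally) a detection-flag column are consumed;
#' multi-section FE headers and QC blocks are out of scope.
#'
#' Probes are taken as the union across files; a probe absent from a file is
#' recorded as `NA` (missing, never silently 0). Duplicate rows for the same
#' probe within a file (replicate spots) are averaged (signal) / OR-ed (flag).
#'
#' @param paths character vector of file paths, one per array.
#' @param signal_column name of the signal column to consume (the upstream
#'   software offers several, e.g. total gene signal vs processed signal; the
#'   choice is the caller's).
#' @param flag_column optional name of a 0/1 detection-flag column; when
#'   given, a parallel logical present/absent matrix is attached as the
#'   `"detection_flags"` attribute.
#' @param probe_column name of the probe identifier column.
#' @param sample_ids sample identifiers, one per file; defaults to the file
#'   base names without extension.
#' @return a [probe_matrix()] (linear scale), optionally carrying a
#'   `"detection_flags"` attribute.
#' @export
read_agilent_fe <- function(paths, signal_column, flag_column = NULL,
                            probe_column = "ProbeName", sample_ids = NULL) {
  if (length(paths) < 1L) stop_input("read_agilent_fe needs >= 1 file")
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  if (length(sample_ids) != length(paths)) {
    stop_input("sample_ids must match paths in length")
  }
  per_file <- lapply(seq_along(paths), function(i) {
    df <- utils::read.delim(paths[i], header = TRUE, sep = "\t", quote = "",
                            check.names = FALSE, stringsAsFactors = FALSE)
    for (col in c(probe_column, signal_column, flag_column)) {
      if (!col %in% colnames(df)) {
        stop_input("column '", col, "' not found in ", paths[i],
                   "; available: ", paste(colnames(df), collapse = ", "))
      }
    }
    sig <- tapply(as.numeric(df[[signal_column]]), df[[probe_column]], mean)
    out <- list(signal = sig)
    if (!is.null(flag_column)) {
      out$flag <- tapply(as.numeric(df[[flag_column]]) != 0, df[[probe_column]], any)
    }
    out
  })
  probes <- sort(unique(unlist(lapply(per_file, function(f) names(f$signal)))))
  vals <- matrix(NA_real_, nrow = length(probes), ncol = length(paths),
                 dimnames = list(probes, sample_ids))
  flags <- if (!is.null(flag_column)) {
    matrix(NA, nrow = length(probes), ncol = length(paths),
           dimnames = list(probes, sample_ids))
  }
  for (i in seq_along(per_file)) {
    sig <- per_file[[i]]$signal
    vals[names(sig), i] <- sig
    if (!is.null(flag_column)) flags[names(per_file[[i]]$flag), i] <- per_file[[i]]$flag
  }
  out <- probe_matrix(vals, scale_tag = "linear")
  if (!is.null(flag_column)) attr(out, "detection_flags") <- flags
  out
}
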