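#' Subtract blank-medium background
#'
#' Conditioned-medium arrays carry signal from the unconditioned medium
#' itself; blank media processed identically provide the background
#' estimate. For every conditioned-medium sample, the mean intensity of the
#' blanks sharing its `culture_medium` is subtracted probe-wise (falling
#' back to the pooled mean of all blanks when no medium-matched blank
#' exists); results are floored at 0 and the blank arrays are dropped from
#' the output. Cell pellets, blood and WBC samples are left untouched: no
#' blank exists for them.
#'
#' @param matrix a [probe_matrix()].
#' @param sheet a [sample_sheet()] covering the matrix columns.
#' @return a [probe_matrix()] without the blank columns.
#' @export
subtract_background <- function(matrix, sheet) {
  sheet <- sheet[sheet$sample_id %in% colnames(matrix), , drop = FALSE]
  blanks <- sheet[sheet$compartment == "blank_medium", , drop = FALSE]
  cond <- sheet[sheet$compartment == "conditioned_medium", , drop = FALSE]
  out <- unclass(matrix)[, , drop = FALSE]
  if (nrow(cond)) {
    if (!nrow(blanks)) {
      stop_input("conditioned-medium sample in medium '", cond$culture_medium[1L],
                 "' has no blank-medium sample to subtract")
    }
    pooled_bg <- rowMeans(out[, blanks$sample_id, drop = FALSE])
    for (k in seq_len(nrow(cond))) {
      med <- cond$culture_medium[k]
      match_ids <- blanks$sample_id[blanks$culture_medium == med]
      bg <- if (length(match_ids)) {
        rowMeans(out[, match_ids, drop = FALSE])
      } else {
        pooled_bg
      }
      out[, cond$sample_id[k]] <- pmax(out[, cond$sample_id[k]] - bg, 0)
    }
  }
  keep <- setdiff(colnames(out), blanks$sample_id)
  pm_like(out[, keep, drop = FALSE], matrix)
}

#' Call detection against an intensity threshold
#'
#' A probe is detected in a sample when its processed intensity is strictly
#' greater than the threshold (a probe exactly at threshold is undetected:
#' deterministic tie rule).
#'
#' @param matrix a [probe_matrix()] (linear scale).
#' @param threshold a [derive_detection_threshold()] result or a nonnegative
#'   number on the same scale as the matrix.
#' @return a `detection_matrix`: logical probe x sample matrix with a
#'   `detected_counts` attribute (per-sample detected totals) and the
#'   threshold recorded.
#' @export
call_detection <- function(matrix, threshold) {
  if (inherits(threshold, "detection_threshold")) {
    if (!identical(threshold$scale_tag, scale_tag(matrix))) {
      stop_input("threshold scale (", threshold$scale_tag,
                 ") does not match matrix scale (", scale_tag(matrix), ")")
    }
    threshold <- threshold$value
  }
  if (!is_scalar_number(threshold) || threshold < 0) {
    stop_input("threshold must be a nonnegative number")
  }
  det <- unclass(matrix) > threshold
  det[is.na(det)] <- FALSE
  structure(det, detected_counts = colSums(det), threshold = threshold,
            class = c("detection_matrix", "matrix", "array"))
}

#' @export
print.detection_matrix <- function(x, ...) {
  counts <- attr(x, "detected_counts")
  cat(sprintf("detection_matrix: %d probes x %d samples, threshold %.4g\n",
              nrow(x), ncol(x), attr(x, "threshold")))
  cat(sprintf("  detected per sample: mean %.1f (range %d-%d)\n",
              mean(counts), min(counts), max(counts)))
  invisible(x)
}

#' Fraction-of-total intensity normalisation
#'
#' The pipeline's core transform: each sample's intensities are divided by
#' the sample's total intensity over the QC-passing probes, yielding a
#' fraction vector that sums to 1. This makes expression patterns comparable
#' across samples regardless of total signal -- in particular it is exactly
#' invariant to per-sample rescaling of the input, which is what tolerates
#' variable RNA input amounts. With a detection mask enabled, undetected
#' entries are zeroed before totalling, so signatures are defined over
#' detected miRNAs only.
#'
#' @param matrix a [probe_matrix()].
#' @param qc_pass character vector of QC-passing probe ids (default: all
#'   probes). Failing probes are excluded from both numerator and total.
#' @param mask optional [call_detection()] matrix; undetected cells are set
#'   to 0 before normalisation.
#' @return a `fraction_matrix` over the `qc_pass` probes; every column sums
#'   to 1.
#' @export
normalize_total <- function(matrix, qc_pass = NULL, mask = NULL) {
  vals <- unclass(matrix)[, , drop = FALSE]
  if (!is.null(qc_pass)) {
    missing_probes <- setdiff(qc_pass, rownames(vals))
    if (length(missing_probes)) {
      stop_input("qc_pass probe '", missing_probes[1L], "' not in matrix")
    }
    vals <- vals[qc_pass, , drop = FALSE]
  }
  if (!is.null(mask)) {
    m <- mask[rownames(vals), colnames(vals), drop = FALSE]
    vals[!m] <- 0
  }
  vals[is.na(vals)] <- 0
  totals <- colSums(vals)
  zero <- which(totals <= 0)
  if (length(zero)) {
    stop_input("sample '", colnames(vals)[zero[1L]],
               "' has zero total intensity over the normalisation probes")
  }
  fr <- sweep(vals, 2L, totals, "/")
  structure(fr, sample_totals = totals,
            class = c("fraction_matrix", "matrix", "array"))
}

#' @export
print.fraction_matrix <- function(x, ...) {
  cat(sprintf("fraction_matrix: %d probes x %d samples (columns sum to 1)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Union of detected miRNAs over a sample group
#'
#' @param detection a [call_detection()] matrix.
#' @param samples sample ids of the group.
#' @param min_detect_samples minimum number of group samples a miRNA must be
#'   detected in (default 1: "detected across the samples").
#' @return character vector of miRNA ids.
#' @export
detected_union <- function(detection, samples, min_detect_samples = 1L) {
  missing_s <- setdiff(samples, colnames(detection))
  if (length(missing_s)) stop_input("sample '", missing_s[1L], "' not in detection matrix")
  counts <- rowSums(detection[, samples, drop = FALSE])
  rownames(detection)[counts >= min_detect_samples]
}
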