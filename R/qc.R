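#' Per-probe dose-response quality control
#'
#' Across the serial-dilution arrays, a quantitative probe's intensity should
#' rise linearly with RNA input. For every probe this computes the Pearson
#' correlation (and its two-sided p-value) between intensity and `input_ng`
#' over the dilution members; probes without significant correlation are
#' failed and disregarded in all further analyses. Probes with zero intensity
#' variance (undefined r, e.g. fully saturated responses) fail.
#'
#' @param matrix a [probe_matrix()] containing the dilution arrays.
#' @param sheet a [sample_sheet()]; rows with `dilution_member = TRUE` define
#'   the series (>= 3 distinct inputs required).
#' @param alpha significance level for the pass call (default 0.05).
#' @return a `probe_qc` object: `$probe_stats` (probe_id, pearson_r, p_value,
#'   n_points, pass), `$filtered_fraction`, `$pass` (character vector of
#'   passing probe ids), `$alpha`.
#' @export
probe_dose_response <- function(matrix, sheet, alpha = 0.05) {
  dil <- sheet[sheet$dilution_member, , drop = FALSE]
  dil <- dil[dil$sample_id %in% colnames(matrix), , drop = FALSE]
  if (length(unique(dil$input_ng)) < 3L) {
    stop_input("dose-response QC requires >= 3 dilution samples with distinct ",
               "input_ng (correlation p undefined for n < 3)")
  }
  x <- dil$input_ng
  sub <- matrix[, dil$sample_id, drop = FALSE]
  n_probe <- nrow(sub)
  r <- rep(NA_real_, n_probe)
  p <- rep(NA_real_, n_probe)
  for (i in seq_len(n_probe)) {
    y <- sub[i, ]
    if (anyNA(y) || stats::sd(y) == 0) next
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    r[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  pass <- !is.na(r) & is.finite(r) & !is.na(p) & p < alpha
  stats_df <- data.frame(probe_id = rownames(sub), pearson_r = r, p_value = p,
                         n_points = length(x), pass = pass,
                         stringsAsFactors = FALSE)
  structure(list(
    probe_stats = stats_df,
    pass = rownames(sub)[pass],
    filtered_fraction = sum(!pass) / n_probe,
    alpha = alpha
  ), class = "probe_qc")
}

#' @export
print.probe_qc <- function(x, ...) {
  cat(sprintf("probe_qc: %d/%d probes pass (filtered fraction %.4f, alpha %g)\n",
              length(x$pass), nrow(x$probe_stats), x$filtered_fraction, x$alpha))
  invisible(x)
}

#' Derive the detection threshold from a dilution series
#'
#' Walking up the dilution series, a probe that is absent at one input but
#' present at the next larger input is "newly detected" at that step; the
#' detection threshold is the arithmetic mean of the intensities of all such
#' first-detection events, pooled over all steps (per-step sets and means are
#' also recorded). The threshold is reported on the scale of the input
#' matrix.
#'
#' @param matrix a [probe_matrix()] containing the dilution arrays.
#' @param sheet a [sample_sheet()] with `dilution_member` rows at strictly
#'   increasing `input_ng`.
#' @param present optional logical probe x sample present/absent matrix (e.g.
#'   the feature-extraction detection flags); by default a probe is present
#'   when its (background-handled) signal is > 0.
#' @return a `detection_threshold`: `$value`, `$n_contributing_probes`,
#'   `$per_step_new_probe_ids`, `$per_step_means`, `$scale_tag`.
#' @export
derive_detection_threshold <- function(matrix, sheet, present = NULL) {
  dil <- sheet[sheet$dilution_member, , drop = FALSE]
  dil <- dil[dil$sample_id %in% colnames(matrix), , drop = FALSE]
  if (nrow(dil) < 2L) stop_input("threshold derivation requires >= 2 dilution samples")
  if (anyDuplicated(dil$input_ng)) {
    stop_input("dilution inputs must be strictly increasing (duplicate input_ng)")
  }
  dil <- dil[order(dil$input_ng), , drop = FALSE]
  sub <- matrix[, dil$sample_id, drop = FALSE]
  if (is.null(present)) {
    pres <- sub > 0
  } else {
    pres <- present[rownames(sub), dil$sample_id, drop = FALSE]
  }
  steps <- list()
  means <- numeric(0)
  pooled <- numeric(0)
  for (k in 2:ncol(sub)) {
    new <- which(pres[, k] & !pres[, k - 1L])
    step_name <- sprintf("%g->%g", dil$input_ng[k - 1L], dil$input_ng[k])
    steps[[step_name]] <- rownames(sub)[new]
    vals <- sub[new, k]
    means[step_name] <- if (length(vals)) mean(vals) else NA_real_
    pooled <- c(pooled, vals)
  }
  if (!length(pooled)) {
    stop_input("no newly detected probes at any dilution step; the detection ",
               "threshold is undefined -- supply a manual threshold instead")
  }
  structure(list(
    value = mean(pooled),
    n_contributing_probes = length(pooled),
    per_step_new_probe_ids = steps,
    per_step_means = means,
    scale_tag = scale_tag(matrix)
  ), class = "detection_threshold")
}

#' @export
print.detection_threshold <- function(x, ...) {
  cat(sprintf("detection_threshold: %.4g (%s scale) from %d first-detection events over %d steps\n",
              x$value, x$scale_tag, x$n_contributing_probes,
              length(x$per_step_new_probe_ids)))
  invisible(x)
}

#' Normalisation robustness across the dilution series
#'
#' Fraction-of-total normalisation should make expression patterns
#' comparable across RNA inputs. Each dilution sample's fraction-normalised
#' vector is Spearman-correlated against the reference input's vector; the
#' self-correlation row equals 1 by construction.
#'
#' @param matrix a [probe_matrix()] containing the dilution arrays.
#' @param sheet a [sample_sheet()].
#' @param reference_input reference `input_ng` (must be in the series),
#'   conventionally the 100 ng protocol standard.
#' @param qc_pass optional character vector of QC-passing probe ids to
#'   restrict to.
#' @return data.frame (input_ng, spearman_rho, p_value, n).
#' @export
pattern_robustness <- function(matrix, sheet, reference_input = 100,
                               qc_pass = NULL) {
  dil <- sheet[sheet$dilution_member, , drop = FALSE]
  dil <- dil[dil$sample_id %in% colnames(matrix), , drop = FALSE]
  dil <- dil[order(dil$input_ng), , drop = FALSE]
  if (!reference_input %in% dil$input_ng) {
    stop_input("reference_input ", reference_input, " not in the dilution series")
  }
  fr <- normalize_total(matrix[, dil$sample_id, drop = FALSE], qc_pass = qc_pass)
  ref <- fr[, which(dil$input_ng == reference_input)[1L]]
  out <- lapply(seq_len(ncol(fr)), function(j) {
    cr <- spearman_cor(fr[, j], ref, policy = "union")
    data.frame(input_ng = dil$input_ng[j], spearman_rho = cr$rho,
               p_value = cr$p_value, n = cr$n)
  })
  do.call(rbind, out)
}
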