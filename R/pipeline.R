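#' Run the full secretome analysis pipeline
#'
#' Chains the stages end-to-end on one intensity matrix + sample sheet:
#' dilution QC (when a dilution series is present), detection-threshold
#' derivation, blank-medium background subtraction, detection calls,
#' fraction-of-total normalisation, averaged intracellular/secretory
#' signatures and the origin partition, blood endothelial/non-endothelial
#' classification and block correlations (when blood samples are present),
#' culture-grid within/between-group correlation comparison, PCA, and
#' time-course trend classification (when time points are present).
#'
#' @param matrix a [probe_matrix()].
#' @param sheet a [sample_sheet()] covering every matrix column.
#' @param config an [analysis_config()]. With `detection_threshold =
#'   "derive"` a dilution series is required.
#' @param stage run up to this stage: `"qc"`, `"normalize"`, `"signatures"`,
#'   `"compare"`, `"timecourse"` or `"all"`.
#' @return a `secretome_analysis` list with one element per completed stage.
#' @export
run_pipeline <- function(matrix, sheet, config = analysis_config(),
                         stage = c("all", "qc", "normalize", "signatures",
                                   "compare", "timecourse")) {
  stage <- match.arg(stage)
  missing_cols <- setdiff(colnames(matrix), sheet$sample_id)
  if (length(missing_cols)) {
    stop_input("sample '", missing_cols[1L], "' in matrix but not in sample sheet")
  }
  sheet <- sheet[sheet$sample_id %in% colnames(matrix), , drop = FALSE]
  res <- list(config = config)
  class(res) <- "secretome_analysis"

  has_dilution <- any(sheet$dilution_member)
  if (stage == "qc" && !has_dilution) {
    stop_input("dilution series required for the qc stage")
  }
  if (has_dilution) {
    res$qc <- probe_dose_response(matrix, sheet, alpha = config$alpha)
    res$threshold <- if (identical(config$detection_threshold, "derive")) {
      derive_detection_threshold(matrix, sheet)
    } else {
      config$detection_threshold
    }
    dil_inputs <- sheet$input_ng[sheet$dilution_member]
    ref <- if (100 %in% dil_inputs) 100 else max(dil_inputs)
    res$robustness <- pattern_robustness(matrix, sheet, reference_input = ref,
                                         qc_pass = res[["qc"]]$pass)
  } else {
    if (identical(config$detection_threshold, "derive")) {
      stop_input("dilution series required to derive the detection threshold; ",
                 "supply a numeric detection_threshold instead")
    }
    res$threshold <- config$detection_threshold
  }
  qc_pass <- if (is.null(res[["qc"]])) rownames(matrix) else res[["qc"]]$pass
  res$qc_pass <- qc_pass
  if (stage == "qc") return(res)

  bg <- subtract_background(matrix, sheet)
  analysis_sheet <- sheet[sheet$compartment != "blank_medium" &
                            !sheet$dilution_member, , drop = FALSE]
  bg <- bg[, setdiff(colnames(bg), sheet$sample_id[sheet$dilution_member]),
           drop = FALSE]
  bg <- pm_like(bg, matrix)
  res$detection <- call_detection(bg, res$threshold)
  res$intensities <- bg
  res$fractions <- normalize_total(bg, qc_pass = qc_pass, mask = res$detection)
  if (stage == "normalize") return(res)

  sig <- compute_signatures(res, analysis_sheet, config)
  res[names(sig)] <- sig
  if (stage == "signatures") return(res)

  cmp <- compute_comparisons(res, analysis_sheet, config)
  res[names(cmp)] <- cmp
  if (stage == "compare") return(res)

  tc <- compute_timecourse(res, analysis_sheet, config)
  res[names(tc)] <- tc
  res
}

# Averaged signatures, origin partition, blood classification.
compute_signatures <- function(res, sheet, config) {
  out <- list()
  grid_cells <- grid_samples(sheet, "cell")
  grid_media <- grid_samples(sheet, "conditioned_medium")
  if (length(grid_cells) && length(grid_media)) {
    cell_set <- detected_union(res$detection, grid_cells, config$min_detect_samples)
    media_set <- detected_union(res$detection, grid_media, config$min_detect_samples)
    out$partition <- partition_origin(cell_set, media_set)
    out$int_signature <- average_signature(res$fractions, res$detection,
                                           grid_cells, config$min_detect_samples,
                                           label = "endothelial int-miR")
    out$sec_signature <- average_signature(res$fractions, res$detection,
                                           grid_media, config$min_detect_samples,
                                           label = "endothelial sec-miR")
    blood <- sheet$sample_id[sheet$compartment %in% c("serum", "plasma")]
    if (length(blood)) {
      reference <- switch(config$endothelial_reference,
                          cells = cell_set, media = media_set,
                          both = union(cell_set, media_set))
      out$blood_origin <- classify_blood(
        res$detection[, blood, drop = FALSE], reference,
        reference_used = config$endothelial_reference)
    }
  }
  out
}

# Correlation matrices, block summaries, group tests and PCA.
compute_comparisons <- function(res, sheet, config) {
  out <- list()
  policy <- config$correlation_subset_policy
  if (!is.null(res$int_signature) && !is.null(res$sec_signature)) {
    out$int_vs_sec <- spearman_cor(res$int_signature, res$sec_signature,
                                   policy = policy)
  }
  for (frac in c("int", "sec")) {
    comp <- if (frac == "int") "cell" else "conditioned_medium"
    ids <- grid_samples(sheet, comp)
    meta <- sheet[match(ids, sheet$sample_id), ]
    if (length(ids) >= 4L && length(unique(meta$donor)) >= 2L &&
        length(unique(meta$culture_medium)) >= 2L) {
      cm <- correlation_matrix(res$fractions[, ids, drop = FALSE], policy = policy)
      by_donor <- within_between_stats(cm, stats::setNames(meta$donor, ids))
      by_medium <- within_between_stats(cm, stats::setNames(meta$culture_medium, ids))
      wd <- attr(by_donor, "values")$within    # same line, different media
      wm <- attr(by_medium, "values")$within   # same medium, different lines
      tests <- lapply(c("student_t", "welch_t", "mann_whitney"), function(tt) {
        compare_coefficient_groups(wd, wm, test = tt)
      })
      out[[paste0(frac, "_grid")]] <- list(
        cormat = cm, within_line = by_donor["within" == by_donor$block, ],
        within_medium = by_medium["within" == by_medium$block, ],
        within_line_values = wd, within_medium_values = wm, tests = tests)
    }
  }
  blood_ids <- sheet$sample_id[sheet$compartment %in% c("serum", "plasma")]
  if (length(blood_ids) >= 1L && !is.null(res$sec_signature)) {
    profiles <- stats::setNames(
      lapply(blood_ids, function(s) res$fractions[, s]), blood_ids)
    profiles$int_sig <- res$int_signature
    profiles$sec_sig <- res$sec_signature
    cm <- correlation_matrix(profiles, policy = policy)
    grouping <- stats::setNames(
      c(sheet$compartment[match(blood_ids, sheet$sample_id)], "int_sig", "sec_sig"),
      c(blood_ids, "int_sig", "sec_sig"))
    pairs <- list(c("serum", "sec_sig"), c("plasma", "sec_sig"),
                  c("serum", "int_sig"), c("plasma", "int_sig"),
                  c("serum", "plasma"))
    pairs <- Filter(function(p) all(p %in% grouping), pairs)
    cm <- block_stats(cm, grouping, pairs)
    serum_sec <- block_values(cm$rho, grouping, "serum", "sec_sig")
    plasma_sec <- block_values(cm$rho, grouping, "plasma", "sec_sig")
    tests <- NULL
    if (length(serum_sec) >= 2L && length(plasma_sec) >= 2L) {
      tests <- lapply(c("student_t", "welch_t", "mann_whitney"), function(tt) {
        compare_coefficient_groups(serum_sec, plasma_sec, test = tt)
      })
    }
    out$blood_blocks <- list(cormat = cm, blocks = cm$blocks, tests = tests,
                             serum_vs_sec = serum_sec, plasma_vs_sec = plasma_sec)
  }
  if (ncol(res$fractions) >= 2L) {
    out$pca <- pca_profiles(res$fractions)
  }
  out
}

compute_timecourse <- function(res, sheet, config) {
  out <- list()
  for (frac in c("sec", "int")) {
    comp <- if (frac == "sec") "conditioned_medium" else "cell"
    tc <- sheet[sheet$compartment == comp & !is.na(sheet$time_min), , drop = FALSE]
    if (length(unique(tc$time_min)) >= 3L) {
      out[[paste0(frac, "_trends")]] <- trend_classify(
        res$fractions, sheet, fraction = frac, mode = "normalized",
        alpha = config$alpha, detection = res$detection)
      out[[paste0(frac, "_trends_intensity")]] <- trend_classify(
        res$intensities, sheet, fraction = frac, mode = "intensity",
        alpha = config$alpha, detection = res$detection)
      out[[paste0(frac, "_total_signal")]] <- total_signal_trajectory(
        res$intensities, sheet, fraction = frac, qc_pass = res$qc_pass)
    }
  }
  if (!is.null(out$sec_trends) && !is.null(out$int_trends)) {
    out$trend_cross_reference <- cross_reference(out$sec_trends, out$int_trends)
  }
  out
}

# Culture-grid samples of a compartment: outside the dilution and
# time-course arms when a grid exists, otherwise any non-dilution sample.
grid_samples <- function(sheet, compartment) {
  sel <- sheet$compartment == compartment & !sheet$dilution_member
  grid <- sel & is.na(sheet$time_min)
  if (any(grid)) sheet$sample_id[grid] else sheet$sample_id[sel]
}

#' @export
print.secretome_analysis <- function(x, ...) {
  cat("secretome_analysis\n")
  if (!is.null(x[["qc"]])) {
    cat(sprintf("  QC: filtered fraction %.4f", x[["qc"]]$filtered_fraction))
    if (inherits(x$threshold, "detection_threshold")) {
      cat(sprintf("; derived detection threshold %.4g", x$threshold$value))
    }
    cat("\n")
  }
  if (!is.null(x$partition)) {
    p <- x$partition
    cat(sprintf("  partition: %d int-only / %d both / %d sec-only (universe %d)\n",
                length(p$int_only), length(p$both), length(p$sec_only),
                length(p$universe)))
  }
  if (!is.null(x$int_vs_sec)) {
    cat(sprintf("  int vs sec signature: rho = %.3f (p = %.3g)\n",
                x$int_vs_sec$rho, x$int_vs_sec$p_value))
  }
  if (!is.null(x$blood_blocks)) {
    b <- x$blood_blocks$blocks
    for (k in seq_len(nrow(b))) {
      cat(sprintf("  block rho(%s, %s) = %.3f (+/- %.3f, %d pairs)\n",
                  b$group_a[k], b$group_b[k], b$mean_rho[k], b$sd_rho[k],
                  b$n_pairs[k]))
    }
  }
  if (!is.null(x$sec_trends)) {
    ct <- x$sec_trends$counts
    cat(sprintf("  sec trends: %d up / %d down / %d unchanged of %d\n",
                ct[["increasing"]], ct[["decreasing"]], ct[["unchanged"]],
                x$sec_trends$total_detected))
  }
  invisible(x)
}

#' Numeric summary of a pipeline run
#'
#' Flattens the key computed quantities of a [run_pipeline()] result into a
#' JSON-serialisable list (used by the command-line `run` output).
#'
#' @param res a `secretome_analysis`.
#' @return a named list of numbers.
#' @export
pipeline_summary <- function(res) {
  out <- list()
  if (!is.null(res[["qc"]])) {
    out$filtered_fraction <- res[["qc"]]$filtered_fraction
    if (inherits(res$threshold, "detection_threshold")) {
      out$detection_threshold <- res$threshold$value
    }
  }
  if (is.numeric(res$threshold)) out$detection_threshold <- res$threshold
  if (!is.null(res$detection)) {
    out$mean_detected_per_sample <- mean(attr(res$detection, "detected_counts"))
  }
  if (!is.null(res$partition)) {
    p <- res$partition
    out$partition_int_only <- length(p$int_only)
    out$partition_sec_only <- length(p$sec_only)
    out$partition_both <- length(p$both)
    out$partition_universe <- length(p$universe)
  }
  if (!is.null(res$int_vs_sec)) out$int_vs_sec_rho <- res$int_vs_sec$rho
  for (frac in c("int", "sec")) {
    g <- res[[paste0(frac, "_grid")]]
    if (!is.null(g)) {
      out[[paste0(frac, "_within_line_rho")]] <- g$within_line$mean_rho
      out[[paste0(frac, "_within_medium_rho")]] <- g$within_medium$mean_rho
    }
  }
  if (!is.null(res$blood_blocks)) {
    b <- res$blood_blocks$blocks
    for (k in seq_len(nrow(b))) {
      out[[sprintf("rho_%s_vs_%s", b$group_a[k], b$group_b[k])]] <- b$mean_rho[k]
    }
  }
  if (!is.null(res$sec_trends)) {
    ct <- res$sec_trends$counts
    out$sec_increasing <- unname(ct[["increasing"]])
    out$sec_decreasing <- unname(ct[["decreasing"]])
    out$sec_unchanged <- unname(ct[["unchanged"]])
  }
  if (!is.null(res$int_trends)) {
    ct <- res$int_trends$counts
    out$int_unchanged <- unname(ct[["unchanged"]])
    out$int_total_detected <- res$int_trends$total_detected
  }
  out
}
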