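#' Classify per-miRNA time trends
#'
#' For every detected miRNA of a fraction (secretory = conditioned medium,
#' intracellular = cell pellet), the Pearson correlation of its expression
#' with time (raw minutes) is computed across the time-course samples,
#' replicates averaged per time point first. Categories follow the raw
#' p < alpha rule: `increasing` (p < alpha, r > 0), `decreasing` (p < alpha,
#' r < 0), otherwise `unchanged`; zero-variance series (undefined r) are
#' `unchanged`. Benjamini-Hochberg q-values are reported as a supplementary
#' column but play no part in the categories.
#'
#' @param matrix a [normalize_total()] fraction matrix (`mode =
#'   "normalized"`) or a background-handled [probe_matrix()] (`mode =
#'   "intensity"`).
#' @param sheet a [sample_sheet()]; time-course samples are those of the
#'   fraction's compartment carrying `time_min` (>= 3 distinct time points
#'   required).
#' @param fraction `"sec"` or `"int"`.
#' @param mode scale label recorded in the records.
#' @param alpha significance level (default 0.05).
#' @param average_replicates average replicate arrays per time point before
#'   correlating (default TRUE: replicates are technical); FALSE uses every
#'   array as a point.
#' @param detection optional [call_detection()] matrix restricting the table
#'   to miRNAs detected in >= 1 time-course sample; by default any positive
#'   value counts.
#' @return a `trend_table`: `$records` (mirna, mode, pearson_r, p_value,
#'   q_value, category, n_timepoints), `$counts`, `$total_detected`.
#' @export
trend_classify <- function(matrix, sheet, fraction = c("sec", "int"),
                           mode = c("normalized", "intensity"), alpha = 0.05,
                           average_replicates = TRUE, detection = NULL) {
  fraction <- match.arg(fraction)
  mode <- match.arg(mode)
  comp <- if (fraction == "sec") "conditioned_medium" else "cell"
  tc <- sheet[sheet$compartment == comp & !is.na(sheet$time_min) &
                sheet$sample_id %in% colnames(matrix), , drop = FALSE]
  times <- sort(unique(tc$time_min))
  if (length(times) < 3L) {
    stop_input("trend classification requires >= 3 distinct time points for the ",
               fraction, " fraction")
  }
  sub <- unclass(matrix)[, tc$sample_id, drop = FALSE]
  detected <- if (is.null(detection)) {
    rowSums(sub > 0) >= 1L
  } else {
    rowSums(detection[rownames(sub), tc$sample_id, drop = FALSE]) >= 1L
  }
  sub <- sub[detected, , drop = FALSE]
  if (average_replicates) {
    expr <- vapply(times, function(t) {
      rowMeans(sub[, tc$sample_id[tc$time_min == t], drop = FALSE])
    }, numeric(nrow(sub)))
    tvec <- times
  } else {
    expr <- sub
    tvec <- tc$time_min
  }
  n_m <- nrow(expr)
  r <- rep(NA_real_, n_m)
  p <- rep(NA_real_, n_m)
  for (i in seq_len(n_m)) {
    y <- expr[i, ]
    # Balanced flat profiles are constant only up to float summation error;
    # relative variation below 1e-9 is treated as zero variance.
    if (stats::sd(y) == 0 || stats::sd(y) < 1e-9 * mean(abs(y))) next
    ct <- stats::cor.test(tvec, y, method = "pearson", alternative = "two.sided")
    r[i] <- unname(ct$estimate)
    p[i] <- ct$p.value
  }
  category <- rep("unchanged", n_m)
  sig <- !is.na(p) & p < alpha
  category[sig & r > 0] <- "increasing"
  category[sig & r < 0] <- "decreasing"
  records <- data.frame(
    mirna = rownames(expr), mode = mode, pearson_r = r, p_value = p,
    q_value = stats::p.adjust(p, method = "BH"), category = category,
    n_timepoints = length(times), stringsAsFactors = FALSE)
  counts <- c(increasing = sum(category == "increasing"),
              decreasing = sum(category == "decreasing"),
              unchanged = sum(category == "unchanged"))
  structure(list(records = records, counts = counts,
                 total_detected = n_m, fraction = fraction,
                 mode = mode, alpha = alpha),
            class = "trend_table")
}

#' @export
print.trend_table <- function(x, ...) {
  cat(sprintf("trend_table (%s, %s): %d increasing / %d decreasing / %d unchanged of %d detected\n",
              x$fraction, x$mode, x$counts[["increasing"]],
              x$counts[["decreasing"]], x$counts[["unchanged"]],
              x$total_detected))
  invisible(x)
}

#' Cross-reference secretory and intracellular trends
#'
#' Joins the two trend tables on miRNA id to expose synchronous intra- and
#' extracellular changes (e.g. secretory decreases backed by intracellular
#' increases, the signature of secreted reserves).
#'
#' @param sec,int `trend_table`s from the same time course.
#' @return list: `$table` (mirna, sec_category, int_category),
#'   `$contingency` (sec x int category counts).
#' @export
cross_reference <- function(sec, int) {
  joined <- merge(
    sec$records[, c("mirna", "category")],
    int$records[, c("mirna", "category")],
    by = "mirna", suffixes = c("_sec", "_int"))
  names(joined) <- c("mirna", "sec_category", "int_category")
  if (!nrow(joined)) warning("secretory and intracellular trend tables share no miRNAs")
  lev <- c("increasing", "decreasing", "unchanged")
  contingency <- table(factor(joined$sec_category, lev),
                       factor(joined$int_category, lev),
                       dnn = c("sec", "int"))
  list(table = joined, contingency = contingency)
}

#' Total signal intensity over the time course
#'
#' Per time point, the sum of QC-passing probe intensities (replicates
#' averaged) -- conditioned media accumulate secreted miRNA, so their totals
#' rise steadily while cell-pellet totals stay level.
#'
#' @param matrix a background-handled [probe_matrix()].
#' @param sheet a [sample_sheet()].
#' @param fraction `"sec"` or `"int"`.
#' @param qc_pass optional QC-passing probe ids.
#' @return data.frame (time_min, total_intensity).
#' @export
total_signal_trajectory <- function(matrix, sheet, fraction = c("sec", "int"),
                                    qc_pass = NULL) {
  fraction <- match.arg(fraction)
  comp <- if (fraction == "sec") "conditioned_medium" else "cell"
  tc <- sheet[sheet$compartment == comp & !is.na(sheet$time_min) &
                sheet$sample_id %in% colnames(matrix), , drop = FALSE]
  vals <- unclass(matrix)[, tc$sample_id, drop = FALSE]
  if (!is.null(qc_pass)) vals <- vals[qc_pass, , drop = FALSE]
  times <- sort(unique(tc$time_min))
  totals <- vapply(times, function(t) {
    mean(colSums(vals[, tc$sample_id[tc$time_min == t], drop = FALSE]))
  }, numeric(1))
  data.frame(time_min = times, total_intensity = totals)
}
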