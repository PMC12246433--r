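#' Average a group of samples into a signature
#'
#' A signature is a normalised fraction vector over detected miRNAs for a
#' sample group (e.g. the average endothelial intracellular profile over the
#' sixteen cell-pellet arrays). miRNAs detected in at least
#' `min_detect_samples` of the group enter the support; per-miRNA fractions
#' are arithmetically averaged (undetected = 0) and then renormalised to sum
#' to 1, which keeps the signature on the simplex regardless of differing
#' per-sample supports.
#'
#' @param fractions a [normalize_total()] matrix.
#' @param detection a [call_detection()] matrix.
#' @param samples sample ids to average (nonempty).
#' @param min_detect_samples support inclusion rule (default 1).
#' @param label signature label.
#' @return a `mirna_signature`: `$fractions` (named, over the support, sum
#'   1), `$support`, `$n_samples`, `$provenance`.
#' @export
average_signature <- function(fractions, detection, samples,
                              min_detect_samples = 1L, label = "signature") {
  if (!length(samples)) stop_input("average_signature: empty sample set")
  if (min_detect_samples > length(samples)) {
    stop_input("min_detect_samples (", min_detect_samples,
               ") exceeds the group size (", length(samples), ")")
  }
  missing_s <- setdiff(samples, colnames(fractions))
  if (length(missing_s)) stop_input("sample '", missing_s[1L], "' not in fraction matrix")
  sub <- unclass(fractions)[, samples, drop = FALSE]
  det <- detection[rownames(sub), samples, drop = FALSE]
  sub[!det] <- 0
  support <- rownames(sub)[rowSums(det) >= min_detect_samples]
  if (!length(support)) {
    stop_input("signature '", label, "' has empty support under min_detect_samples = ",
               min_detect_samples)
  }
  means <- rowMeans(sub[support, , drop = FALSE])
  structure(list(
    label = label,
    fractions = means / sum(means),
    support = support,
    n_samples = length(samples),
    provenance = samples
  ), class = "mirna_signature")
}

#' @export
print.mirna_signature <- function(x, ...) {
  cat(sprintf("mirna_signature '%s': %d miRNAs averaged over %d sample(s)\n",
              x$label, length(x$support), x$n_samples))
  invisible(x)
}

#' Partition miRNAs by intracellular/secretory origin
#'
#' Splits the detected miRNA universe into three disjoint sets: exclusively
#' intracellular (detected in cell pellets only), exclusively secreted
#' (conditioned media only) and expressed both intra- and extracellularly.
#'
#' @param cell_set miRNAs detected across the cell samples (see
#'   [detected_union()]).
#' @param media_set miRNAs detected across the conditioned-medium samples.
#' @return an `origin_partition`: `$int_only`, `$sec_only`, `$both`,
#'   `$universe` (their union).
#' @export
partition_origin <- function(cell_set, media_set) {
  structure(list(
    int_only = setdiff(cell_set, media_set),
    sec_only = setdiff(media_set, cell_set),
    both = intersect(cell_set, media_set),
    universe = union(cell_set, media_set)
  ), class = "origin_partition")
}

#' @export
print.origin_partition <- function(x, ...) {
  cat(sprintf("origin_partition: %d intracellular-only | %d both | %d secreted-only (universe %d)\n",
              length(x$int_only), length(x$both), length(x$sec_only),
              length(x$universe)))
  invisible(x)
}

#' Classify blood miRNAs as endothelial or non-endothelial
#'
#' For each blood sample, its detected miRNAs are split by presence in the
#' endothelial reference set: present = endothelial-origin candidate (the
#' SE/PE sets of serum/plasma), absent = non-endothelial (SN/PN).
#'
#' @param blood_detection a [call_detection()] matrix over the blood
#'   samples.
#' @param reference nonempty character vector of endothelial reference
#'   miRNAs (cell-sample union by default in the pipeline; the secretory or
#'   combined union are equally valid references).
#' @param reference_used label recording which reference was chosen.
#' @return a `blood_origin`: per sample `$E` and `$N` miRNA sets.
#' @export
classify_blood <- function(blood_detection, reference,
                           reference_used = "cells") {
  if (!length(reference)) stop_input("classify_blood: empty reference set")
  per_sample <- lapply(colnames(blood_detection), function(s) {
    det <- rownames(blood_detection)[blood_detection[, s]]
    list(E = intersect(det, reference), N = setdiff(det, reference))
  })
  names(per_sample) <- colnames(blood_detection)
  structure(list(samples = per_sample, reference_used = reference_used,
                 reference_size = length(reference)),
            class = "blood_origin")
}

#' @export
print.blood_origin <- function(x, ...) {
  cat(sprintf("blood_origin (reference: %s, %d miRNAs):\n",
              x$reference_used, x$reference_size))
  for (s in names(x$samples)) {
    cat(sprintf("  %s: %d endothelial / %d non-endothelial\n", s,
                length(x$samples[[s]]$E), length(x$samples[[s]]$N)))
  }
  invisible(x)
}
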