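#' Spearman correlation between two miRNA profiles
#'
#' Rank correlation with average-tie handling between two fraction vectors
#' over the same miRNA namespace. Under the default `union` policy the
#' comparison runs over miRNAs present in either profile, with absences
#' filled as 0 -- whole "patterns" are compared, so non-overlapping supports
#' are penalised; `intersection` restricts to the shared support for
#' sensitivity analysis. Two-sided p-values use the exact small-sample null
#' distribution (n <= 10, no ties) and the t approximation otherwise.
#'
#' @param x,y named numeric vectors (fractions) or [average_signature()]
#'   objects.
#' @param policy `"union"` or `"intersection"` over the two supports
#'   (entries > 0).
#' @return a `cor_result`: `$rho`, `$p_value`, `$n`, `$policy`. Zero rank
#'   variance yields `rho = NA` (undefined, reported as such).
#' @export
spearman_cor <- function(x, y, policy = c("union", "intersection")) {
  policy <- match.arg(policy)
  x <- as_profile(x)
  y <- as_profile(y)
  ids <- union(names(x), names(y))
  xv <- stats::setNames(numeric(length(ids)), ids)
  yv <- xv
  xv[names(x)] <- x
  yv[names(y)] <- y
  keep <- if (policy == "union") xv > 0 | yv > 0 else xv > 0 & yv > 0
  xv <- xv[keep]
  yv <- yv[keep]
  n <- length(xv)
  if (n < 3L) stop_input("spearman_cor: fewer than 3 paired observations after '",
                         policy, "' restriction")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          policy = policy, note = "zero rank variance"),
                     class = "cor_result"))
  }
  ties <- anyDuplicated(xv) > 0L || anyDuplicated(yv) > 0L
  ct <- suppressWarnings(stats::cor.test(xv, yv, method = "spearman",
                                         exact = (n <= 10L && !ties),
                                         alternative = "two.sided"))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
                 policy = policy),
            class = "cor_result")
}

as_profile <- function(x) {
  if (inherits(x, "mirna_signature")) return(x$fractions)
  if (!is.numeric(x) || is.null(names(x))) {
    stop_input("profiles must be named numeric vectors or mirna_signature objects")
  }
  x
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("spearman rho = %.4f (p = %.3g, n = %d, policy = %s)\n",
              x$rho, x$p_value, x$n, x$policy))
  invisible(x)
}

#' Pairwise Spearman correlation matrix
#'
#' @param profiles a named list of profiles (named numeric vectors and/or
#'   [average_signature()] objects) or a [normalize_total()] matrix (columns
#'   are profiles).
#' @param policy subset policy passed to [spearman_cor()].
#' @return a `cor_block_summary`: `$rho` and `$p` symmetric matrices (unit
#'   diagonal), `$policy`; blocks unset until [block_stats()].
#' @export
correlation_matrix <- function(profiles, policy = c("union", "intersection")) {
  policy <- match.arg(policy)
  if (is.matrix(profiles)) {
    profiles <- stats::setNames(
      lapply(seq_len(ncol(profiles)), function(j) profiles[, j]),
      colnames(profiles))
  }
  if (length(profiles) < 2L) stop_input("correlation_matrix needs >= 2 profiles")
  if (is.null(names(profiles))) names(profiles) <- seq_along(profiles)
  k <- length(profiles)
  rho <- matrix(1, k, k, dimnames = list(names(profiles), names(profiles)))
  p <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      cr <- spearman_cor(profiles[[i]], profiles[[j]], policy = policy)
      rho[i, j] <- rho[j, i] <- cr$rho
      p[i, j] <- p[j, i] <- cr$p_value
    }
  }
  structure(list(rho = rho, p = p, policy = policy, blocks = NULL),
            class = "cor_block_summary")
}

#' Block summaries of a correlation matrix
#'
#' Summarises named regions of a pairwise correlation matrix as the mean of
#' all pairwise coefficients in the block and the (population-style) SD from
#' that mean. Within-group blocks are formed from unique off-diagonal pairs;
#' cross-group blocks from all cross pairs.
#'
#' @param cormat a [correlation_matrix()] result.
#' @param grouping named character vector mapping every sample to a group
#'   label.
#' @param block_pairs list of `c(groupA, groupB)` pairs to summarise
#'   (default: every within- and between-group combination).
#' @return the `cor_block_summary` with `$blocks`: data.frame (group_a,
#'   group_b, mean_rho, sd_rho, n_pairs).
#' @export
block_stats <- function(cormat, grouping, block_pairs = NULL) {
  rho <- cormat$rho
  miss <- setdiff(rownames(rho), names(grouping))
  if (length(miss)) stop_input("grouping does not cover sample '", miss[1L], "'")
  groups <- unique(unname(grouping[rownames(rho)]))
  if (is.null(block_pairs)) {
    block_pairs <- list()
    for (i in seq_along(groups)) {
      for (j in i:length(groups)) {
        block_pairs[[length(block_pairs) + 1L]] <- c(groups[i], groups[j])
      }
    }
  }
  rows <- lapply(block_pairs, function(pair) {
    vals <- block_values(rho, grouping, pair[1L], pair[2L])
    if (!length(vals)) {
      stop_input("empty correlation block (", pair[1L], ", ", pair[2L], ")")
    }
    data.frame(group_a = pair[1L], group_b = pair[2L],
               mean_rho = mean(vals), sd_rho = sd_pop(vals),
               n_pairs = length(vals), stringsAsFactors = FALSE)
  })
  cormat$blocks <- do.call(rbind, rows)
  cormat
}

block_values <- function(rho, grouping, a, b) {
  ia <- which(grouping[rownames(rho)] == a)
  ib <- which(grouping[colnames(rho)] == b)
  if (a == b) {
    if (length(ia) < 2L) return(numeric(0))
    pairs <- utils::combn(ia, 2L)
    rho[cbind(pairs[1L, ], pairs[2L, ])]
  } else {
    as.vector(rho[ia, ib, drop = FALSE])
  }
}

#' Pooled within-group vs between-group correlation summary
#'
#' Pools all unique within-group off-diagonal pairs into one summary and all
#' between-group pairs into another -- e.g. grouping by donor line gives the
#' "same line across media" coefficients, grouping by medium the "same
#' medium across lines" ones.
#'
#' @param cormat a [correlation_matrix()] result.
#' @param grouping named character vector mapping samples to groups.
#' @return data.frame with rows `within` and `between` (mean_rho, sd_rho,
#'   n_pairs), plus the raw coefficient vectors as the `"values"` attribute
#'   (for group tests).
#' @export
within_between_stats <- function(cormat, grouping) {
  rho <- cormat$rho
  miss <- setdiff(rownames(rho), names(grouping))
  if (length(miss)) stop_input("grouping does not cover sample '", miss[1L], "'")
  ids <- rownames(rho)
  pairs <- utils::combn(seq_along(ids), 2L)
  same <- grouping[ids[pairs[1L, ]]] == grouping[ids[pairs[2L, ]]]
  vals <- rho[cbind(pairs[1L, ], pairs[2L, ])]
  within <- vals[same]
  between <- vals[!same]
  out <- data.frame(
    block = c("within", "between"),
    mean_rho = c(mean(within), mean(between)),
    sd_rho = c(sd_pop(within), sd_pop(between)),
    n_pairs = c(length(within), length(between)),
    stringsAsFactors = FALSE)
  attr(out, "values") <- list(within = within, between = between)
  out
}

#' Compare two groups of correlation coefficients
#'
#' @param group_a,group_b numeric coefficient vectors (nonempty; t tests
#'   require >= 2 per group).
#' @param test `"student_t"`, `"welch_t"` or `"mann_whitney"`.
#' @return list: `$p_value` (two-sided), `$test`, `$direction` (`"a<b"`,
#'   `"a>b"` or `"a=b"` by group means).
#' @export
compare_coefficient_groups <- function(group_a, group_b,
                                       test = c("student_t", "welch_t", "mann_whitney")) {
  test <- match.arg(test)
  if (!length(group_a) || !length(group_b)) {
    stop_input("both coefficient groups must be nonempty")
  }
  if (test != "mann_whitney" && (length(group_a) < 2L || length(group_b) < 2L)) {
    stop_input("t-tests require >= 2 coefficients per group")
  }
  if (test != "mann_whitney" &&
      stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(p_value = 1, test = test, direction = "a=b"))
    }
    stop_input("undefined t statistic: both groups have zero variance")
  }
  p <- switch(test,
    student_t = stats::t.test(group_a, group_b, var.equal = TRUE)$p.value,
    welch_t = stats::t.test(group_a, group_b, var.equal = FALSE)$p.value,
    mann_whitney = suppressWarnings(
      stats::wilcox.test(group_a, group_b, alternative = "two.sided"))$p.value
  )
  dmean <- mean(group_a) - mean(group_b)
  list(p_value = p, test = test,
       direction = if (dmean < 0) "a<b" else if (dmean > 0) "a>b" else "a=b")
}

#' Principal component analysis of fraction profiles
#'
#' Samples are observations, miRNAs variables; centred, unscaled by default
#' (the standard configuration of the underlying decomposition).
#'
#' @param fractions a [normalize_total()] matrix (probes x samples).
#' @param center,scale. passed to the decomposition.
#' @return a `mirna_pca`: `$scores` (samples x PCs), `$loadings`,
#'   `$var_explained` (proportions, non-increasing).
#' @export
pca_profiles <- function(fractions, center = TRUE, scale. = FALSE) {
  if (ncol(fractions) < 2L) stop_input("PCA needs >= 2 samples")
  x <- t(unclass(fractions))
  if (scale.) {
    keep <- apply(x, 2L, stats::sd) > 0
    x <- x[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = center, scale. = scale.)
  tot <- sum(pc$sdev^2)
  structure(list(
    scores = pc$x,
    loadings = pc$rotation,
    var_explained = if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev)),
    sdev = pc$sdev
  ), class = "mirna_pca")
}

#' @export
print.mirna_pca <- function(x, ...) {
  ve <- x$var_explained
  cat(sprintf("mirna_pca: %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * ve[1L],
              if (length(ve) > 1L) 100 * ve[2L] else 0))
  invisible(x)
}
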