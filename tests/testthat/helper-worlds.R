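# Shared fixtures: small synthetic worlds and independent oracles.

cat_map <- c(up = "increasing", down = "decreasing", flat = "unchanged")

small_config <- function(..., seed = 1L) {
  generator_config(
    n_mirnas = 60L,
    overlap_design = c(int_only = 10L, sec_only = 10L, shared = 20L),
    wbc_int_support = 40L, wbc_sec_support = 30L, other_support = 20L,
    seed = seed, ...)
}

zero_noise <- function(config_fun = small_config, ...) {
  config_fun(noise_cv = 0, noise_floor_sd = 0, censor_floor = 0, ...)
}

# Rank-then-Pearson Spearman oracle (average ranks), independent of the
# package implementation.
rho_brute <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Pearson r by the explicit sum-of-products formula.
pearson_brute <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
# (tie-free inputs).
mann_whitney_brute <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(length(pooled), n1), 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Brute-force detection-threshold oracle: scan the present/absent matrix
# for first-detection events and average their intensities.
threshold_brute <- function(mat, inputs) {
  ord <- order(inputs)
  mat <- mat[, ord, drop = FALSE]
  pres <- mat > 0
  vals <- numeric(0)
  for (k in 2:ncol(mat)) {
    new <- pres[, k] & !pres[, k - 1L]
    vals <- c(vals, mat[new, k])
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

make_matrix <- function(values, probes = NULL, samples = NULL) {
  values <- as.matrix(values)
  rownames(values) <- probes %||% rownames(values) %||%
    sprintf("p%d", seq_len(nrow(values)))
  colnames(values) <- samples %||% colnames(values) %||%
    sprintf("s%d", seq_len(ncol(values)))
  probe_matrix(values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
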