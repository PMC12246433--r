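# Internal helpers shared across modules.

COMPARTMENTS <- c("cell", "conditioned_medium", "blank_medium",
                  "serum", "plasma", "wbc", "wbc_medium")

CULTURE_MEDIA <- c("MCDB", "MCDB-S", "HIM-V", "EGM-2MV", "none")

#' @keywords internal
stop_input <- function(...) {
  msg <- paste0(...)
  cond <- structure(
    class = c("secmir_input_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

# Population-style standard deviation (divide by n, not n - 1): block
# summaries report the SD of the pairwise coefficients themselves.
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Dirichlet draw via normalised gammas.
rdirichlet1 <- function(n, conc) {
  g <- stats::rgamma(n, shape = conc, rate = 1)
  if (sum(g) <= 0) g <- rep(1, n)
  g / sum(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
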