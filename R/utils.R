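# Internal helpers shared across modules.

# Deterministic per-subject seed derived from the cohort seed. Kept below
# 2^31 so it is always a valid R integer.
subject_seed <- function(seed, index) {
  as.integer((as.double(seed) + 999983 * as.double(index)) %% 2147483629L + 1)
}

# Draw from N(mean, sd) truncated to (lo, hi) by rejection.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) {
    if (mean <= lo || mean >= hi) {
      abort(sprintf("degenerate truncated normal: mean %g outside (%g, %g)",
                    mean, lo, hi))
    }
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single finite number in [%g, %g]",
                  name, lo, hi))
  }
  invisible(x)
}

is_flag <- function(x) is.logical(x) && length(x) == 1 && !is.na(x)

# One epoch as a channels x samples matrix (safe for single-channel arrays).
epoch_mat <- function(data, e) {
  d <- dim(data)
  matrix(data[e, , ], d[2], d[3])
}
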