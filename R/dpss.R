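# Discrete prolate spheroidal (Slepian) sequences.
#
# Computed from the classical symmetric tridiagonal eigenproblem whose
# eigenvectors are the DPSS (diagonal ((N-1-2t)/2)^2 cos(2*pi*w), off-diagonal
# t(N-t)/2, t = 0..N-1, w the normalized half-bandwidth). The tapers are the
# K leading eigenvectors, unit-normalized, with the standard polarity
# convention (symmetric tapers have positive mean; antisymmetric tapers start
# positive). Concentration ratios are obtained from the Toeplitz sinc kernel.

dpss_env <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw, k) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  cached <- dpss_env[[key]]
  if (!is.null(cached)) return(cached)
  if (k < 1 || k > n) abort("`k` must be between 1 and n")
  w <- nw / n
  tt <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w)
  diag_off <- (tt[-1] * (n - tt[-1])) / 2
  # dense symmetric tridiagonal; eigen() returns eigenvalues descending
  M <- diag(diag_main)
  M[cbind(2:n, 1:(n - 1))] <- diag_off
  M[cbind(1:(n - 1), 2:n)] <- diag_off
  ev <- eigen(M, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tapers[, j]
    v <- v / sqrt(sum(v^2))
    if (j %% 2 == 1) {                       # symmetric order: positive mean
      if (sum(v) < 0) v <- -v
    } else {                                 # antisymmetric: positive start
      if (v[2] < 0) v <- -v
    }
    tapers[, j] <- v
  }
  # concentration in [-w, w]: lambda_j = v' S v with S the sinc kernel
  i_minus_j <- outer(tt, tt, "-")
  S <- sin(2 * pi * w * i_minus_j) / (pi * i_minus_j)
  diag(S) <- 2 * w
  eigvals <- vapply(seq_len(k), function(j) {
    v <- tapers[, j]
    drop(crossprod(v, S %*% v))
  }, numeric(1))
  out <- list(tapers = tapers, eigvals = eigvals, nw = nw)
  dpss_env[[key]] <- out
  out
}
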