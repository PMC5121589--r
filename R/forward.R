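#' Synthetic leadfield
#'
#' A toy forward model: each source's gain column is Gaussian, spatially
#' smoothed across neighbouring grid sources with a squared-exponential
#' kernel so nearby sources project similarly, and normalized to unit norm.
#' Anatomy-derived (BEM) leadfields are out of scope; this stands in for them
#' so the beamformer path can be exercised end to end.
#'
#' @param grid A [build_source_grid()] object.
#' @param n_sensors Number of sensors.
#' @param smoothness Spatial correlation length of the gain columns, mm.
#' @param seed Integer seed.
#' @return Object of class `leadfield`: list with `gain`
#'   (n_sensors x n_sources), `n_sensors`, `grid`.
#' @export
make_leadfield <- function(grid, n_sensors, smoothness = 15, seed = 1L) {
  stopifnot(inherits(grid, "source_grid"))
  n_sources <- nrow(grid$positions)
  if (n_sensors < 2) abort("`n_sensors` must be >= 2")
  withr::with_seed(as.integer(seed), {
    raw <- matrix(rnorm(n_sensors * n_sources), n_sensors, n_sources)
    d <- as.matrix(stats::dist(grid$positions))
    K <- exp(-d^2 / (2 * smoothness^2))
    gain <- raw %*% K
    gain <- sweep(gain, 2, sqrt(colSums(gain^2)), "/")
    if (any(!is.finite(gain)) || any(colSums(abs(gain)) == 0))
      abort("degenerate leadfield draw; change the seed")
    structure(list(gain = gain, n_sensors = n_sensors, grid = grid),
              class = "leadfield")
  })
}

#' Project source epochs to sensor space
#'
#' Applies the leadfield gain to source-space epochs and adds white sensor
#' noise.
#'
#' @param epochs Source-space [epoch_array()].
#' @param leadfield A [make_leadfield()] object.
#' @param noise_sd Sensor noise SD relative to the RMS of the projected
#'   signal (default 0.05).
#' @param seed Integer seed for the sensor noise.
#' @return A sensor-space [epoch_array()].
#' @export
project_to_sensors <- function(epochs, leadfield, noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_array"), inherits(leadfield, "leadfield"))
  if (epochs$space != "source") abort("`epochs` must be in source space")
  d <- dim(epochs$data)
  if (d[2] != ncol(leadfield$gain))
    abort("source count of epochs does not match the leadfield")
  withr::with_seed(as.integer(seed), {
    out <- array(0, c(d[1], leadfield$n_sensors, d[3]))
    for (e in seq_len(d[1])) {
      out[e, , ] <- leadfield$gain %*% epoch_mat(epochs$data, e)
    }
    if (noise_sd > 0) {
      scale <- noise_sd * sqrt(mean(out^2))
      out <- out + array(rnorm(length(out), 0, scale), dim(out))
    }
    epoch_array(out, epochs$sampling_rate, "sensor")
  })
}

#' Band-pass filter epochs
#'
#' Zero-phase (forward-backward) Butterworth filtering of every epoch and
#' channel, cascading a high-pass at `lo` and a low-pass at `hi`. Epochs are
#' mirror-padded with `pad_seconds` of signal on both sides before filtering
#' and trimmed afterwards, so edge transients stay outside the retained
#' window. Stop-band attenuation is at least 20 dB one octave outside the
#' band.
#'
#' @param epochs An [epoch_array()].
#' @param lo,hi Band edges in Hz; `hi` must be below Nyquist.
#' @param pad_seconds Mirror padding on each side, seconds (default 2).
#' @return A filtered [epoch_array()] of the same shape.
#' @export
bandpass_epochs <- function(epochs, lo = 2, hi = 45, pad_seconds = 2) {
  stopifnot(inherits(epochs, "epoch_array"))
  fs <- epochs$sampling_rate
  if (hi >= fs / 2) abort("`hi` must be below the Nyquist frequency")
  if (lo <= 0 || lo >= hi) abort("band edges must satisfy 0 < lo < hi")
  d <- dim(epochs$data)
  n_pad <- min(as.integer(round(pad_seconds * fs)), d[3] - 1)
  bh <- signal::butter(3, lo / (fs / 2), type = "high")
  bl <- signal::butter(5, hi / (fs / 2), type = "low")
  out <- epochs$data
  for (e in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- epochs$data[e, ch, ]
      if (n_pad > 0) {
        x <- c(rev(x[2:(n_pad + 1)]), x, rev(x[(d[3] - n_pad):(d[3] - 1)]))
      }
      y <- signal::filtfilt(bh, x)
      y <- signal::filtfilt(bl, y)
      if (n_pad > 0) y <- y[(n_pad + 1):(n_pad + d[3])]
      out[e, ch, ] <- y
    }
  }
  epoch_array(out, fs, epochs$space)
}

#' Epoch-averaged sensor covariance
#'
#' Average over epochs of the per-epoch sample covariance across channels
#' (channels demeaned within epoch). This is the covariance the LCMV filter
#' is built from.
#'
#' @param epochs An [epoch_array()].
#' @return Symmetric positive semi-definite `channels x channels` matrix.
#' @export
epoch_covariance <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_array"))
  d <- dim(epochs$data)
  if (d[1] < 2) abort("at least 2 epochs required")
  if (d[3] < d[2]) {
    warn("fewer samples than channels: covariance is rank-deficient, regularization mandatory")
  }
  acc <- matrix(0, d[2], d[2])
  for (e in seq_len(d[1])) {
    x <- epoch_mat(epochs$data, e)
    x <- x - rowMeans(x)
    acc <- acc + tcrossprod(x) / (d[3] - 1)
  }
  cov <- acc / d[1]
  (cov + t(cov)) / 2
}

#' LCMV beamformer spatial filter
#'
#' Linearly constrained minimum variance filter in the Van Veen formulation:
#' for each source with gain column `l`, the weight row is
#' `(l' C^-1 l)^-1 l' C^-1`, where `C` is the (regularized) sensor
#' covariance. Each filter passes its own source with unit gain while
#' minimizing output variance.
#'
#' @param leadfield A [make_leadfield()] object (or compatible list with a
#'   `gain` matrix).
#' @param cov Sensor covariance matrix.
#' @param reg Regularization as a fraction of the mean sensor variance
#'   (`reg * trace(C)/n` added to the diagonal). Default 0.05.
#' @return Object of class `spatial_filter`: list with `weights`
#'   (n_sources x n_sensors) and `regularization`.
#' @export
lcmv_filter <- function(leadfield, cov, reg = 0.05) {
  gain <- leadfield$gain
  n_sensors <- nrow(gain)
  stopifnot(nrow(cov) == n_sensors, ncol(cov) == n_sensors)
  check_number(reg, "reg", lo = 0)
  C <- cov + reg * sum(diag(cov)) / n_sensors * diag(n_sensors)
  Ci_gain <- tryCatch(
    solve(C, gain),
    error = function(e) abort(paste0(
      "regularized covariance is singular: ", conditionMessage(e),
      "; raise `reg`"))
  )
  denom <- colSums(gain * Ci_gain)
  if (any(abs(denom) < .Machine$double.eps))
    abort("leadfield column with zero projected power; raise `reg`")
  weights <- t(sweep(Ci_gain, 2, denom, "/"))
  structure(list(weights = weights, regularization = reg),
            class = "spatial_filter")
}

#' Reconstruct source time series
#'
#' Applies a spatial filter to sensor-space epochs, yielding source-space
#' epochs (`weights %*% sensor_data` per epoch).
#'
#' @param filter A [lcmv_filter()] object.
#' @param epochs A sensor-space [epoch_array()].
#' @return A source-space [epoch_array()].
#' @export
reconstruct_sources <- function(filter, epochs) {
  stopifnot(inherits(filter, "spatial_filter"), inherits(epochs, "epoch_array"))
  d <- dim(epochs$data)
  if (ncol(filter$weights) != d[2])
    abort(sprintf("filter expects %d sensors, epochs have %d channels",
                  ncol(filter$weights), d[2]))
  out <- array(0, c(d[1], nrow(filter$weights), d[3]))
  for (e in seq_len(d[1])) {
    out[e, , ] <- filter$weights %*% epoch_mat(epochs$data, e)
  }
  epoch_array(out, epochs$sampling_rate, "source")
}
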