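#' Power spectrum container
#'
#' Per-subject power spectra over a set of sources: a `sources x frequencies`
#' matrix on a common frequency axis, either raw or normalized to relative
#' power (each source row divided by its total power over the axis).
#'
#' @param freqs Frequency axis, Hz (strictly increasing).
#' @param power `n_sources x n_freqs` non-negative matrix.
#' @param normalized Whether rows are relative power (sum to 1).
#' @param subject_id Optional subject label.
#' @return Object of class `power_spectrum`.
#' @export
power_spectrum <- function(freqs, power, normalized = FALSE,
                           subject_id = NA_character_) {
  power <- as.matrix(power)
  if (length(freqs) != ncol(power))
    abort("`freqs` length must match the number of power columns")
  if (is.unsorted(freqs, strictly = TRUE))
    abort("`freqs` must be strictly increasing")
  if (any(power < 0)) abort("power values must be non-negative")
  if (normalized) {
    sums <- rowSums(power)
    if (any(abs(sums - 1) > 1e-9))
      abort("normalized spectra must have rows summing to 1")
  }
  structure(list(freqs = as.numeric(freqs), power = power,
                 normalized = normalized, subject_id = subject_id),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d sources x %d freqs (%g-%g Hz)%s%s\n",
              nrow(x$power), length(x$freqs), min(x$freqs), max(x$freqs),
              if (x$normalized) ", relative" else "",
              if (is.na(x$subject_id)) "" else paste0(", ", x$subject_id)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.power_spectrum <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    source = rep(seq_len(nrow(x$power)), times = length(x$freqs)),
    freq = rep(x$freqs, each = nrow(x$power)),
    power = as.vector(x$power)
  )
}

#' Multitaper power spectral density
#'
#' DPSS (Slepian) multitaper estimate per source: per-epoch, per-taper
#' periodograms averaged over tapers and epochs. The time-bandwidth product
#' follows the epoch length and the requested spectral smoothing
#' (half-bandwidth): `NW = epoch_duration * smoothing`, with `2*NW - 1`
#' tapers; 4-s epochs at 0.5 Hz smoothing give NW = 2 and 3 tapers. The
#' frequency axis runs from `fmin` to `fmax` in `fstep` steps; bins are taken
#' from the epoch's native resolution (every second native bin for 4-s
#' epochs at 0.5 Hz steps), or from a zero-padded transform when
#' `zero_pad = TRUE` and the native grid does not contain the requested
#' axis.
#'
#' @param epochs An [epoch_array()].
#' @param fmin,fmax,fstep Frequency axis, Hz. Defaults 2-45 Hz at 0.5 Hz.
#' @param smoothing Spectral smoothing half-bandwidth, Hz (default 0.5).
#' @param zero_pad Allow zero-padding when the requested axis is finer than
#'   the native resolution.
#' @param subject_id Optional label stored in the result.
#' @return An unnormalized [power_spectrum()].
#' @export
multitaper_psd <- function(epochs, fmin = 2, fmax = 45, fstep = 0.5,
                           smoothing = 0.5, zero_pad = FALSE,
                           subject_id = NA_character_) {
  stopifnot(inherits(epochs, "epoch_array"))
  fs <- epochs$sampling_rate
  d <- dim(epochs$data)
  n <- d[3]
  duration <- n / fs
  if (fmax >= fs / 2) abort("`fmax` must be below the Nyquist frequency")
  if (fmin <= 0 || fmin >= fmax || fstep <= 0)
    abort("require 0 < fmin < fmax and fstep > 0")
  nw <- duration * smoothing
  k <- floor(2 * nw - 1)
  if (k < 1) {
    abort(sprintf(paste0(
      "smoothing %g Hz is too small for %g-s epochs (time-bandwidth %.2f ",
      "gives no usable taper); increase `smoothing`"), smoothing, duration, nw))
  }
  target <- seq(fmin, fmax, by = fstep)
  n_fft <- n
  repeat {
    native <- (0:(n_fft %/% 2)) * fs / n_fft
    idx <- match_bins(target, native)
    if (!anyNA(idx)) break
    if (!zero_pad)
      abort(paste0("requested frequency axis is not on the native grid of ",
                   "these epochs; set `zero_pad = TRUE`"))
    n_fft <- n_fft + n
    if (n_fft > 64 * n) abort("cannot reach the requested axis by zero-padding")
  }
  tap <- dpss_tapers(n, nw, k)$tapers
  x <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n)  # samples x (epoch*ch)
  acc <- matrix(0, length(target), ncol(x))
  for (j in seq_len(k)) {
    xt <- x * tap[, j]
    if (n_fft > n) xt <- rbind(xt, matrix(0, n_fft - n, ncol(xt)))
    X <- stats::mvfft(xt)[idx, , drop = FALSE]
    acc <- acc + (Mod(X)^2)
  }
  acc <- acc * (2 / (k * fs))                       # one-sided density
  # average over epochs for each channel
  pw <- array(acc, c(length(target), d[1], d[2]))
  power <- t(apply(pw, c(1, 3), mean))              # channels x freqs
  power <- matrix(power, d[2], length(target))
  power_spectrum(target, power, normalized = FALSE, subject_id = subject_id)
}

match_bins <- function(target, native, tol = 1e-6) {
  vapply(target, function(f) {
    j <- which.min(abs(native - f))
    if (abs(native[j] - f) < tol) j else NA_integer_
  }, integer(1))
}

#' Normalize a spectrum to relative power
#'
#' Divides each source row by its own total power over the full frequency
#' axis (the 2-45 Hz analysis range by construction), so each row sums to 1.
#' Idempotent on already-normalized rows.
#'
#' @param spectrum A [power_spectrum()].
#' @return A normalized [power_spectrum()].
#' @export
normalize_relative <- function(spectrum) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  sums <- rowSums(spectrum$power)
  bad <- which(sums <= 0)
  if (length(bad) > 0)
    abort(sprintf("source row(s) %s have zero total power and cannot be normalized",
                  paste(bad, collapse = ", ")))
  power_spectrum(spectrum$freqs, sweep(spectrum$power, 1, sums, "/"),
                 normalized = TRUE, subject_id = spectrum$subject_id)
}

#' Detect the individual alpha frequency
#'
#' Averages the spectrum over a region-of-interest source set (posterior
#' sources by default in the pipeline) and returns the frequency of the
#' highest local maximum inside the search range. When no local maximum
#' exists in range (e.g. a monotone 1/f spectrum with no alpha bump), the
#' global in-range argmax is returned and flagged as a fallback.
#'
#' @param spectrum A [power_spectrum()].
#' @param roi_sources Integer source indices to average over.
#' @param search_lo,search_hi Search range, Hz (default 6-13).
#' @param method Label describing the averaging space.
#' @return Object of class `iaf_estimate`: list with `iaf`, `method`,
#'   `search_range`, `fallback`.
#' @export
detect_iaf <- function(spectrum, roi_sources, search_lo = 6, search_hi = 13,
                       method = c("source-average-peak", "sensor-average-peak")) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  method <- match.arg(method)
  if (length(roi_sources) == 0) abort("`roi_sources` must be non-empty")
  if (any(roi_sources < 1 | roi_sources > nrow(spectrum$power)))
    abort("`roi_sources` out of range")
  f <- spectrum$freqs
  if (search_lo < min(f) || search_hi > max(f) || search_lo >= search_hi)
    abort("search range must lie inside the frequency axis")
  avg <- colMeans(spectrum$power[roi_sources, , drop = FALSE])
  in_range <- which(f >= search_lo - 1e-9 & f <= search_hi + 1e-9)
  # local maxima on the full axis (strictly above both neighbours)
  n <- length(avg)
  is_lmax <- c(FALSE, avg[2:(n - 1)] > avg[1:(n - 2)] &
                 avg[2:(n - 1)] > avg[3:n], FALSE)
  cand <- intersect(which(is_lmax), in_range)
  if (length(cand) > 0) {
    peak <- cand[which.max(avg[cand])]
    fallback <- FALSE
  } else {
    peak <- in_range[which.max(avg[in_range])]
    fallback <- TRUE
  }
  structure(list(iaf = f[peak], method = method,
                 search_range = c(search_lo, search_hi), fallback = fallback),
            class = "iaf_estimate")
}

#' @export
print.iaf_estimate <- function(x, ...) {
  cat(sprintf("<iaf_estimate> %.2f Hz (%s%s)\n", x$iaf, x$method,
              if (x$fallback) ", fallback: no local maximum" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.iaf_estimate <- function(x, ...) {
  tibble::tibble(iaf = x$iaf, method = x$method,
                 search_lo = x$search_range[1], search_hi = x$search_range[2],
                 fallback = x$fallback)
}

#' Frequency band definition
#'
#' @param name Band label.
#' @param lo,hi Band edges in Hz, inside the 2-45 Hz analysis range.
#' @return Object of class `band_definition`.
#' @export
band_definition <- function(name, lo, hi) {
  if (lo >= hi) abort("band must satisfy lo < hi")
  if (lo < 2 - 1e-9 || hi > 45 + 1e-9)
    abort(sprintf("band [%g, %g] Hz lies outside the 2-45 Hz analysis range",
                  lo, hi))
  structure(list(name = name, lo = lo, hi = hi), class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s [%g, %g] Hz\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' IAF-anchored alpha band
#'
#' The alpha band is anchored to the individual alpha frequency as
#' `[IAF - 2.5, IAF + 2]` Hz (a 9.4 Hz IAF gives 6.9-11.4 Hz).
#'
#' @param iaf Individual alpha frequency, Hz, within (4, 14).
#' @return A [band_definition()] named `"alpha"`.
#' @export
alpha_band_from_iaf <- function(iaf) {
  check_number(iaf, "iaf")
  if (iaf <= 4 || iaf >= 14) abort("`iaf` must lie within (4, 14) Hz")
  band_definition("alpha", iaf - 2.5, iaf + 2.0)
}

#' Band relative power per source
#'
#' Sum of relative power over the frequency bins inside the band (edges
#' inclusive; bins are point frequencies on the 0.5 Hz grid).
#'
#' @param spectrum A normalized [power_spectrum()].
#' @param band A [band_definition()].
#' @return Tibble with `source` and `power` (one row per source), plus the
#'   band name.
#' @export
band_relative_power <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "power_spectrum"),
            inherits(band, "band_definition"))
  if (!spectrum$normalized)
    abort("`spectrum` must be normalized (see normalize_relative())")
  sel <- spectrum$freqs >= band$lo - 1e-9 & spectrum$freqs <= band$hi + 1e-9
  if (!any(sel))
    abort(sprintf("band [%g, %g] Hz contains no bins of the frequency axis",
                  band$lo, band$hi))
  tibble::tibble(
    source = seq_len(nrow(spectrum$power)),
    band = band$name,
    power = rowSums(spectrum$power[, sel, drop = FALSE])
  )
}
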