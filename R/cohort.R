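#' Generate a synthetic cohort
#'
#' Draws a full cohort under a [cohort_config()]: per-group latent alpha peak
#' frequencies (truncated normal on (4, 14) Hz), latent alpha relative
#' powers, ages, neuropsychological scores and hippocampal volumes, plus the
#' source grid. Subject epochs are produced deterministically from the
#' cohort seed; by default they are generated on demand with
#' [subject_epochs()] rather than held in memory, so cohorts at realistic
#' source counts stay light.
#'
#' Two calls with the same config produce bitwise-identical subject tables
#' and signals.
#'
#' @param config A [cohort_config()].
#' @param keep_epochs If `TRUE`, attach all subjects' epoch arrays to the
#'   returned object (memory-heavy for large cohorts).
#' @return An object of class `meg_cohort`: list with `subjects` (tibble, one
#'   row per subject with id, group, age, latent truths, scores and
#'   hippocampal volume), `grid` ([build_source_grid()]), `config`, and
#'   optionally `epochs` (named list of [epoch_array] objects).
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   group_sizes = c(noSCD = 4, MCI = 4), n_per_axis = 2, epoch_count = 3))
#' dplyr::count(cohort$subjects, group)
#' @export
generate_cohort <- function(config, keep_epochs = FALSE) {
  validate_cohort_config(config)
  grid <- build_source_grid(config$n_per_axis, config$grid_spacing,
                            config$neighbor_radius)
  groups <- names(config$group_sizes)
  n_samp <- as.integer(round(config$epoch_duration * config$sampling_rate))
  freqs_pos <- (1:(n_samp %/% 2)) * config$sampling_rate / n_samp
  subjects <- withr::with_seed(config$seed, {
    purrr::map_dfr(groups, function(g) {
      n <- config$group_sizes[[g]]
      iaf <- rnorm_trunc(n, config$iaf_mean[[g]], config$iaf_sd[[g]], 4, 14)
      # the latent alpha relative power must exceed the 1/f background's own
      # alpha-band fraction, else no oscillation amplitude can realize it
      relpower <- vapply(iaf, function(f0) {
        floor_p <- relpower_floor(f0, config$background_exponent, freqs_pos)
        rnorm_trunc(1, config$alpha_relpower_mean[[g]],
                    config$alpha_relpower_sd, floor_p + 0.02, 0.95)
      }, numeric(1))
      tibble::tibble(
        group = g,
        age = rnorm(n, config$age_mean[[g]], config$age_sd[[g]]),
        iaf_true = iaf,
        alpha_relpower_true = relpower
      )
    }) |>
      dplyr::mutate(
        subject_id = sprintf("S%03d", dplyr::row_number()),
        .before = 1
      ) |>
      add_scores(config$score_coefficients)
  })
  cohort <- structure(
    list(subjects = subjects, grid = grid, config = config),
    class = "meg_cohort"
  )
  if (keep_epochs) {
    cohort$epochs <- setNames(
      purrr::map(subjects$subject_id, ~ subject_epochs(cohort, .x)),
      subjects$subject_id
    )
  }
  cohort
}

add_scores <- function(subjects, coefs) {
  for (i in seq_len(nrow(coefs))) {
    row <- coefs[i, ]
    subjects[[row$criterion]] <-
      row$intercept + row$beta_power * subjects$alpha_relpower_true +
      row$beta_peak * subjects$iaf_true +
      rnorm(nrow(subjects), 0, row$noise_sd)
  }
  subjects
}

#' @export
print.meg_cohort <- function(x, ...) {
  cat(sprintf("<meg_cohort> %d subjects (%s), %d sources, seed %d\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(x$config$group_sizes),
                            x$config$group_sizes), collapse = "/"),
              nrow(x$grid$positions), x$config$seed))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.meg_cohort <- function(x, ...) x$subjects

#' Epoch array container
#'
#' @param data Numeric array `epochs x channels x samples` with no NA.
#' @param sampling_rate Sampling rate in Hz.
#' @param space Either `"sensor"` or `"source"`.
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, sampling_rate, space = c("source", "sensor")) {
  space <- match.arg(space)
  if (!is.array(data) || length(dim(data)) != 3)
    abort("`data` must be a 3-d array (epochs x channels x samples)")
  if (anyNA(data)) abort("epoch data must not contain NA")
  check_number(sampling_rate, "sampling_rate", lo = .Machine$double.eps)
  structure(list(data = data, sampling_rate = sampling_rate, space = space),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_array> %d epochs x %d %s channels x %d samples @ %g Hz\n",
              d[1], d[2], x$space, d[3], x$sampling_rate))
  invisible(x)
}

# Fraction of the 1/f background's 2-45 Hz power that already falls in the
# subject's IAF-anchored alpha band: the infeasibility floor for the target
# alpha relative power.
relpower_floor <- function(f0, exponent, freqs_pos,
                           band_lo = f0 - 2.5, band_hi = f0 + 2) {
  w <- freqs_pos^(-exponent)
  in_band <- freqs_pos >= 2 & freqs_pos <= 45
  in_alpha <- freqs_pos >= band_lo & freqs_pos <= band_hi & in_band
  sum(w[in_alpha]) / sum(w[in_band])
}

# Analytic calibration of the oscillation amplitude.
#
# The background is synthesized with one-sided bin powers w_k = f_k^-e
# (normalized to unit total variance). Given a target alpha relative power p
# over the 2-45 Hz analysis range, the sinusoid power a^2/2 must satisfy
#   p = (a^2/2 + N_alpha) / (a^2/2 + N_band)
# where N_band / N_alpha are the background powers inside 2-45 Hz and inside
# the subject's IAF-anchored alpha band. Solvable only when p exceeds the
# background's own alpha fraction.
alpha_amplitude <- function(f0, target_relpower, freqs_pos, exponent,
                            band_lo = f0 - 2.5, band_hi = f0 + 2) {
  w <- freqs_pos^(-exponent)
  w <- w / sum(w)
  in_band <- freqs_pos >= 2 & freqs_pos <= 45
  in_alpha <- freqs_pos >= band_lo & freqs_pos <= band_hi
  n_band <- sum(w[in_band])
  n_alpha <- sum(w[in_alpha & in_band])
  p <- target_relpower
  s2 <- (p * n_band - n_alpha) / (1 - p)
  if (s2 <= 0) {
    abort(sprintf(paste0(
      "target alpha relative power %.3f is below the 1/f background's own ",
      "alpha fraction %.3f; increase the target or the background exponent"),
      p, n_alpha / n_band))
  }
  sqrt(2 * s2)
}

# 1/f^e Gaussian noise, unit variance in expectation, via spectral shaping.
# Returns an n_samples x n_series matrix.
shaped_noise <- function(n_samples, n_series, exponent, freqs_pos) {
  n <- n_samples
  w <- freqs_pos^(-exponent)
  w <- w / sum(w)
  half <- length(freqs_pos)           # n/2 bins: k = 1 .. n/2
  # c_k chosen so each one-sided bin contributes w_k to the variance
  ck <- n * sqrt(w) / 2
  z1 <- matrix(rnorm(half * n_series), half, n_series)
  z2 <- matrix(rnorm(half * n_series), half, n_series)
  X <- matrix(0 + 0i, n, n_series)
  X[2:(half + 1), ] <- ck * (z1 + 1i * z2)
  # Nyquist bin must be real; double weight compensates the missing mirror
  X[half + 1, ] <- sqrt(2) * ck[half] * z1[half, ]
  X[n:(half + 2), ] <- Conj(X[2:half, ])
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

#' Regenerate a subject's epochs
#'
#' Epochs are a sinusoid at the subject's latent alpha peak frequency
#' (uniform random phase per epoch and source) over 1/f^exponent background
#' noise, in source space. The draw depends only on the cohort seed and the
#' subject's position in the cohort, so it is reproducible without storing
#' the arrays.
#'
#' @param cohort A [generate_cohort()] object.
#' @param subject Subject id (e.g. `"S001"`).
#' @return An [epoch_array()] in source space.
#' @export
subject_epochs <- function(cohort, subject) {
  stopifnot(inherits(cohort, "meg_cohort"))
  idx <- match(subject, cohort$subjects$subject_id)
  if (is.na(idx)) abort(sprintf("unknown subject id `%s`", subject))
  cfg <- cohort$config
  row <- cohort$subjects[idx, ]
  n_samples <- as.integer(round(cfg$epoch_duration * cfg$sampling_rate))
  n_sources <- nrow(cohort$grid$positions)
  n_epochs <- cfg$epoch_count
  freqs_pos <- (1:(n_samples %/% 2)) * cfg$sampling_rate / n_samples
  a <- alpha_amplitude(row$iaf_true, row$alpha_relpower_true, freqs_pos,
                       cfg$background_exponent)
  t_axis <- (seq_len(n_samples) - 1) / cfg$sampling_rate
  withr::with_seed(subject_seed(cfg$seed, idx), {
    noise <- shaped_noise(n_samples, n_epochs * n_sources,
                          cfg$background_exponent, freqs_pos)
    phases <- runif(n_epochs * n_sources, 0, 2 * pi)
    osc <- a * cos(outer(2 * pi * row$iaf_true * t_axis, phases, "+"))
    x <- noise + osc
    dat <- aperm(array(x, c(n_samples, n_epochs, n_sources)), c(2, 3, 1))
    epoch_array(dat, cfg$sampling_rate, "source")
  })
}

#' Write cohort tables to CSV
#'
#' Persists the subject table (one row per subject: id, group, age, latent
#' truths, scores, hippocampal volume) and the source grid (positions and
#' adjacency pairs) as plain CSV files.
#'
#' @param cohort A [generate_cohort()] object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "meg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    subjects = file.path(dir, "subjects.csv"),
    grid = file.path(dir, "grid_positions.csv"),
    adjacency = file.path(dir, "grid_adjacency.csv")
  )
  readr::write_csv(cohort$subjects, paths[["subjects"]])
  readr::write_csv(tibble::as_tibble(cohort$grid$positions), paths[["grid"]])
  adj <- which(cohort$grid$adjacency & upper.tri(cohort$grid$adjacency),
               arr.ind = TRUE)
  readr::write_csv(tibble::tibble(from = adj[, 1], to = adj[, 2]),
                   paths[["adjacency"]])
  invisible(paths)
}
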