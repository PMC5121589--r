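#' Default score-generator coefficients
#'
#' The cohort generator produces each neuropsychological score (and the
#' ICV-normalized hippocampal volume) as a linear function of the subject's
#' latent alpha relative power and latent alpha peak frequency plus Gaussian
#' noise:
#' `score = intercept + beta_power * alpha_relpower + beta_peak * iaf + noise`.
#'
#' The default battery contains the 14 neuropsychological criteria plus
#' hippocampal volume. Slopes are non-zero only for the criteria where the
#' corresponding predictor carries a real association in the emulated study
#' design (11 criteria driven by peak frequency, 5 by alpha power), and the
#' intercepts are anchored so that a control-group subject at the reference
#' predictor values (`power_ref`, `iaf_ref`) hits the control-group mean
#' score.
#'
#' @param power_ref Reference alpha relative power (control-group mean).
#' @param iaf_ref Reference alpha peak frequency in Hz (control-group mean).
#' @return A tibble with columns `criterion`, `intercept`, `beta_power`,
#'   `beta_peak`, `noise_sd`.
#' @export
default_score_coefficients <- function(power_ref = 0.32, iaf_ref = 9.8) {
  base <- tibble::tribble(
    ~criterion,            ~mean_ref, ~beta_power, ~beta_peak, ~noise_sd,
    "mmse",                   29,        0,          0.47,      1.4,
    "direct_digit",            8.5,      0,          0,         2.0,
    "inverse_digit",           6.2,      7.28,       0,         1.9,
    "immediate_recall",       42.7,      0,          4.29,     10.5,
    "delayed_recall",         26.3,      0,          3.81,      8.2,
    "rule_shift",              3.5,      4.10,       0.42,      1.0,
    "fas_phonemic",           14.4,      0,          0,         4.2,
    "fas_semantic",           18.4,      0,          1.09,      3.2,
    "tmta_hits",              24.0,      0,          0.22,      0.7,
    "tmta_time",              48.2,      0,         -8.72,     25.0,
    "tmtb_hits",              23.2,     18.56,       2.02,      4.3,
    "tmtb_time",              97.0,   -326.4,        0,        70.0,
    "ideomotor_praxis",        7.8,      0,          0.30,      0.9,
    "bnt",                    53.0,     28.86,       2.41,      7.9,
    "hippocampal_volume",      5e-3,    0,           2.2e-4,    5e-4
  )
  base |>
    dplyr::mutate(
      intercept = .data$mean_ref - .data$beta_power * power_ref -
        .data$beta_peak * iaf_ref
    ) |>
    dplyr::select("criterion", "intercept", "beta_power", "beta_peak",
                  "noise_sd")
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the statistical structure of the simulated study population: three
#' groups (controls without subjective cognitive decline, SCD, and MCI) of
#' sizes 39/41/51, group-specific alpha peak frequency distributions
#' (9.8/9.6/9.0 Hz, SD 0.9), group-specific alpha relative power, ages, and
#' the score generator of [default_score_coefficients()]. Signal parameters
#' control the per-subject epochs: a sinusoid at the subject's latent alpha
#' peak frequency with uniformly random phase per epoch over 1/f background
#' noise, with the sinusoid amplitude calibrated analytically so the target
#' alpha relative power (over the 2-45 Hz analysis range) is achieved in
#' expectation.
#'
#' Signal-size defaults are desk scale: 250 Hz sampling, 20 four-second
#' epochs per subject and a 5x5x5 source grid; all overridable.
#'
#' @param group_sizes Named integer vector, subjects per group.
#' @param iaf_mean,iaf_sd Named numeric vectors (per group), Hz. Latent alpha
#'   peak frequencies are drawn from the group normal law truncated to
#'   (4, 14) Hz.
#' @param alpha_relpower_mean Named per-group mean alpha relative power
#'   (fraction of 2-45 Hz power inside the IAF-anchored alpha band).
#' @param alpha_relpower_sd Common SD of the latent alpha relative power.
#' @param age_mean,age_sd Named per-group age distributions, years.
#' @param background_exponent Exponent of the 1/f^exponent background noise.
#' @param epoch_count Epochs per subject (subjects need >= 15 usable epochs
#'   to enter the analysis; the generator always produces `epoch_count`).
#' @param epoch_duration Epoch length, seconds.
#' @param sampling_rate Sampling rate, Hz.
#' @param n_per_axis,grid_spacing,neighbor_radius Source-grid geometry passed
#'   to [build_source_grid()]; `n_per_axis`^3 sources.
#' @param score_coefficients Tibble as from [default_score_coefficients()].
#' @param seed Integer seed governing the cohort-level generator stream.
#'
#' @return An object of class `cohort_config` (validated list).
#' @export
cohort_config <- function(group_sizes = c(noSCD = 39, SCD = 41, MCI = 51),
                          iaf_mean = c(noSCD = 9.8, SCD = 9.6, MCI = 9.0),
                          iaf_sd = c(noSCD = 0.9, SCD = 0.9, MCI = 0.9),
                          alpha_relpower_mean = c(noSCD = 0.32, SCD = 0.27,
                                                  MCI = 0.25),
                          alpha_relpower_sd = 0.06,
                          age_mean = c(noSCD = 70.4, SCD = 71.6, MCI = 73.0),
                          age_sd = c(noSCD = 3.7, SCD = 4.5, MCI = 3.7),
                          background_exponent = 1.0,
                          epoch_count = 20,
                          epoch_duration = 4,
                          sampling_rate = 250,
                          n_per_axis = 5,
                          grid_spacing = 10,
                          neighbor_radius = 1.01 * grid_spacing,
                          score_coefficients = default_score_coefficients(
                            power_ref = unname(alpha_relpower_mean[1]),
                            iaf_ref = unname(iaf_mean[1])),
                          seed = 1L) {
  cfg <- structure(
    list(group_sizes = group_sizes, iaf_mean = iaf_mean, iaf_sd = iaf_sd,
         alpha_relpower_mean = alpha_relpower_mean,
         alpha_relpower_sd = alpha_relpower_sd,
         age_mean = age_mean, age_sd = age_sd,
         background_exponent = background_exponent,
         epoch_count = epoch_count, epoch_duration = epoch_duration,
         sampling_rate = sampling_rate,
         n_per_axis = n_per_axis, grid_spacing = grid_spacing,
         neighbor_radius = neighbor_radius,
         score_coefficients = score_coefficients,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

config_error <- function(field, msg) {
  abort(sprintf("invalid cohort configuration: field `%s` %s", field, msg),
        class = "alphaspec_config_error")
}

validate_cohort_config <- function(cfg) {
  groups <- names(cfg$group_sizes)
  if (is.null(groups) || any(groups == ""))
    config_error("group_sizes", "must be a named vector of group counts")
  if (any(cfg$group_sizes < 1) || any(cfg$group_sizes != round(cfg$group_sizes)))
    config_error("group_sizes", "must contain integer counts >= 1")
  for (field in c("iaf_mean", "iaf_sd", "alpha_relpower_mean",
                  "age_mean", "age_sd")) {
    v <- cfg[[field]]
    if (!all(groups %in% names(v)))
      config_error(field, "must name every group in `group_sizes`")
  }
  if (any(cfg$iaf_mean[groups] <= 4) || any(cfg$iaf_mean[groups] >= 14))
    config_error("iaf_mean", "must lie within (4, 14) Hz")
  if (any(cfg$iaf_sd[groups] < 0))
    config_error("iaf_sd", "must be non-negative")
  if (any(cfg$alpha_relpower_mean[groups] <= 0) ||
      any(cfg$alpha_relpower_mean[groups] >= 1))
    config_error("alpha_relpower_mean", "must lie within (0, 1)")
  if (cfg$alpha_relpower_sd < 0)
    config_error("alpha_relpower_sd", "must be non-negative")
  if (cfg$epoch_count < 1 || cfg$epoch_count != round(cfg$epoch_count))
    config_error("epoch_count", "must be an integer >= 1")
  if (cfg$epoch_duration <= 0)
    config_error("epoch_duration", "must be positive")
  if (cfg$sampling_rate <= 0)
    config_error("sampling_rate", "must be positive")
  n_samp <- cfg$epoch_duration * cfg$sampling_rate
  if (abs(n_samp - round(n_samp)) > 1e-9)
    config_error("epoch_duration", "times `sampling_rate` must be an integer")
  if (cfg$background_exponent < 0)
    config_error("background_exponent", "must be non-negative")
  sc <- cfg$score_coefficients
  needed <- c("criterion", "intercept", "beta_power", "beta_peak", "noise_sd")
  if (!is.data.frame(sc) || !all(needed %in% names(sc)))
    config_error("score_coefficients",
                 "must be a data frame with columns criterion, intercept, beta_power, beta_peak, noise_sd")
  if (anyDuplicated(sc$criterion))
    config_error("score_coefficients", "must not repeat criteria")
  if (any(sc$noise_sd < 0))
    config_error("score_coefficients", "must have non-negative noise_sd")
  if (length(cfg$seed) != 1 || is.na(cfg$seed))
    config_error("seed", "must be a single integer")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  groups: ",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  IAF: %s Hz\n",
              paste(sprintf("%s %.1f±%.1f", names(x$group_sizes),
                            x$iaf_mean[names(x$group_sizes)],
                            x$iaf_sd[names(x$group_sizes)]), collapse = ", ")))
  cat(sprintf("  signals: %d epochs x %gs @ %g Hz, %d sources, 1/f^%g noise\n",
              x$epoch_count, x$epoch_duration, x$sampling_rate,
              x$n_per_axis^3, x$background_exponent))
  invisible(x)
}
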