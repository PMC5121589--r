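#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end analysis with the study
#' defaults: 2-45 Hz band-pass with 2-s padding, multitaper PSD at 2-45 Hz
#' in 0.5 Hz steps with 0.5 Hz smoothing, IAF-anchored alpha band, 4-14 Hz
#' peak-fitting range, cluster-based permutation tests with 2000 Monte-Carlo
#' repetitions at alpha 0.05 with age as covariate, and FDR q = 0.1 for the
#' regression battery.
#'
#' @param cohort A [cohort_config()].
#' @param filter_band Band-pass edges, Hz.
#' @param pad_seconds Mirror padding before filtering, seconds.
#' @param psd List with `fmin`, `fmax`, `fstep`, `smoothing` (Hz).
#' @param fit_range Peak-fitting range, Hz.
#' @param iaf_search IAF search range, Hz.
#' @param n_perm,cluster_alpha,alpha Cluster-test parameters.
#' @param fdr_q FDR level for the regression battery.
#' @param skip_inverse If `TRUE` (default), spectra are computed directly on
#'   the source-space synthetic epochs; if `FALSE`, epochs are projected to
#'   sensors through a synthetic leadfield, band-passed, and reconstructed
#'   with the LCMV beamformer first.
#' @param n_sensors,lcmv_reg,sensor_noise Forward/inverse stage parameters.
#' @param output_dir Optional directory for CSV artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            filter_band = c(2, 45),
                            pad_seconds = 2,
                            psd = list(fmin = 2, fmax = 45, fstep = 0.5,
                                       smoothing = 0.5),
                            fit_range = c(4, 14),
                            iaf_search = c(6, 13),
                            n_perm = 2000,
                            cluster_alpha = 0.05,
                            alpha = 0.05,
                            fdr_q = 0.1,
                            skip_inverse = TRUE,
                            n_sensors = 64,
                            lcmv_reg = 0.05,
                            sensor_noise = 0.05,
                            output_dir = NULL) {
  validate_cohort_config(cohort)
  if (fit_range[1] < psd$fmin || fit_range[2] > psd$fmax)
    abort("`fit_range` must lie within the PSD range")
  structure(
    list(cohort = cohort, filter_band = filter_band,
         pad_seconds = pad_seconds, psd = psd, fit_range = fit_range,
         iaf_search = iaf_search, n_perm = n_perm,
         cluster_alpha = cluster_alpha, alpha = alpha, fdr_q = fdr_q,
         skip_inverse = skip_inverse, n_sensors = n_sensors,
         lcmv_reg = lcmv_reg, sensor_noise = sensor_noise,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Compute per-subject relative power spectra for a cohort
#'
#' For every subject: regenerate epochs, optionally run the forward/inverse
#' stage (sensor projection, 2-45 Hz band-pass, LCMV reconstruction),
#' estimate the multitaper PSD and normalize to relative power.
#'
#' @param cohort A [generate_cohort()] object.
#' @param config A [pipeline_config()] (defaults used when omitted).
#' @return Named list of normalized [power_spectrum()] objects.
#' @export
cohort_spectra <- function(cohort, config = pipeline_config(cohort = cohort$config)) {
  stopifnot(inherits(cohort, "meg_cohort"))
  leadfield <- NULL
  if (!config$skip_inverse) {
    leadfield <- make_leadfield(cohort$grid, config$n_sensors,
                                seed = cohort$config$seed)
  }
  ids <- cohort$subjects$subject_id
  spectra <- purrr::map(seq_along(ids), function(i) {
    ep <- subject_epochs(cohort, ids[i])
    if (!config$skip_inverse) {
      sens <- project_to_sensors(ep, leadfield,
                                 noise_sd = config$sensor_noise,
                                 seed = subject_seed(cohort$config$seed, i + 7))
      sens <- bandpass_epochs(sens, config$filter_band[1],
                              config$filter_band[2], config$pad_seconds)
      cov <- epoch_covariance(sens)
      filt <- lcmv_filter(leadfield, cov, config$lcmv_reg)
      ep <- reconstruct_sources(filt, sens)
    }
    sp <- multitaper_psd(ep, config$psd$fmin, config$psd$fmax,
                         config$psd$fstep, config$psd$smoothing,
                         subject_id = ids[i])
    normalize_relative(sp)
  })
  setNames(spectra, ids)
}

#' Per-subject spectral measures
#'
#' From normalized spectra: the subject's IAF (posterior-ROI average
#' spectrum), the IAF-anchored alpha band relative power per source, and the
#' fitted alpha peak frequency per source.
#'
#' @param cohort A [generate_cohort()] object.
#' @param spectra Output of [cohort_spectra()].
#' @param config A [pipeline_config()].
#' @return List with `iaf` (tibble subject_id, iaf, fallback), `alpha_power`
#'   and `f_p` (`subjects x sources` matrices, rows in subject order), and
#'   `peak_fits` (full tibble from [fit_cohort_peaks()]).
#' @export
spectral_measures <- function(cohort, spectra,
                              config = pipeline_config(cohort = cohort$config)) {
  roi <- roi_posterior(cohort$grid)
  ids <- cohort$subjects$subject_id
  iaf_tbl <- purrr::map_dfr(ids, function(id) {
    est <- detect_iaf(spectra[[id]], roi,
                      config$iaf_search[1], config$iaf_search[2])
    tibble::tibble(subject_id = id, iaf = est$iaf, fallback = est$fallback)
  })
  n_sources <- nrow(cohort$grid$positions)
  alpha_power <- matrix(NA_real_, length(ids), n_sources,
                        dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    band <- alpha_band_from_iaf(iaf_tbl$iaf[i])
    alpha_power[i, ] <- band_relative_power(spectra[[ids[i]]], band)$power
  }
  peak_fits <- fit_cohort_peaks(spectra, config$fit_range[1],
                                config$fit_range[2])
  f_p <- matrix(NA_real_, length(ids), n_sources, dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    rows <- peak_fits[peak_fits$subject_id == ids[i], ]
    f_p[i, rows$source] <- rows$f_p
  }
  list(iaf = iaf_tbl, alpha_power = alpha_power, f_p = f_p,
       peak_fits = peak_fits)
}

#' Group summary table
#'
#' Per-group mean and SD of measured IAF, alpha relative power, age, every
#' score and hippocampal volume, plus the sample-size-weighted overall IAF
#' mean (the study-level IAF that anchors the common alpha band).
#'
#' @param subjects Cohort subject table (`group`, `age`, scores).
#' @param iaf Per-subject IAF estimates, Hz (aligned with `subjects`).
#' @param alpha_power Per-subject mean alpha relative power.
#' @return Object of class `group_summary`: tibble (`variable`, one
#'   mean/sd column pair per group) with attributes `overall_iaf` and
#'   `overall_iaf_1dp`.
#' @export
summarize_groups <- function(subjects, iaf, alpha_power) {
  if (nrow(subjects) == 0) abort("empty cohort")
  if (length(iaf) != nrow(subjects) || length(alpha_power) != nrow(subjects))
    abort("`iaf` and `alpha_power` must align with `subjects`")
  base_cols <- c("subject_id", "group", "iaf_true", "alpha_relpower_true")
  score_cols <- setdiff(names(subjects), c(base_cols, "age"))
  dat <- subjects |>
    dplyr::mutate(iaf = iaf, alpha_relpower = alpha_power) |>
    dplyr::select("group", "age", "iaf", "alpha_relpower",
                  dplyr::all_of(score_cols))
  long <- dat |>
    tidyr::pivot_longer(-"group", names_to = "variable") |>
    dplyr::group_by(.data$group, .data$variable) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  group_means <- dplyr::filter(long, .data$variable == "iaf")
  overall <- sum(group_means$mean * group_means$n) / sum(group_means$n)
  wide <- long |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("mean", "sd"),
                       names_glue = "{group}_{.value}")
  ord <- c("iaf", "alpha_relpower", "age", score_cols)
  wide <- wide[match(ord, wide$variable), ]
  structure(wide, class = c("group_summary", class(wide)),
            overall_iaf = overall,
            overall_iaf_1dp = round(overall, 1))
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group summary (overall IAF %.1f Hz):\n",
              attr(x, "overall_iaf_1dp")))
  NextMethod()
}

#' Run the full analysis pipeline
#'
#' Executes the end-to-end run on a synthetic cohort: simulate, (optional)
#' forward/inverse, multitaper relative-power spectra, IAF and alpha band
#' power, per-source Gaussian-peak fits, group summary, pairwise
#' cluster-based permutation tests (alpha relative power and peak frequency,
#' age-covaried), and the FDR-corrected two-predictor regression battery.
#' Fully reproducible under the cohort seed. When `config$output_dir` is
#' set, all result tables are persisted as CSV.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_report`: list with `subjects`,
#'   `group_summary`, `iaf`, `contrasts` (per measure, named lists of
#'   `cluster_test`), `battery` (a `regression_battery`), `measures`, and
#'   `provenance` (stage parameters, seeds and timings).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  stage_times <- numeric(0)
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stage_times[[name]] <<- t1 - t0
    t0 <<- t1
  }

  cohort <- generate_cohort(config$cohort)
  tick("simulate")
  spectra <- cohort_spectra(cohort, config)
  tick("spectra")
  meas <- spectral_measures(cohort, spectra, config)
  tick("measures")

  alpha_scalar <- subject_average(meas$alpha_power)
  summary_tbl <- summarize_groups(cohort$subjects, meas$iaf$iaf, alpha_scalar)
  tick("summary")

  contrasts <- list()
  if (length(config$cohort$group_sizes) >= 2) {
    for (mname in c("alpha_relpower", "f_p")) {
      maps <- if (mname == "alpha_relpower") meas$alpha_power else meas$f_p
      contrasts[[mname]] <- run_contrast_battery(
        cohort$subjects, maps, cohort$grid,
        n_perm = config$n_perm, cluster_alpha = config$cluster_alpha,
        alpha = config$alpha, seed = config$cohort$seed
      )
    }
  }
  tick("cluster_tests")

  criteria <- config$cohort$score_coefficients$criterion
  reg_data <- cohort$subjects |>
    dplyr::mutate(alpha_power = alpha_scalar,
                  peak_freq = subject_average(meas$f_p))
  battery <- fit_battery(reg_data, criteria, q = config$fdr_q)
  tick("regressions")

  report <- structure(
    list(subjects = cohort$subjects, group_summary = summary_tbl,
         iaf = meas$iaf, contrasts = contrasts, battery = battery,
         measures = meas, grid = cohort$grid,
         provenance = list(
           seed = config$cohort$seed,
           n_subjects = nrow(cohort$subjects),
           n_sources = nrow(cohort$grid$positions),
           skip_inverse = config$skip_inverse,
           n_perm = config$n_perm, fdr_q = config$fdr_q,
           psd = config$psd, fit_range = config$fit_range,
           stage_seconds = stage_times)),
    class = "pipeline_report"
  )
  if (!is.null(config$output_dir)) write_report_csv(report, config$output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d subjects, %d sources (seed %d)\n",
              x$provenance$n_subjects, x$provenance$n_sources,
              x$provenance$seed))
  cat(sprintf("  overall IAF: %.1f Hz\n",
              attr(x$group_summary, "overall_iaf_1dp")))
  for (mname in names(x$contrasts)) {
    sig <- purrr::map_int(x$contrasts[[mname]], function(ct)
      sum(purrr::map_dbl(ct$clusters, "p_value") <= ct$alpha))
    cat(sprintf("  %s: significant clusters per contrast: %s\n", mname,
                paste(sprintf("%s=%d", names(sig), sig), collapse = ", ")))
  }
  slopes <- dplyr::filter(x$battery$results, .data$term != "intercept")
  cat(sprintf("  regression battery: %d/%d FDR-significant coefficients\n",
              sum(slopes$fdr_significant), nrow(slopes)))
  invisible(x)
}

write_report_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(tibble::as_tibble(report$group_summary),
                   file.path(dir, "group_summary.csv"))
  readr::write_csv(report$iaf, file.path(dir, "iaf.csv"))
  readr::write_csv(report$battery$results, file.path(dir, "regressions.csv"))
  readr::write_csv(report$measures$peak_fits, file.path(dir, "peak_fits.csv"))
  for (mname in names(report$contrasts)) {
    tbl <- purrr::imap_dfr(report$contrasts[[mname]], function(ct, nm) {
      td <- tidy(ct)
      td$sources <- purrr::map_chr(td$sources, paste, collapse = ";")
      dplyr::mutate(td, contrast = nm, measure = mname, .before = 1)
    })
    readr::write_csv(tbl, file.path(dir, paste0("clusters_", mname, ".csv")))
  }
  invisible(dir)
}
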