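# Reference Slepian tapers (N = 32, NW = 2, K = 3) computed independently
# with scipy.signal.windows.dpss, frozen here; first half of each symmetric/
# antisymmetric sequence.
dpss_ref <- list(
  t0 = c(0.0076069007, 0.0152457048, 0.0259418936, 0.0399680614,
         0.0574087920, 0.0781242126, 0.1017293937, 0.1275930454,
         0.1548572735, 0.1824781798, 0.2092850323, 0.2340538043,
         0.2555893013, 0.2728090371, 0.2848216227, 0.2909927340),
  t1 = c(0.0397633505, 0.0652443295, 0.0950446947, 0.1276523935,
         0.1610476782, 0.1928371660, 0.2204387303, 0.2413013177,
         0.2531389998, 0.2541559080, 0.2432385406, 0.2200943901,
         0.1853207097, 0.1403940332, 0.0875790664, 0.0297638872),
  t2 = c(0.1292421989, 0.1710608681, 0.2082433759, 0.2367603410,
         0.2530824846, 0.2546044516, 0.2399912864, 0.2094034678,
         0.1645689592, 0.1086875190, 0.0461716100, -0.0177526507,
         -0.0775442532, -0.1278931106, -0.1642538317, -0.1833087467),
  lambda = c(0.9999464570, 0.9976568658, 0.9601251891)
)

test_that("DPSS tapers match the independent reference and are orthonormal", {
  dp <- alphaspec:::dpss_tapers(32, 2, 3)
  ref <- cbind(c(dpss_ref$t0, rev(dpss_ref$t0)),
               c(dpss_ref$t1, -rev(dpss_ref$t1)),
               c(dpss_ref$t2, rev(dpss_ref$t2)))
  expect_equal(dp$tapers, ref, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(dp$eigvals, dpss_ref$lambda, tolerance = 1e-8)
  expect_equal(crossprod(dp$tapers), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("multitaper spectrum localizes a sinusoid and handles edge cases", {
  ep <- make_sinusoid_epochs(10, n_epochs = 2)
  sp <- multitaper_psd(ep)
  expect_equal(sp$freqs, seq(2, 45, 0.5))
  expect_equal(sp$freqs[which.max(sp$power[1, ])], 10)

  zeros <- epoch_array(array(0, c(2, 2, 1000)), 250, "source")
  expect_true(all(multitaper_psd(zeros)$power == 0))

  # white noise: flat within +/-20% of its mean over 2-45 Hz
  set.seed(4)
  wn <- epoch_array(array(rnorm(60 * 1 * 1000), c(60, 1, 1000)), 250, "source")
  spw <- multitaper_psd(wn)
  expect_true(all(abs(spw$power[1, ] / mean(spw$power[1, ]) - 1) < 0.2))

  # smoothing too small for the epoch length: no usable taper
  short <- epoch_array(array(rnorm(2 * 1 * 250), c(2, 1, 250)), 250, "source")
  expect_error(multitaper_psd(short, smoothing = 0.3), "taper")
  # 1-s epochs cannot express a 0.5 Hz grid natively, but can zero-padded
  expect_error(multitaper_psd(short, smoothing = 1), "zero_pad")
  spz <- multitaper_psd(short, smoothing = 1, zero_pad = TRUE)
  expect_equal(spz$freqs, seq(2, 45, 0.5))
})

test_that("relative-power normalization is a row-stochastic projection", {
  set.seed(9)
  f <- seq(2, 45, 0.5)
  pw <- matrix(runif(3 * length(f)), 3, length(f))
  pw[3, ] <- 2 * pw[1, ]                       # proportional rows
  sp <- power_spectrum(f, pw)
  ns <- normalize_relative(sp)
  expect_equal(rowSums(ns$power), rep(1, 3))
  expect_true(ns$normalized)
  # idempotent; scale invariant
  expect_equal(normalize_relative(ns)$power, ns$power)
  expect_equal(ns$power[1, ], ns$power[3, ])

  pw0 <- pw; pw0[2, ] <- 0
  expect_error(normalize_relative(power_spectrum(f, pw0)), "2")
})

test_that("IAF detection follows the highest-local-maximum rule", {
  f <- seq(2, 45, 0.5)
  bump <- function(center, height) height * exp(-(f - center)^2 / 0.8)
  base <- 0.5 * f^-1

  single <- power_spectrum(f, rbind(base + bump(9.5, 1)))
  expect_equal(detect_iaf(single, 1)$iaf, 9.5)
  expect_false(detect_iaf(single, 1)$fallback)

  two <- power_spectrum(f, rbind(base + bump(8, 1) + bump(11, 0.6)))
  expect_equal(detect_iaf(two, 1)$iaf, 8)

  mono <- power_spectrum(f, rbind(2 * f^-1.3))
  est <- detect_iaf(mono, 1, search_lo = 6, search_hi = 13)
  expect_true(est$fallback)
  expect_equal(est$iaf, 6)

  expect_error(detect_iaf(single, integer(0)), "non-empty")
  expect_error(detect_iaf(single, 1, search_lo = 1), "inside")
})

test_that("the alpha band is anchored at IAF - 2.5 to IAF + 2", {
  b <- alpha_band_from_iaf(9.4)
  expect_equal(c(b$lo, b$hi), c(6.9, 11.4))
  b2 <- alpha_band_from_iaf(10)
  expect_equal(c(b2$lo, b2$hi), c(7.5, 12))
  expect_error(alpha_band_from_iaf(4.4), "2-45")
  expect_error(alpha_band_from_iaf(14.5), "\\(4, 14\\)")
})

test_that("band relative power sums bins with inclusive edges", {
  f <- seq(2, 45, 0.5)
  uniform <- normalize_relative(power_spectrum(f, rbind(rep(1, length(f)))))
  expect_equal(band_relative_power(uniform, band_definition("all", 2, 45))$power, 1)
  # 10 bins at 0.5 Hz spacing out of 87
  expect_equal(band_relative_power(uniform, band_definition("b", 7, 11.5))$power,
               10 / 87)

  spike <- matrix(0, 1, length(f)); spike[f == 10] <- 1
  sp <- power_spectrum(f, spike, normalized = TRUE)
  expect_equal(band_relative_power(sp, band_definition("alpha", 6.9, 11.4))$power, 1)

  # completeness: band powers over a partition of 2-45 sum to 1
  set.seed(2)
  rnd <- normalize_relative(power_spectrum(f, matrix(runif(2 * 87), 2)))
  parts <- list(band_definition("lo", 2, 10),
                band_definition("mid", 10.5, 30),
                band_definition("hi", 30.5, 45))
  tot <- Reduce(`+`, lapply(parts, function(b) band_relative_power(rnd, b)$power))
  expect_equal(tot, rep(1, 2))

  expect_error(band_relative_power(rnd, band_definition("x", 45.5, 46)),
               "2-45")
  unnorm <- power_spectrum(f, matrix(runif(87), 1))
  expect_error(band_relative_power(unnorm, parts[[1]]), "normalized")
})

test_that("cohorts with fixed latent IAF are recovered within one bin", {
  cohort <- generate_cohort(fixed_iaf_config(iaf = 9.5, relpower = 0.4))
  spectra <- cohort_spectra(cohort)
  roi <- roi_posterior(cohort$grid)
  for (id in cohort$subjects$subject_id) {
    est <- detect_iaf(spectra[[id]], roi)
    expect_lt(abs(est$iaf - 9.5), 0.5 + 1e-9)
  }
})

test_that("raising the generator's alpha power raises measured band power", {
  measure <- function(relpower) {
    cohort <- generate_cohort(fixed_iaf_config(iaf = 9.8, relpower = relpower,
                                               n = 2, seed = 11))
    spectra <- cohort_spectra(cohort)
    mean(vapply(spectra, function(sp) {
      mean(band_relative_power(sp, alpha_band_from_iaf(9.8))$power)
    }, numeric(1)))
  }
  m1 <- measure(0.25); m2 <- measure(0.40); m3 <- measure(0.60)
  expect_lt(m1, m2)
  expect_lt(m2, m3)
  # and the measured values track the analytic targets
  expect_lt(abs(m2 - 0.40), 0.08)
})
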