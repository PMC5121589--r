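make_dipole_scene <- function(seed = 3, n_sensors = 16, active = 5,
                              n_epochs = 2, fs = 250, n = 500) {
  grid <- build_source_grid(2, 10)
  lf <- make_leadfield(grid, n_sensors, seed = seed)
  sig <- sin(2 * pi * 10 * (0:(n - 1)) / fs)
  sens <- array(0, c(n_epochs, n_sensors, n))
  for (e in seq_len(n_epochs)) sens[e, , ] <- lf$gain %*%
      rbind(matrix(0, active - 1, n), sig,
            matrix(0, nrow(grid$positions) - active, n))
  list(grid = grid, leadfield = lf, sig = sig, active = active,
       epochs = epoch_array(sens, fs, "sensor"))
}

test_that("band-pass keeps in-band content and rejects out-of-band content", {
  ep10 <- make_sinusoid_epochs(10, n_epochs = 1)
  out10 <- bandpass_epochs(ep10, 2, 45)
  expect_gte(cor(as.vector(out10$data), as.vector(ep10$data)), 0.99)

  ep60 <- make_sinusoid_epochs(60, n_epochs = 1)
  out60 <- bandpass_epochs(ep60, 2, 45)
  expect_lte(sqrt(mean(out60$data^2)), 0.1 * sqrt(mean(ep60$data^2)))

  # one octave outside the band: at least 20 dB down
  ep90 <- make_sinusoid_epochs(90, fs = 400, n_epochs = 1)
  out90 <- bandpass_epochs(ep90, 2, 45)
  expect_lte(sqrt(mean(out90$data^2)), 0.1 * sqrt(mean(ep90$data^2)))
  ep1 <- make_sinusoid_epochs(1, n_epochs = 1)
  out1 <- bandpass_epochs(ep1, 2, 45)
  expect_lte(sqrt(mean(out1$data^2)), 0.1 * sqrt(mean(ep1$data^2)))

  dc <- epoch_array(array(1, c(1, 1, 1000)), 250, "source")
  expect_lt(abs(mean(bandpass_epochs(dc, 2, 45)$data)), 1e-3)

  expect_error(bandpass_epochs(ep10, 2, 130), "Nyquist")
})

test_that("epoch covariance averages per-epoch sample covariances", {
  set.seed(1)
  x <- matrix(rnorm(4 * 300), 4, 300)
  same <- array(0, c(3, 4, 300))
  for (e in 1:3) same[e, , ] <- x
  ep <- epoch_array(same, 250, "sensor")
  single <- tcrossprod(x - rowMeans(x)) / (300 - 1)
  expect_equal(epoch_covariance(ep), single, tolerance = 1e-12)

  # independent unit-variance channels: near-diagonal, diagonal near 1
  set.seed(2)
  noise <- array(rnorm(40 * 2 * 2000), c(40, 2, 2000))
  cn <- epoch_covariance(epoch_array(noise, 250, "sensor"))
  expect_equal(diag(cn), c(1, 1), tolerance = 0.05)
  expect_lt(abs(cn[1, 2]), 0.05)

  zeros <- epoch_array(array(0, c(2, 3, 100)), 250, "sensor")
  expect_equal(epoch_covariance(zeros), matrix(0, 3, 3))

  wide <- epoch_array(array(rnorm(2 * 10 * 5), c(2, 10, 5)), 250, "sensor")
  expect_warning(epoch_covariance(wide), "regularization")
})

test_that("LCMV filters satisfy unit gain and the identity-covariance form", {
  scene <- make_dipole_scene()
  cov <- epoch_covariance(scene$epochs)
  filt <- lcmv_filter(scene$leadfield, cov, reg = 0.05)
  gains <- unname(diag(filt$weights %*% scene$leadfield$gain))
  expect_equal(gains, rep(1, length(gains)), tolerance = 1e-6)

  # C = I: weights reduce to l' / ||l||^2
  gain <- scene$leadfield$gain
  fid <- lcmv_filter(scene$leadfield, diag(nrow(gain)), reg = 0)
  expected <- t(sweep(gain, 2, colSums(gain^2), "/"))
  expect_equal(fid$weights, expected, tolerance = 1e-10)
})

test_that("a noiseless single dipole is reconstructed at its source", {
  scene <- make_dipole_scene()
  cov <- epoch_covariance(scene$epochs)
  filt <- lcmv_filter(scene$leadfield, cov, reg = 1e-8)
  rec <- reconstruct_sources(filt, scene$epochs)
  expect_gte(abs(cor(rec$data[1, scene$active, ], scene$sig)), 0.999)
  # the reconstructed alpha source peaks at the simulated frequency bin
  sp <- multitaper_psd(rec, smoothing = 1)
  expect_equal(sp$freqs[which.max(sp$power[scene$active, ])], 10)
})

test_that("reconstruction is linear and respects shapes", {
  scene <- make_dipole_scene()
  filt <- lcmv_filter(scene$leadfield, epoch_covariance(scene$epochs), 0.05)
  x <- scene$epochs
  y <- epoch_array(x$data * 0.5 + 1, x$sampling_rate, "sensor")
  lin <- reconstruct_sources(
    epoch_array(2 * x$data + 3 * y$data, x$sampling_rate, "sensor"), # nolint
    filter = filt)
  ref <- 2 * reconstruct_sources(filt, x)$data +
    3 * reconstruct_sources(filt, y)$data
  expect_equal(lin$data, ref, tolerance = 1e-10)

  ident <- structure(list(weights = diag(16), regularization = 0),
                     class = "spatial_filter")
  expect_equal(reconstruct_sources(ident, x)$data, x$data)
  zero <- structure(list(weights = matrix(0, 8, 16), regularization = 0),
                    class = "spatial_filter")
  expect_true(all(reconstruct_sources(zero, x)$data == 0))
  bad <- epoch_array(array(0, c(1, 5, 10)), 250, "sensor")
  expect_error(reconstruct_sources(filt, bad), "sensors")
})
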