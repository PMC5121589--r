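test_that("default cohort reproduces the three-group study structure", {
  cohort <- generate_cohort(cohort_config(seed = 1))
  counts <- table(cohort$subjects$group)
  expect_equal(nrow(cohort$subjects), 131)
  expect_equal(unname(counts[c("noSCD", "SCD", "MCI")]),
               as.array(c(39, 41, 51)), ignore_attr = TRUE)
  expect_true(all(cohort$subjects$hippocampal_volume > 0))
  expect_true(all(cohort$subjects$iaf_true > 4 & cohort$subjects$iaf_true < 14))
  # every configured criterion materializes as a column
  expect_true(all(cohort$config$score_coefficients$criterion %in%
                    names(cohort$subjects)))
})

test_that("generation is bitwise reproducible under a fixed seed", {
  c1 <- generate_cohort(tiny_config(seed = 42))
  c2 <- generate_cohort(tiny_config(seed = 42))
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(subject_epochs(c1, "S003")$data,
                   subject_epochs(c2, "S003")$data)
  c3 <- generate_cohort(tiny_config(seed = 43))
  expect_false(identical(c1$subjects$iaf_true, c3$subjects$iaf_true))
})

test_that("degenerate variances give exact latent values and affine scores", {
  cfg <- tiny_config(iaf_sd = c(noSCD = 0, MCI = 0))
  cohort <- generate_cohort(cfg)
  expect_equal(cohort$subjects$iaf_true,
               unname(cfg$iaf_mean[cohort$subjects$group]))

  # noiseless, power-free scores are an exact affine function of iaf_true
  coefs <- tibble::tibble(criterion = "probe", intercept = 2,
                          beta_power = 0, beta_peak = 3, noise_sd = 0)
  cohort2 <- generate_cohort(tiny_config(score_coefficients = coefs))
  expect_equal(cohort2$subjects$probe, 2 + 3 * cohort2$subjects$iaf_true,
               tolerance = 1e-12)
})

test_that("group-mean latent IAFs recover the configured means", {
  cohort <- generate_cohort(cohort_config(seed = 7))
  cfg <- cohort$config
  stats <- dplyr::summarise(dplyr::group_by(cohort$subjects, group),
                            m = mean(iaf_true), n = dplyr::n())
  for (i in seq_len(nrow(stats))) {
    g <- stats$group[i]
    expect_lt(abs(stats$m[i] - cfg$iaf_mean[[g]]),
              3 * cfg$iaf_sd[[g]] / sqrt(stats$n[i]))
  }
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(cohort_config(group_sizes = c(noSCD = 0, SCD = 41, MCI = 51)),
               "group_sizes")
  expect_error(cohort_config(iaf_mean = c(noSCD = 15, SCD = 9.6, MCI = 9)),
               "iaf_mean")
  expect_error(cohort_config(alpha_relpower_mean =
                               c(noSCD = 1.2, SCD = 0.27, MCI = 0.25)),
               "alpha_relpower_mean")
  expect_error(cohort_config(epoch_duration = 4, sampling_rate = 250.3),
               "epoch_duration")
})

test_that("epochs contain the planted oscillation at the latent frequency", {
  cfg <- fixed_iaf_config(iaf = 10, relpower = 0.6, n = 1, epoch_count = 4)
  cohort <- generate_cohort(cfg)
  ep <- subject_epochs(cohort, "S001")
  expect_false(anyNA(ep$data))
  # per-epoch periodogram argmax within one native bin of the latent IAF
  n <- dim(ep$data)[3]
  freqs <- (0:(n - 1)) * ep$sampling_rate / n
  keep <- freqs > 2 & freqs < 45
  for (e in seq_len(dim(ep$data)[1])) {
    pg <- Mod(fft(ep$data[e, 1, ]))^2
    fmax <- freqs[keep][which.max(pg[keep])]
    expect_lt(abs(fmax - 10), ep$sampling_rate / n + 1e-9)
  }
})

test_that("cubic grids have the expected adjacency structure", {
  g <- build_source_grid(3, spacing = 10, neighbor_radius = 10.1)
  expect_true(isSymmetric(g$adjacency))
  expect_true(all(!diag(g$adjacency)))
  interior <- which(rowSums(abs(g$positions - 10) < 1e-9) == 3)
  expect_equal(sum(g$adjacency[interior, ]), 6)

  # radius covering all 26 cube offsets (10 * sqrt(3) = 17.32)
  g26 <- build_source_grid(3, spacing = 10, neighbor_radius = 17.4)
  expect_equal(sum(g26$adjacency[interior, ]), 26)

  g2 <- build_source_grid(c(2, 1, 1), spacing = 10)
  expect_equal(sum(g2$adjacency) / 2, 1)

  expect_warning(build_source_grid(2, spacing = 10, neighbor_radius = 5),
                 "no adjacencies")
  # adjacent pairs always lie within the configured radius
  d <- as.matrix(dist(g26$positions))
  expect_true(all(d[g26$adjacency] <= 17.4))
})

test_that("cohort CSV export round-trips the subject table", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(tiny_config())
  paths <- write_cohort_csv(cohort, dir)
  back <- readr::read_csv(paths[["subjects"]], show_col_types = FALSE)
  expect_equal(nrow(back), nrow(cohort$subjects))
  expect_equal(back$iaf_true, cohort$subjects$iaf_true, tolerance = 1e-9)
})
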