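null_maps <- function(n, s, seed) {
  set.seed(seed)
  matrix(rnorm(n * s), n, s)
}

test_that("a planted connected effect is recovered as a significant cluster", {
  grid <- build_source_grid(3, 10)
  set.seed(1)
  n <- 80
  groups <- rep(c("A", "B"), each = n / 2)
  age <- rnorm(n, 70, 4)
  maps <- matrix(rnorm(n * 27), n, 27)
  planted <- c(5, 11, 13, 14, 15, 17, 22, 23)  # connected region around 14
  maps[groups == "B", planted] <- maps[groups == "B", planted] + 1.5
  res <- cluster_permutation_test(maps, groups, age, grid,
                                  n_perm = 500, seed = 2)
  expect_gt(length(res$clusters), 0)
  top <- res$clusters[[1]]
  expect_lte(top$p_value, 0.05)
  jaccard <- length(intersect(top$sources, planted)) /
    length(union(top$sources, planted))
  expect_gte(jaccard, 0.5)
  expect_true(all(which(res$sig_mask) %in%
                    unlist(purrr::map(purrr::keep(res$clusters,
                                                  ~ .x$p_value <= 0.05),
                                      "sources"))))
})

test_that("cluster p-values are deterministic under a fixed seed", {
  grid <- build_source_grid(2, 10)
  maps <- null_maps(20, 8, seed = 5)
  maps[11:20, 1:4] <- maps[11:20, 1:4] + 1
  groups <- rep(c("A", "B"), each = 10)
  age <- rnorm(20, 70, 4)
  r1 <- cluster_permutation_test(maps, groups, age, grid, n_perm = 300,
                                 seed = 7)
  r2 <- cluster_permutation_test(maps, groups, age, grid, n_perm = 300,
                                 seed = 7)
  expect_identical(purrr::map_dbl(r1$clusters, "p_value"),
                   purrr::map_dbl(r2$clusters, "p_value"))
  # Monte-Carlo p-values cannot go below 1/(n_perm + 1)
  expect_true(all(purrr::map_dbl(r1$clusters, "p_value") >= 1 / 301))
})

test_that("identical groups produce no significant clusters", {
  grid <- build_source_grid(2, 10)
  base <- null_maps(10, 8, seed = 3)
  maps <- rbind(base, base)           # exact copies in both groups
  groups <- rep(c("A", "B"), each = 10)
  res <- cluster_permutation_test(maps, groups, NULL, grid, n_perm = 200,
                                  seed = 1)
  expect_equal(length(res$clusters), 0)
  expect_false(any(res$sig_mask))
})

test_that("Monte-Carlo p-values match exhaustive label enumeration", {
  grid <- build_source_grid(2, 10)
  set.seed(3)
  maps <- matrix(rnorm(10 * 8), 10, 8)
  maps[6:10, c(1, 2, 5)] <- maps[6:10, c(1, 2, 5)] + 2
  groups <- rep(c("A", "B"), each = 5)
  n_perm <- 500
  mc <- cluster_permutation_test(maps, groups, NULL, grid, n_perm = n_perm,
                                 seed = 9)
  ex <- cluster_permutation_test(maps, groups, NULL, grid,
                                 method = "exhaustive")
  expect_gt(length(mc$clusters), 0)
  expect_gt(length(ex$clusters), 0)
  expect_lt(abs(mc$clusters[[1]]$p_value - ex$clusters[[1]]$p_value),
            2 / sqrt(n_perm))
})

test_that("cluster membership is invariant to source relabeling", {
  grid <- build_source_grid(2, 10)
  set.seed(6)
  maps <- matrix(rnorm(24 * 8), 24, 8)
  maps[13:24, c(1, 2, 3)] <- maps[13:24, c(1, 2, 3)] + 1.5
  groups <- rep(c("A", "B"), each = 12)
  age <- rnorm(24, 70, 4)
  perm <- sample(8)
  grid_perm <- grid
  grid_perm$positions <- grid$positions[perm, ]
  grid_perm$adjacency <- grid$adjacency[perm, perm]
  r0 <- cluster_permutation_test(maps, groups, age, grid, n_perm = 300,
                                 seed = 11)
  rp <- cluster_permutation_test(maps[, perm], groups, age, grid_perm,
                                 n_perm = 300, seed = 11)
  srcs0 <- purrr::map(r0$clusters, "sources")
  # map permuted cluster indices back to original labels
  srcsp <- purrr::map(rp$clusters, ~ sort(perm[.x$sources]))
  expect_setequal(purrr::map_chr(srcs0, paste, collapse = ","),
                  purrr::map_chr(srcsp, paste, collapse = ","))
})

test_that("low-coverage sources are excluded and missing values tolerated", {
  grid <- build_source_grid(2, 10)
  maps <- null_maps(20, 8, seed = 8)
  maps[1:10, 3] <- NA                 # 50% coverage: below the 80% floor
  maps[1, 5] <- NA                    # 95% coverage: kept, subject dropped
  groups <- rep(c("A", "B"), each = 10)
  res <- cluster_permutation_test(maps, groups, NULL, grid, n_perm = 100,
                                  seed = 2)
  expect_false(3 %in% res$tested_sources)
  expect_true(5 %in% res$tested_sources)
  expect_true(is.na(res$statistic_map[3]))
})

test_that("the contrast battery validates labels and mirrors group structure", {
  grid <- build_source_grid(3, 10)
  cohort <- generate_cohort(cohort_config(seed = 21))
  subj <- cohort$subjects
  set.seed(8)
  maps <- matrix(subj$iaf_true, nrow(subj), 27) +
    matrix(rnorm(nrow(subj) * 27, 0, 0.3), nrow(subj), 27)
  res <- run_contrast_battery(subj, maps, grid, n_perm = 500, seed = 4)
  expect_named(res, c("noSCD_vs_SCD", "noSCD_vs_MCI", "SCD_vs_MCI"))
  min_p <- purrr::map_dbl(res, function(ct) {
    ps <- purrr::map_dbl(ct$clusters, "p_value")
    if (length(ps) == 0) 1 else min(ps)
  })
  # slowing pattern: contrasts against MCI significant, noSCD vs SCD not
  expect_lte(min_p[["noSCD_vs_MCI"]], 0.05)
  expect_lte(min_p[["SCD_vs_MCI"]], 0.05)
  expect_gt(min_p[["noSCD_vs_SCD"]], 0.05)

  expect_error(run_contrast_battery(subj, maps, grid,
                                    contrasts = list(c("noSCD", "bogus"))),
               "unknown group")
  expect_equal(run_contrast_battery(subj, maps, grid, contrasts = list()),
               list())
})
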