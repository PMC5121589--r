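# Fast covariate-adjusted group statistics over many sources.
#
# X is the full design (intercept, group indicator, optional age); Y is a
# subjects x sources matrix. Returns the t statistic of the group column for
# every source, vectorized across sources.
group_t_map <- function(X, Y) {
  n <- nrow(X)
  p <- ncol(X)
  XtX_inv <- solve(crossprod(X))
  B <- XtX_inv %*% crossprod(X, Y)
  E <- Y - X %*% B
  rss <- colSums(E^2)
  se <- sqrt(pmax(rss, 0) / (n - p) * XtX_inv[2, 2])
  tval <- B[2, ] / se
  tval[se == 0] <- 0
  list(t = tval, df = n - p)
}

# Clusters of supra-threshold sources. `tval` is the per-source t (NA for
# untested sources); positive and negative clusters are formed separately;
# mass is the signed sum of t. Returns list of list(sources, mass).
form_clusters <- function(tval, threshold, adj_list) {
  out <- list()
  for (sign_dir in c(1, -1)) {
    active <- which(!is.na(tval) & sign_dir * tval > threshold)
    comps <- connected_components(active, adj_list)
    for (cmp in comps) {
      out[[length(out) + 1]] <- list(sources = cmp, mass = sum(tval[cmp]))
    }
  }
  out
}

max_cluster_mass <- function(tval, threshold, adj_list) {
  cl <- form_clusters(tval, threshold, adj_list)
  if (length(cl) == 0) return(0)
  max(vapply(cl, function(x) abs(x$mass), numeric(1)))
}

# Missingness patterns: sources sharing the same set of observed subjects are
# processed together so the permutation statistics stay vectorized.
missing_patterns <- function(Y, tested) {
  keys <- apply(!is.na(Y[, tested, drop = FALSE]), 2, paste, collapse = "")
  split(tested, keys)
}

#' Cluster-based permutation test over the source grid
#'
#' Two-group comparison of per-source maps (alpha relative power or alpha
#' peak frequency) with age as a covariate, corrected for multiple
#' comparisons by cluster-based permutation: per source, the covariate-
#' adjusted group t from `value ~ group + age`; sources with parametric
#' `p < cluster_alpha` are grouped into connected clusters under the grid
#' adjacency (positive and negative effects separately); cluster mass is the
#' summed t; the null distribution of the maximum absolute cluster mass is
#' built by Monte-Carlo permutation under the Freedman-Lane scheme (age fit
#' retained, reduced-model residuals permuted). Cluster p-values are
#' `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' Sources where fewer than `min_coverage` of subjects have a value (e.g.
#' sources without a detectable alpha peak) are excluded; remaining missing
#' values are handled by subject-wise exclusion per source.
#'
#' With `age = NULL` the test reduces to a plain label-permutation two-sample
#' cluster test; in that case `method = "exhaustive"` enumerates all
#' group-label assignments instead of sampling (small samples only).
#'
#' @param maps `subjects x sources` numeric matrix (NA allowed).
#' @param groups Per-subject labels; exactly 2 groups, each n >= 5.
#' @param age Per-subject covariate, or `NULL` for no covariate.
#' @param grid A [build_source_grid()] matching the source dimension.
#' @param n_perm Number of Monte-Carlo permutations (study default 2000).
#' @param cluster_alpha Parametric threshold forming clusters (default 0.05).
#' @param alpha Cluster-level significance level (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @param method `"monte-carlo"` (default) or `"exhaustive"`.
#' @param min_coverage Minimum fraction of non-missing subjects per source.
#' @return Object of class `cluster_test`; see [tidy.cluster_test()].
#' @export
cluster_permutation_test <- function(maps, groups, age = NULL, grid,
                                     n_perm = 2000, cluster_alpha = 0.05,
                                     alpha = 0.05, seed = 1L,
                                     method = c("monte-carlo", "exhaustive"),
                                     min_coverage = 0.8) {
  method <- match.arg(method)
  maps <- as.matrix(maps)
  groups <- factor(groups)
  if (nlevels(groups) != 2) abort("exactly 2 groups are required per contrast")
  if (any(table(groups) < 5)) abort("both groups need n >= 5")
  n <- nrow(maps)
  if (length(groups) != n) abort("`groups` length must match rows of `maps`")
  if (!is.null(age) && length(age) != n)
    abort("`age` length must match rows of `maps`")
  stopifnot(inherits(grid, "source_grid"))
  S <- ncol(maps)
  if (nrow(grid$positions) != S)
    abort("grid source count does not match `maps` columns")
  if (method == "exhaustive" && !is.null(age))
    abort("exhaustive enumeration requires `age = NULL` (exchangeable labels)")

  coverage <- colMeans(!is.na(maps))
  tested <- which(coverage >= min_coverage & coverage > 0)
  adj_list <- adjacency_list(grid$adjacency)
  g_num <- as.numeric(groups == levels(groups)[2])

  stat_map <- rep(NA_real_, S)
  if (length(tested) == 0) {
    return(new_cluster_test(list(), rep(FALSE, S), stat_map, tested,
                            n_perm, seed, alpha, cluster_alpha, method,
                            levels(groups)))
  }
  patterns <- missing_patterns(maps, tested)

  # per-pattern fixed pieces
  pieces <- purrr::map(patterns, function(src) {
    obs <- which(!is.na(maps[, src[1]]))
    X <- if (is.null(age)) cbind(1, g_num[obs]) else
      cbind(1, g_num[obs], age[obs])
    Z <- if (is.null(age)) matrix(1, length(obs), 1) else cbind(1, age[obs])
    Y <- maps[obs, src, drop = FALSE]
    Hz_y <- Z %*% solve(crossprod(Z), crossprod(Z, Y))
    list(src = src, obs = obs, X = X, Y = Y, Hz_y = Hz_y, Rz_y = Y - Hz_y)
  })

  thr_of <- function(df) qt(1 - cluster_alpha / 2, df)
  fill_stats <- function(Ys) {
    tval <- rep(NA_real_, S)
    thr <- rep(NA_real_, S)
    for (i in seq_along(pieces)) {
      pc <- pieces[[i]]
      st <- group_t_map(pc$X, Ys[[i]])
      tval[pc$src] <- st$t
      thr[pc$src] <- thr_of(st$df)
    }
    list(t = tval, thr = thr)
  }

  obs_stats <- fill_stats(purrr::map(pieces, "Y"))
  stat_map <- obs_stats$t
  # thresholds can differ across patterns; clusters use supra-threshold
  # indicator built per source
  supra <- function(st) {
    z <- st$t
    z[!is.na(z) & abs(z) <= st$thr] <- NA  # keep only supra-threshold t
    z
  }
  # use a 0 threshold on the pre-masked map so form_clusters sees only
  # supra-threshold sources
  obs_clusters <- form_clusters(supra(obs_stats), 0, adj_list)

  # the permutation null is only needed when there is a cluster to test
  null_max <- numeric(0)
  if (length(obs_clusters) > 0 || method == "exhaustive") {
    if (method == "monte-carlo") {
      null_max <- withr::with_seed(as.integer(seed), {
        vapply(seq_len(n_perm), function(b) {
          perm <- sample.int(n)
          Ys <- purrr::map(pieces, function(pc) {
            local_rank <- rank(perm[pc$obs], ties.method = "first")
            pc$Hz_y + pc$Rz_y[order(local_rank), , drop = FALSE]
          })
          st <- fill_stats(Ys)
          max_cluster_mass(supra(st), 0, adj_list)
        }, numeric(1))
      })
    } else {
      # exhaustive over group-label assignments (no covariate): relabel the
      # design, keep the data fixed
      n1 <- sum(g_num == 1)
      combos <- combn(n, n1)
      null_max <- apply(combos, 2, function(idx1) {
        g_perm <- numeric(n)
        g_perm[idx1] <- 1
        tval <- rep(NA_real_, S)
        thr <- rep(NA_real_, S)
        for (pc in pieces) {
          Xp <- cbind(1, g_perm[pc$obs])
          st <- group_t_map(Xp, pc$Y)
          tval[pc$src] <- st$t
          thr[pc$src] <- thr_of(st$df)
        }
        max_cluster_mass(supra(list(t = tval, thr = thr)), 0, adj_list)
      })
    }
  }

  denom <- if (method == "monte-carlo") n_perm + 1 else length(null_max)
  clusters <- purrr::map(obs_clusters, function(cl) {
    exceed <- sum(null_max >= abs(cl$mass) - 1e-12)
    p <- if (method == "monte-carlo") (1 + exceed) / denom else exceed / denom
    list(sources = cl$sources, mass = cl$mass, p_value = p)
  })
  sig_mask <- rep(FALSE, S)
  for (cl in clusters) {
    if (cl$p_value <= alpha) sig_mask[cl$sources] <- TRUE
  }
  new_cluster_test(clusters, sig_mask, stat_map, tested, n_perm, seed,
                   alpha, cluster_alpha, method, levels(groups))
}

new_cluster_test <- function(clusters, sig_mask, stat_map, tested, n_perm,
                             seed, alpha, cluster_alpha, method, group_levels) {
  ord <- order(purrr::map_dbl(clusters, ~ -abs(.x$mass)))
  structure(
    list(clusters = clusters[ord], sig_mask = sig_mask,
         statistic_map = stat_map, tested_sources = tested,
         n_permutations = n_perm, seed = seed, alpha = alpha,
         cluster_alpha = cluster_alpha, method = method,
         group_levels = group_levels),
    class = "cluster_test"
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %s vs %s, %d permutations (%s)\n",
              x$group_levels[1], x$group_levels[2], x$n_permutations,
              x$method))
  if (length(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_along(x$clusters)) {
      cl <- x$clusters[[i]]
      cat(sprintf("  cluster %d: %d sources, mass %.2f, p = %.4g%s\n",
                  i, length(cl$sources), cl$mass, cl$p_value,
                  if (cl$p_value <= x$alpha) " *" else ""))
    }
  }
  invisible(x)
}

#' Tidy a cluster permutation test
#'
#' @param x A [cluster_permutation_test()] result.
#' @param ... Unused.
#' @return Tibble with one row per cluster: `cluster`, `n_sources`,
#'   `sources` (list-column), `mass`, `p_value`, `significant`.
#' @exportS3Method generics::tidy
tidy.cluster_test <- function(x, ...) {
  tibble::tibble(
    cluster = seq_along(x$clusters),
    n_sources = purrr::map_int(x$clusters, ~ length(.x$sources)),
    sources = purrr::map(x$clusters, "sources"),
    mass = purrr::map_dbl(x$clusters, "mass"),
    p_value = purrr::map_dbl(x$clusters, "p_value"),
    significant = purrr::map_lgl(x$clusters, ~ .x$p_value <= x$alpha)
  )
}

#' @exportS3Method generics::glance
glance.cluster_test <- function(x, ...) {
  tibble::tibble(
    n_clusters = length(x$clusters),
    n_significant = sum(purrr::map_dbl(x$clusters, "p_value") <= x$alpha),
    min_p = if (length(x$clusters) > 0)
      min(purrr::map_dbl(x$clusters, "p_value")) else NA_real_,
    n_tested_sources = length(x$tested_sources),
    n_permutations = x$n_permutations
  )
}

#' Pairwise cluster tests across the cohort's groups
#'
#' Runs one [cluster_permutation_test()] per group pair on a per-source
#' measure (alpha relative power or alpha peak frequency).
#'
#' @param subjects Cohort subject table with `subject_id`, `group`, `age`.
#' @param maps `subjects x sources` matrix, rows aligned with `subjects`.
#' @param grid Source grid.
#' @param contrasts List of 2-element character vectors of group labels;
#'   default all pairs in group order.
#' @param use_age Include age as covariate (default TRUE).
#' @param ... Passed to [cluster_permutation_test()].
#' @return Named list of `cluster_test` objects (`"A_vs_B"`).
#' @export
run_contrast_battery <- function(subjects, maps, grid, contrasts = NULL,
                                 use_age = TRUE, ...) {
  groups <- unique(as.character(subjects$group))
  if (is.null(contrasts)) {
    contrasts <- combn(groups, 2, simplify = FALSE)
  }
  out <- list()
  for (ct in contrasts) {
    if (length(ct) != 2 || !all(ct %in% groups))
      abort(sprintf("unknown group label in contrast (%s)",
                    paste(ct, collapse = ", ")))
    sel <- subjects$group %in% ct
    res <- cluster_permutation_test(
      maps[sel, , drop = FALSE],
      factor(subjects$group[sel], levels = ct),
      age = if (use_age) subjects$age[sel] else NULL,
      grid = grid, ...
    )
    out[[paste(ct, collapse = "_vs_")]] <- res
  }
  out
}
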