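#' Subject averages of a per-source measure
#'
#' Averages a `subjects x sources` matrix across sources (ignoring missing
#' sources per subject), as done before regressing cognition on alpha power
#' and peak frequency.
#'
#' @param measure_matrix `subjects x sources` numeric matrix; row names (or
#'   `subject_ids`) label subjects.
#' @param subject_ids Optional subject labels used in error messages.
#' @return Per-subject numeric vector of means.
#' @export
subject_average <- function(measure_matrix, subject_ids = rownames(measure_matrix)) {
  m <- as.matrix(measure_matrix)
  all_missing <- rowSums(!is.na(m)) == 0
  if (any(all_missing)) {
    who <- if (!is.null(subject_ids)) subject_ids[all_missing] else
      which(all_missing)
    abort(sprintf("subject(s) %s have no non-missing source values",
                  paste(who, collapse = ", ")))
  }
  rowMeans(m, na.rm = TRUE)
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up procedure at level `q`: sort p-values ascending, find the largest
#' k with `p_(k) <= k q / m`, flag the k smallest. Implemented through
#' `p.adjust(..., "BH")`, which is algebraically the same rule.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param q FDR level (the study uses q = 0.1).
#' @return Logical vector, `TRUE` where the hypothesis is rejected.
#' @export
bh_fdr <- function(p_values, q = 0.1) {
  if (length(p_values) == 0) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]")
  check_number(q, "q", lo = 0, hi = 1)
  p.adjust(p_values, method = "BH") <= q
}

#' Two-predictor regression battery
#'
#' For each criterion (neuropsychological score or hippocampal volume), fits
#' the ordinary least squares model
#' `y = beta0 + beta1 * alpha_power + beta2 * peak_freq + e`, both
#' predictors entered in a single step, and corrects the coefficient
#' p-values with Benjamini-Hochberg FDR at level `q`. By default the FDR
#' family pools both predictors' p-values across all criteria (one family of
#' `2 x n_criteria` tests); `family = "per-predictor"` corrects each
#' predictor's column of p-values separately.
#'
#' @param data Data frame with one row per subject, columns `alpha_power`,
#'   `peak_freq`, and every criterion.
#' @param criteria Character vector of criterion column names.
#' @param q FDR level (default 0.1).
#' @param family `"pooled"` (default) or `"per-predictor"`.
#' @param standardize Z-score the predictors before fitting (default FALSE;
#'   coefficients are then on the raw scale as reported).
#' @return Object of class `regression_battery`; `tidy()` gives one row per
#'   criterion-coefficient with estimates, p-values and FDR flags.
#' @export
fit_battery <- function(data, criteria, q = 0.1,
                        family = c("pooled", "per-predictor"),
                        standardize = FALSE) {
  family <- match.arg(family)
  if (!all(c("alpha_power", "peak_freq") %in% names(data)))
    abort("`data` must contain `alpha_power` and `peak_freq` columns")
  missing_cols <- setdiff(criteria, names(data))
  if (length(missing_cols) > 0)
    abort(sprintf("criteria not in `data`: %s",
                  paste(missing_cols, collapse = ", ")))
  if (nrow(data) <= 5) abort("need n > 5 subjects")
  x1 <- data$alpha_power
  x2 <- data$peak_freq
  if (anyNA(x1) || anyNA(x2)) abort("predictors must be complete")
  if (standardize) {
    x1 <- as.numeric(scale(x1))
    x2 <- as.numeric(scale(x2))
  }
  X <- cbind(1, x1, x2)
  if (qr(X)$rank < 3)
    abort("degenerate design: alpha power and peak frequency are collinear")

  rows <- purrr::map_dfr(criteria, function(cr) {
    y <- data[[cr]]
    if (anyNA(y)) abort(sprintf("criterion `%s` has missing values", cr))
    fit <- lm(y ~ x1 + x2)
    sm <- summary(fit)$coefficients
    tibble::tibble(
      criterion = cr,
      term = c("intercept", "alpha_power", "peak_freq"),
      estimate = unname(sm[, 1]), std_error = unname(sm[, 2]),
      p_value = unname(sm[, 4])
    )
  })
  slopes <- rows$term != "intercept"
  rows$fdr_significant <- NA
  if (family == "pooled") {
    rows$fdr_significant[slopes] <- bh_fdr(rows$p_value[slopes], q)
  } else {
    for (tm in c("alpha_power", "peak_freq")) {
      sel <- rows$term == tm
      rows$fdr_significant[sel] <- bh_fdr(rows$p_value[sel], q)
    }
  }
  structure(list(results = rows, q = q, family = family,
                 n = nrow(data), criteria = criteria),
            class = "regression_battery")
}

#' @export
print.regression_battery <- function(x, ...) {
  cat(sprintf("<regression_battery> %d criteria, n = %d, FDR q = %g (%s)\n",
              length(x$criteria), x$n, x$q, x$family))
  sig <- dplyr::filter(x$results, .data$term != "intercept",
                       .data$fdr_significant)
  if (nrow(sig) == 0) {
    cat("  no FDR-significant coefficients\n")
  } else {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %s ~ %s: %.3g (p = %.3g)\n", sig$criterion[i],
                  sig$term[i], sig$estimate[i], sig$p_value[i]))
    }
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.regression_battery <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.regression_battery <- function(x, ...) {
  slopes <- dplyr::filter(x$results, .data$term != "intercept")
  tibble::tibble(
    n = x$n, n_criteria = length(x$criteria), q = x$q, family = x$family,
    n_significant = sum(slopes$fdr_significant)
  )
}
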