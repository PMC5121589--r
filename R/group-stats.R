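#' Age-adjusted group comparison (ANCOVA)
#'
#' Fits `value ~ group + age` and tests the group factor with the nested-
#' model F test (equivalent to the Type-II ANCOVA F for a single factor and
#' covariate). When the factor is significant at 0.05, covariate-adjusted
#' group means and Tukey HSD pairwise contrasts are computed via
#' \pkg{emmeans}.
#'
#' @param values Per-subject scalar outcome.
#' @param groups Per-subject group labels (>= 2 groups, each n >= 3).
#' @param age Per-subject age covariate, years.
#' @param tukey_alpha Significance level gating the pairwise step.
#' @return Object of class `ancova_fit`: list with `f_stat`, `p_value`, `df`
#'   (numerator, denominator), `adjusted_means` (tibble), `pairwise` (tibble
#'   of Tukey-adjusted contrasts, or NULL when the factor is not
#'   significant), `age_coef`, and the underlying `model`.
#' @export
ancova_group_effect <- function(values, groups, age, tukey_alpha = 0.05) {
  if (anyNA(values) || anyNA(groups) || anyNA(age))
    abort("missing values must be handled upstream")
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (any(table(groups) < 3)) abort("each group needs n >= 3")
  if (sd(values) == 0)
    abort("`values` is constant: the model is degenerate")
  dat <- data.frame(value = values, group = groups, age = age)
  full <- lm(value ~ group + age, data = dat)
  reduced <- lm(value ~ age, data = dat)
  an <- anova(reduced, full)
  f_stat <- an$F[2]
  p_value <- an$`Pr(>F)`[2]
  df <- c(an$Df[2], an$Res.Df[2])
  emm <- emmeans::emmeans(full, "group")
  adj <- tibble::as_tibble(summary(emm))[, c("group", "emmean", "SE")]
  names(adj) <- c("group", "adjusted_mean", "se")
  pairwise <- NULL
  if (is.finite(p_value) && p_value < tukey_alpha) {
    pw <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
    pairwise <- tibble::tibble(
      contrast = as.character(pw$contrast),
      estimate = pw$estimate,
      p_adjusted = pw$p.value
    )
  }
  structure(
    list(f_stat = f_stat, p_value = p_value, df = df,
         adjusted_means = adj, pairwise = pairwise,
         age_coef = unname(coef(full)[["age"]]), model = full),
    class = "ancova_fit"
  )
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("<ancova_fit> F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$f_stat, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("  Tukey HSD contrasts:\n")
    for (i in seq_len(nrow(x$pairwise))) {
      cat(sprintf("    %s: %.3f (p = %.4g)\n", x$pairwise$contrast[i],
                  x$pairwise$estimate[i], x$pairwise$p_adjusted[i]))
    }
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ancova_fit <- function(x, ...) {
  if (is.null(x$pairwise)) {
    return(tibble::tibble(contrast = character(), estimate = numeric(),
                          p_adjusted = numeric()))
  }
  x$pairwise
}

#' @exportS3Method generics::glance
glance.ancova_fit <- function(x, ...) {
  tibble::tibble(f_stat = x$f_stat, df_num = x$df[1], df_den = x$df[2],
                 p_value = x$p_value, age_coef = x$age_coef)
}
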