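#' Choose a parametric or non-parametric two-sample test
#'
#' Shapiro-Wilk normality screening of each sample at `alpha_normality`; the
#' unpaired t-test is used when both samples are compatible with normality,
#' the Mann-Whitney U test otherwise. The normality p-values that produced
#' the decision are recorded.
#'
#' @param a,b numeric samples, each with n >= 3.
#' @param alpha_normality significance level of the normality screen.
#' @return List with `test` (`"t_unpaired"` or `"mann_whitney_u"`) and
#'   `shapiro_p` (length 2).
#' @export
choose_test <- function(a, b, alpha_normality = 0.05) {
  if (length(a) < 3 || length(b) < 3)
    stop("each sample needs n >= 3 for the normality screen")
  p <- c(shapiro.test(a)$p.value, shapiro.test(b)$p.value)
  list(test = if (all(p >= alpha_normality)) "t_unpaired" else "mann_whitney_u",
       shapiro_p = p)
}

#' Two-group comparison of a trajectory metric
#'
#' Runs the requested (or automatically chosen) two-sided test and returns a
#' `mer_comparison` record. The Mann-Whitney statistic is reported with the
#' smaller-U convention, `U = min(U_a, U_b)`; p-values are exact for small
#' untied samples and use the tie-corrected normal approximation otherwise.
#' The unpaired t-test is the classical equal-variance form.
#'
#' @param a,b numeric samples.
#' @param test `"t_unpaired"`, `"mann_whitney_u"`, or `NULL` to choose via
#'   [choose_test()].
#' @param alpha significance level.
#' @param metric metric name carried into the record.
#' @param adjusted_alpha optional Bonferroni-adjusted level; when given, the
#'   `significant_adjusted` flag compares against it.
#' @return A one-row data frame of class `mer_comparison`: metric, group
#'   sizes, test, statistic, p-value, alpha(s) and significance flags.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6), test = "mann_whitney_u")
compare_groups <- function(a, b, test = NULL, alpha = 0.05,
                           metric = "metric", adjusted_alpha = NA_real_) {
  shapiro_p <- c(NA_real_, NA_real_)
  if (is.null(test)) {
    ch <- choose_test(a, b)
    test <- ch$test
    shapiro_p <- ch$shapiro_p
  }
  if (test == "t_unpaired") {
    if (sd(c(a - mean(a), b - mean(b))) == 0)
      stop("degenerate t-test: both samples have zero variance")
    ht <- t.test(a, b, var.equal = TRUE)
    stat <- unname(ht$statistic); p <- ht$p.value
  } else if (test == "mann_whitney_u") {
    ht <- suppressWarnings(wilcox.test(a, b, exact = NULL, correct = TRUE))
    u_a <- unname(ht$statistic)
    stat <- min(u_a, length(a) * length(b) - u_a)
    p <- ht$p.value
  } else stop(sprintf("unknown test '%s'", test))
  out <- data.frame(metric = metric, n_a = length(a), n_b = length(b),
                    test = test, statistic = stat, p_value = p,
                    alpha = alpha, adjusted_alpha = adjusted_alpha,
                    significant = p < alpha,
                    significant_adjusted = if (is.na(adjusted_alpha)) NA else
                      p < adjusted_alpha,
                    shapiro_p_a = shapiro_p[1], shapiro_p_b = shapiro_p[2])
  class(out) <- c("mer_comparison", class(out))
  out
}

#' Compare a metric across three or more groups
#'
#' One-way ANOVA when every group passes the Shapiro-Wilk screen, otherwise
#' the Kruskal-Wallis rank-sum test.
#'
#' @param values numeric vector of metric values.
#' @param groups parallel group labels (>= 3 levels).
#' @param alpha significance level.
#' @return A `mer_comparison` row with test `"anova"` or `"kruskal_wallis"`.
#' @export
compare_k_groups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 3) stop("use compare_groups() for two groups")
  norm_p <- tapply(values, groups, function(v) shapiro.test(v)$p.value)
  if (all(norm_p >= 0.05)) {
    fit <- aov(values ~ groups)
    s <- summary(fit)[[1]]
    test <- "anova"; stat <- s$`F value`[1]; p <- s$`Pr(>F)`[1]
  } else {
    ht <- kruskal.test(values, groups)
    test <- "kruskal_wallis"; stat <- unname(ht$statistic); p <- ht$p.value
  }
  out <- data.frame(metric = "metric", n_a = NA_integer_, n_b = NA_integer_,
                    test = test, statistic = stat, p_value = p, alpha = alpha,
                    adjusted_alpha = NA_real_, significant = p < alpha,
                    significant_adjusted = NA,
                    shapiro_p_a = NA_real_, shapiro_p_b = NA_real_)
  class(out) <- c("mer_comparison", class(out))
  out
}

#' Bonferroni-adjusted comparison of the non-beta band powers
#'
#' Compares the mean band-power fractions of the given bands between the two
#' groups of a metric table, reporting both raw significance at `alpha` and
#' Bonferroni-adjusted significance at `alpha / length(bands)` (0.0125 for the
#' default four bands at alpha 0.05).
#'
#' @param metrics metric table from [cohort_metrics()] with a `group` column
#'   and `mean_<band>_power` columns.
#' @param bands character vector of band names.
#' @param group_col name of the group column.
#' @param alpha family significance level.
#' @return A `mer_comparison` data frame, one row per band.
#' @export
multiband_compare <- function(metrics, bands = c("delta", "theta", "alpha", "gamma"),
                              group_col = "group", alpha = 0.05) {
  gl <- unique(metrics[[group_col]])
  if (length(gl) != 2) stop("multiband_compare expects exactly two groups")
  adj <- alpha / length(bands)
  rows <- lapply(bands, function(bn) {
    col <- paste0("mean_", bn, "_power")
    if (!col %in% names(metrics)) stop(sprintf("missing column '%s'", col))
    a <- metrics[[col]][metrics[[group_col]] == gl[1]]
    b <- metrics[[col]][metrics[[group_col]] == gl[2]]
    compare_groups(a, b, alpha = alpha, metric = col, adjusted_alpha = adj)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mer_comparison", "data.frame")
  out
}

#' @export
print.mer_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    cat(sprintf("%s: %s, statistic = %.4g, p = %.4g (n = %s vs %s)%s\n",
                r$metric, r$test, r$statistic, r$p_value, r$n_a, r$n_b,
                if (isTRUE(r$significant)) " *" else ""))
    if (!is.na(r$adjusted_alpha))
      cat(sprintf("  Bonferroni alpha = %.4g: %s\n", r$adjusted_alpha,
                  if (isTRUE(r$significant_adjusted)) "significant"
                  else "not significant"))
  }
  invisible(x)
}
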