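#' Paired per-chromosome comparison with a normality gate
#'
#' Pairwise differences (B - A, paired by chromosome) are tested for
#' normality with a Shapiro-Wilk test; a paired t-test is used when the
#' differences are compatible with normality (Shapiro p > \code{gate_alpha}),
#' a paired Wilcoxon signed-rank test otherwise (exact distribution for
#' n <= 25, normal approximation with continuity correction above, zero
#' differences dropped). Chromosomes with a missing value in either group
#' are dropped pairwise.
#'
#' @param valuesA,valuesB Named numeric vectors (names are chromosomes).
#' @param gate_alpha Normality gate threshold (default 0.05).
#' @param metric,groupA,groupB Optional labels carried into the result.
#' @return Object of class \code{paired_comparison}: list with
#'   \code{n_pairs}, \code{n_dropped}, \code{shapiro_p}, \code{test_used}
#'   (\code{"paired_t"}/\code{"paired_wilcoxon"}), \code{p_value},
#'   \code{mean_diff}, \code{degenerate} (all differences zero), plus the
#'   labels.
#' @export
paired_compare <- function(valuesA, valuesB, gate_alpha = 0.05,
                           metric = NA_character_, groupA = "A", groupB = "B") {
  common <- intersect(names(valuesA), names(valuesB))
  a <- valuesA[common]
  b <- valuesB[common]
  ok <- is.finite(a) & is.finite(b)
  n_dropped <- sum(!ok) + length(setdiff(union(names(valuesA), names(valuesB)), common))
  d <- (b - a)[ok]
  if (length(d) < 3) stop_config("paired_compare needs at least 3 complete pairs")

  degenerate <- all(d == 0)
  if (degenerate) {
    res <- list(shapiro_p = NA_real_, test_used = "paired_wilcoxon", p_value = 1)
  } else if (length(unique(d)) == 1) {
    # constant non-zero differences: Shapiro undefined, fall through to Wilcoxon
    p <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
    res <- list(shapiro_p = NA_real_, test_used = "paired_wilcoxon", p_value = p)
  } else {
    sw <- shapiro.test(d)$p.value
    if (sw > gate_alpha) {
      res <- list(shapiro_p = sw, test_used = "paired_t",
                  p_value = t.test(d)$p.value)
    } else {
      exact <- length(d) <= 25
      p <- suppressWarnings(wilcox.test(d, exact = exact, correct = TRUE)$p.value)
      res <- list(shapiro_p = sw, test_used = "paired_wilcoxon", p_value = p)
    }
  }
  structure(c(list(metric = metric, groupA = groupA, groupB = groupB,
                   n_pairs = length(d), n_dropped = n_dropped,
                   mean_diff = mean(d), degenerate = degenerate), res),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("paired comparison%s: %s vs %s, %d pairs\n",
              if (is.na(x$metric)) "" else paste0(" [", x$metric, "]"),
              x$groupB, x$groupA, x$n_pairs))
  cat(sprintf("  mean difference %.4g; Shapiro p %s -> %s, p = %.4g%s\n",
              x$mean_diff,
              if (is.na(x$shapiro_p)) "NA" else sprintf("%.3f", x$shapiro_p),
              x$test_used, x$p_value,
              if (x$degenerate) " (degenerate: all differences zero)" else ""))
  invisible(x)
}

#' Linear trend over a rank profile
#'
#' Ordinary least squares of a rank-level statistic on the rank mean values;
#' reports the slope, raw and adjusted R-squared (the adjusted convention
#' may be negative for a null fit) and the slope's two-sided p-value.
#'
#' @param x Rank mean values (excluded ranks removed beforehand).
#' @param y Rank-level statistic.
#' @param response,predictor Optional labels.
#' @return Object of class \code{trend_fit}: list with \code{slope},
#'   \code{intercept}, \code{r2}, \code{adj_r2}, \code{p_value}, \code{n}.
#' @export
fit_linear_trend <- function(x, y, response = "y", predictor = "x") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_config("fit_linear_trend needs at least 3 points")
  if (stats::var(x) == 0) stop_config("zero variance in the predictor")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # silence the perfect-fit warning
  structure(list(response = response, predictor = predictor,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 p_value = sm$coefficients[2, 4], n = length(x)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("linear trend %s ~ %s (n = %d): slope %.4g, R2 = %.2f (adj), p = %.3g\n",
              x$response, x$predictor, x$n, x$slope, x$adj_r2, x$p_value))
  invisible(x)
}
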