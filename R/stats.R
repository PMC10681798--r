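#' Distribution summary of per-cell measurements
#'
#' The descriptors used to characterise single-cell heterogeneity: mean,
#' sample standard deviation (n - 1), median, interquartile range
#' (percentiles by linear interpolation), coefficient of variation in
#' percent (100 * sd / mean), minimum and maximum.
#'
#' @param values numeric vector, length >= 2.
#' @return A `summary_stats` list with fields `n`, `mean`, `std`, `median`,
#'   `iqr`, `cv_percent`, `min`, `max`.
#' @examples
#' summary_stats(c(1, 2, 3)) # cv 50%
#' @export
summary_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values))
    stop_f("need >= 2 non-missing values")
  m <- mean(values)
  s <- sd(values)
  structure(list(n = length(values), mean = m, std = s,
                 median = median(values),
                 iqr = unname(quantile(values, 0.75, type = 7) -
                              quantile(values, 0.25, type = 7)),
                 cv_percent = 100 * s / m,
                 min = min(values), max = max(values)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d  mean = %.4g (+/- %.4g std)  median = %.4g (IQR %.4g)  CV = %.1f%%\n",
    x$n, x$mean, x$std, x$median, x$iqr, x$cv_percent))
  invisible(x)
}

test_result <- function(test_name, statistic, p_value, n, method = NA,
                        seed = NA, alpha = 0.05) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n = n, method = method,
                 seed = seed, alpha = alpha),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g, p = %.4g (n = %s%s)\n", x$test_name,
              x$statistic, x$p_value, paste(x$n, collapse = ", "),
              if (!is.na(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS test comparing two empirical distributions, the test used
#' to compare replicate foci-count distributions. The statistic is
#' `D = sup |ECDF_a - ECDF_b|`; the p-value is exact for small samples and
#' asymptotic otherwise, with the method recorded in the result.
#'
#' @param a,b numeric samples (each n >= 1).
#' @param alpha significance level recorded in the result.
#' @return A `test_result` with `test_name = "ks_two_sample"`.
#' @export
ks_two_sample <- function(a, b, alpha = 0.05) {
  if (length(a) < 1 || length(b) < 1) stop_f("both samples must be non-empty")
  r <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
  test_result("ks_two_sample", r$statistic, r$p.value,
              n = c(length(a), length(b)), method = r$method, alpha = alpha)
}

#' Normality assessment against a simulated Normal sample
#'
#' Draws one Normal sample with the observed mean and standard deviation,
#' `sim_size_factor` times larger than the data, and compares data and
#' simulation with the two-sample KS test. This is a pragmatic screen for
#' departures from normality in large per-cell datasets; the simulated
#' sample size and seed are recorded so the test is exactly reproducible.
#'
#' @param values numeric sample, n >= 8.
#' @param sim_size_factor simulated sample is `sim_size_factor * n` draws.
#' @param seed integer seed for the simulation.
#' @param alpha significance level recorded in the result.
#' @return A `test_result` with `test_name = "ks_normality_sim"`.
#' @export
ks_normality_vs_sim <- function(values, sim_size_factor = 10, seed = 1,
                                alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 8) stop_f("need n >= 8 for the normality screen")
  s <- sd(values)
  if (s == 0) stop_f("zero standard deviation; normality test undefined")
  sim <- with_seed(seed, rnorm(sim_size_factor * length(values),
                               mean = mean(values), sd = s))
  r <- ks_two_sample(values, sim, alpha = alpha)
  test_result("ks_normality_sim", r$statistic, r$p_value, n = r$n,
              method = r$method, seed = as.integer(seed), alpha = alpha)
}

#' Kruskal-Wallis rank test across groups
#'
#' Non-parametric comparison of per-cell measurements between independent
#' experiments (e.g. samples prepared on different days). Returns the
#' tie-corrected H statistic with a chi-squared p-value on k - 1 degrees of
#' freedom. If all values are identical across groups, H = 0 and p = 1.
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 1).
#' @param alpha significance level recorded in the result.
#' @return A `test_result` with `test_name = "kruskal_wallis"`.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop_f("'groups' must be a list of >= 2 samples")
  if (any(vapply(groups, length, integer(1)) < 1))
    stop_f("every group needs n >= 1")
  if (length(unique(unlist(groups))) == 1L)
    return(test_result("kruskal_wallis", 0, 1,
                       n = vapply(groups, length, integer(1)),
                       method = "degenerate: all values identical",
                       alpha = alpha))
  r <- kruskal.test(groups)
  test_result("kruskal_wallis", r$statistic, r$p.value,
              n = vapply(groups, length, integer(1)), method = r$method,
              alpha = alpha)
}

#' Correlation between foci counts and mitochondrial area
#'
#' Pearson correlation by default (Spearman available), used to relate the
#' per-cell nucleoid count to the mitochondrial network area.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-zero variance.
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha significance level recorded in the result.
#' @return A `test_result` with `test_name` `"pearson"` or `"spearman"`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman"),
                        alpha = 0.05) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_f("'x' and 'y' must have equal length")
  if (length(x) < 3) stop_f("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop_f("zero variance in 'x' or 'y'; correlation undefined")
  r <- suppressWarnings(cor.test(x, y, method = method))
  test_result(method, r$estimate, r$p.value, n = length(x),
              method = r$method, alpha = alpha)
}

#' Summaries and tests over a batch results table
#'
#' Convenience front-end over the per-cell results CSV: restrict to one
#' prominence, summarise filtered counts, area and density, and compare
#' experiments with the Kruskal-Wallis test and pairwise per-group
#' summaries.
#'
#' @param records results data frame (from [run_batch()] or
#'   [read_cell_csv()]).
#' @param prominence prominence to analyse; defaults to the single value
#'   present, otherwise required.
#' @param group_by grouping column, typically `"experiment_id"`.
#' @return A list with `summary` (per-measure [summary_stats()]),
#'   `by_group` (per-group summaries of filtered counts), `kruskal`
#'   (between-group test, `NULL` if < 2 groups) and `correlation`
#'   (count-area Pearson test).
#' @export
batch_stats <- function(records, prominence = NULL,
                        group_by = "experiment_id") {
  stopifnot(is.data.frame(records))
  ps <- sort(unique(records$prominence))
  if (is.null(prominence)) {
    if (length(ps) != 1)
      stop_f("several prominences present (%s); pick one",
             paste(ps, collapse = ", "))
    prominence <- ps
  }
  r <- records[records$prominence == prominence, , drop = FALSE]
  if (nrow(r) < 2) stop_f("fewer than 2 cells at prominence %s", prominence)
  out <- list(
    prominence = prominence,
    summary = list(n_foci_filtered = summary_stats(r$n_foci_filtered),
                   mito_area_um2 = summary_stats(r$mito_area_um2),
                   density_per_um2 = if (!anyNA(r$density_per_um2))
                     summary_stats(r$density_per_um2) else NULL),
    by_group = NULL, kruskal = NULL, correlation = NULL)
  g <- r[[group_by]]
  if (!is.null(g) && length(unique(g[!is.na(g)])) >= 2) {
    grp <- split(r$n_foci_filtered, g)
    out$by_group <- lapply(grp, summary_stats)
    out$kruskal <- kruskal_wallis(grp)
  }
  if (nrow(r) >= 3 && sd(r$n_foci_filtered) > 0 && sd(r$mito_area_um2) > 0)
    out$correlation <- correlation(r$n_foci_filtered, r$mito_area_um2)
  out
}
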