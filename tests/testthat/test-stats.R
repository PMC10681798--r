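test_that("summary_stats matches hand-computed descriptors", {
  s <- summary_stats(c(1, 2, 3))
  expect_equal(s$n, 3L)
  expect_equal(s$mean, 2)
  expect_equal(s$std, 1)
  expect_equal(s$median, 2)
  expect_equal(s$iqr, 1)
  expect_equal(s$cv_percent, 50)
  expect_equal(c(s$min, s$max), c(1, 3))
  expect_error(summary_stats(5), ">= 2")
})

test_that("CoV reproduces printed heterogeneity values from their moments", {
  # construct two-point samples with exactly the published mean and sd,
  # then check the CoV the package computes rounds to the printed percent
  two_point <- function(m, s) c(m - s / sqrt(2), m + s / sqrt(2))
  expect_equal(round(summary_stats(two_point(339, 188))$cv_percent, 1), 55.5)
  expect_equal(round(summary_stats(two_point(211.4, 137.1))$cv_percent, 1),
               64.9)
  expect_equal(round(summary_stats(two_point(644, 345))$cv_percent, 1), 53.6)
})

test_that("summary is order-invariant; concatenation keeps location", {
  set.seed(1)
  x <- rnorm(50, 10, 3)
  a <- summary_stats(x)
  b <- summary_stats(sample(x))
  expect_equal(a, b)
  d <- summary_stats(c(x, x))
  expect_equal(d$mean, a$mean)
  expect_equal(d$median, a$median)
  expect_equal(d$min, a$min)
  expect_equal(d$max, a$max)
})

test_that("KS statistic equals a brute-force ECDF sup-difference", {
  sup_d <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(vapply(g, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
  }
  set.seed(42)
  for (trial in 1:100) {
    a <- sample(0:30, sample(3:25, 1), replace = TRUE)
    b <- rnorm(sample(3:25, 1), mean = runif(1, 0, 20), sd = 5)
    r <- ks_two_sample(a, b)
    expect_equal(r$statistic, sup_d(a, b), tolerance = 1e-12)
    expect_gte(r$p_value, 0)
    expect_lte(r$p_value, 1)
  }
})

test_that("KS edge cases: identical and disjoint samples", {
  x <- c(3, 1, 4, 1, 5)
  r <- ks_two_sample(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  d <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(d$statistic, 1)
  # exact enumeration: P(D = 1) for 3 vs 3 = 2 / choose(6, 3)
  expect_equal(d$p_value, 0.1, tolerance = 1e-9)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("KS D is invariant under monotone transformation and reordering", {
  set.seed(9)
  a <- rlnorm(40); b <- rlnorm(35, 0.4)
  d0 <- ks_two_sample(a, b)$statistic
  expect_equal(ks_two_sample(log(a), log(b))$statistic, d0)
  expect_equal(ks_two_sample(sample(a), sample(b))$statistic, d0)
})

test_that("normality screen is reproducible and seed-recorded", {
  set.seed(3)
  x <- rnorm(100)
  r1 <- ks_normality_vs_sim(x, seed = 7)
  r2 <- ks_normality_vs_sim(x, seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$seed, 7L)
  expect_equal(r1$n[2], 1000L) # 10x simulated sample
  expect_error(ks_normality_vs_sim(rep(1, 20), seed = 1), "zero standard")
  expect_error(ks_normality_vs_sim(1:5, seed = 1), "n >= 8")
})

test_that("Kruskal-Wallis matches the hand-rank formula without ties", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  # ranks 1..6: H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2
  h_hand <- 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2)
  r <- kruskal_wallis(g)
  expect_equal(r$statistic, h_hand, tolerance = 1e-12)
  expect_equal(r$p_value, stats::pchisq(h_hand, df = 1, lower.tail = FALSE))
  # three identical groups
  expect_equal(kruskal_wallis(list(1:3, 1:3, 1:3))$statistic, 0)
  # all values identical -> degenerate H = 0, p = 1
  dg <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(dg$statistic, 0)
  expect_equal(dg$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
})

test_that("Kruskal-Wallis is invariant under monotone transformation", {
  set.seed(5)
  g <- list(rnorm(20, 1), rnorm(25, 2), rnorm(15, 1.5))
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(lapply(g, function(x) exp(x / 2)))$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("correlation handles exact linear data and bad input", {
  x <- 1:10
  expect_equal(correlation(x, 2 * x + 1)$statistic, 1)
  expect_equal(correlation(x, -x)$statistic, -1)
  expect_equal(correlation(x, (2 * x + 1)^3, method = "spearman")$statistic,
               1)
  expect_error(correlation(1:5, 1:4), "equal length")
  expect_error(correlation(1:2, 1:2), "n >= 3")
  expect_error(correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("correlation recovers the generating coefficient", {
  set.seed(12)
  z <- rnorm(2000)
  x <- exp(0.4 * z + 0.3 * rnorm(2000))
  y <- exp(0.4 * z + 0.3 * rnorm(2000))
  rho_true <- cor(0.4 * z + 0.3 * rnorm(2000), 0.4 * z) # approx target
  r <- correlation(x, y)
  expect_gt(r$statistic, 0.5)
  expect_lt(r$p_value, 1e-10)
})

test_that("batch_stats summarises, groups and correlates a results table", {
  set.seed(21)
  n <- 60
  area <- rlnorm(n, log(200), 0.3)
  cnt <- as.integer(round(area * rnorm(n, 1.5, 0.15)))
  rec <- data.frame(
    cell_id = sprintf("c%03d", 1:n), source_image = "x.tif",
    experiment_id = rep(c("e1", "e2", "e3"), length.out = n),
    prominence = 83L, n_foci_raw = cnt + 5L, n_foci_filtered = cnt,
    mito_area_um2 = area, density_per_um2 = cnt / area,
    pixel_size_um = 0.1, stringsAsFactors = FALSE)
  s <- batch_stats(rec)
  expect_equal(s$prominence, 83L)
  expect_equal(s$summary$n_foci_filtered$n, n)
  expect_length(s$by_group, 3)
  expect_s3_class(s$kruskal, "test_result")
  expect_gt(s$correlation$statistic, 0.8)
  multi <- rbind(rec, transform(rec, prominence = 44L))
  expect_error(batch_stats(multi), "several prominences")
  expect_equal(batch_stats(multi, prominence = 83)$summary$n_foci_filtered$n,
               n)
})
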