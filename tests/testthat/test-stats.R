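# Correlation, permutation FDR, binned scatter, LOESS and group tests.

test_that("correlation matches hand-computed values and stats::cor", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlation(x, 2 * x + 1), 1)
  expect_equal(correlation(x, -x), -1)
  y <- c(2, 1, 4, 3, 6)
  expect_equal(correlation(x, y), stats::cor(x, y))
  expect_equal(correlation(x, y, "spearman"),
               stats::cor(rank(x), rank(y)))
  # spearman is invariant under monotone transforms
  expect_equal(correlation(exp(x), y^3, "spearman"),
               correlation(x, y, "spearman"))
  expect_error(correlation(x, rep(1, 5)), "zero variance")
  expect_error(correlation(x, y[1:4]), "equal length")
  expect_error(correlation(c(1, 2, NA, 4, 5), y), "finite")
})

test_that("permutation FDR flags strong signal and is deterministic", {
  withr::with_seed(10, {
    x <- runif(60)
    y <- x + rnorm(60, sd = 0.05)
  })
  r1 <- permutation_fdr(x, y, "spearman", n_iterations = 2000, seed = 3)
  expect_lt(r1$fdr, 0.001)
  expect_true(r1$significant)
  r2 <- permutation_fdr(x, y, "spearman", n_iterations = 2000, seed = 3)
  expect_identical(r1, r2)
  # FDR is bounded below by 1/(B+1)
  expect_gte(r1$fdr, 1 / 2001)
  # monotone transforms leave the spearman result unchanged
  r3 <- permutation_fdr(exp(x), y^3, "spearman", n_iterations = 2000,
                        seed = 3)
  expect_equal(r3$coefficient, r1$coefficient)
  expect_equal(r3$fdr, r1$fdr)
  expect_error(permutation_fdr(x, y, n_iterations = 50), "n_iterations")
})

test_that("permutation FDR is calibrated on independent noise", {
  withr::with_seed(11, {
    x <- rnorm(40)
    y <- rnorm(40)
  })
  r <- permutation_fdr(x, y, "pearson", n_iterations = 4000, seed = 2)
  # null data: FDR roughly matches the parametric p-value
  p <- stats::cor.test(x, y)$p.value
  expect_equal(r$fdr, p, tolerance = 0.05)
  # one-sided halves the null exceedance probability in expectation
  r1 <- permutation_fdr(x, y, "pearson", n_iterations = 4000, seed = 2,
                        sided = "one")
  expect_lte(r1$fdr, r$fdr + 0.02)
})

test_that("binned scatter means partition the sample exactly", {
  x <- c(0.01, 0.02, 0.11, 0.12, 0.13, 0.29)
  y <- c(1, 3, 5, 7, 9, 4)
  b <- binned_scatter(x, y, 0.1)
  expect_equal(b$bin_center, c(0.05, 0.15, 0.25))
  expect_equal(b$mean_y, c(2, 7, 4))
  expect_equal(b$count, c(2L, 3L, 1L))
  expect_equal(b$sem_y[1], stats::sd(c(1, 3)) / sqrt(2))
  expect_equal(b$sem_y[3], 0)
  # pooled identity: count-weighted bin means reproduce the global mean
  withr::with_seed(14, {
    x2 <- runif(500); y2 <- rnorm(500)
  })
  b2 <- binned_scatter(x2, y2, 0.07)
  expect_equal(sum(b2$mean_y * b2$count) / sum(b2$count), mean(y2))
  expect_equal(sum(b2$count), 500L)
  expect_error(binned_scatter(x, y, 0), "bin_width")
})

test_that("binned means are monotone over the transition range of the link", {
  link <- lamin_link_params()
  withr::with_seed(101, {
    s <- runif(1500, 0, 0.2)
    lam <- link_curve(s, link) * lognormal_noise(1500, link$noise_cv)
  })
  b <- binned_scatter(s, lam, 0.01)
  full <- b[b$count >= 5, ]
  frac_up <- mean(diff(full$mean_y) > 0)
  expect_gte(frac_up, 0.9)
})

test_that("LOESS reproduces linear trends and recovers the sigmoid", {
  withr::with_seed(15, x <- sort(runif(80, 0, 1)))
  y <- 2 * x + 1
  tr <- loess_trend(x, y, span = 0.75)
  expect_equal(tr$fit, 2 * tr$x + 1, tolerance = 1e-6)
  # fit is symmetric in observation order
  ord <- sample(seq_along(x))
  tr2 <- loess_trend(x[ord], y[ord], span = 0.75)
  expect_equal(tr2$fit, tr$fit, tolerance = 1e-8)
  # noiseless sigmoid recovered within 2% of its range
  link <- lamin_link_params()
  s <- seq(0, 0.3, length.out = 150)
  lam <- link_curve(s, link)
  tr3 <- loess_trend(s, lam, span = 0.3)
  truth <- link_curve(tr3$x, link)
  expect_lt(max(abs(tr3$fit - truth)),
            0.02 * (link$max_level - link$base_level))
  expect_error(loess_trend(x[1:5], y[1:5]), "n >= 10")
  expect_error(loess_trend(x, y, span = 0.01), "span")
})

test_that("group comparisons match stats:: and obey F = t^2", {
  withr::with_seed(16, {
    a <- rnorm(20, 0); b <- rnorm(20, 1)
  })
  v <- c(a, b); g <- rep(c("a", "b"), each = 20)
  tt <- group_compare(v, g, "t_test_two_sided")
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(tt$p_value, ref$p.value)
  expect_equal(tt$statistic, unname(ref$statistic))
  an <- group_compare(v, g, "anova_one_way")
  expect_equal(an$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(an$p_value, tt$p_value, tolerance = 1e-10)
  # three groups
  withr::with_seed(17, cc <- rnorm(20, 2))
  v3 <- c(a, b, cc); g3 <- rep(c("a", "b", "c"), each = 20)
  an3 <- group_compare(v3, g3, "anova_one_way")
  expect_lt(an3$p_value, 1e-6)
  expect_error(group_compare(v3, g3, "t_test_two_sided"), "exactly 2")
  expect_error(group_compare(v, rep("a", 40)), "at least 2 groups")
})
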