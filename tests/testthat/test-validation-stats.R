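test_that("root-sum-square error combination is exact", {
  expect_equal(combine_errors(c(3, 4)), 5)
  expect_equal(combine_errors(7), 7)
  expect_equal(combine_errors(numeric(0)), 0)
  # permutation invariance and first-degree homogeneity
  set.seed(2)
  comps <- runif(6, 0, 10)
  expect_equal(combine_errors(comps), combine_errors(rev(comps)))
  expect_equal(combine_errors(3.7 * comps), 3.7 * combine_errors(comps))
  expect_gte(combine_errors(comps), max(comps))
  expect_error(combine_errors(c(3, -1)), "non-negative")
})

test_that("reproducibility variation is a percent deviation from the mean", {
  expect_equal(reproducibility_variation(c(100, 100, 100)), 0)
  expect_equal(reproducibility_variation(c(90, 110)), 10)
  # averaged over subjects
  expect_equal(reproducibility_variation(list(c(90, 110), c(100, 100))), 5)
  # invariant to units scaling
  reps <- list(c(95, 103, 108, 99, 101, 97, 104), c(88, 112, 100, 95, 105, 99, 101))
  expect_equal(reproducibility_variation(reps),
               reproducibility_variation(lapply(reps, `*`, 1e3)))
  expect_error(reproducibility_variation(list(c(100))), "2 repeats")
})

test_that("agreement on identical and mirrored series is exact", {
  a <- c(100, 120, 90, 105, 130)
  rep_id <- agreement_analysis(a, a)
  expect_equal(rep_id$pearson_r, 1)
  expect_equal(rep_id$ba_mean_diff, 0)
  expect_equal(rep_id$ba_sd_diff, 0)
  expect_equal(rep_id$ba_limits, c(0, 0))
  rep_neg <- agreement_analysis(a, -a)
  expect_equal(rep_neg$pearson_r, -1)
  expect_error(agreement_analysis(a, rep(5, 5)), "zero variance")
  expect_error(agreement_analysis(a, a[1:3]), "paired")
})

test_that("agreement statistics match textbook formula oracles", {
  set.seed(31)
  n <- 60
  a <- rnorm(n, 100, 15)
  b <- 0.8 * a + rnorm(n, 20, 10)
  rep_ <- agreement_analysis(a, b)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t_r <- r * sqrt((n - 2) / (1 - r^2))
  p_r <- 2 * pt(-abs(t_r), n - 2)
  d <- a - b
  t_d <- mean(d) / (sd(d) / sqrt(n))
  p_d <- 2 * pt(-abs(t_d), n - 1)
  expect_equal(rep_$pearson_r, r, tolerance = 1e-10)
  expect_equal(rep_$p_value, p_r, tolerance = 1e-10)
  expect_equal(rep_$paired_t_p, p_d, tolerance = 1e-10)
  expect_equal(rep_$ba_mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(rep_$ba_sd_diff, sd(d), tolerance = 1e-12)
  expect_equal(rep_$ba_limits, mean(d) + c(-2, 2) * sd(d), tolerance = 1e-12)
  # limits symmetric about the mean difference
  expect_equal(mean(rep_$ba_limits), rep_$ba_mean_diff)
  # sign convention flips the difference
  rep_flip <- agreement_analysis(a, b, diff_sign = "b_minus_a")
  expect_equal(rep_flip$ba_mean_diff, -rep_$ba_mean_diff)
})

test_that("r is invariant under positive affine transforms", {
  set.seed(32)
  a <- rnorm(40, 50, 5); b <- rnorm(40, 60, 8)
  r0 <- agreement_analysis(a, b)$pearson_r
  expect_equal(agreement_analysis(2.5 * a + 7, b)$pearson_r, r0, tolerance = 1e-12)
  expect_equal(agreement_analysis(a, 0.3 * b - 2)$pearson_r, r0, tolerance = 1e-12)
})

test_that("Bland-Altman limits cover about 95% of normal differences", {
  set.seed(33)
  n <- 10000
  a <- rnorm(n, 100, 10)
  b <- a + rnorm(n, 2, 8)
  rep_ <- agreement_analysis(a, b)
  d <- a - b
  cover <- mean(d >= rep_$ba_limits[1] & d <= rep_$ba_limits[2])
  expect_lt(abs(cover - 0.95), 0.02)
})

test_that("normality screen separates normal from uniform samples", {
  set.seed(34)
  ok <- normality_screen(rnorm(500))
  expect_gt(ok$p_value, 0.05)
  bad <- normality_screen(runif(500))
  expect_lt(bad$p_value, 0.05)
  expect_error(normality_screen(rep(3, 10)), "identical")
  expect_error(normality_screen(c(1, 2, 3)), "at least 5")
})
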