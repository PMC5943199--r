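test_that("constant input with linear tissue gives the exact closed form", {
  sch <- default_frame_schema()
  t <- frame_midpoints(sch)
  cc <- 40; Ki <- 0.25; vb <- 0.3
  aif <- tac(sch, rep(cc, 85), "aorta")
  tissue <- tac(sch, Ki * cc * t + vb * cc, "kidney")
  pts <- patlak_transform(tissue, aif)
  expect_equal(pts$x, t, tolerance = 1e-12)
  expect_equal(pts$y, Ki * t + vb, tolerance = 1e-12)
  # full pipeline with a first-frame anchor
  anchor <- peak_descriptor(1, 1, tissue$values[1], t[1], t[1])
  win <- select_fit_window(pts, anchor)
  fit <- fit_patlak(pts, win)
  expect_equal(fit$K, Ki, tolerance = 1e-8)
  expect_equal(fit$intercept, vb, tolerance = 1e-8)
})

test_that("tissue identical to the input function gives y = 1", {
  aif <- simulate_aif()
  pts <- patlak_transform(aif, aif)
  expect_true(all(abs(pts$y - 1) < 1e-12))
})

test_that("frames below the input floor are excluded", {
  sch <- uniform_schema(10)
  cp <- c(0, 0.1, rep(50, 8))
  aif <- tac(sch, cp)
  pts <- patlak_transform(tac(sch, rep(10, 10)), aif, floor_frac = 0.01)
  expect_equal(pts$frame_index, 3:10)
  expect_error(patlak_transform(tac(sch, rep(1, 10)), tac(sch, rep(0, 10))),
               "identically zero")
  expect_error(patlak_transform(tac(uniform_schema(10), rep(1, 10)),
                                tac(uniform_schema(10, dt_s = 4), rep(1, 10))),
               "schema")
})

test_that("transform agrees with a fine-grid oracle on simulated kinetics", {
  aif <- simulate_aif()
  tr <- mid_truth()
  kid <- simulate_kidney_tac(aif, tr, noise_sd = 0)
  pts <- patlak_transform(kid, aif)
  fine <- attr(aif, "fine")
  dt <- fine$t[2] - fine$t[1]
  cum_fine <- cumsum((fine$c + c(0, fine$c[-length(fine$c)])) / 2 * dt)
  m <- frame_midpoints(aif$schema)
  late <- pts$time_min > 0.5
  x_oracle <- vapply(pts$frame_index[late], function(i) {
    j <- which.min(abs(fine$t - m[i]))
    cum_fine[j] / fine$c[j]
  }, numeric(1))
  expect_lt(max(abs(pts$x[late] - x_oracle) / x_oracle), 0.01)
})

test_that("window selection follows the peak-anchored two-minute rule", {
  sch <- default_frame_schema()
  aif <- tac(sch, rep(30, 85))
  tissue <- tac(sch, 0.3 * frame_midpoints(sch) * 30 + 10)
  pts <- patlak_transform(tissue, aif)
  anchor <- peak_descriptor(2, 9, 1, frame_midpoints(sch)[2], frame_midpoints(sch)[9])
  win <- select_fit_window(pts, anchor)
  # frame 9 has midpoint 42.5 s; last midpoint at/below 2 min is frame 24
  expect_equal(pts$frame_index[win[1]], 9L)
  expect_equal(pts$frame_index[win[length(win)]], 24L)
  expect_length(win, 16)

  late_anchor <- peak_descriptor(30, 40, 1, 2.5, 3.3)
  expect_error(select_fit_window(pts, late_anchor), "at least 3")
  first_anchor <- peak_descriptor(1, 1, 1, 0, frame_midpoints(sch)[1])
  win_all <- select_fit_window(pts, first_anchor)
  expect_equal(pts$frame_index[win_all], 1:24)
})

test_that("OLS fit matches a normal-equations oracle", {
  sch <- default_frame_schema()
  aif <- tac(sch, rep(30, 85))
  set.seed(21)
  y_noise <- 0.3 * frame_midpoints(sch) + 0.5 + rnorm(85, 0, 0.05)
  tissue <- tac(sch, y_noise * 30)
  pts <- patlak_transform(tissue, aif)
  win <- select_fit_window(pts, peak_descriptor(1, 1, 1, 0, 0))
  fit <- fit_patlak(pts, win)
  x <- pts$x[win]; y <- pts$y[win]; n <- length(x)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (n - 2)
  se_slope <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(fit$K, beta[2], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$stderr_K, se_slope, tolerance = 1e-10)
})

test_that("a constant ordinate fits a zero slope", {
  sch <- uniform_schema(20)
  aif <- tac(sch, rep(10, 20))
  tissue <- tac(sch, rep(5, 20))
  pts <- patlak_transform(tissue, aif)
  fit <- fit_patlak(pts, 1:20)
  expect_equal(fit$K, 0, tolerance = 1e-12)
  expect_error(fit_patlak(pts, 1:2), "at least 3")
})

test_that("GFR combines slopes and volumes linearly", {
  v <- voi_volumes(150, 150)
  est <- compute_gfr(0.3, 0.3, v)
  expect_equal(est$gfr_total_ml_min, 90)
  expect_equal(est$gfr_total_ml_min, est$gfr_left_ml_min + est$gfr_right_ml_min)
  est2 <- compute_gfr(0, 0.4, voi_volumes(120, 180))
  expect_equal(est2$gfr_total_ml_min, 0.4 * 180)
  expect_warning(compute_gfr(-0.1, 0.3, v), "negative")
  expect_error(voi_volumes(-5, 100), "positive")
  expect_warning(voi_volumes(10, 100), "plausibility")
  # error propagation: K errors scale by volume and combine in quadrature
  est3 <- compute_gfr(0.3, 0.3, v, stderr_left = 0.02, stderr_right = 0.02)
  expect_equal(est3$error_ml_min, sqrt(2 * (0.02 * 150)^2))
})

test_that("simulated subject recovers ground-truth GFR within 10%", {
  aif_true <- simulate_aif()
  tr <- mid_truth(Ki = 0.2)
  left <- simulate_kidney_tac(aif_true, tr, noise_sd = 2, seed = 101)
  right <- simulate_kidney_tac(aif_true, tr, noise_sd = 2, seed = 102)
  aif <- add_frame_noise(aif_true, 2, seed = 103)
  res <- patlak_gfr(aif, left, right, voi_volumes(150, 150))
  expect_lt(abs(res$gfr$gfr_total_ml_min - 60) / 60, 0.10)
  expect_gt(res$fit_left$stderr_K, 0)
})
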