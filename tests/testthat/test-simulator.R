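test_that("cohort generation is seed-deterministic and leaves the RNG alone", {
  set.seed(999); before <- runif(1)
  set.seed(999)
  a <- simulate_cohort(3, seed = 42)
  mid <- runif(1)
  b <- simulate_cohort(3, seed = 42)
  expect_identical(a$truth, b$truth)
  expect_identical(a$subjects[[2]]$left_tac$values, b$subjects[[2]]$left_tac$values)
  expect_identical(a$subjects[[3]]$aif$values, b$subjects[[3]]$aif$values)
  # cohort simulation must not disturb the caller's RNG stream
  expect_identical(before, mid)
})

test_that("simulated AIF has the expected peak and tail behaviour", {
  aif <- simulate_aif()
  expect_equal(max(aif$values), 157.8)
  pk <- detect_peak(aif)
  expect_lt(pk$max_time, 1)  # maximum within the first minute
  # no recirculation tail: the curve decays to (near) zero
  bare <- simulate_aif(tail_fraction = 0)
  expect_lt(bare$values[85], 1e-4 * max(bare$values))
  # with a tail the late curve stays clearly above the no-tail case
  expect_gt(aif$values[85], 1e-3 * max(aif$values))
  expect_gt(aif$values[85], 100 * bare$values[85])
})

test_that("identity and closed-form limits of the kidney model", {
  # Ki = 0, vb = 1, effectively instantaneous transit -> kidney equals AIF
  aif <- simulate_aif()
  tr <- kinetic_truth(0, 1, flow_scale = 1e7)
  kid <- simulate_kidney_tac(aif, tr, noise_sd = 0)
  expect_equal(kid$values, aif$values, tolerance = 1e-9)
  # constant AIF, vb = 0 -> pure linear accumulation Ki * c * t
  sch <- default_frame_schema()
  caif <- tac(sch, rep(30, 85), "aorta")
  tr2 <- kinetic_truth(0.4, 0)
  kid2 <- simulate_kidney_tac(caif, tr2, noise_sd = 0)
  expect_equal(kid2$values, 0.4 * 30 * frame_midpoints(sch), tolerance = 1e-6)
})

test_that("kidney curve matches an independent ODE oracle within 1%", {
  skip_if_not_installed("deSolve")
  aif <- simulate_aif()
  tr <- mid_truth()
  kid <- simulate_kidney_tac(aif, tr, noise_sd = 0)
  fine <- attr(aif, "fine")
  dt <- fine$t[2] - fine$t[1]
  kker <- renalpet:::gamma_kernel(0.15, 45 / tr$flow_scale, dt)
  cps <- renalpet:::conv_causal(fine$c, kker)
  cp_f <- approxfun(fine$t, fine$c, rule = 2)
  cps_f <- approxfun(fine$t, cps, rule = 2)
  lag <- tr$drain_delay_min
  deriv <- function(t, y, parms) {
    cp_lag <- if (t > lag) cp_f(t - lag) else 0
    influx <- tr$Ki * cp_f(t) + tr$drain_frac * tr$Ki * cp_lag
    loss <- if (t > tr$trap_min) tr$loss_rate else 0
    list(c(influx - loss * y[1],
           tr$k_ex * (cps_f(t) - y[2])))
  }
  sol <- deSolve::ode(c(A = 0, Ce = 0), times = fine$t, func = deriv,
                      parms = NULL, method = "lsoda")
  ck_oracle <- tr$vb * cps + tr$ve * sol[, "Ce"] + sol[, "A"]
  oracle_frames <- renalpet:::frame_average(fine$t, ck_oracle, aif$schema)
  late <- frame_midpoints(aif$schema) > 0.5
  expect_lt(max(abs(kid$values[late] - oracle_frames[late]) /
                  oracle_frames[late]), 0.01)
})

test_that("pure trapping is non-decreasing once the flush has settled", {
  aif <- simulate_aif()
  tr <- mid_truth()
  tr$loss_rate <- 0; tr$drain_frac <- 0
  kid <- simulate_kidney_tac(aif, tr, noise_sd = 0)
  m <- frame_midpoints(kid$schema)
  expect_true(all(diff(kid$values[m > 2.5]) > -1e-9))
})

test_that("downstream loss produces a hump then decline between 3 and 5 min", {
  aif <- simulate_aif()
  kid <- simulate_kidney_tac(aif, mid_truth(), noise_sd = 0)
  m <- frame_midpoints(kid$schema)
  late <- which(m > 2.5)
  hump <- late[which.max(kid$values[late])]
  expect_gte(m[hump], 2.5)
  expect_lte(m[hump], 5.5)
  # the hump is a genuine local maximum: the curve declines afterwards
  expect_lt(kid$values[85], kid$values[hump])
  # and the flush peak still dominates the first five minutes
  pk <- detect_peak(smooth_bezier(kid))
  expect_lt(pk$max_time, 2)
})

test_that("noise scales with frame duration and clips at zero", {
  sch <- default_frame_schema()
  x <- tac(sch, rep(50, 85))
  set.seed(77)
  reps <- replicate(300, add_frame_noise(x, 4)$values)
  sd_short <- sd(reps[10, ])   # 5-s frame
  sd_long <- sd(reps[80, ])    # 60-s frame
  expect_equal(sd_short, 4, tolerance = 0.2)
  expect_equal(sd_long, 4 * sqrt(5 / 60), tolerance = 0.2)
  y <- tac(sch, rep(0.01, 85))
  expect_true(all(add_frame_noise(y, 4, seed = 1)$values >= 0))
})

test_that("default cohort spans the expected healthy GFR range", {
  co <- simulate_cohort(24, seed = 3)
  expect_equal(nrow(co$truth), 24)
  expect_true(all(co$truth$gfr_truth > 70))
  expect_true(all(co$truth$gfr_truth < 200))
  expect_lt(min(co$truth$gfr_truth), 100)
  expect_gt(max(co$truth$gfr_truth), 140)
  # degenerate ranges give identical parameters, noise seeds aside
  cod <- simulate_cohort(4, seed = 9,
                         ranges = list(ki = c(0.4, 0.4), vb = c(0.4, 0.4)))
  expect_equal(var(cod$truth$Ki), 0)
  expect_equal(var(cod$truth$vb), 0)
})
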