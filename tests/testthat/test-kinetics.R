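test_that("dilution series divides down to the floor inclusively", {
  s <- dilution_series(400, 1.6, 23.8)
  expect_equal(length(s), 7L)
  expect_equal(s, 400 / 1.6^(0:6), tolerance = 1e-12)
  expect_equal(dilution_series(400, 1.6, 400), 400)
  expect_error(dilution_series(400, 1.0, 23.8), "factor")
  expect_error(dilution_series(-1, 1.6, 23.8))
})

test_that("initial rates recover exact linear declines and clamp rises", {
  t <- seq(0, 600, 20)
  # exact decline of 1 uM/s in concentration units, mapped to absorbance
  eps <- 12300
  conc <- 400 - 1.0 * t
  cv <- progress_curve(t[conc > 0], conc[conc > 0] * 1e-6 * eps, 400, 0.01)
  r <- initial_rate(cv, epsilon292 = eps)
  expect_equal(r$rate, 1.0, tolerance = 1e-9)
  expect_equal(r$specific_activity, 100, tolerance = 1e-6)
  # constant absorbance -> zero rate
  flat <- progress_curve(t, rep(1.0, length(t)), 400, 0.01)
  expect_equal(initial_rate(flat)$rate, 0)
  # rising absorbance -> warning + clamp
  rise <- progress_curve(t, 1 + 1e-4 * t, 400, 0.01)
  expect_warning(r2 <- initial_rate(rise), "clamped")
  expect_equal(r2$rate, 0)
})

test_that("short-time rates from the depletion law match v = kcat e0 s/(km+s)", {
  kcat <- 6.08; km <- 109.7; e0 <- 1e-3
  for (s0 in c(400, 61.04, 23.84)) {
    cv <- make_progress_curves(kcat, km, e0, s0)[[1]]
    v_true <- kcat * e0 * s0 / (km + s0)
    expect_equal(initial_rate(cv)$rate, v_true, tolerance = 0.01)
  }
})

test_that("Michaelis-Menten fits recover noise-free parameters", {
  kcat <- 6.08; km <- 109.7; e0 <- 1e-3
  s0 <- dilution_series(400, 1.6, 23.8)
  curves <- make_progress_curves(kcat, km, e0, s0)
  rates <- vapply(curves, function(cv) initial_rate(cv)$rate, numeric(1))
  fit <- mm_fit(rates, s0, e0)
  expect_true(fit$converged)
  expect_equal(fit$kcat, kcat, tolerance = 1e-3)
  expect_equal(fit$km, km, tolerance = 5e-3)
})

test_that("fits agree with the brute-force grid oracle to 3 significant figures", {
  e0 <- 0.05
  s <- dilution_series(400, 1.6, 23.8)
  v <- 1.0 * e0 * s / (50 + s)
  fit <- mm_fit(v, s, e0)
  grid <- oracle_mm_grid(v, s, e0)
  expect_equal(fit$kcat, unname(grid["kcat"]), tolerance = 5e-3)
  expect_equal(fit$km, unname(grid["km"]), tolerance = 5e-3)
})

test_that("in the saturating regime kcat*e0 equals the plateau rate", {
  e0 <- 0.01; kcat <- 4; km <- 2
  s <- c(200, 400, 800, 1600, 3200)   # all >> km
  v <- kcat * e0 * s / (km + s)
  fit <- mm_fit(v, s, e0)
  expect_equal(fit$kcat * e0, max(v), tolerance = 2e-3)
})

test_that("kcat is invariant to jointly rescaling e0 and the rates", {
  s <- dilution_series(400, 1.6, 23.8)
  e0 <- 0.03
  v <- 6.08 * e0 * s / (109.7 + s)
  f1 <- mm_fit(v, s, e0)
  f2 <- mm_fit(10 * v, s, 10 * e0)
  expect_equal(f1$kcat, f2$kcat, tolerance = 1e-9)
  expect_equal(f1$km, f2$km, tolerance = 1e-9)
})

test_that("noisy-rate recovery stays within the estimator's sampling error", {
  # 5% multiplicative Gaussian noise on the seven rates propagates to a
  # median absolute kcat error of 3-4% for this design (measured across
  # seeds); assert the recovery stays inside that sampling band
  s <- dilution_series(400, 1.6, 23.8)
  e0 <- 0.03
  v_true <- 6.08 * e0 * s / (109.7 + s)
  set.seed(42)
  errs <- replicate(100, {
    v <- v_true * (1 + rnorm(length(s), 0, 0.05))
    abs(mm_fit(v, s, e0)$kcat - 6.08) / 6.08
  })
  expect_lt(median(errs), 0.05)
})

test_that("quench-mode slopes reproduce collinear rates and reject 1 point", {
  tq <- c(0, 1, 2, 4, 6)
  eps <- 12300
  conc <- 100 - 2 * tq            # uM, 2 uM/min
  a <- cbind(conc * 1e-6 * eps, (50 - 0.5 * tq) * 1e-6 * eps)
  r <- quench_rates(tq, a, epsilon292 = eps)
  expect_equal(unname(r), c(2, 0.5), tolerance = 1e-9)
  expect_error(quench_rates(0, a[1, , drop = FALSE]), "3 quenched")
})

test_that("quench-mode data from the depletion generator refit within 2%", {
  kcat <- 3.2; km <- 80; e0 <- 1e-3
  s0 <- dilution_series(400, 1.6, 23.8)
  curves <- make_progress_curves(kcat, km, e0, s0, dt = 60, duration = 360)
  tq_min <- curves[[1]]$times / 60
  a <- vapply(curves, function(cv) cv$a292, numeric(length(tq_min)))
  r_min <- quench_rates(tq_min, a)         # uM/min
  fit <- mm_fit(r_min / 60, s0, e0)        # back to uM/s
  expect_equal(fit$kcat, kcat, tolerance = 0.02)
  expect_equal(fit$km, km, tolerance = 0.02)
})
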