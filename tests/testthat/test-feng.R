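test_that("feng_eval is zero up to onset and continuous at tau", {
  p <- pop_params()
  expect_identical(feng_eval(p, p$tau), 0)
  expect_identical(feng_eval(p, 0), 0)
  eps <- 1e-9
  expect_lt(abs(feng_eval(p, p$tau + eps)), 1e-6)
  # property: continuity at onset across a box of valid parameter draws
  set.seed(11)
  for (i in 1:20) {
    q <- feng_params(tau = runif(1, 0, 2), A1 = runif(1, 1, 30),
                     A2 = runif(1, 0, 0.1), A3 = runif(1, 0, 0.1),
                     lam1 = runif(1, 5, 50), lam2 = runif(1, 0.05, 1),
                     lam3 = runif(1, 0.001, 0.04))
    expect_identical(feng_eval(q, q$tau), 0)
    expect_lt(abs(feng_eval(q, q$tau + 1e-8)), 1e-5)
  }
})

test_that("pure gamma-variate peaks at 1/lam1 with value A1/(e lam1)", {
  p <- feng_params(tau = 0, A1 = 1, A2 = 0, A3 = 0, lam1 = 1,
                   lam2 = 0.5, lam3 = 0.25)
  expect_equal(feng_eval(p, 1), exp(-1), tolerance = 1e-12)
  # canonical parameters: grid-searched peak matches the first-order closed
  # form 1/lam1 + (A2+A3)/A1 (the exponential amplitudes nudge the peak a
  # few percent past the pure gamma-variate location 1/lam1)
  pp <- pop_params()
  tg <- seq(pp$tau, pp$tau + 0.5, by = 1e-5)
  t_peak <- tg[which.max(feng_eval(pp, tg))] - pp$tau
  expect_equal(t_peak, 1 / pp$lam1 + (pp$A2 + pp$A3) / pp$A1,
               tolerance = 0.01)
  expect_equal(t_peak, 1 / pp$lam1, tolerance = 0.06)
})

test_that("parameter validation names the violated constraint", {
  expect_error(feng_params(0, 1, 0, 0, 1, 2, 0.5), "lam1 > lam2")
  expect_error(feng_params(0, 1, 0, 0, 3, 0.2, 0.5), "lam2 > lam3")
  expect_error(feng_params(0, 1, 0, 0, 3, 0.2, -0.1), "lam3 > 0")
  expect_error(feng_params(0, -1, 0, 0, 3, 0.2, 0.1), "A1 > 0")
  expect_error(feng_params(-0.5, 1, 0, 0, 3, 0.2, 0.1), "tau >= 0")
  expect_error(feng_params(0, 1, -0.1, 0, 3, 0.2, 0.1), "A2 >= 0")
})

test_that("feng_auc matches closed forms and a fine trapezoid oracle", {
  # int_0^inf t e^-t dt = 1
  p <- feng_params(0, 1, 0, 0, 1, 0.5, 0.25)
  expect_equal(feng_auc(p, 0, 200), 1, tolerance = 1e-10)
  expect_error(feng_auc(p, 5, 5), "t0 < t1")
  expect_error(feng_auc(p, 7, 5), "t0 < t1")
  pp <- pop_params()
  tg <- seq(0, 65, by = 0.001)
  expect_equal(feng_auc(pp, 0, 65), trapz(tg, feng_eval(pp, tg)),
               tolerance = 1e-3)
  # window not containing onset
  tg2 <- seq(35, 65, by = 0.001)
  expect_equal(feng_auc(pp, 35, 65), trapz(tg2, feng_eval(pp, tg2)),
               tolerance = 1e-6)
})

test_that("feng_auc is monotone nondecreasing in T and converges", {
  pp <- pop_params()
  Ts <- c(1, 2, 5, 10, 30, 65, 100, 500, 1000)
  aucs <- vapply(Ts, function(T) feng_auc(pp, 0, T), numeric(1))
  expect_true(all(diff(aucs) >= 0))
  expect_equal(aucs[length(aucs)], aucs[length(aucs) - 1],
               tolerance = 1e-2)
})

test_that("feng_fit recovers generating parameters from noiseless curves", {
  truth <- feng_params(tau = 0.7, A1 = 15, A2 = 0.02, A3 = 0.02,
                       lam1 = 18, lam2 = 0.2, lam3 = 0.01)
  fit <- feng_fit(curve_on_schedule(truth), seed = 3)
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-8)
  expect_equal(coef(fit), coef(truth), tolerance = 0.01)
  # parameter-recovery property across draws from the population box
  set.seed(5)
  for (i in 1:3) {
    f <- exp(rnorm(6, 0, 0.1))
    q <- feng_params(tau = runif(1, 0.4, 1.0), A1 = 15.9 * f[1],
                     A2 = 0.02 * f[2], A3 = 0.02 * f[3], lam1 = 17.8 * f[4],
                     lam2 = 0.18 * f[5], lam3 = 0.01 * f[6])
    fq <- feng_fit(curve_on_schedule(q), seed = i)
    expect_equal(coef(fq), coef(q), tolerance = 0.01)
  }
})

test_that("feng_fit is deterministic given the seed and rejects degenerate input", {
  crv <- curve_on_schedule(pop_params())
  f1 <- feng_fit(crv, seed = 9)
  f2 <- feng_fit(crv, seed = 9)
  expect_identical(coef(f1), coef(f2))
  zeros <- sampled_curve(c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9),
                         c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), rep(0, 10))
  expect_error(feng_fit(zeros, seed = 1), "degenerate|no positive peak")
  short <- sampled_curve(0:4, 1:5, c(0, 1, 2, 1, 0.5))
  expect_error(feng_fit(short, seed = 1), "at least 10 frames")
})

test_that("fit object methods behave like a model fit", {
  fit <- feng_fit(curve_on_schedule(pop_params()), seed = 2)
  expect_s3_class(fit, "feng_fit")
  expect_named(coef(fit), c("tau", "A1", "A2", "A3", "lam1", "lam2", "lam3"))
  expect_length(residuals(fit), 62)
  expect_equal(fitted(fit) + residuals(fit), fit$curve$value, tolerance = 1e-12)
  expect_equal(predict(fit, newtimes = 10), feng_eval(fit$params, 10))
  expect_output(print(fit), "Feng input-function fit")
  expect_output(print(summary(fit)), "per-start RSS")
})
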