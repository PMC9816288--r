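test_that("default schedule is the 62-frame 65-min protocol", {
  sch <- default_schedule()
  expect_identical(nrow(sch), 62L)
  expect_identical(sum(sch$duration), 3900)
  expect_identical(sch$duration[1:2], c(10, 10))
  # contiguous, non-overlapping and bit-stable
  expect_identical(sch$start, cumsum(c(0, sch$duration[-62])))
  expect_identical(default_schedule(), sch)
})

test_that("kinetic_params validates and implies the closed-form Ki", {
  kp <- kinetic_params(0.1, 0.25, 0.08, 0.05)
  expect_equal(ki_true(kp), 0.1 * 0.08 / (0.25 + 0.08))
  expect_identical(ki_true(kinetic_params(0.1, 0.2, 0)), 0)
  expect_error(kinetic_params(0, 0.2, 0.1), "K1 > 0")
  expect_error(kinetic_params(0.1, 0.2, 0.1, 1), "vB")
})

test_that("tissue forward model: blood-only voxel returns the input", {
  pp <- pop_params()
  sch <- default_schedule()
  # vB -> 1 limit approached numerically (vB = 1 itself is excluded)
  kp <- kinetic_params(1e-9, 0.2, 0.05, vB = 1 - 1e-12)
  tac <- simulate_tissue_tac(pp, kp, sch)
  expect_equal(tac$value, feng_eval(pp, schedule_mid_times_min(sch)),
               tolerance = 1e-6)
})

test_that("tissue forward model: k3 = 0 step-input steady state is K1/k2", {
  sch <- default_schedule()
  kp <- kinetic_params(0.1, 0.2, 0, vB = 0)
  tac <- simulate_tissue_tac(function(t) rep(1, length(t)), kp, sch)
  expect_equal(tac$value[62], 0.1 / 0.2, tolerance = 1e-3)
})

test_that("closed-form convolution agrees with the RK4 ODE oracle", {
  pp <- pop_params()
  sch <- default_schedule()
  kp <- kinetic_params(0.1, 0.25, 0.08, vB = 0.04)
  tac <- simulate_tissue_tac(pp, kp, sch)
  ode <- rk4_2tcm(pp, kp, t_end = 65, dt = 0.002)
  mids <- schedule_mid_times_min(sch)
  ct_ode <- approx(ode$t, ode$ct, xout = mids)$y
  cp_ode <- feng_eval(pp, mids)
  meas_ode <- (1 - kp$vB) * ct_ode + kp$vB * cp_ode
  late <- mids > 2
  expect_equal(tac$value[late], meas_ode[late], tolerance = 5e-3)
})

test_that("measured curve is a convex combination of tissue and plasma", {
  pp <- pop_params()
  sch <- default_schedule()
  mids <- schedule_mid_times_min(sch)
  cp <- feng_eval(pp, mids)
  ct0 <- simulate_tissue_tac(pp, kinetic_params(0.1, 0.25, 0.08, vB = 0), sch)$value
  for (vb in c(0.2, 0.5, 0.8)) {
    mixed <- simulate_tissue_tac(pp, kinetic_params(0.1, 0.25, 0.08, vB = vb), sch)$value
    expect_equal(mixed, (1 - vb) * ct0 + vb * cp, tolerance = 1e-10)
    expect_true(all(mixed >= pmin(ct0, cp) - 1e-12 &
                      mixed <= pmax(ct0, cp) + 1e-12))
  }
})

test_that("reversible-limit curve has vanishing Patlak slope at late t*", {
  pp <- pop_params()
  sch <- default_schedule()
  tac <- simulate_tissue_tac(pp, kinetic_params(0.1, 0.3, 0, vB = 0), sch)
  pts <- patlak_transform(tac, pp)
  slopes <- vapply(c(20, 35, 50), function(ts) patlak_fit(pts, ts)$Ki, numeric(1))
  expect_true(all(diff(abs(slopes)) < 0))
  expect_lt(abs(slopes[3]), 1e-5)
})

test_that("generate_population is deterministic and honours degenerate configs", {
  cfg <- population_config(cv = 0, noise_level = 0)
  p1 <- generate_population(3, cfg, seed = 10)
  p2 <- generate_population(3, cfg, seed = 10)
  expect_identical(p1, p2)
  # zero CV: only the delay differs between subjects
  c1 <- coef(p1[[1]]$true_aif); c2 <- coef(p1[[2]]$true_aif)
  expect_identical(c1[-1], c2[-1])
  expect_false(c1[["tau"]] == c2[["tau"]])
})

test_that("drawn delays average to the range midpoint and fits recover them", {
  pop <- generate_population(16, noiseless_config(), seed = 2)
  taus <- vapply(pop, function(s) s$true_aif$tau, numeric(1))
  sem <- sqrt(diff(c(0.4, 1.0))^2 / 12 / 16)
  expect_lt(abs(mean(taus) - 0.7), 2 * sem)
})

test_that("full parameter-recovery loop on noiseless subjects", {
  pop <- small_population()
  for (su in pop) {
    fit <- feng_fit(su$idif, seed = su$seed)
    expect_equal(coef(fit), coef(su$true_aif), tolerance = 0.01)
  }
})

test_that("frame noise scales with sqrt(value/duration) and clips at zero", {
  cfg <- population_config(noise_level = 0.5)
  pop <- generate_population(1, cfg, seed = 33)
  expect_true(all(pop[[1]]$idif$value >= 0))
  # same seed, zero noise, values differ only by the noise term
  pop0 <- generate_population(1, population_config(noise_level = 0), seed = 33)
  expect_identical(coef(pop[[1]]$true_aif), coef(pop0[[1]]$true_aif))
  expect_false(all(pop[[1]]$idif$value == pop0[[1]]$idif$value))
})

test_that("phantom voxels carry their region TAC exactly when noiseless", {
  su <- small_population()[[1]]
  ph <- generate_phantom(su, dims = c(16, 16, 8))
  expect_identical(sort(unique(as.vector(ph$labels))), c(0L, 1L, 2L, 3L))
  counts <- table(ph$labels)
  for (k in seq_along(ph$label_names)) {
    vox <- which(ph$labels == k, arr.ind = TRUE)[1, ]
    tacv <- ph$volume[vox[1], vox[2], vox[3], ]
    expect_identical(as.numeric(tacv), as.numeric(ph$region_tacs[[k]]))
  }
  # histogram matches the voxel membership of the label map
  expect_identical(as.integer(counts[-1]),
                   vapply(1:3, function(k) sum(ph$labels == k), integer(1)))
  expect_error(generate_phantom(su, dims = c(2, 2, 2)), "dims")
})
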