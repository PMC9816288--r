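test_that("a single-subject PBIF reproduces that subject's normalized curve", {
  su <- small_population()[[1]]
  pb <- build_pbif(list(su$idif), seed = 3)
  expect_identical(pb$n_subjects, 1L)
  expect_equal(sampled_auc(pb$curve, 0, 65), 1, tolerance = 1e-6)
  nrm <- normalize_idif(su$idif, 65)
  mids <- frame_mid_times(nrm)
  # PBIF is the fitted model of the normalized curve, delay kept (mean of one)
  expect_equal(predict(pb, mids), nrm$value, tolerance = 0.02)
  expect_equal(pb$mean_delay, su$true_aif$tau, tolerance = 0.01)
})

test_that("averaging N identical IDIFs equals the single-subject PBIF", {
  su <- small_population()[[2]]
  pb1 <- build_pbif(list(su$idif), seed = 3)
  pb3 <- build_pbif(list(su$idif, su$idif, su$idif), seed = 3)
  expect_equal(pb3$curve$value, pb1$curve$value, tolerance = 1e-6)
  expect_equal(pb3$mean_delay, pb1$mean_delay, tolerance = 1e-6)
})

test_that("PBIF mean delay equals the mean of the fitted subject delays", {
  pop <- small_population()
  pb <- small_pbif()
  taus <- vapply(pop, function(s) s$true_aif$tau, numeric(1))
  expect_equal(pb$mean_delay, mean(taus), tolerance = 0.01)
  expect_equal(sampled_auc(pb$curve, 0, 65), 1, tolerance = 1e-6)
})

test_that("build_pbif is invariant to uniform rescaling of an input IDIF", {
  pop <- small_population()
  idifs <- lapply(pop, `[[`, "idif")
  idifs2 <- idifs
  idifs2[[1]] <- sampled_curve(idifs[[1]]$frame_start, idifs[[1]]$frame_end,
                               idifs[[1]]$value * 7.3)
  pb1 <- build_pbif(idifs, seed = 7)
  pb2 <- build_pbif(idifs2, seed = 7)
  # normalization removes amplitude; agreement is limited only by the
  # per-subject fit tolerance
  expect_equal(pb2$curve$value, pb1$curve$value, tolerance = 1e-5)
})

test_that("build_pbif reports which member fits failed", {
  pop <- small_population()
  idifs <- lapply(pop, `[[`, "idif")
  idifs[[2]] <- sampled_curve(idifs[[2]]$frame_start, idifs[[2]]$frame_end,
                              rep(0, length(idifs[[2]]$value)))
  expect_error(build_pbif(idifs, seed = 1), "subject 2")
  expect_error(build_pbif(list(), seed = 1), "nonempty")
})

test_that("tail-AUC scaling is exact for every canonical window", {
  su <- small_population()[[1]]
  pb <- small_pbif()
  for (w in list(c(35, 65), c(40, 65), c(45, 65), c(50, 65), c(55, 65))) {
    sp <- scale_pbif(pb, su$idif, w)
    expect_gt(sp$scale_factor, 0)
    expect_equal(sampled_auc(sp$curve_sched, w[1], w[2]),
                 sampled_auc(su$idif, w[1], w[2]), tolerance = 1e-9)
  }
})

test_that("scale factors respond linearly to the subject amplitude", {
  pb <- small_pbif()
  su <- small_population()[[3]]
  sp1 <- scale_pbif(pb, su$idif, c(55, 65))
  double <- sampled_curve(su$idif$frame_start, su$idif$frame_end,
                          su$idif$value * 2)
  sp2 <- scale_pbif(pb, double, c(55, 65))
  expect_equal(sp2$scale_factor, 2 * sp1$scale_factor, tolerance = 1e-12)
  # scaling the (unnormalized) PBIF curve itself back gives s = 1 up to
  # resampling error of the dense grid
  pbif_as_idif <- sampled_curve(pb$curve$frame_start, pb$curve$frame_end,
                                pb$curve$value, label = "self")
  sp_self <- scale_pbif(pb, pbif_as_idif, c(55, 65))
  expect_equal(sp_self$scale_factor, 1, tolerance = 1e-4)
  expect_error(scale_pbif(pb, su$idif, c(65, 55)), "ta < tb")
})

test_that("amplitude+delay-only populations are reproduced everywhere on the tail", {
  # members share one shape: the sPBIF should match each subject's AIF on
  # [ta, 65] within fit tolerance
  cfg <- population_config(cv = 0, noise_level = 0)
  pop <- generate_population(3, cfg, seed = 8)
  amp <- c(0.7, 1.0, 1.6)
  idifs <- lapply(seq_along(pop), function(i)
    sampled_curve(pop[[i]]$idif$frame_start, pop[[i]]$idif$frame_end,
                  pop[[i]]$idif$value * amp[i]))
  pb <- build_pbif(idifs, seed = 5)
  for (i in seq_along(pop)) {
    sp <- scale_pbif(pb, idifs[[i]], c(35, 65))
    mids <- frame_mid_times(idifs[[i]])
    late <- mids >= 35
    expect_equal(sp$curve_sched$value[late], idifs[[i]]$value[late],
                 tolerance = 0.01)
  }
})

test_that("PBIF and sPBIF serialize to JSON and back", {
  pb <- small_pbif()
  su <- small_population()[[1]]
  path <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_pbif(pb, path, curve_csv = csv)
  back <- read_pbif(path, curve_csv = csv)
  expect_equal(coef(back$params), coef(pb$params), tolerance = 1e-12)
  expect_equal(back$mean_delay, pb$mean_delay, tolerance = 1e-12)
  expect_equal(back$curve$value, pb$curve$value, tolerance = 1e-12)
  sp <- scale_pbif(pb, su$idif, c(45, 65))
  write_pbif(sp, path)
  back2 <- read_pbif(path)
  expect_s3_class(back2, "spbif")
  expect_equal(back2$scale_factor, sp$scale_factor, tolerance = 1e-12)
  expect_equal(coef(back2$params), coef(sp$params), tolerance = 1e-12)
  expect_identical(back2$label, sp$label)
})
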