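test_that("voxel-wise Patlak recovers each region's closed-form Ki on a noiseless phantom", {
  su <- small_population()[[1]]
  ph <- generate_phantom(su, dims = c(16, 16, 8))
  img <- voxelwise_patlak(ph, su$true_aif, t_star = 45)
  expect_identical(dim(img$ki_map), c(16L, 16L, 8L))
  expect_identical(img$n_failed, 0L)
  expect_true(all(is.nan(img$ki_map[!img$mask])))
  for (k in seq_along(ph$label_names)) {
    role <- ph$region_roles[k]
    if (role == "blood") next   # blood pool has no net influx model
    vox_ki <- img$ki_map[ph$labels == k]
    roi <- su$roi_tacs[[role]]
    # measured curve mixes in fractional blood volume, so the Patlak slope
    # of the measured TAC is exactly (1 - vB) Ki
    truth <- (1 - roi$kinetics$vB) * roi$ki_true
    expect_equal(unname(vox_ki), rep(truth, length(vox_ki)), tolerance = 0.02)
  }
})

test_that("a one-voxel mask reproduces the ROI-level fit exactly", {
  su <- small_population()[[1]]
  ph <- generate_phantom(su, dims = c(12, 12, 6))
  vox <- which(ph$labels == 2L, arr.ind = TRUE)[1, ]
  mask <- array(FALSE, dim(ph$labels)); mask[vox[1], vox[2], vox[3]] <- TRUE
  img <- voxelwise_patlak(ph, su$true_aif, t_star = 45, mask = mask)
  tac <- sampled_curve(ph$schedule$start / 60,
                       (ph$schedule$start + ph$schedule$duration) / 60,
                       ph$volume[vox[1], vox[2], vox[3], ])
  roi <- patlak_fit(patlak_transform(tac, su$true_aif), 45)
  expect_equal(img$ki_map[vox[1], vox[2], vox[3]], roi$Ki, tolerance = 1e-12)
  expect_equal(img$v_map[vox[1], vox[2], vox[3]], roi$V, tolerance = 1e-12)
})

test_that("voxel-wise fits agree with per-voxel ROI fits across a region", {
  su <- small_population()[[2]]
  ph <- generate_phantom(su, dims = c(12, 12, 6), noise_level = 0.3, seed = 4)
  img <- voxelwise_patlak(ph, su$true_aif, t_star = 40)
  sel <- which(ph$labels > 0L, arr.ind = TRUE)
  sel <- sel[seq_len(min(50, nrow(sel))), , drop = FALSE]
  for (r in seq_len(nrow(sel))) {
    v <- sel[r, ]
    tac <- sampled_curve(ph$schedule$start / 60,
                         (ph$schedule$start + ph$schedule$duration) / 60,
                         ph$volume[v[1], v[2], v[3], ])
    roi <- patlak_fit(patlak_transform(tac, su$true_aif), 40)
    expect_equal(img$ki_map[v[1], v[2], v[3]], roi$Ki, tolerance = 1e-10)
  }
})

test_that("voxelwise_patlak validates timing and shapes", {
  su <- small_population()[[1]]
  ph <- generate_phantom(su, dims = c(8, 8, 4))
  short <- frame_schedule(ph$schedule$start[1:10], ph$schedule$duration[1:10])
  expect_error(voxelwise_patlak(ph$volume, su$true_aif, 45, schedule = short),
               "frame count mismatch")
  expect_error(voxelwise_patlak(ph$volume, su$true_aif, 45,
                                schedule = ph$schedule,
                                mask = array(TRUE, c(2, 2, 2))),
               "mask shape")
  expect_error(voxelwise_patlak(ph, su$true_aif, t_star = 64.9), "fewer than 2")
})

test_that("identical maps give SSIM 1 and infinite PSNR; offsets follow the closed form", {
  su <- small_population()[[1]]
  ph <- generate_phantom(su, dims = c(12, 12, 6))
  img <- voxelwise_patlak(ph, su$true_aif, t_star = 35)
  m <- image_metrics(img, img)
  expect_equal(m$ssim, 1, tolerance = 1e-12)
  expect_identical(m$psnr, Inf)
  expect_identical(m$mean_rc, 0)
  expect_identical(m$mean_abs_rc, 0)
  # constant relative scaling: RC exactly 1% everywhere, SD 0
  img2 <- img; img2$ki_map <- img$ki_map * 1.01
  m2 <- image_metrics(img2, img)
  expect_equal(m2$mean_rc, 1, tolerance = 1e-9)
  expect_equal(m2$sd_rc, 0, tolerance = 1e-9)
  # constant offset c = range/100 within the mask: PSNR = 10 log10(1e4)
  rv <- img$ki_map[img$mask]
  R <- max(rv)                     # background Ki ~ 0 inside mask floor
  img3 <- img; img3$ki_map[img$mask] <- rv + R / 100
  m3 <- image_metrics(img3, img)
  expect_equal(m3$psnr, 40, tolerance = 0.01)
})

test_that("SSIM is symmetric and metrics are affine-invariant with recomputed range", {
  set.seed(9)
  a <- array(runif(14 * 12 * 10), c(14, 12, 10))
  b <- a + array(rnorm(length(a), 0, 0.03), dim(a))
  dr <- max(a) - min(a)
  expect_equal(ssim3d(a, b, dr), ssim3d(b, a, dr), tolerance = 1e-12)
  expect_true(abs(ssim3d(a, b, dr)) <= 1)
  # same positive rescaling applied to both images, range recomputed:
  # SSIM and PSNR are exactly invariant
  m1 <- image_metrics(b, a)
  m2 <- image_metrics(5 * b, 5 * a)
  expect_equal(m2$ssim, m1$ssim, tolerance = 1e-10)
  expect_equal(m2$psnr, m1$psnr, tolerance = 1e-10)
  expect_equal(m2$mean_rc, m1$mean_rc, tolerance = 1e-10)
  expect_error(image_metrics(b, a, mask = array(FALSE, dim(a))), "empty mask")
})

test_that("image metrics serialize with infinity encoded as 'inf'", {
  su <- small_population()[[1]]
  ph <- generate_phantom(su, dims = c(8, 8, 4))
  img <- voxelwise_patlak(ph, su$true_aif, t_star = 35)
  m <- image_metrics(img, img)
  path <- withr::local_tempfile(fileext = ".json")
  write_image_metrics(m, path)
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(d$psnr, "inf")
  expect_equal(d$ssim, 1)
})
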