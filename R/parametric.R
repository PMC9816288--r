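#' Voxel-wise Patlak parametric maps
#'
#' Applies the Patlak linearization per masked voxel of a 4D dynamic volume
#' (indirect, image-space parametric imaging). The per-voxel ordinary
#' least-squares slope/intercept are computed vectorized across voxels;
#' voxels where the fit is degenerate are set to NaN and counted.
#'
#' @param volume a \code{"phantom"} object, or a 4D array (x, y, z, frame).
#' @param input_fn input function (\code{feng_params}, \code{spbif},
#'   \code{pbif}, or \code{sampled_curve} on the schedule).
#' @param t_star Patlak start time, minutes.
#' @param schedule \code{\link{frame_schedule}}; taken from the phantom when
#'   \code{volume} is one.
#' @param mask 3D logical array; default: non-background labels for a
#'   phantom, all voxels otherwise.
#' @return An object of class \code{"parametric_image"}: \code{ki_map},
#'   \code{v_map} (NaN outside mask), \code{mask}, \code{t_star},
#'   \code{input_label}, \code{n_failed}.
#' @export
voxelwise_patlak <- function(volume, input_fn, t_star, schedule = NULL,
                             mask = NULL) {
  if (inherits(volume, "phantom")) {
    if (is.null(schedule)) schedule <- volume$schedule
    if (is.null(mask)) mask <- volume$labels > 0L
    volume <- volume$volume
  }
  if (is.null(schedule))
    stop("voxelwise_patlak: schedule required for a raw 4D array", call. = FALSE)
  d <- dim(volume)
  if (length(d) != 4L)
    stop("voxelwise_patlak: volume must be 4D (x, y, z, frame)", call. = FALSE)
  if (d[4] != nrow(schedule))
    stop("voxelwise_patlak: frame count mismatch: volume has ", d[4],
         " frames, schedule ", nrow(schedule), call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3]))
    stop("voxelwise_patlak: mask shape mismatch", call. = FALSE)
  mids <- schedule_mid_times_min(schedule)
  ser <- .input_series(input_fn, mids)
  use <- is.finite(ser$cp) & ser$cp > 0 & mids >= t_star
  if (sum(use) < 2L)
    stop("voxelwise_patlak: fewer than 2 usable frames after t* = ", t_star,
         call. = FALSE)
  x <- ser$intcp[use] / ser$cp[use]
  nvox <- prod(d[1:3])
  flat <- matrix(volume, nrow = nvox, ncol = d[4])
  sel <- which(as.vector(mask))
  Y <- flat[sel, use, drop = FALSE] / rep(ser$cp[use], each = length(sel))
  n <- length(x)
  mx <- mean(x)
  sxx <- sum((x - mx)^2)
  my <- rowMeans(Y)
  ki <- as.vector((Y - my) %*% (x - mx)) / sxx
  v <- my - ki * mx
  bad <- !is.finite(ki) | !is.finite(v)
  ki[bad] <- NaN; v[bad] <- NaN
  ki_map <- array(NaN, d[1:3]); v_map <- array(NaN, d[1:3])
  ki_map[sel] <- ki; v_map[sel] <- v
  structure(list(ki_map = ki_map, v_map = v_map, mask = mask,
                 t_star = t_star, input_label = ser$label,
                 n_failed = sum(bad)),
            class = "parametric_image")
}

#' @export
print.parametric_image <- function(x, ...) {
  d <- dim(x$ki_map)
  cat(sprintf("parametric_image %dx%dx%d (input %s, t* = %g min): %d masked voxels, %d failed\n",
              d[1], d[2], d[3], x$input_label, x$t_star, sum(x$mask), x$n_failed))
  cat(sprintf("  Ki range in mask: %.4g - %.4g ml/g/min\n",
              min(x$ki_map[x$mask], na.rm = TRUE),
              max(x$ki_map[x$mask], na.rm = TRUE)))
  invisible(x)
}

# separable 3D box sum with edge truncation (windows shrink at borders)
.boxsum1d <- function(v, h) {
  cs <- cumsum(c(0, v))
  n <- length(v)
  i <- seq_len(n)
  cs[pmin(i + h, n) + 1L] - cs[pmax(i - h, 1L) - 1L + 1L]
}
.box3d <- function(a, k) {
  h <- (k - 1L) %/% 2L
  d <- dim(a)
  a <- apply(a, c(2, 3), .boxsum1d, h = h)
  dim(a) <- d
  a <- aperm(apply(a, c(1, 3), .boxsum1d, h = h), c(2, 1, 3))
  dim(a) <- d
  a <- aperm(apply(a, c(1, 2), .boxsum1d, h = h), c(2, 3, 1))
  dim(a) <- d
  a
}

#' Structural similarity between two 3D images
#'
#' Mean SSIM with a uniform cubic window (default 7x7x7), standard
#' stabilization constants K1 = 0.01, K2 = 0.03 and sample-normalized local
#' (co)variances. Symmetric in its two image arguments for a fixed
#' \code{data_range}.
#'
#' @param a,b 3D arrays of identical shape.
#' @param data_range dynamic range L entering the constants
#'   \code{C1 = (K1 L)^2}, \code{C2 = (K2 L)^2}.
#' @param window odd window edge length (default 7).
#' @param mask optional 3D logical array; the SSIM map is averaged over the
#'   masked voxels (default: all).
#' @return Mean SSIM (scalar in [-1, 1]).
#' @export
ssim3d <- function(a, b, data_range, window = 7L, mask = NULL) {
  if (!identical(dim(a), dim(b)))
    stop("ssim3d: shape mismatch", call. = FALSE)
  if (window %% 2L != 1L) stop("ssim3d: window must be odd", call. = FALSE)
  if (!is.finite(data_range) || data_range <= 0)
    stop("ssim3d: data_range must be > 0", call. = FALSE)
  N <- .box3d(array(1, dim(a)), window)
  mu_a <- .box3d(a, window) / N
  mu_b <- .box3d(b, window) / N
  # sample-normalized second moments (n/(n-1) correction, as in the common
  # reference implementations)
  corr <- N / pmax(N - 1, 1)
  va <- (.box3d(a * a, window) / N - mu_a^2) * corr
  vb <- (.box3d(b * b, window) / N - mu_b^2) * corr
  cab <- (.box3d(a * b, window) / N - mu_a * mu_b) * corr
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  smap <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  if (is.null(mask)) mean(smap) else mean(smap[mask])
}

#' Image fidelity metrics between two parametric maps
#'
#' Voxel-wise percent relative change \code{RC = 100 (test - ref)/ref}
#' (mean and SD of RC and of |RC|, excluding voxels where |ref| is below
#' \code{rc_floor} times the masked maximum), mean SSIM
#' (\code{\link{ssim3d}} with data range = ref max - min within the mask)
#' and PSNR \code{= 10 log10(range^2 / MSE)} with range = ref max within the
#' mask. Identical images report \code{psnr = Inf}.
#'
#' @param test,ref \code{"parametric_image"} objects or 3D arrays.
#' @param mask 3D logical; default: intersection of the two image masks
#'   (arrays: all finite voxels).
#' @param rc_floor relative-change exclusion floor as a fraction of the
#'   masked max |ref| (default 0.01).
#' @param window SSIM window (default 7).
#' @return A list of class \code{"image_metrics"}: \code{mean_rc},
#'   \code{sd_rc}, \code{mean_abs_rc}, \code{sd_abs_rc} (percent),
#'   \code{ssim}, \code{psnr} (dB), plus bookkeeping \code{n_voxels},
#'   \code{n_rc_excluded}, \code{rc_floor}.
#' @export
image_metrics <- function(test, ref, mask = NULL, rc_floor = 0.01,
                          window = 7L) {
  get_map <- function(x) if (inherits(x, "parametric_image")) x$ki_map else x
  get_mask <- function(x) if (inherits(x, "parametric_image")) x$mask else NULL
  tm <- get_map(test); rm_ <- get_map(ref)
  if (!identical(dim(tm), dim(rm_)))
    stop("image_metrics: shape mismatch", call. = FALSE)
  if (is.null(mask)) {
    mask <- is.finite(tm) & is.finite(rm_)
    mt <- get_mask(test); mr <- get_mask(ref)
    if (!is.null(mt)) mask <- mask & mt
    if (!is.null(mr)) mask <- mask & mr
  }
  if (!any(mask)) stop("image_metrics: empty mask", call. = FALSE)
  tv <- tm[mask]; rv <- rm_[mask]
  floor_abs <- rc_floor * max(abs(rv))
  rc_ok <- abs(rv) >= floor_abs & floor_abs > 0
  if (!any(rc_ok))
    stop("image_metrics: no voxels above the relative-change floor", call. = FALSE)
  rc <- 100 * (tv[rc_ok] - rv[rc_ok]) / rv[rc_ok]
  rng <- max(rv) - min(rv)
  ssim <- if (rng > 0) {
    t0 <- tm; r0 <- rm_
    t0[!mask] <- 0; r0[!mask] <- 0
    ssim3d(t0, r0, data_range = rng, window = window, mask = mask)
  } else if (all(tv == rv)) 1 else NA_real_
  mse <- mean((tv - rv)^2)
  peak <- max(rv)
  psnr <- if (mse == 0) Inf else 10 * log10(peak^2 / mse)
  structure(list(mean_rc = mean(rc), sd_rc = stats::sd(rc),
                 mean_abs_rc = mean(abs(rc)), sd_abs_rc = stats::sd(abs(rc)),
                 ssim = ssim, psnr = psnr, n_voxels = sum(mask),
                 n_rc_excluded = sum(!rc_ok), rc_floor = rc_floor),
            class = "image_metrics")
}

#' @export
print.image_metrics <- function(x, ...) {
  cat(sprintf("image metrics over %d voxels (%d excluded from RC by floor %.3g):\n",
              x$n_voxels, x$n_rc_excluded, x$rc_floor))
  cat(sprintf("  RC %.3g +/- %.3g %%   |RC| %.3g +/- %.3g %%\n",
              x$mean_rc, x$sd_rc, x$mean_abs_rc, x$sd_abs_rc))
  cat(sprintf("  SSIM %.5f   PSNR %s dB\n", x$ssim,
              if (is.infinite(x$psnr)) "inf" else sprintf("%.2f", x$psnr)))
  invisible(x)
}

#' @rdname image_metrics
#' @param x an \code{"image_metrics"} object.
#' @param path JSON output path (\code{Inf} serialized as \code{"inf"}).
#' @export
write_image_metrics <- function(x, path) {
  out <- unclass(x)
  if (is.infinite(out$psnr)) out$psnr <- "inf"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
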