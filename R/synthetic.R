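#' Irreversible two-tissue-compartment microparameters
#'
#' Ground-truth kinetics for the simulator: plasma-to-tissue transport
#' \code{K1} (ml/g/min), efflux \code{k2} (1/min), phosphorylation \code{k3}
#' (1/min, irreversible: k4 = 0), and fractional blood volume \code{vB}.
#' The implied net influx rate (Patlak slope) is
#' \code{Ki = K1 * k3 / (k2 + k3)}.
#'
#' @param K1 ml/g/min, > 0.
#' @param k2 1/min, > 0.
#' @param k3 1/min, >= 0.
#' @param vB blood volume fraction in [0, 1).
#' @return An object of class \code{"kinetic_params"}.
#' @export
kinetic_params <- function(K1, k2, k3, vB = 0) {
  if (!is.finite(K1) || K1 <= 0) stop("kinetic_params: K1 > 0 required", call. = FALSE)
  if (!is.finite(k2) || k2 <= 0) stop("kinetic_params: k2 > 0 required", call. = FALSE)
  if (!is.finite(k3) || k3 < 0) stop("kinetic_params: k3 >= 0 required", call. = FALSE)
  if (!is.finite(vB) || vB < 0 || vB >= 1)
    stop("kinetic_params: vB in [0, 1) required", call. = FALSE)
  structure(list(K1 = K1, k2 = k2, k3 = k3, vB = vB), class = "kinetic_params")
}

#' @rdname kinetic_params
#' @param kp a \code{kinetic_params} object.
#' @export
ki_true <- function(kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (kp$k3 == 0) return(0)
  kp$K1 * kp$k3 / (kp$k2 + kp$k3)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("2TCM params: K1 = %.4g ml/g/min, k2 = %.4g, k3 = %.4g 1/min, vB = %.3g (Ki = %.4g)\n",
              x$K1, x$k2, x$k3, x$vB, ki_true(x)))
  invisible(x)
}

#' Dynamic PET frame schedule
#'
#' @param start frame start times, seconds.
#' @param duration frame durations, seconds.
#' @return An object of class \code{"frame_schedule"}: a data frame with
#'   columns \code{start} and \code{duration} (seconds).
#' @export
frame_schedule <- function(start, duration) {
  start <- as.numeric(start); duration <- as.numeric(duration)
  if (length(start) != length(duration) || length(start) == 0L)
    stop("frame_schedule: start/duration length mismatch", call. = FALSE)
  if (any(duration <= 0)) stop("frame_schedule: durations must be > 0", call. = FALSE)
  if (is.unsorted(start, strictly = TRUE))
    stop("frame_schedule: starts must be strictly increasing", call. = FALSE)
  if (length(start) > 1L &&
      any(abs(start[-1] - (start + duration)[-length(start)]) > 1e-9))
    stop("frame_schedule: frames must be contiguous", call. = FALSE)
  structure(data.frame(start = start, duration = duration),
            class = c("frame_schedule", "data.frame"))
}

#' The default 62-frame dynamic whole-body FDG schedule
#'
#' 2 x 10 s, 30 x 2 s, 4 x 10 s, 8 x 30 s, 4 x 60 s, 5 x 120 s and
#' 9 x 300 s: 62 contiguous frames covering 65 min. The two initial 10-s
#' frames absorb the delay between acquisition start and tracer injection.
#'
#' @return A \code{\link{frame_schedule}}.
#' @export
default_schedule <- function() {
  dur <- c(rep(10, 2), rep(2, 30), rep(10, 4), rep(30, 8),
           rep(60, 4), rep(120, 5), rep(300, 9))
  frame_schedule(start = cumsum(c(0, dur[-length(dur)])), duration = dur)
}

#' @rdname frame_schedule
#' @param schedule a \code{frame_schedule}.
#' @export
schedule_mid_times_min <- function(schedule) {
  (schedule$start + schedule$duration / 2) / 60
}

# sampled_curve skeleton (zero values) on a schedule, minutes
.schedule_curve <- function(schedule, value, label = "") {
  sampled_curve(schedule$start / 60, (schedule$start + schedule$duration) / 60,
                value, label = label)
}

# convolution of one Feng term with e^(-beta t), closed form on shifted time:
#   J0: int_0^T c e^(-l u) e^(-beta (T-u)) du
#   J1: int_0^T c u e^(-l u) e^(-beta (T-u)) du
.conv_exp <- function(l, beta, T) {
  d <- beta - l
  if (abs(d) < 1e-9) return(T * exp(-beta * T))
  (exp(-l * T) - exp(-beta * T)) / d
}
.conv_texp <- function(l, beta, T) {
  d <- beta - l
  if (abs(d) < 1e-9) return(T^2 / 2 * exp(-beta * T))
  T * exp(-l * T) / d - (exp(-l * T) - exp(-beta * T)) / d^2
}

# analytic int_0^t Cp and int_0^t Cp(s) e^(-beta(t-s)) ds for a Feng input
.feng_conv <- function(params, beta, t) {
  tp <- pmax(t - params$tau, 0)
  A1 <- params$A1; A2 <- params$A2; A3 <- params$A3
  A1 * .conv_texp(params$lam1, beta, tp) -
    (A2 + A3) * .conv_exp(params$lam1, beta, tp) +
    A2 * .conv_exp(params$lam2, beta, tp) +
    A3 * .conv_exp(params$lam3, beta, tp)
}

.feng_cumint <- function(params, t) {
  vapply(t, function(ti) if (ti <= params$tau) 0 else feng_auc(params, 0, ti),
         numeric(1))
}

#' Simulate a tissue time-activity curve from the irreversible 2TCM
#'
#' Forward model: the tissue concentration is the convolution of the plasma
#' input with the impulse response
#' \eqn{K_1[k_3/(k_2+k_3) + k_2/(k_2+k_3) e^{-(k_2+k_3)t}]}; the measured
#' PET value mixes in fractional blood volume,
#' \code{(1 - vB) * Ct + vB * Cp}, sampled at frame mid-times. For a Feng
#' input the convolution is evaluated in closed form; a plain R function
#' input is convolved numerically on a fine grid.
#'
#' @param aif a \code{\link{feng_params}} object, or a function of time
#'   (minutes) returning plasma concentration.
#' @param kp a \code{\link{kinetic_params}} object.
#' @param schedule a \code{\link{frame_schedule}}.
#' @return A \code{\link{sampled_curve}} of measured tissue concentration.
#' @export
simulate_tissue_tac <- function(aif, kp, schedule) {
  stopifnot(inherits(kp, "kinetic_params"), inherits(schedule, "frame_schedule"))
  beta <- kp$k2 + kp$k3
  if (beta <= 0)
    stop("simulate_tissue_tac: k2 + k3 must be > 0", call. = FALSE)
  t <- schedule_mid_times_min(schedule)
  if (inherits(aif, "feng_params")) {
    cp <- feng_eval(aif, t)
    intcp <- .feng_cumint(aif, t)
    conv <- .feng_conv(aif, beta, t)
  } else if (is.function(aif)) {
    dt <- 0.002
    tg <- seq(0, max(t) + dt, by = dt)
    cpg <- aif(tg)
    intg <- cumsum(c(0, (cpg[-1] + cpg[-length(cpg)]) / 2 * dt))[seq_along(tg)]
    # exponential-decay accumulator: y' = cp - beta y, trapezoidal update
    e <- exp(-beta * dt)
    yg <- numeric(length(tg))
    for (i in seq_along(tg)[-1])
      yg[i] <- yg[i - 1] * e + dt * (cpg[i] + cpg[i - 1] * e) / 2
    cp <- stats::approx(tg, cpg, xout = t)$y
    intcp <- stats::approx(tg, intg, xout = t)$y
    conv <- stats::approx(tg, yg, xout = t)$y
  } else stop("simulate_tissue_tac: aif must be feng_params or a function",
              call. = FALSE)
  ct <- kp$K1 * (kp$k3 / beta * intcp + kp$k2 / beta * conv)
  measured <- (1 - kp$vB) * ct + kp$vB * cp
  .schedule_curve(schedule, measured, label = "tissue")
}

#' Population configuration for the synthetic cohort generator
#'
#' The stated world of the simulator: the population mean arterial input is
#' the canonical normalized input-function shape rescaled so its 0-65 min
#' AUC equals \code{target_auc} (default 550 kBq min/ml, a typical
#' oncological FDG cohort mean); subjects perturb the six positive Feng
#' parameters log-normally with coefficient of variation \code{cv} and draw
#' the delay uniformly from \code{delay_range}. Each subject carries
#' \code{n_lesions} tumor ROIs with kinetics drawn uniformly from
#' \code{tumor_prior} plus one gray-matter ROI with fixed typical kinetics.
#' Frame noise is zero-mean Gaussian with standard deviation
#' \code{noise_level * sqrt(value / frame_duration_min)}, clipped at zero.
#'
#' @param mean_params population mean \code{\link{feng_params}}; by default
#'   the canonical shape parameters (tau 0.72 min, A1 15.9, A2 0.02,
#'   A3 0.02, lam1 17.8, lam2 0.18, lam3 0.01 1/min) with amplitudes
#'   rescaled to \code{target_auc}.
#' @param target_auc mean 0-65 min AUC, kBq min/ml (ignored if
#'   \code{mean_params} given).
#' @param cv log-normal coefficient of variation applied to A1..A3 and
#'   lam1..lam3 (default 0.10).
#' @param delay_range uniform range of the per-subject delay, minutes.
#' @param tumor_prior list of c(lo, hi) uniform ranges for K1, k2, k3, vB.
#' @param gray_matter fixed gray-matter \code{\link{kinetic_params}}.
#' @param n_lesions tumor lesions per subject (default 4).
#' @param noise_level noise scale in (kBq/ml) sqrt(min); 0 disables noise.
#' @param schedule the frame schedule (default \code{\link{default_schedule}}).
#' @return A list of class \code{"population_config"}.
#' @export
population_config <- function(mean_params = NULL, target_auc = 550,
                              cv = 0.10, delay_range = c(0.4, 1.0),
                              tumor_prior = list(K1 = c(0.05, 0.3),
                                                 k2 = c(0.1, 0.5),
                                                 k3 = c(0.02, 0.15),
                                                 vB = c(0.02, 0.1)),
                              gray_matter = kinetic_params(0.1, 0.15, 0.07, 0.04),
                              n_lesions = 4L, noise_level = 0.05,
                              schedule = default_schedule()) {
  if (is.null(mean_params)) {
    shape <- feng_params(tau = 0.72, A1 = 15.9, A2 = 0.02, A3 = 0.02,
                         lam1 = 17.8, lam2 = 0.18, lam3 = 0.01)
    s <- target_auc / feng_auc(shape, 0, 65)
    mean_params <- feng_params(shape$tau, shape$A1 * s, shape$A2 * s,
                               shape$A3 * s, shape$lam1, shape$lam2, shape$lam3)
  }
  validate_feng_params(mean_params)
  if (cv < 0) stop("population_config: cv must be >= 0", call. = FALSE)
  if (length(delay_range) != 2L || delay_range[2] < delay_range[1] ||
      delay_range[1] < 0)
    stop("population_config: invalid delay_range", call. = FALSE)
  for (nm in c("K1", "k2", "k3", "vB")) {
    r <- tumor_prior[[nm]]
    if (is.null(r) || length(r) != 2L || r[2] < r[1])
      stop("population_config: invalid tumor prior bounds for ", nm, call. = FALSE)
  }
  if (noise_level < 0) stop("population_config: noise_level must be >= 0",
                            call. = FALSE)
  structure(list(mean_params = mean_params, cv = cv,
                 delay_range = delay_range, tumor_prior = tumor_prior,
                 gray_matter = gray_matter, n_lesions = as.integer(n_lesions),
                 noise_level = noise_level, schedule = schedule),
            class = "population_config")
}

.add_frame_noise <- function(curve, noise_level) {
  if (noise_level <= 0) return(curve)
  sd <- noise_level * sqrt(pmax(curve$value, 0) / frame_durations(curve))
  v <- pmax(curve$value + stats::rnorm(length(sd), 0, sd), 0)
  sampled_curve(curve$frame_start, curve$frame_end, v, label = curve$label)
}

#' Generate a synthetic population of dynamic-PET subjects
#'
#' Deterministic given \code{seed}; subject \code{i} uses \code{seed + i},
#' so individual subjects can be regenerated in isolation. Each subject
#' holds its true arterial input (Feng parameters), the image-derived input
#' function (the true input sampled on the schedule, optionally with frame
#' noise), and labeled tissue TACs with recorded ground-truth kinetics.
#'
#' @param n number of subjects.
#' @param config a \code{\link{population_config}}.
#' @param seed integer seed.
#' @return A list of \code{"subject_dataset"} objects, each with elements
#'   \code{true_aif}, \code{idif}, \code{roi_tacs} (label -> list(curve,
#'   kinetics, ki_true)), \code{schedule}, \code{seed}.
#' @export
generate_population <- function(n, config = population_config(), seed = 1L) {
  stopifnot(inherits(config, "population_config"))
  if (n < 1L) stop("generate_population: n >= 1 required", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  lapply(seq_len(n), function(i) .generate_subject(config, as.integer(seed) + i))
}

.lognorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

.generate_subject <- function(config, subject_seed) {
  set.seed(subject_seed)
  m <- config$mean_params
  for (try in 1:20) {
    f <- .lognorm_factor(6, config$cv)
    tau <- stats::runif(1, config$delay_range[1], config$delay_range[2])
    p <- list(tau = tau, A1 = m$A1 * f[1], A2 = m$A2 * f[2], A3 = m$A3 * f[3],
              lam1 = m$lam1 * f[4], lam2 = m$lam2 * f[5], lam3 = m$lam3 * f[6])
    if (p$lam1 > p$lam2 && p$lam2 > p$lam3) break
  }
  true_aif <- feng_params(p$tau, p$A1, p$A2, p$A3, p$lam1, p$lam2, p$lam3)
  sched <- config$schedule
  idif <- .schedule_curve(sched, feng_eval(true_aif, schedule_mid_times_min(sched)),
                          label = "IDIF")
  idif <- .add_frame_noise(idif, config$noise_level)

  roi_tacs <- list()
  if (config$n_lesions > 0L) {
    for (j in seq_len(config$n_lesions)) {
      pr <- config$tumor_prior
      kp <- kinetic_params(K1 = stats::runif(1, pr$K1[1], pr$K1[2]),
                           k2 = stats::runif(1, pr$k2[1], pr$k2[2]),
                           k3 = stats::runif(1, pr$k3[1], pr$k3[2]),
                           vB = stats::runif(1, pr$vB[1], pr$vB[2]))
      cv <- simulate_tissue_tac(true_aif, kp, sched)
      cv$label <- paste0("tumor_", j)
      roi_tacs[[cv$label]] <- list(curve = .add_frame_noise(cv, config$noise_level),
                                   kinetics = kp, ki_true = ki_true(kp))
    }
  }
  gm <- simulate_tissue_tac(true_aif, config$gray_matter, sched)
  gm$label <- "gray_matter"
  roi_tacs[["gray_matter"]] <- list(curve = .add_frame_noise(gm, config$noise_level),
                                    kinetics = config$gray_matter,
                                    ki_true = ki_true(config$gray_matter))
  structure(list(true_aif = true_aif, idif = idif, roi_tacs = roi_tacs,
                 schedule = sched, seed = subject_seed),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("subject_dataset (seed %d): %d frames, ROIs: %s\n", x$seed,
              length(x$idif$value), paste(names(x$roi_tacs), collapse = ", ")))
  invisible(x)
}

#' Build a 4D dynamic phantom from a synthetic subject
#'
#' Places labeled regions (axis-aligned spheres) inside a voxel grid; every
#' voxel of a region carries that region's TAC (the subject's IDIF for the
#' blood-pool region) plus optional iid frame noise. The background is
#' near-zero uptake. A desk-scale stand-in for whole-body parametric
#' imaging.
#'
#' @param subject a \code{"subject_dataset"}.
#' @param dims integer voxel counts, default \code{c(32, 32, 32)}.
#' @param layout named list of regions: each
#'   \code{list(center = c(x, y, z) in voxel units, radius = voxels,
#'   role = "blood" | roi label in subject$roi_tacs)}. Default: one blood
#'   pool, one tumor (first lesion), one gray-matter sphere.
#' @param noise_level frame-noise scale as in
#'   \code{\link{population_config}} (default 0).
#' @param seed integer seed for the voxel noise.
#' @return A list of class \code{"phantom"}: \code{volume} (4D array
#'   x,y,z,frame), \code{labels} (3D integer array, 0 = background),
#'   \code{label_names}, \code{region_roles}, \code{region_tacs},
#'   \code{schedule}.
#' @export
generate_phantom <- function(subject, dims = c(32L, 32L, 32L),
                             layout = NULL, noise_level = 0, seed = 1L) {
  stopifnot(inherits(subject, "subject_dataset"))
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 4L))
    stop("generate_phantom: dims too small to place regions", call. = FALSE)
  if (is.null(layout)) {
    c0 <- dims / 2
    layout <- list(
      blood = list(center = c(dims[1] * 0.25, c0[2], c0[3]),
                   radius = max(min(dims) / 8, 1.2), role = "blood"),
      tumor = list(center = c(dims[1] * 0.7, dims[2] * 0.7, c0[3]),
                   radius = max(min(dims) / 6, 1.6),
                   role = names(subject$roi_tacs)[1]),
      gray_matter = list(center = c(dims[1] * 0.7, dims[2] * 0.3, c0[3]),
                         radius = max(min(dims) / 6, 1.6),
                         role = "gray_matter"))
  }
  nt <- length(subject$idif$value)
  labels <- array(0L, dims)
  region_tacs <- list()
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                               z = seq_len(dims[3])))
  for (k in seq_along(layout)) {
    reg <- layout[[k]]
    if (any(reg$center < 1) || any(reg$center > dims) || reg$radius < 1)
      stop("generate_phantom: region '", names(layout)[k],
           "' does not fit inside dims", call. = FALSE)
    d2 <- (idx[, 1] - reg$center[1])^2 + (idx[, 2] - reg$center[2])^2 +
      (idx[, 3] - reg$center[3])^2
    inside <- d2 <= reg$radius^2
    labels[idx[inside, , drop = FALSE]] <- k
    tac <- if (identical(reg$role, "blood")) subject$idif$value
    else {
      roi <- subject$roi_tacs[[reg$role]]
      if (is.null(roi)) stop("generate_phantom: unknown role '", reg$role, "'",
                             call. = FALSE)
      roi$curve$value
    }
    region_tacs[[names(layout)[k]]] <- tac
  }
  vol <- array(0, c(dims, nt))
  flat_labels <- as.vector(labels)
  nvox <- prod(dims)
  for (f in seq_len(nt)) {
    frame <- numeric(nvox)
    for (k in seq_along(layout))
      frame[flat_labels == k] <- region_tacs[[k]][f]
    vol[, , , f] <- frame
  }
  if (noise_level > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
    durmin <- subject$schedule$duration / 60
    for (f in seq_len(nt)) {
      sl <- vol[, , , f]
      sd <- noise_level * sqrt(pmax(sl, 0) / durmin[f])
      vol[, , , f] <- pmax(sl + stats::rnorm(length(sl), 0, sd), 0)
    }
  }
  structure(list(volume = vol, labels = labels, label_names = names(layout),
                 region_roles = vapply(layout, `[[`, character(1), "role"),
                 region_tacs = region_tacs, schedule = subject$schedule),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("phantom: %d x %d x %d voxels, %d frames; regions: %s\n",
              d[1], d[2], d[3], d[4], paste(x$label_names, collapse = ", ")))
  invisible(x)
}
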