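#' Serialize Feng parameters as flat JSON
#'
#' Keys \code{tau, A1, A2, A3, lam1, lam2, lam3}; numbers at full precision.
#'
#' @param params a \code{\link{feng_params}} object.
#' @param path file path.
#' @return \code{read_feng_params} returns a \code{feng_params};
#'   \code{write_feng_params} returns \code{path} invisibly.
#' @export
write_feng_params <- function(params, path) {
  validate_feng_params(params)
  jsonlite::write_json(as.list(coef(params)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feng_params
#' @export
read_feng_params <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  feng_params(d$tau, d$A1, d$A2, d$A3, d$lam1, d$lam2, d$lam3)
}

# --- minimal NIfTI-1 I/O ----------------------------------------------------
# Single-file .nii / .nii.gz, float32 data, identity orientation. Written by
# hand because no NIfTI package is available in this R installation; covers
# exactly what the phantom pipeline needs.

.pad_char <- function(s, n) {
  r <- charToRaw(substr(s, 1, n))
  c(r, raw(n - length(r)))
}

#' Minimal NIfTI-1 volume I/O
#'
#' Writes/reads single-file NIfTI-1 (\code{.nii}, gzipped if the path ends
#' in \code{.gz}) with float32 data and identity orientation. Intended for
#' 3D label maps / parametric maps and 4D dynamic phantoms; values
#' round-trip within float32 precision.
#'
#' @param arr numeric array, 3 or 4 dimensions.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param pixdim voxel dimensions (mm) and, for 4D, frame spacing; recycled
#'   to the array rank.
#' @return \code{write_nifti} returns \code{path} invisibly;
#'   \code{read_nifti} returns a list with \code{data} and \code{pixdim}.
#' @export
write_nifti <- function(arr, path, pixdim = c(1, 1, 1, 1)) {
  d <- dim(arr)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("write_nifti: array must be 3D or 4D", call. = FALSE)
  ndim <- length(d)
  dim8 <- c(ndim, d, rep(1L, 7L - ndim))
  pd <- rep_len(as.numeric(pixdim), ndim)
  pixdim8 <- c(1, pd, rep(0, 7 - ndim))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")
  writeBin(raw(10 + 18 + 4 + 2 + 1 + 1), con)             # data_type..dim_info
  writeBin(as.integer(dim8), con, size = 2, endian = "little")
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")  # intent_p1..p3
  writeBin(c(0L, 16L, 32L, 0L), con, size = 2, endian = "little") # intent/datatype/bitpix/slice_start
  writeBin(pixdim8, con, size = 4, endian = "little")
  writeBin(c(352, 1, 0), con, size = 4, endian = "little") # vox_offset, scl_slope, scl_inter
  writeBin(c(0L), con, size = 2, endian = "little")        # slice_end
  writeBin(raw(2), con)                                    # slice_code, xyzt_units
  writeBin(c(0, 0, 0, 0), con, size = 4, endian = "little") # cal_max..toffset
  writeBin(c(0L, 0L), con, size = 4, endian = "little")    # glmax, glmin
  writeBin(.pad_char("spbif phantom", 80), con)            # descrip
  writeBin(raw(24), con)                                   # aux_file
  writeBin(c(0L, 1L), con, size = 2, endian = "little")    # qform, sform
  writeBin(rep(0, 6), con, size = 4, endian = "little")    # quatern/qoffset
  srow <- rbind(c(pd[1], 0, 0, 0), c(0, pd[2], 0, 0), c(0, 0, pd[3], 0))
  writeBin(as.numeric(t(srow)), con, size = 4, endian = "little")
  writeBin(raw(16), con)                                   # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)            # magic
  writeBin(raw(4), con)                                    # extender
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  if (length(hdr) < 352 || readBin(hdr[1:4], "integer", 1, 4, endian = "little") != 348L)
    stop("read_nifti: not a NIfTI-1 file: ", path, call. = FALSE)
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1")
    stop("read_nifti: unsupported magic '", magic, "'", call. = FALSE)
  dim8 <- readBin(hdr[41:56], "integer", 8, 2, endian = "little")
  ndim <- dim8[1]
  d <- dim8[2:(1 + ndim)]
  datatype <- readBin(hdr[71:72], "integer", 1, 2, endian = "little")
  pixdim8 <- readBin(hdr[77:108], "double", 8, 4, endian = "little")
  vox_offset <- readBin(hdr[109:112], "double", 1, 4, endian = "little")
  if (vox_offset > 352) readBin(con, "raw", vox_offset - 352)
  n <- prod(d)
  data <- switch(as.character(datatype),
                 "16" = readBin(con, "double", n, 4, endian = "little"),
                 "64" = readBin(con, "double", n, 8, endian = "little"),
                 "8" = readBin(con, "integer", n, 4, endian = "little"),
                 "4" = readBin(con, "integer", n, 2, endian = "little"),
                 stop("read_nifti: unsupported datatype code ", datatype,
                      call. = FALSE))
  arr <- array(as.numeric(data), d)
  list(data = arr, pixdim = pixdim8[2:(1 + ndim)])
}

#' Frame-timing JSON sidecar
#'
#' Stores \code{FrameTimesStart} and \code{FrameDuration} in seconds
#' alongside a 4D NIfTI volume.
#'
#' @param schedule a \code{\link{frame_schedule}}.
#' @param path JSON path.
#' @return \code{read_frame_sidecar} returns a \code{frame_schedule}.
#' @export
write_frame_sidecar <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  jsonlite::write_json(list(FrameTimesStart = schedule$start,
                            FrameDuration = schedule$duration,
                            Units = "s"),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_frame_sidecar
#' @export
read_frame_sidecar <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(d$FrameTimesStart) || is.null(d$FrameDuration))
    stop("read_frame_sidecar: missing FrameTimesStart/FrameDuration", call. = FALSE)
  frame_schedule(d$FrameTimesStart, d$FrameDuration)
}

#' Experiment configuration
#'
#' Bundles the protocol constants for the end-to-end experiment: cohort
#' sizes, the five scaling windows, the Patlak start-time grid, the IDIF
#' reference, and the synthetic-population settings. Validated on
#' construction.
#'
#' @param seed global integer seed. Sub-stage seeds fan out
#'   deterministically: generation cohort \code{seed}, validation cohort
#'   \code{seed + 10000}, PBIF fitting \code{seed + 20000}, phantom noise
#'   \code{seed + 30000}.
#' @param n_generation,n_validation cohort sizes (default 16 and 8).
#' @param windows list of scaling windows (default the five canonical
#'   windows 35-65 ... 55-65 min).
#' @param t_stars Patlak start times, minutes.
#' @param reference list(t_star =) for the IDIF reference.
#' @param population a \code{\link{population_config}}.
#' @param phantom_dims voxel grid for the parametric stage.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(seed = 1L, n_generation = 16L, n_validation = 8L,
                       windows = list(c(35, 65), c(40, 65), c(45, 65),
                                      c(50, 65), c(55, 65)),
                       t_stars = c(35, 40, 45, 50, 55),
                       reference = list(t_star = 35),
                       population = population_config(),
                       phantom_dims = c(24L, 24L, 24L)) {
  span <- sum(population$schedule$duration) / 60
  for (w in windows) {
    if (length(w) != 2L || w[1] >= w[2] || w[1] < 0 || w[2] > span)
      stop("run_config: window [", paste(w, collapse = ", "),
           "] outside [0, ", span, "] or start >= end", call. = FALSE)
  }
  if (any(t_stars < 0 | t_stars >= span))
    stop("run_config: t_star values must lie within the scan span", call. = FALSE)
  if (n_generation < 1L || n_validation < 1L)
    stop("run_config: cohort sizes must be >= 1", call. = FALSE)
  structure(list(seed = as.integer(seed), n_generation = as.integer(n_generation),
                 n_validation = as.integer(n_validation), windows = windows,
                 t_stars = t_stars, reference = reference,
                 population = population, phantom_dims = phantom_dims),
            class = "run_config")
}

#' Run the full abbreviated-protocol experiment
#'
#' End-to-end pipeline on synthetic data: simulate the generation and
#' validation cohorts, build the PBIF from the generation IDIFs, scale it to
#' each validation subject over every window, compare full-curve AUCs
#' (paired Wilcoxon), run the factorial bias/precision evaluation, and (if
#' \code{do_parametric}) build a phantom from the first validation subject
#' and compute parametric-image fidelity metrics for the best-performing
#' sPBIF at the reference and an abbreviated start time.
#'
#' @param config a \code{\link{run_config}}.
#' @param outdir optional output directory; when given, writes the
#'   evaluation table, AUC table, metrics and a JSON manifest (config,
#'   seeds, package version) for reproducibility.
#' @param do_parametric run the voxel-wise stage (default TRUE).
#' @return A list of class \code{"spbif_experiment"}: \code{pbif},
#'   \code{auc_comparison}, \code{eval_table}, \code{metrics} (list per
#'   comparison), \code{config}.
#' @export
run_experiment <- function(config = run_config(), outdir = NULL,
                           do_parametric = TRUE) {
  stopifnot(inherits(config, "run_config"))
  gen <- generate_population(config$n_generation, config$population,
                             seed = config$seed)
  val <- generate_population(config$n_validation, config$population,
                             seed = config$seed + 10000L)
  pbif <- build_pbif(lapply(gen, `[[`, "idif"), T_ref = 65,
                     seed = config$seed + 20000L)
  spbifs_by_window <- lapply(config$windows, function(w)
    lapply(val, function(su) scale_pbif(pbif, su$idif, w)))
  aucs <- compare_aucs(lapply(val, `[[`, "idif"), spbifs_by_window)
  eval_table <- run_factorial(val, pbif, windows = config$windows,
                              t_stars = config$t_stars,
                              reference = config$reference)
  metrics <- NULL
  if (do_parametric) {
    ph <- generate_phantom(val[[1]], dims = config$phantom_dims,
                           seed = config$seed + 30000L)
    ref_img <- voxelwise_patlak(ph, val[[1]]$idif,
                                t_star = config$reference$t_star)
    sp_best <- scale_pbif(pbif, val[[1]]$idif, c(55, 65))
    metrics <- list(
      "sPBIF_55-65_t35" = image_metrics(
        voxelwise_patlak(ph, sp_best, t_star = config$reference$t_star),
        ref_img),
      "sPBIF_55-65_t45" = image_metrics(
        voxelwise_patlak(ph, sp_best, t_star = 45), ref_img))
  }
  out <- structure(list(pbif = pbif, auc_comparison = aucs,
                        eval_table = eval_table, metrics = metrics,
                        config = config),
                   class = "spbif_experiment")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_eval_table(eval_table, file.path(outdir, "eval_table.csv"))
    utils::write.csv(aucs$table, file.path(outdir, "auc_table.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(aucs$tests, file.path(outdir, "auc_tests.csv"),
                     row.names = FALSE, quote = FALSE)
    write_pbif(pbif, file.path(outdir, "pbif.json"),
               curve_csv = file.path(outdir, "pbif_curve.csv"))
    if (!is.null(metrics))
      for (nm in names(metrics))
        write_image_metrics(metrics[[nm]],
                            file.path(outdir, paste0("metrics_", nm, ".json")))
    manifest <- list(
      package = "spbif",
      version = as.character(utils::packageVersion("spbif")),
      seed = config$seed,
      seed_fanout = list(generation = config$seed,
                         validation = config$seed + 10000L,
                         pbif = config$seed + 20000L,
                         phantom = config$seed + 30000L),
      n_generation = config$n_generation, n_validation = config$n_validation,
      windows = lapply(config$windows, as.numeric),
      t_stars = config$t_stars,
      reference_t_star = config$reference$t_star,
      noise_level = config$population$noise_level,
      cv = config$population$cv,
      delay_range = config$population$delay_range)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.spbif_experiment <- function(x, ...) {
  cat("Abbreviated-protocol sPBIF experiment\n")
  cat(sprintf("  cohorts: %d generation + %d validation subjects (seed %d)\n",
              x$config$n_generation, x$config$n_validation, x$config$seed))
  print(x$pbif)
  print(x$auc_comparison)
  cat("\n")
  ref35 <- x$eval_table[x$eval_table$t_star == x$config$reference$t_star &
                          !x$eval_table$failed, ]
  print.data.frame(ref35, row.names = FALSE, digits = 3)
  if (!is.null(x$metrics)) {
    cat("\nParametric-image fidelity vs IDIF reference:\n")
    for (nm in names(x$metrics)) {
      cat(" ", nm, ": ")
      print(x$metrics[[nm]])
    }
  }
  invisible(x)
}
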