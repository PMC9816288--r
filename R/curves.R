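#' Frame-sampled time-activity curve
#'
#' A time-activity curve (TAC) with explicit frame bounds: values are
#' activity concentrations (kBq/ml, assumed decay-corrected) associated with
#' the frame mid-times. Frames must be non-overlapping and in increasing
#' order.
#'
#' @param frame_start,frame_end frame bounds in minutes.
#' @param value activity concentration per frame, kBq/ml.
#' @param label free-text label, e.g. \code{"IDIF"} or \code{"tumor"}.
#' @return An object of class \code{"sampled_curve"}.
#' @export
sampled_curve <- function(frame_start, frame_end, value, label = "") {
  frame_start <- as.numeric(frame_start)
  frame_end <- as.numeric(frame_end)
  value <- as.numeric(value)
  n <- length(frame_start)
  if (length(frame_end) != n || length(value) != n)
    stop("sampled_curve: frame_start, frame_end, value must have equal length",
         call. = FALSE)
  if (n == 0L) stop("sampled_curve: empty curve", call. = FALSE)
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_end)) ||
      any(!is.finite(value)))
    stop("sampled_curve: non-finite entries", call. = FALSE)
  if (is.unsorted(frame_start, strictly = TRUE))
    stop("sampled_curve: frame_start must be strictly increasing", call. = FALSE)
  if (any(frame_end <= frame_start))
    stop("sampled_curve: frame_end must exceed frame_start", call. = FALSE)
  if (n > 1L && any(frame_start[-1] < frame_end[-n] - 1e-9))
    stop("sampled_curve: frames overlap", call. = FALSE)
  structure(list(frame_start = frame_start, frame_end = frame_end,
                 value = value, label = as.character(label)[1]),
            class = "sampled_curve")
}

#' @rdname sampled_curve
#' @param curve a \code{sampled_curve}.
#' @export
frame_mid_times <- function(curve) (curve$frame_start + curve$frame_end) / 2

#' @rdname sampled_curve
#' @export
frame_durations <- function(curve) curve$frame_end - curve$frame_start

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("sampled_curve '%s': %d frames, %.3g-%.3g min, peak %.4g\n",
              x$label, length(x$value), x$frame_start[1],
              x$frame_end[length(x$value)], max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.sampled_curve <- function(x, ...) {
  data.frame(frame_start_min = x$frame_start, frame_end_min = x$frame_end,
             value_kBq_ml = x$value)
}

#' @export
plot.sampled_curve <- function(x, log = "", ...) {
  graphics::plot(frame_mid_times(x), x$value, type = "b", pch = 20, log = log,
                 xlab = "time [min]", ylab = "concentration [kBq/ml]",
                 main = x$label, ...)
  invisible(x)
}

#' Trapezoidal area under a sampled curve
#'
#' Integrates the piecewise-linear interpolant of the (frame mid-time, value)
#' pairs over \code{[t0, t1]}, with linear interpolation at the window edges.
#' The interpolant is extended flat from the first frame mid-time back to the
#' first frame start and from the last mid-time to the last frame end, so a
#' constant curve over frames spanning \code{[0, T]} integrates to exactly
#' \code{T} times the constant.
#'
#' @param curve a \code{\link{sampled_curve}}.
#' @param t0,t1 window bounds in minutes.
#' @return The trapezoidal integral (concentration x minutes).
#' @export
sampled_auc <- function(curve, t0, t1) {
  stopifnot(inherits(curve, "sampled_curve"))
  if (!is.finite(t0) || !is.finite(t1) || t1 <= t0)
    stop("sampled_auc: need t0 < t1", call. = FALSE)
  mids <- frame_mid_times(curve)
  n <- length(mids)
  knots <- c(curve$frame_start[1], mids, curve$frame_end[n])
  vals <- c(curve$value[1], curve$value, curve$value[n])
  # drop duplicate knots (single-frame degenerate mid == bounds impossible,
  # but guard equal first start/mid on zero-width grids)
  keep <- !duplicated(knots)
  knots <- knots[keep]; vals <- vals[keep]
  a <- max(t0, knots[1]); b <- min(t1, knots[length(knots)])
  if (b <= a)
    stop("sampled_auc: window [", t0, ", ", t1,
         "] disjoint from sampled span [", knots[1], ", ",
         knots[length(knots)], "]", call. = FALSE)
  inner <- knots[knots > a & knots < b]
  xs <- c(a, inner, b)
  ys <- stats::approx(knots, vals, xout = xs, rule = 2)$y
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Normalize an input function to unit area
#'
#' Divides a sampled curve by its area under the curve over
#' \code{[0, T_ref]}, the first step of population-based input-function
#' construction, so that curves from subjects with different injected doses
#' become comparable in shape.
#'
#' @param curve a \code{\link{sampled_curve}}.
#' @param T_ref reference horizon in minutes (default 65).
#' @return A \code{sampled_curve} with AUC 1 over \code{[0, T_ref]}.
#' @export
normalize_idif <- function(curve, T_ref = 65) {
  auc <- sampled_auc(curve, 0, T_ref)
  if (!is.finite(auc) || auc <= 0)
    stop("normalize_idif: nonpositive AUC (", signif(auc, 4), ") over [0, ",
         T_ref, "]", call. = FALSE)
  sampled_curve(curve$frame_start, curve$frame_end, curve$value / auc,
                label = curve$label)
}

#' Read and write time-activity curve CSV files
#'
#' The TAC dialect is a UTF-8 CSV with header
#' \code{frame_start_min,frame_end_min,value_kBq_ml}, one row per frame,
#' '.' decimal separator. \code{write_tac}/\code{read_tac} round-trip values
#' to full double precision.
#'
#' @param path file path.
#' @param curve a \code{\link{sampled_curve}}.
#' @param label label to attach on read (default: file base name).
#' @return \code{read_tac} returns a \code{sampled_curve};
#'   \code{write_tac} returns \code{path} invisibly.
#' @export
read_tac <- function(path, label = NULL) {
  d <- utils::read.csv(path, colClasses = "numeric")
  need <- c("frame_start_min", "frame_end_min", "value_kBq_ml")
  if (!all(need %in% names(d)))
    stop("read_tac: ", path, " missing columns ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  sampled_curve(d$frame_start_min, d$frame_end_min, d$value_kBq_ml,
                label = if (is.null(label)) sub("\\.csv$", "", basename(path))
                        else label)
}

#' @rdname read_tac
#' @export
write_tac <- function(curve, path) {
  stopifnot(inherits(curve, "sampled_curve"))
  d <- as.data.frame(curve)
  # format full precision so read(write(x)) is bit-exact on the text level
  d[] <- lapply(d, function(col) sprintf("%.17g", col))
  utils::write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
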