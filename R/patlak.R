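# input-function series at the tissue frame mid-times: concentration cp(t_i)
# and running integral int_0^{t_i} cp.  For a sampled input the integral uses
# the frame-bounds trapezoid (values are frame averages): full preceding
# frames plus half the current frame.  For an analytic input both come from
# the closed-form Feng expressions - the abbreviated-protocol premise that
# the early input shape is known from the population model, not from early
# image frames.
.input_series <- function(input_fn, mids, ct = NULL) {
  if (inherits(input_fn, "spbif") || inherits(input_fn, "pbif"))
    input_fn <- input_fn$params
  if (inherits(input_fn, "feng_params")) {
    list(cp = feng_eval(input_fn, mids), intcp = .feng_cumint(input_fn, mids),
         label = "feng", onset = input_fn$tau)
  } else if (inherits(input_fn, "sampled_curve")) {
    cmids <- frame_mid_times(input_fn)
    if (length(cmids) != length(mids) || any(abs(cmids - mids) > 1e-6))
      stop("patlak: input-function frames do not match the tissue schedule",
           call. = FALSE)
    d <- frame_durations(input_fn)
    v <- input_fn$value
    full <- cumsum(v * d)
    intcp <- c(0, full[-length(full)]) + v * d / 2
    # leading zero frames (before tracer arrival) are structural
    lead0 <- if (any(v > 0)) which(v > 0)[1] - 1L else 0L
    onset <- if (lead0 > 0L) cmids[lead0] else -Inf
    list(cp = v, intcp = intcp, label = input_fn$label, onset = onset)
  } else stop("patlak: unsupported input-function type ",
              paste(class(input_fn), collapse = "/"), call. = FALSE)
}

#' Patlak linearization of a tissue curve against an input function
#'
#' Computes the graphical-analysis coordinates
#' \eqn{x(t) = \int_0^t C_p(s) ds / C_p(t)} (normalized time, minutes) and
#' \eqn{y(t) = C_t(t)/C_p(t)} at the tissue frame mid-times. For an
#' irreversible tracer the points approach a line with slope \eqn{K_i} and
#' intercept \eqn{V} after the equilibration time. Frames with nonpositive
#' input concentration are excluded with a warning.
#'
#' @param ct tissue \code{\link{sampled_curve}}.
#' @param cp input function: a \code{\link{sampled_curve}} on the same
#'   schedule, a \code{\link{feng_params}}, a \code{"pbif"} or an
#'   \code{"spbif"} (analytic inputs use closed-form integrals).
#' @return A data frame with columns \code{t} (frame mid-time, min),
#'   \code{x}, \code{y}; attribute \code{"n_excluded"} counts dropped
#'   frames.
#' @export
patlak_transform <- function(ct, cp) {
  stopifnot(inherits(ct, "sampled_curve"))
  mids <- frame_mid_times(ct)
  ser <- .input_series(cp, mids)
  ok <- is.finite(ser$cp) & ser$cp > 0
  if (!any(ok))
    stop("patlak_transform: input function nonpositive at every frame",
         call. = FALSE)
  # frames before tracer onset of an analytic input are structurally zero
  # and dropped silently; only unexpected nonpositive frames are flagged
  unexpected <- !ok & mids > ser$onset
  if (any(unexpected))
    warning("patlak_transform: excluded ", sum(unexpected),
            " frame(s) with nonpositive input concentration", call. = FALSE)
  out <- data.frame(t = mids[ok], x = ser$intcp[ok] / ser$cp[ok],
                    y = ct$value[ok] / ser$cp[ok])
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Fit the Patlak line
#'
#' Ordinary least squares through the transformed points whose original
#' frame mid-time is at or after the linearization start time \code{t_star}.
#' A frame qualifies iff its mid-time >= \code{t_star}. The slope is the net
#' influx rate \eqn{K_i} (ml/g/min) and the intercept the tracer
#' distribution volume \eqn{V} (ml/g).
#'
#' @param points output of \code{\link{patlak_transform}}.
#' @param t_star linearization start time, minutes.
#' @return An object of class \code{"patlak_fit"} with \code{Ki}, \code{V},
#'   \code{r_squared}, \code{t_star}, \code{n_points}, \code{residuals} and
#'   the used \code{points}.
#' @export
patlak_fit <- function(points, t_star) {
  if (!is.data.frame(points) || !all(c("t", "x", "y") %in% names(points)))
    stop("patlak_fit: points must come from patlak_transform", call. = FALSE)
  use <- points$t >= t_star
  if (sum(use) < 2L)
    stop("patlak_fit: fewer than 2 points at or after t* = ", t_star,
         " min (sampled span ", signif(min(points$t), 4), "-",
         signif(max(points$t), 4), " min)", call. = FALSE)
  x <- points$x[use]; y <- points$y[use]
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0)
    stop("patlak_fit: degenerate abscissa (all x equal)", call. = FALSE)
  ki <- sum((x - mx) * (y - my)) / sxx
  v <- my - ki * mx
  res <- y - (ki * x + v)
  tss <- sum((y - my)^2)
  rss <- sum(res^2)
  r2 <- if (tss <= .Machine$double.eps * max(1, my^2) * n) {
    if (rss <= tss + 1e-30) 1 else 0
  } else max(0, min(1, 1 - rss / tss))
  structure(list(Ki = ki, V = v, r_squared = r2, t_star = t_star,
                 n_points = n, residuals = res,
                 points = points[use, , drop = FALSE]),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("Patlak fit (t* = %g min, %d points): Ki = %.5g ml/g/min, V = %.5g ml/g, r^2 = %.4f\n",
              x$t_star, x$n_points, x$Ki, x$V, x$r_squared))
  invisible(x)
}

#' @export
coef.patlak_fit <- function(object, ...) c(Ki = object$Ki, V = object$V)

#' @export
residuals.patlak_fit <- function(object, ...) object$residuals

#' @export
predict.patlak_fit <- function(object, newx = NULL, ...) {
  if (is.null(newx)) newx <- object$points$x
  object$Ki * newx + object$V
}

#' @export
summary.patlak_fit <- function(object, ...) {
  cat(sprintf("Patlak graphical analysis\n  t* = %g min, n = %d points\n",
              object$t_star, object$n_points))
  cat(sprintf("  Ki = %.5g ml/g/min\n  V  = %.5g ml/g\n  r^2 = %.5f\n",
              object$Ki, object$V, object$r_squared))
  cat(sprintf("  residual sd = %.3g\n", stats::sd(object$residuals)))
  invisible(object)
}

#' @export
plot.patlak_fit <- function(x, full_points = NULL, ...) {
  pts <- if (is.null(full_points)) x$points else full_points
  graphics::plot(pts$x, pts$y, pch = 1, xlab = "normalized time [min]",
                 ylab = "Ct/Cp", main = sprintf("Patlak plot (t* = %g min)",
                                                x$t_star), ...)
  graphics::points(x$points$x, x$points$y, pch = 19)
  graphics::abline(x$V, x$Ki, col = 2)
  invisible(x)
}

#' Patlak analysis of a subject's labeled ROIs
#'
#' Applies \code{\link{patlak_transform}} and \code{\link{patlak_fit}} to
#' each labeled tissue TAC of a synthetic subject.
#'
#' @param subject a \code{"subject_dataset"}.
#' @param input_fn input function object, or the string \code{"idif"} for
#'   the subject's own IDIF.
#' @param t_star linearization start time, minutes.
#' @param labels ROI labels (default: all).
#' @return Named list of \code{"patlak_fit"} objects.
#' @export
roi_patlak <- function(subject, input_fn = "idif", t_star = 35, labels = NULL) {
  stopifnot(inherits(subject, "subject_dataset"))
  if (identical(input_fn, "idif")) input_fn <- subject$idif
  if (is.null(labels)) labels <- names(subject$roi_tacs)
  missing <- setdiff(labels, names(subject$roi_tacs))
  if (length(missing))
    stop("roi_patlak: missing label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- lapply(labels, function(lb)
    patlak_fit(patlak_transform(subject$roi_tacs[[lb]]$curve, input_fn), t_star))
  names(out) <- labels
  out
}
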