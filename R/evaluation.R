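#' Percent bias, precision and agreement of paired Ki estimates
#'
#' Per-item percent bias \code{100 * (test - ref) / ref}, its mean
#' (\emph{bias}), its sample standard deviation with n-1 denominator
#' (\emph{precision}), and the r-squared of the ordinary least-squares
#' regression of test on reference.
#'
#' @param test,ref numeric vectors of equal length, paired by lesion/ROI;
#'   \code{ref} must be nonzero everywhere.
#' @return A list of class \code{"percent_bias"}: \code{bias} (per item, %),
#'   \code{mean_bias}, \code{precision}, \code{r_squared}, \code{n}.
#'   \code{precision} and \code{r_squared} are \code{NA} for n = 1.
#' @export
percent_bias <- function(test, ref) {
  if (length(test) != length(ref) || length(ref) < 1L)
    stop("percent_bias: test and ref must have equal length >= 1", call. = FALSE)
  bad <- which(ref == 0)
  if (length(bad))
    stop("percent_bias: reference value is zero at item(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  b <- 100 * (test - ref) / ref
  n <- length(b)
  r2 <- if (n >= 2L && stats::var(ref) > 0) {
    fit <- stats::lm(test ~ ref)
    suppressWarnings(summary(fit)$r.squared)   # exact fits are legitimate here
  } else NA_real_
  structure(list(bias = b, mean_bias = mean(b),
                 precision = if (n >= 2L) stats::sd(b) else NA_real_,
                 r_squared = r2, n = n),
            class = "percent_bias")
}

#' @export
print.percent_bias <- function(x, ...) {
  cat(sprintf("n = %d: mean bias %.3g%%, precision (SD of bias) %.3g%%, r^2 = %.4g\n",
              x$n, x$mean_bias, x$precision, x$r_squared))
  invisible(x)
}

# exact two-sided Wilcoxon signed-rank p on paired differences, zeros
# dropped (classic convention); all-zero differences report p = 1.
.wilcoxon_signed_rank <- function(d) {
  d <- d[d != 0]
  if (length(d) == 0L) return(list(statistic = NA_real_, p = 1, n = 0L))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = length(d) <= 25,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, n = length(d))
}

#' Compare full-curve AUCs of IDIFs and scaled PBIFs
#'
#' Per-subject areas over the horizon (trapezoidal for the sampled IDIF and
#' the sPBIF dense curve) plus a paired two-sided Wilcoxon signed-rank test
#' per scaling window (exact distribution for n <= 25; zero differences
#' dropped, all-zero reported as p = 1).
#'
#' @param idifs list of subject IDIF \code{\link{sampled_curve}}s.
#' @param spbifs list of \code{"spbif"} objects, parallel to \code{idifs},
#'   or a nested list (one inner list per window).
#' @param horizon integration window, default \code{c(0, 65)} minutes.
#' @return A list of class \code{"auc_comparison"}: \code{table}
#'   (subject, window, auc_idif, auc_spbif) and \code{tests} (window,
#'   n_nonzero, statistic, p_value; p is NA when fewer than 2 subjects).
#' @export
compare_aucs <- function(idifs, spbifs, horizon = c(0, 65)) {
  if (length(spbifs) && inherits(spbifs[[1]], "spbif"))
    spbifs <- list(spbifs)
  rows <- do.call(rbind, lapply(spbifs, function(group) {
    if (length(group) != length(idifs))
      stop("compare_aucs: spbif group length must match idifs", call. = FALSE)
    do.call(rbind, lapply(seq_along(idifs), function(i) {
      sp <- group[[i]]
      data.frame(subject = i, window = sp$label,
                 auc_idif = sampled_auc(idifs[[i]], horizon[1], horizon[2]),
                 auc_spbif = sampled_auc(sp$curve, horizon[1], horizon[2]))
    }))
  }))
  tests <- do.call(rbind, lapply(split(rows, rows$window), function(g) {
    d <- g$auc_spbif - g$auc_idif
    if (nrow(g) < 2L)
      return(data.frame(window = g$window[1], n_nonzero = sum(d != 0),
                        statistic = NA_real_, p_value = NA_real_))
    w <- .wilcoxon_signed_rank(d)
    data.frame(window = g$window[1], n_nonzero = w$n,
               statistic = if (is.null(w$statistic)) NA_real_ else w$statistic,
               p_value = w$p)
  }))
  rownames(tests) <- NULL
  structure(list(table = rows, tests = tests, horizon = horizon),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC comparison over [%g, %g] min, %d subjects\n",
              x$horizon[1], x$horizon[2], length(unique(x$table$subject))))
  agg <- stats::aggregate(cbind(auc_idif, auc_spbif) ~ window, x$table, mean)
  m <- merge(agg, x$tests, by = "window")
  print(m, row.names = FALSE, digits = 4)
  invisible(x)
}

.tissue_class <- function(label) {
  ifelse(grepl("^tumor", label), "tumor", label)
}

#' Factorial evaluation of scaled PBIFs against the IDIF reference
#'
#' For every combination of scaling window and Patlak start time, computes
#' per-lesion Ki with the subject's sPBIF, compares against the reference Ki
#' (by default the subject's own IDIF with t* = 35 min) via
#' \code{\link{percent_bias}}, and pools lesions flat across subjects within
#' each tissue class.
#'
#' @param population list of \code{"subject_dataset"} objects (the
#'   validation group).
#' @param pbif a \code{\link{build_pbif}} result.
#' @param windows list of scaling windows, default the five canonical
#'   windows 35-65 ... 55-65 min.
#' @param t_stars Patlak start times, minutes (default 35, 40, 45, 50, 55).
#' @param reference list(t_star =) for the IDIF reference (default 35 min).
#' @param test_input \code{"spbif"} (default) or \code{"idif"} for a
#'   self-consistency run in which the test input is the reference input.
#' @return A data frame of class \code{"patlak_eval"} with one row per
#'   (window, t_star, tissue class): \code{mean_bias}, \code{precision},
#'   \code{r_squared} (all %/unitless), \code{n}, \code{failed}.
#' @export
run_factorial <- function(population, pbif,
                          windows = list(c(35, 65), c(40, 65), c(45, 65),
                                         c(50, 65), c(55, 65)),
                          t_stars = c(35, 40, 45, 50, 55),
                          reference = list(t_star = 35),
                          test_input = c("spbif", "idif")) {
  test_input <- match.arg(test_input)
  if (!length(population))
    stop("run_factorial: empty population", call. = FALSE)
  ref_ki <- lapply(population, function(su)
    vapply(roi_patlak(su, "idif", reference$t_star), `[[`, numeric(1), "Ki"))
  labels <- names(ref_ki[[1]])
  rows <- list()
  for (w in windows) {
    spbifs <- lapply(population, function(su)
      if (test_input == "spbif") scale_pbif(pbif, su$idif, w) else NULL)
    for (ts in t_stars) {
      cell <- tryCatch({
        test_ki <- lapply(seq_along(population), function(i) {
          inp <- if (test_input == "spbif") spbifs[[i]] else population[[i]]$idif
          vapply(roi_patlak(population[[i]], inp, ts), `[[`, numeric(1), "Ki")
        })
        tk <- unlist(test_ki)
        rk <- unlist(ref_ki)
        cls <- .tissue_class(rep(labels, length(population)))
        do.call(rbind, lapply(unique(cls), function(cl) {
          pb <- percent_bias(tk[cls == cl], rk[cls == cl])
          data.frame(window = sprintf("%g-%g", w[1], w[2]), t_star = ts,
                     tissue = cl, mean_bias = pb$mean_bias,
                     precision = pb$precision, r_squared = pb$r_squared,
                     n = pb$n, failed = FALSE)
        }))
      }, error = function(e) {
        warning("run_factorial: cell (", sprintf("%g-%g", w[1], w[2]), ", t* = ",
                ts, ") failed: ", conditionMessage(e), call. = FALSE)
        data.frame(window = sprintf("%g-%g", w[1], w[2]), t_star = ts,
                   tissue = NA_character_, mean_bias = NA_real_,
                   precision = NA_real_, r_squared = NA_real_,
                   n = 0L, failed = TRUE)
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("patlak_eval", "data.frame")
  attr(out, "reference") <- sprintf("IDIF, t* = %g min", reference$t_star)
  out
}

#' @export
print.patlak_eval <- function(x, ...) {
  cat("Patlak Ki bias/precision table (reference: ",
      attr(x, "reference"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.patlak_eval <- function(x, tissue = "tumor", window = NULL, ...) {
  d <- x[x$tissue == tissue & !x$failed, ]
  if (!is.null(window)) d <- d[d$window == window, ]
  if (!nrow(d)) stop("plot.patlak_eval: nothing to plot", call. = FALSE)
  bp <- graphics::barplot(d$mean_bias, names.arg = paste(d$window, d$t_star),
                          las = 2, ylab = "bias [%]",
                          ylim = range(0, d$mean_bias - d$precision,
                                       d$mean_bias + d$precision, na.rm = TRUE),
                          main = sprintf("Ki bias +/- SD (%s)", tissue), ...)
  ok <- is.finite(d$precision)
  graphics::arrows(bp[ok], d$mean_bias[ok] - d$precision[ok],
                   bp[ok], d$mean_bias[ok] + d$precision[ok],
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' @rdname run_factorial
#' @param x a \code{"patlak_eval"} table.
#' @param path CSV output path.
#' @export
write_eval_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
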