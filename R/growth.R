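#' Maximum-slope growth parameters from a single curve
#'
#' Non-parametric growth-rate extraction: an ordinary least-squares line is
#' fitted to every window of `fitrange` consecutive points and the largest
#' fitted slope is reported, together with the window midpoint time, the
#' coefficient of determination of the winning fit, the initial and final
#' levels (means of the first/last `fitrange` points) and a lag estimate
#' (where the winning regression line crosses the initial level). No growth
#' model is assumed, so the estimate is robust to atypical curve shapes.
#'
#' Windows containing missing values are skipped, not imputed. The lag is
#' reported as NA when the winning slope is not positive or when the
#' crossing time precedes the first timepoint by more than one sampling
#' interval.
#'
#' @param t numeric vector of strictly increasing timestamps (hours)
#' @param y numeric vector of population-size proxies (same length as t)
#' @param fitrange number of consecutive points per regression window
#'   (default 12)
#' @param smooth apply a rolling median (window 3) to y before fitting
#' @return one-row data.frame: max_slope, t_max, lag, y0, y_end, r2,
#'   fitrange
#' @export
fit_max_slope <- function(t, y, fitrange = 12, smooth = FALSE) {
  fitrange <- as.integer(fitrange)
  if (fitrange < 2) stop("fitrange must be at least 2")
  if (length(t) != length(y)) stop("t and y must have the same length")
  if (length(t) < fitrange)
    stop("curve has ", length(t), " points, shorter than fitrange ", fitrange)
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (smooth && length(y) >= 3) {
    ok <- is.finite(y)
    if (all(ok)) y <- stats::runmed(y, 3, endrule = "keep")
  }

  n <- length(t)
  best <- list(slope = -Inf, icpt = NA_real_, mid = NA_real_, r2 = NA_real_)
  for (s in seq_len(n - fitrange + 1L)) {
    idx <- s:(s + fitrange - 1L)
    ys <- y[idx]
    if (any(!is.finite(ys))) next
    xs <- t[idx]
    if (max(xs) == min(xs)) stop("singular fit: constant time within window")
    xm <- mean(xs); ym <- mean(ys)
    sxx <- sum((xs - xm)^2)
    sxy <- sum((xs - xm) * (ys - ym))
    slope <- sxy / sxx
    if (slope > best$slope) {
      syy <- sum((ys - ym)^2)
      r2 <- if (syy <= .Machine$double.eps * max(1, ym^2)) 1
            else max(0, min(1, sxy^2 / (sxx * syy)))
      best <- list(slope = slope, icpt = ym - slope * xm, mid = xm, r2 = r2)
    }
  }
  if (!is.finite(best$slope))
    stop("no usable window (all windows contain missing values)")

  first_ok <- which(is.finite(y))
  y0 <- mean(y[utils::head(first_ok, fitrange)])
  y_end <- mean(y[utils::tail(first_ok, fitrange)])
  lag <- NA_real_
  if (best$slope > 0) {
    cross <- (y0 - best$icpt) / best$slope
    step <- stats::median(diff(t))
    if (cross >= t[1] - step) lag <- max(0, cross)
  }
  data.frame(max_slope = best$slope, t_max = best$mid, lag = lag,
             y0 = y0, y_end = y_end, r2 = best$r2, fitrange = fitrange)
}

#' Growth parameters for every curve of a timecourse table
#'
#' Applies [fit_max_slope()] to each position column of a timecourse table
#' (first column `timepoint`, remaining columns one curve per position).
#' Curves whose fit fails carry missing values and a reason code instead of
#' aborting the run.
#'
#' @param table timecourse data.frame (see [quantify_timecourse()])
#' @param fitrange window length passed to [fit_max_slope()]
#' @param smooth rolling-median pre-smoothing flag
#' @param plots_dir optional directory; one diagnostic PNG per curve showing
#'   the curve and the winning regression window
#' @return data.frame with one row per position: position, max_slope, t_max,
#'   lag, y0, y_end, r2, fitrange, reason ("" on success)
#' @export
summarize_curves <- function(table, fitrange = 12, smooth = FALSE,
                             plots_dir = NULL) {
  stopifnot(is.data.frame(table), ncol(table) >= 2)
  if (names(table)[1] != "timepoint")
    stop("first column of a timecourse table must be 'timepoint'")
  if (!is.null(plots_dir) && !dir.exists(plots_dir))
    dir.create(plots_dir, recursive = TRUE)
  tt <- table$timepoint
  poss <- names(table)[-1]
  out <- vector("list", length(poss))
  for (i in seq_along(poss)) {
    y <- table[[poss[i]]]
    fit <- tryCatch(fit_max_slope(tt, y, fitrange, smooth),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      out[[i]] <- data.frame(position = poss[i], max_slope = NA_real_,
                             t_max = NA_real_, lag = NA_real_, y0 = NA_real_,
                             y_end = NA_real_, r2 = NA_real_,
                             fitrange = fitrange,
                             reason = conditionMessage(fit))
    } else {
      out[[i]] <- cbind(data.frame(position = poss[i]), fit, reason = "")
      if (!is.null(plots_dir))
        plot_curve(plots_dir, poss[i], tt, y, fit, fitrange)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

plot_curve <- function(dir, pos, tt, y, fit, fitrange) {
  f <- file.path(dir, paste0("curve_", pos, ".png"))
  grDevices::png(f, width = 480, height = 360)
  on.exit(grDevices::dev.off())
  graphics::plot(tt, y, pch = 16, cex = 0.6, xlab = "time (h)",
                 ylab = "population proxy", main = pos)
  half <- (fitrange - 1) / 2
  sel <- tt >= fit$t_max - half * stats::median(diff(tt)) - 1e-9 &
    tt <= fit$t_max + half * stats::median(diff(tt)) + 1e-9
  graphics::abline(h = fit$y0, col = "grey60", lty = 2)
  if (is.finite(fit$lag))
    graphics::abline(a = fit$y0 - fit$max_slope * fit$lag, b = fit$max_slope,
                     col = "red3")
  graphics::points(tt[sel], y[sel], col = "red3", pch = 16, cex = 0.7)
  invisible(f)
}

#' Mean growth rate per sampling interval
#'
#' For every pair of consecutive timepoints, the mean over all positions of
#' the per-position rate (y[i+1] - y[i]) / (t[i+1] - t[i]). Summarises how
#' fast the plate as a whole is growing at each moment of the timecourse.
#'
#' @param table timecourse data.frame (first column `timepoint`)
#' @return data.frame with t_mid (interval midpoint, hours) and rate
#' @export
mean_growth_rate <- function(table) {
  stopifnot(is.data.frame(table), ncol(table) >= 2)
  tt <- table$timepoint
  if (length(tt) < 2) stop("at least 2 timepoints are required")
  y <- as.matrix(table[, -1, drop = FALSE])
  dt <- diff(tt)
  rates <- apply(y, 2, diff) / dt   # recycles dt down rows
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1)
  data.frame(t_mid = (tt[-1] + tt[-length(tt)]) / 2,
             rate = rowMeans(rates, na.rm = TRUE))
}
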