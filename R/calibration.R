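#' Exclude the most uncertain position estimates before calibration
#'
#' Removes fixes whose precision score (HPE) lies in the upper 5% of
#' the dataset, i.e. above the 95th percentile, before any error
#' calibration is attempted. The percentile uses linear interpolation
#' between order statistics (the default sample quantile).
#'
#' @param fixes a \code{position_fixes} data frame.
#' @param prob quantile defining the cutoff (default 0.95).
#' @return list with \code{fixes} (retained rows) and \code{hpe_cutoff}.
#' @export
exclude_extreme_hpe <- function(fixes, prob = 0.95) {
  if (nrow(fixes) == 0L) stop("no fixes supplied")
  if (nrow(fixes) < 20L) {
    warning("fewer than 20 fixes; HPE exclusion skipped")
    return(list(fixes = fixes, hpe_cutoff = max(fixes$hpe)))
  }
  cutoff <- unname(stats::quantile(fixes$hpe, prob, type = 7))
  keep <- fixes$hpe <= cutoff
  list(fixes = fixes[keep, , drop = FALSE], hpe_cutoff = cutoff)
}

#' Bin receiver-fix deviations and compute 2DRMS per HPE bin
#'
#' Receivers with surveyed GPS coordinates yield per-fix deviations
#' (dx, dy) = estimate - truth. Within each HPE bin \code{[k*w, (k+1)*w)}
#' the twice-distance-root-mean-squared statistic is
#' \deqn{2DRMS = 2 \sqrt{MSE_x + MSE_y}}
#' with MSE the mean squared deviation about the surveyed truth pooled
#' over all surveyed receivers (an accuracy, not precision, statistic).
#' Approximately the 95%-containment radius for bivariate normal error.
#'
#' @param receiver_fixes data frame with columns \code{hpe}, \code{dx},
#'   \code{dy} (m).
#' @param bin_width HPE bin width; default 1 (bins \code{[k, k+1)} with
#'   midpoint k + 0.5).
#' @return data frame (the bin table) with columns \code{lower},
#'   \code{mid}, \code{n}, \code{drms2}; empty bins omitted.
#' @export
compute_2drms_bins <- function(receiver_fixes, bin_width = 1) {
  if (is.null(receiver_fixes) || nrow(receiver_fixes) == 0L)
    stop("no surveyed receiver fixes: calibration impossible")
  stopifnot(all(c("hpe", "dx", "dy") %in% names(receiver_fixes)),
            bin_width > 0)
  k <- floor(receiver_fixes$hpe / bin_width)
  agg <- lapply(split(receiver_fixes, k), function(b) {
    data.frame(lower = floor(b$hpe[1L] / bin_width) * bin_width,
               n = nrow(b),
               drms2 = 2 * sqrt(mean(b$dx^2) + mean(b$dy^2)))
  })
  tab <- do.call(rbind, agg)
  tab$mid <- tab$lower + bin_width / 2
  tab <- tab[order(tab$lower), c("lower", "mid", "n", "drms2")]
  rownames(tab) <- NULL
  tab
}

#' Fit the linear HPE-to-meters calibration
#'
#' Ordinary least squares of per-bin 2DRMS on bin midpoints. The fitted
#' line converts the unitless HPE precision score of an animal fix into
#' an estimated absolute horizontal error in meters at the 95%
#' confidence level.
#'
#' @param bin_table output of \code{\link{compute_2drms_bins}}.
#' @param hpe_cutoff the 95th-percentile HPE cutoff applied upstream
#'   (stored for reporting; optional).
#' @return object of class \code{hpe_calibration}: list with
#'   \code{slope} (m per HPE unit), \code{intercept} (m),
#'   \code{hpe_cutoff} and \code{bin_table}.
#' @export
fit_hpe_regression <- function(bin_table, hpe_cutoff = NA_real_) {
  if (nrow(bin_table) < 2L)
    stop("need at least 2 non-empty HPE bins to fit the calibration")
  fit <- stats::lm(drms2 ~ mid, data = bin_table)
  co <- stats::coef(fit)
  model <- structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                          hpe_cutoff = hpe_cutoff, bin_table = bin_table),
                     class = "hpe_calibration")
  pred <- model$intercept + model$slope * range(bin_table$mid)
  if (any(pred < 0))
    warning("calibration predicts negative error within the fitted HPE range")
  model
}

#' @export
print.hpe_calibration <- function(x, ...) {
  cat("HPE calibration: error_m = ", signif(x$slope, 5), " * HPE + ",
      signif(x$intercept, 5), "\n", sep = "")
  cat("  fitted from ", nrow(x$bin_table), " bins; HPE cutoff ",
      signif(x$hpe_cutoff, 5), "\n", sep = "")
  invisible(x)
}

#' Apply a fitted calibration to animal fixes
#'
#' Adds the estimated metric error \code{hpe_m = slope * hpe +
#' intercept} to every fix. Negative predictions are clamped to zero
#' with a message reporting the count.
#'
#' @param fixes a \code{position_fixes} data frame.
#' @param model an \code{hpe_calibration}.
#' @return \code{fixes} with the \code{hpe_m} column filled.
#' @export
apply_calibration <- function(fixes, model) {
  stopifnot(inherits(model, "hpe_calibration"))
  hm <- model$slope * fixes$hpe + model$intercept
  nneg <- sum(hm < 0)
  if (nneg > 0) {
    message("apply_calibration: clamped ", nneg,
            " negative error estimate(s) to 0")
    hm <- pmax(hm, 0)
  }
  fixes$hpe_m <- hm
  fixes
}

#' Filter fixes by estimated metric error
#'
#' Removes fixes whose estimated error exceeds the threshold (10 m for
#' the movement analyses, 5 m for finer-scale distance-to-reef work).
#'
#' @param fixes calibrated fixes (\code{hpe_m} present).
#' @param threshold_m error threshold in meters (> 0).
#' @return list with \code{fixes} (retained) and \code{report}, a
#'   one-row data frame \code{threshold, n_in, n_out, retention}.
#' @export
filter_positions <- function(fixes, threshold_m) {
  if (!is.numeric(threshold_m) || threshold_m <= 0)
    stop("threshold must be a positive number of meters")
  if (anyNA(fixes$hpe_m))
    stop("hpe_m absent: run apply_calibration first")
  keep <- fixes$hpe_m <= threshold_m
  if (!any(keep)) warning("no fixes retained at threshold ", threshold_m, " m")
  report <- data.frame(threshold = threshold_m, n_in = nrow(fixes),
                       n_out = sum(keep),
                       retention = if (nrow(fixes)) sum(keep) / nrow(fixes)
                                   else NA_real_)
  list(fixes = fixes[keep, , drop = FALSE], report = report)
}

#' Absolute positioning error from a drift test
#'
#' A transmitter towed slowly through the array provides paired
#' positioning-system fixes and GPS truth. Each fix is compared with
#' the GPS position linearly interpolated to the fix time; the
#' Euclidean distance is the absolute error. Fixes outside the GPS
#' track's time span are excluded and counted.
#'
#' @param vps_fixes data frame with \code{t}, \code{x}, \code{y}.
#' @param gps_track data frame with \code{t}, \code{x}, \code{y},
#'   time-sorted.
#' @param region optional: either a character/factor vector (one label
#'   per fix, e.g. "centre"/"edge") or a function \code{f(x, y)}
#'   returning such labels, used to report regional mean errors.
#' @return list with \code{errors} (data frame \code{t, x, y, error}
#'   plus \code{region} when supplied), \code{n_excluded} and
#'   \code{region_means} (named vector, or overall mean when no region).
#' @export
drift_test_error <- function(vps_fixes, gps_track, region = NULL) {
  t0 <- as.numeric(gps_track$t)
  tf <- as.numeric(vps_fixes$t)
  inside <- tf >= min(t0) & tf <= max(t0)
  if (!any(inside)) stop("no temporal overlap between fixes and GPS track")
  fx <- vps_fixes[inside, , drop = FALSE]
  gx <- stats::approx(t0, gps_track$x, xout = as.numeric(fx$t))$y
  gy <- stats::approx(t0, gps_track$y, xout = as.numeric(fx$t))$y
  err <- sqrt((fx$x - gx)^2 + (fx$y - gy)^2)
  out <- data.frame(t = fx$t, x = fx$x, y = fx$y, error = err)
  if (!is.null(region)) {
    lab <- if (is.function(region)) region(fx$x, fx$y)
           else as.character(region)[inside]
    out$region <- lab
    means <- tapply(err, lab, mean)
  } else {
    means <- c(overall = mean(err))
  }
  list(errors = out, n_excluded = sum(!inside), region_means = means)
}
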