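#' Build release-reef residency records
#'
#' Converts visit events and fates into survival-analysis records of
#' time at the release reef. A fish departs (event = TRUE) at its first
#' visit to a reef other than the release reef, or at its emigration
#' fate time if it exits the array without switching first. Fish with
#' fates of predation, tag loss, harvest, surface mortality, unknown,
#' or still at large at study end are right-censored at their fate
#' time. Fish not alive and present for at least \code{min_days} days
#' after release are excluded (tagging-mortality screen).
#'
#' @param visits visit events from \code{\link{detect_visits}}.
#' @param fates fate table (see \code{\link{read_fates}}).
#' @param releases data frame with \code{fish_id}, \code{release_reef},
#'   \code{release_time} (POSIXct UTC); every fish in \code{fates} must
#'   appear here.
#' @param min_days minimum days alive and present for inclusion;
#'   default 4.
#' @return data frame of residency records: \code{fish_id},
#'   \code{duration} (days, > 0) and \code{event} (TRUE = departed).
#' @export
build_residency_records <- function(visits, fates, releases, min_days = 4) {
  censor_fates <- c("predation", "tag_loss", "harvest", "surface_mortality",
                    "unknown", "at_large")
  rows <- lapply(seq_len(nrow(fates)), function(i) {
    id <- fates$fish_id[i]
    rel <- releases[releases$fish_id == id, , drop = FALSE]
    if (nrow(rel) == 0L) stop("fish ", id, " has no release record")
    rt <- rel$release_time[1L]
    fate_days <- as.numeric(difftime(fates$fate_time[i], rt, units = "days"))
    if (fate_days < min_days) return(NULL)  # died at/after release
    v <- visits[visits$fish_id == id, , drop = FALSE]
    v <- v[order(v$t_start), , drop = FALSE]
    away <- v[v$reef_id != rel$release_reef[1L], , drop = FALSE]
    depart_days <- if (nrow(away) > 0L)
      as.numeric(difftime(away$t_start[1L], rt, units = "days")) else Inf
    if (depart_days <= fate_days) {
      data.frame(fish_id = id, duration = depart_days, event = TRUE)
    } else if (fates$fate[i] == "emigration") {
      data.frame(fish_id = id, duration = fate_days, event = TRUE)
    } else if (fates$fate[i] %in% censor_fates) {
      data.frame(fish_id = id, duration = fate_days, event = FALSE)
    } else {
      stop("unhandled fate '", fates$fate[i], "' for fish ", id)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(fish_id = character(), duration = numeric(),
                      event = logical())
  if (any(out$duration <= 0)) stop("non-positive residency duration")
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier estimate of release-reef residency
#'
#' Product-limit estimator of the probability a fish remains at its
#' release reef beyond time t:
#' \deqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}
#' with Greenwood variance and 95% confidence limits on the
#' complementary log-log scale (which keeps the bounds inside [0, 1]).
#' Ties between departures and censorings at the same time follow the
#' standard convention that events precede censorings.
#'
#' @param records residency records (\code{duration}, \code{event}).
#' @param conf confidence level; default 0.95.
#' @return object of class \code{km_curve}: data frame with one row per
#'   distinct event time (\code{time}, \code{n_risk}, \code{n_event},
#'   \code{surv}, \code{se}, \code{lower}, \code{upper}) and attributes
#'   \code{n} (records) and \code{conf}.
#' @export
km_estimate <- function(records, conf = 0.95) {
  if (nrow(records) == 0L) stop("no residency records")
  dur <- records$duration
  ev <- records$event
  times <- sort(unique(dur[ev]))
  if (length(times) == 0L) {
    warning("no departure events: survival curve is identically 1")
    out <- data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer(), surv = numeric(), se = numeric(),
                      lower = numeric(), upper = numeric())
    return(structure(out, class = c("km_curve", "data.frame"),
                     n = nrow(records), conf = conf))
  }
  n_risk <- vapply(times, function(t) sum(dur >= t), 0)
  d <- vapply(times, function(t) sum(dur == t & ev), 0)
  surv <- cumprod(1 - d / n_risk)
  gw <- cumsum(d / (n_risk * (n_risk - d)))  # Inf when a time exhausts risk
  se <- surv * sqrt(gw)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  # CI on log(-log S); undefined at S = 0 or 1
  ok <- surv > 0 & surv < 1 & is.finite(gw)
  se_cll <- ifelse(ok, sqrt(gw) / abs(log(surv)), NA_real_)
  lower <- ifelse(ok, surv^exp(z * se_cll), ifelse(surv == 0, 0, NA_real_))
  upper <- ifelse(ok, surv^exp(-z * se_cll), ifelse(surv == 0, 0, NA_real_))
  out <- data.frame(time = times, n_risk = n_risk, n_event = d, surv = surv,
                    se = se, lower = lower, upper = upper)
  structure(out, class = c("km_curve", "data.frame"),
            n = nrow(records), conf = conf)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier residency curve: ", attr(x, "n"), " fish, ",
      sum(x$n_event), " departures over ", nrow(x), " event times\n",
      sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Median residency time from a Kaplan-Meier curve
#'
#' The median is the smallest event time at which the survival estimate
#' drops to 0.5 or below. Its confidence interval is the range of event
#' times at which the confidence band brackets 0.5 (band-intersection
#' rule).
#'
#' @param curve a \code{km_curve}.
#' @return list with \code{t50} (days; NA with \code{reached = FALSE}
#'   when the curve never falls to 0.5), \code{ci_lower},
#'   \code{ci_upper} and \code{reached}.
#' @export
median_residency <- function(curve) {
  hit <- which(curve$surv <= 0.5)
  if (length(hit) == 0L)
    return(list(t50 = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                reached = FALSE))
  t50 <- curve$time[hit[1L]]
  band <- which(!is.na(curve$lower) & !is.na(curve$upper) &
                  curve$lower <= 0.5 & curve$upper >= 0.5)
  ci <- if (length(band)) range(curve$time[band]) else c(NA_real_, NA_real_)
  list(t50 = t50, ci_lower = ci[1L], ci_upper = ci[2L], reached = TRUE)
}

#' Site-fidelity algebra under exponential decay
#'
#' Assuming release-reef occupancy decays exponentially,
#' \eqn{\hat S(t) = e^{-t R_E}}, site fidelity over an interval
#' \eqn{t_{SF}} is \eqn{SF = e^{-t_{SF} R_E}}, so
#' \eqn{R_E = -\ln(SF)/t_{SF}} and the median residency is
#' \eqn{t_{50} = t_{SF} \ln(0.5) / \ln(SF)}. Annual fidelity (AF) is
#' the special case \eqn{t_{SF} = 365} days. Supply any one of
#' \code{sf} (with its \code{t_sf}), \code{r_e} or \code{t50}; the
#' remaining parameters are completed, mutually consistent to within
#' 1e-12.
#'
#' @param sf site-fidelity proportion in (0, 1]; requires \code{t_sf}.
#' @param t_sf interval over which \code{sf} is measured, days
#'   (default 365).
#' @param r_e daily emigration rate (>= 0).
#' @param t50 median residency, days (> 0).
#' @return object of class \code{fidelity_params}: list with \code{sf},
#'   \code{t_sf}, \code{r_e}, \code{t50}, \code{af}. \code{sf = 1}
#'   (or \code{r_e = 0}) gives infinite median residency.
#' @export
convert_fidelity <- function(sf = NULL, t_sf = 365, r_e = NULL, t50 = NULL) {
  given <- c(sf = !is.null(sf), r_e = !is.null(r_e), t50 = !is.null(t50))
  if (sum(given) != 1L)
    stop("supply exactly one of sf (with t_sf), r_e, or t50")
  if (!is.null(t_sf) && t_sf <= 0) stop("t_sf must be > 0")
  if (!is.null(sf)) {
    if (sf <= 0 || sf > 1) stop("sf must lie in (0, 1]")
    r_e <- -log(sf) / t_sf
  } else if (!is.null(t50)) {
    if (t50 <= 0) stop("t50 must be > 0")
    r_e <- log(2) / t50
  } else if (r_e < 0) {
    stop("r_e must be >= 0")
  }
  t50 <- if (r_e == 0) Inf else log(2) / r_e
  structure(list(sf = exp(-t_sf * r_e), t_sf = t_sf, r_e = r_e, t50 = t50,
                 af = exp(-365 * r_e)),
            class = "fidelity_params")
}

#' @export
print.fidelity_params <- function(x, ...) {
  cat("Site-fidelity parameters (exponential decay):\n",
      "  SF = ", signif(x$sf, 6), " over t_SF = ", x$t_sf, " d\n",
      "  R_E = ", signif(x$r_e, 6), " /d;  t50 = ", signif(x$t50, 6),
      " d;  AF = ", signif(x$af, 6), "\n", sep = "")
  invisible(x)
}
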