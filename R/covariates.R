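# Low-precision solar and lunar ephemerides (Astronomical Almanac
# reductions): apparent ecliptic longitudes good to ~0.01 deg (sun) and
# ~0.3 deg (moon), ample for phase and twilight work.

deg2rad <- function(d) d * pi / 180

julian_day <- function(t) as.numeric(t) / 86400 + 2440587.5

# centuries from J2000.0
.jcent <- function(t) (julian_day(t) - 2451545.0) / 36525

sun_ecliptic_longitude <- function(t) {
  T <- .jcent(t)
  L <- 280.460 + 36000.770 * T          # mean longitude
  g <- deg2rad(357.528 + 35999.050 * T) # mean anomaly
  (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) %% 360
}

moon_ecliptic_longitude <- function(t) {
  T <- .jcent(t)
  s <- function(a, b) sin(deg2rad(a + b * T))
  lam <- 218.316 + 481267.881 * T +
    6.29 * s(134.9, 477198.85) -
    1.27 * s(259.2, -413335.38) +
    0.66 * s(235.7, 890534.23) +
    0.21 * s(269.9, 954397.70) -
    0.19 * s(357.5, 35999.05) -
    0.11 * s(186.6, 966404.05)
  lam %% 360
}

#' Lunar phase as a fraction of the synodic cycle
#'
#' The geocentric elongation of the moon from the sun in ecliptic
#' longitude, expressed as radians divided by pi, so the value lies in
#' [0, 2): 0 is new moon, 0.5 first quarter, 1 full moon, 1.5 last
#' quarter. The quantity is 2-periodic and continuous across the wrap.
#'
#' @param t POSIXct timestamp(s), UTC.
#' @return numeric vector of phases in [0, 2).
#' @export
moon_phase <- function(t) {
  ((moon_ecliptic_longitude(t) - sun_ecliptic_longitude(t)) %% 360) / 180
}

# Solar declination (deg) and equation of time (minutes) at time t.
.solar_basis <- function(t) {
  T <- .jcent(t)
  L0 <- (280.46646 + 36000.76983 * T) %% 360
  M <- deg2rad((357.52911 + 35999.05029 * T) %% 360)
  e <- 0.016708634 - 0.000042037 * T
  C <- (1.914602 - 0.004817 * T) * sin(M) + 0.019993 * sin(2 * M) +
    0.000289 * sin(3 * M)
  lam <- deg2rad(L0 + C)
  eps <- deg2rad(23.439291 - 0.0130042 * T)
  dec <- asin(sin(eps) * sin(lam))
  y <- tan(eps / 2)^2
  eot <- 4 * (y * sin(2 * deg2rad(L0)) - 2 * e * sin(M) +
                4 * e * y * sin(M) * cos(2 * deg2rad(L0)) -
                0.5 * y^2 * sin(4 * deg2rad(L0)) -
                1.25 * e^2 * sin(2 * M)) * 180 / pi
  list(dec = dec, eot = eot)
}

# UTC hour (decimal) at which the sun crosses `alt` degrees; NA when it
# never does on that date. rising = TRUE for the morning crossing.
.sun_cross <- function(date, lat, lon, alt, rising) {
  noon_guess <- as.POSIXct(paste(format(date, "%Y-%m-%d"), "12:00:00"),
                           tz = "UTC") - lon * 240  # 4 min per degree
  # one refinement pass: recompute declination at the event estimate
  est <- noon_guess
  for (pass in 1:2) {
    sb <- .solar_basis(est)
    cosH <- (sin(deg2rad(alt)) - sin(deg2rad(lat)) * sin(sb$dec)) /
      (cos(deg2rad(lat)) * cos(sb$dec))
    if (abs(cosH) > 1) return(as.POSIXct(NA, tz = "UTC"))
    H <- acos(cosH) * 180 / pi  # degrees of hour angle
    solar_noon <- as.POSIXct(paste(format(date, "%Y-%m-%d"), "12:00:00"),
                             tz = "UTC") - lon * 240 - sb$eot * 60
    est <- solar_noon + (if (rising) -1 else 1) * H * 240
  }
  est
}

#' Twilight and sun rise/set intervals for a date and location
#'
#' Dawn is the interval from the commencement of morning nautical
#' twilight (sun at -12 degrees) to sunrise (sun at -0.833 degrees,
#' accounting for refraction and the solar disc); dusk runs from sunset
#' to the end of evening nautical twilight.
#'
#' @param date a Date (or coercible).
#' @param lat,lon degrees; north and east positive.
#' @return list with POSIXct (UTC) elements \code{dawn_start},
#'   \code{sunrise}, \code{sunset}, \code{dusk_end}. NA elements (with
#'   a warning) when the sun does not cross the relevant altitude on
#'   that date (polar conditions).
#' @export
twilight <- function(date, lat, lon) {
  date <- as.Date(date)
  out <- list(dawn_start = .sun_cross(date, lat, lon, -12, TRUE),
              sunrise = .sun_cross(date, lat, lon, -0.833, TRUE),
              sunset = .sun_cross(date, lat, lon, -0.833, FALSE),
              dusk_end = .sun_cross(date, lat, lon, -12, FALSE))
  if (anyNA(unlist(out)))
    warning("twilight undefined at latitude ", lat, " on ", date)
  out
}

#' Assemble the hourly covariate table for movement models
#'
#' Joins hourly behavioural responses (home range, height above
#' bottom, distance to reef) with temporal cycles (UTC hour, day of
#' year, lunar phase), the buoy meteorological series and receiver-
#' logged bottom temperature, by exact UTC hour. Missing environmental
#' hours propagate as NA; rows are never dropped for missing
#' covariates. Response transformations are left to the model layer.
#'
#' @param responses data frame with \code{fish_id}, \code{t} (POSIXct
#'   on whole UTC hours) and one or more response columns.
#' @param env an \code{env_series} from \code{\link{read_environment}}.
#' @param btemp optional data frame \code{t}, \code{bottom_temp}
#'   (deg C) from the centre receiver's log.
#' @param fish_lengths optional named numeric vector (mm) keyed by
#'   fish id, added as \code{fish_length}.
#' @return data frame: the response rows augmented with \code{hour}
#'   (0-23), \code{day_of_year} (1-366), \code{moon_phase} ([0, 2))
#'   and the environmental columns.
#' @export
assemble_covariate_table <- function(responses, env, btemp = NULL,
                                     fish_lengths = NULL) {
  rt <- as.POSIXct(trunc(responses$t, "hours"), tz = "UTC")
  if (!any(rt %in% env$t))
    stop("no overlapping hours between responses and environmental series")
  out <- responses
  out$hour <- as.integer(format(rt, "%H", tz = "UTC"))
  out$day_of_year <- as.integer(format(rt, "%j", tz = "UTC"))
  out$moon_phase <- moon_phase(rt)
  m <- match(rt, env$t)
  for (cl in c("wave_height", "wind_sustained", "wind_gust", "wind_dir",
               "pressure"))
    out[[cl]] <- env[[cl]][m]
  if (!is.null(btemp))
    out$bottom_temp <- btemp$bottom_temp[match(rt, btemp$t)]
  if (!is.null(fish_lengths))
    out$fish_length <- unname(fish_lengths[out$fish_id])
  out
}
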