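#' Simulation configuration
#'
#' Parameters of the synthetic seascape, fish behaviour and
#' observation model. Defaults emulate the study system the pipeline
#' is built for: a ~15 km^2 sandy-bottom array holding a few dozen
#' point reefs with mean nearest-neighbour spacing near 350 m,
#' receivers on a ~500 m grid, reef-attracted fish movement with diel
#' activity modulation, reef switching and exponential emigration, fix
#' intervals of minutes, and positional error growing from ~1 m mean
#' absolute error at the array centre to ~8 m at its far edge with an
#' HPE precision score linearly related to true error.
#'
#' @param seed integer; mandatory, drives every random draw.
#' @param extent side of the square array, m.
#' @param n_reefs number of point reefs.
#' @param min_reef_spacing minimum reef separation, m.
#' @param receiver_spacing receiver grid spacing, m.
#' @param margin inset of reefs from the array boundary, m.
#' @param depth_range seabed depth at the west and east edges, m
#'   (positive down; planar slope between them).
#' @param bathy_cellsize bathymetry cell size, m.
#' @param beta reef attraction rate, 1/s (Ornstein-Uhlenbeck pull).
#' @param sigma_b base step standard deviation, m per sqrt(s).
#' @param diel_mult length-24 activity multiplier on \code{sigma_b} by
#'   UTC hour (crepuscular-peaked by default).
#' @param lambda_switch reef-switch hazard, 1/day.
#' @param switch_dist_scale e-folding distance (m) of the preference
#'   for nearby reefs when switching.
#' @param r_e emigration hazard, 1/day (default ln 2 / 43).
#' @param censor_rates named daily hazards for the non-emigration
#'   fates (predation, tag_loss, harvest, unknown).
#' @param horizon_days study length, days; fish still present are
#'   classed at_large.
#' @param hab_profile length-24 mean height above bottom (m) by hour.
#' @param hab_sd,hab_phi sd and 1-s autocorrelation of the AR(1)
#'   height-above-bottom noise.
#' @param fix_interval range (s) of the uniform draw between fixes.
#' @param err_sd_centre,err_sd_edge per-axis positional error sd (m) at
#'   the array centre and corner; linear in radial distance between
#'   them (defaults give mean absolute errors near 1 m at the centre
#'   and 8 m at the far edge, the drift-test scale).
#' @param s_fix_sdlog lognormal sd of the per-fix variability of the
#'   error scale about its location value (positioning quality varies
#'   fix to fix with conditions, not just with location).
#' @param hpe_a,hpe_b slope and intercept of the true HPE-to-meters
#'   relation (error at 95% = hpe_a * HPE + hpe_b).
#' @param hpe_noise_sdlog lognormal noise on the emitted HPE score.
#' @param depth_sensor_sd depth sensor noise sd, m.
#' @param n_receiver_fixes self-fixes simulated per surveyed receiver.
#' @param t0 release time (POSIXct UTC) shared by the cohort.
#' @param dt_truth truth-trajectory resolution, s.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(seed,
                       extent = 3873, n_reefs = 34, min_reef_spacing = 150,
                       receiver_spacing = 500, margin = 300,
                       depth_range = c(28, 35), bathy_cellsize = 25,
                       beta = 0.001, sigma_b = 0.35,
                       diel_mult = {
                         m <- rep(1, 24); m[c(6:8, 18:20)] <- 1.5; m
                       },
                       lambda_switch = 0.2, switch_dist_scale = 500,
                       r_e = log(2) / 43,
                       censor_rates = c(predation = 0.002, tag_loss = 0.002,
                                        harvest = 0.001, unknown = 0.003),
                       horizon_days = 90,
                       hab_profile = {
                         h <- rep(1, 24); h[c(6:8, 18:20)] <- 2.5; h
                       },
                       hab_sd = 0.5, hab_phi = 0.999,
                       fix_interval = c(60, 180),
                       err_sd_centre = 0.8, err_sd_edge = 6.4,
                       s_fix_sdlog = 0.25,
                       hpe_a = 1.1, hpe_b = 0.5, hpe_noise_sdlog = 0.05,
                       depth_sensor_sd = 0.2, n_receiver_fixes = 400,
                       t0 = as.POSIXct("2016-05-01 00:00:00", tz = "UTC"),
                       dt_truth = 1) {
  if (missing(seed)) stop("seed is mandatory")
  nms <- names(formals(sim_config))
  for (nm in nms) force(get(nm))  # evaluate promises before capture
  cfg <- mget(nms, environment())
  stopifnot(beta >= 0, sigma_b >= 0, lambda_switch >= 0, r_e >= 0,
            all(censor_rates >= 0), min_reef_spacing < extent,
            length(diel_mult) == 24L, length(hab_profile) == 24L,
            fix_interval[1L] > 0, fix_interval[2L] >= fix_interval[1L],
            dt_truth > 0)
  class(cfg) <- "sim_config"
  cfg
}

# per-axis positional error sd by location: linear in radial distance
# from the array centre, err_sd_centre at 0 to err_sd_edge at the array
# corner (the farthest in-array point, so the relation never plateaus)
error_sd_at <- function(config, x, y) {
  cx <- config$extent / 2
  f <- pmin(1, sqrt((x - cx)^2 + (y - cx)^2) / (cx * sqrt(2)))
  config$err_sd_centre + (config$err_sd_edge - config$err_sd_centre) * f
}

#' Generate a synthetic seascape
#'
#' Reefs are placed by rejection sampling at no less than the minimum
#' spacing inside an inset margin; receivers sit on a regular grid
#' (nudged if one lands within 10 m of a reef); bathymetry is a planar
#' west-to-east slope.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{seascape} with \code{stations} (reefs +
#'   receivers), \code{bathy} (a \code{\link{bathy_grid}}) and
#'   \code{boundary} \code{c(xmin, xmax, ymin, ymax)}.
#' @export
generate_seascape <- function(config) {
  set.seed(config$seed)
  lo <- config$margin
  hi <- config$extent - config$margin
  rx <- ry <- numeric(0)
  attempts <- 0L
  while (length(rx) < config$n_reefs) {
    attempts <- attempts + 1L
    if (attempts > 10000L * config$n_reefs)
      stop("cannot place ", config$n_reefs, " reefs at spacing >= ",
           config$min_reef_spacing, " m in this extent")
    px <- stats::runif(1, lo, hi)
    py <- stats::runif(1, lo, hi)
    if (length(rx) == 0L ||
        min((rx - px)^2 + (ry - py)^2) >= config$min_reef_spacing^2) {
      rx <- c(rx, px); ry <- c(ry, py)
    }
  }
  reefs <- data.frame(
    station_id = sprintf("R%02d", seq_len(config$n_reefs)),
    kind = "reef", x = rx, y = ry, surveyed = FALSE,
    stringsAsFactors = FALSE)
  g <- seq(config$receiver_spacing / 2, config$extent,
           by = config$receiver_spacing)
  gx <- rep(g, times = length(g))
  gy <- rep(g, each = length(g))
  # keep receivers at least 10 m from any reef
  for (i in seq_along(gx)) {
    d <- sqrt(min((rx - gx[i])^2 + (ry - gy[i])^2))
    if (d < 10) gx[i] <- gx[i] + 15
  }
  recv <- data.frame(
    station_id = sprintf("S%02d", seq_along(gx)),
    kind = "receiver", x = gx, y = gy, surveyed = TRUE,
    stringsAsFactors = FALSE)
  pad <- 200
  nxy <- ceiling((config$extent + 2 * pad) / config$bathy_cellsize)
  xc <- -pad + (seq_len(nxy) - 0.5) * config$bathy_cellsize
  depth <- matrix(config$depth_range[1L] +
                    diff(config$depth_range) *
                    pmin(1, pmax(0, xc / config$extent)),
                  nrow = nxy, ncol = nxy)
  bathy <- bathy_grid(-pad, -pad, config$bathy_cellsize, depth)
  structure(list(stations = rbind(reefs, recv), bathy = bathy,
                 boundary = c(0, config$extent, 0, config$extent)),
            class = "seascape")
}

# Event layer of the behavioural model: competing exponential hazards
# for emigration and the censoring fates, plus the reef-switch schedule
# (Poisson switches to a distance-weighted random other reef). Caller
# controls the RNG state.
draw_fish_events <- function(config, reefs, release_reef) {
  t_emig <- if (config$r_e > 0) stats::rexp(1, config$r_e) else Inf
  cr <- config$censor_rates
  t_cens <- if (sum(cr) > 0) stats::rexp(1, sum(cr)) else Inf
  end_days <- min(t_emig, t_cens, config$horizon_days)
  if (t_emig <= t_cens && t_emig <= config$horizon_days) {
    fate <- "emigration"
  } else if (t_cens < config$horizon_days) {
    fate <- sample(names(cr), 1L, prob = cr)
  } else {
    fate <- "at_large"
  }
  sched_t <- 0
  sched_r <- release_reef
  if (config$lambda_switch > 0) {
    t <- stats::rexp(1, config$lambda_switch)
    while (t < end_days) {
      cur <- reefs[reefs$station_id == sched_r[length(sched_r)], ]
      others <- reefs[reefs$station_id != cur$station_id, , drop = FALSE]
      w <- exp(-sqrt((others$x - cur$x)^2 + (others$y - cur$y)^2) /
                 config$switch_dist_scale)
      sched_r <- c(sched_r, others$station_id[sample.int(nrow(others), 1L,
                                                         prob = w)])
      sched_t <- c(sched_t, t)
      t <- t + stats::rexp(1, config$lambda_switch)
    }
  }
  list(t_emig = t_emig, t_cens = t_cens, end_days = end_days, fate = fate,
       sched_t = sched_t, sched_r = sched_r)
}

#' Simulate the ground-truth trajectory of one fish
#'
#' Movement is an Euler-discretised Ornstein-Uhlenbeck pull toward the
#' current home reef,
#' \deqn{x_{t+\Delta} = x_t - \beta (x_t - r_t) \Delta +
#'       \sigma_b m(hour) \sqrt{\Delta}\, \epsilon,}
#' at 1-s resolution by default, with reef switches at a constant
#' hazard to a distance-weighted random reef and emigration at hazard
#' \code{r_e} (the fish then walks to the boundary and exits).
#' Non-emigration fates (predation, tag loss, harvest, unknown) arrive
#' as competing exponential hazards; fish still present at the horizon
#' are at_large. Depth follows the configured height-above-bottom
#' profile over the local seabed plus AR(1) noise. The same seed
#' reproduces the bundle exactly.
#'
#' @param seascape from \code{\link{generate_seascape}}.
#' @param config a \code{\link{sim_config}}.
#' @param fish_id label for the fish.
#' @param seed integer seed for this fish.
#' @param release_reef reef id; default a random reef.
#' @return list of class \code{truth_bundle}: \code{fish_id},
#'   \code{release_time}, \code{release_reef}, \code{schedule} (true
#'   reef occupancy: \code{reef_id}, \code{t_start_day}), \code{fate},
#'   \code{fate_days}, \code{emigration_days} (NA if none) and
#'   \code{traj} (data frame \code{t_sec}, \code{x}, \code{y},
#'   \code{depth} at truth resolution).
#' @export
simulate_fish <- function(seascape, config, fish_id = "F01", seed,
                          release_reef = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  reefs <- seascape$stations[seascape$stations$kind == "reef", , drop = FALSE]
  if (is.null(release_reef))
    release_reef <- reefs$station_id[sample.int(nrow(reefs), 1L)]
  ev <- draw_fish_events(config, reefs, release_reef)
  fate <- ev$fate
  end_days <- ev$end_days
  sched_t <- ev$sched_t
  sched_r <- ev$sched_r
  t_emig <- ev$t_emig
  dt <- config$dt_truth
  n <- max(2L, ceiling(end_days * 86400 / dt))
  tsec <- seq_len(n) * dt
  seg <- findInterval(tsec / 86400, sched_t)
  tx <- reefs$x[match(sched_r, reefs$station_id)][seg]
  ty <- reefs$y[match(sched_r, reefs$station_id)][seg]
  hod <- (floor((as.numeric(config$t0) %% 86400 + tsec) / 3600) %% 24) + 1L
  sdt <- config$sigma_b * config$diel_mult[hod] * sqrt(dt)
  a <- 1 - config$beta * dt
  x0 <- reefs$x[reefs$station_id == release_reef]
  y0 <- reefs$y[reefs$station_id == release_reef]
  x <- as.numeric(stats::filter(config$beta * dt * tx +
                                  stats::rnorm(n, 0, sdt),
                                a, "recursive", init = x0))
  y <- as.numeric(stats::filter(config$beta * dt * ty +
                                  stats::rnorm(n, 0, sdt),
                                a, "recursive", init = y0))
  emig_days <- NA_real_
  if (fate == "emigration") {
    emig_days <- end_days
    # walk out: strong pull toward the nearest boundary, 200 m beyond
    bx <- c(seascape$boundary[1L] - 200, seascape$boundary[2L] + 200,
            x[n], x[n])
    by <- c(y[n], y[n], seascape$boundary[3L] - 200,
            seascape$boundary[4L] + 200)
    k <- which.min((bx - x[n])^2 + (by - y[n])^2)
    ne <- ceiling(3600 / dt)
    xe <- as.numeric(stats::filter(0.002 * dt * bx[k] +
                                     stats::rnorm(ne, 0, config$sigma_b *
                                                    sqrt(dt)),
                                   1 - 0.002 * dt, "recursive", init = x[n]))
    ye <- as.numeric(stats::filter(0.002 * dt * by[k] +
                                     stats::rnorm(ne, 0, config$sigma_b *
                                                    sqrt(dt)),
                                   1 - 0.002 * dt, "recursive", init = y[n]))
    out <- which(xe < seascape$boundary[1L] | xe > seascape$boundary[2L] |
                   ye < seascape$boundary[3L] | ye > seascape$boundary[4L])
    ke <- if (length(out)) out[1L] else ne
    x <- c(x, xe[seq_len(ke)])
    y <- c(y, ye[seq_len(ke)])
    tsec <- c(tsec, n * dt + seq_len(ke) * dt)
    hod <- c(hod, (floor((as.numeric(config$t0) %% 86400 +
                            n * dt + seq_len(ke) * dt) / 3600) %% 24) + 1L)
    n <- n + ke
  }
  seabed <- bathy_depth_at(seascape$bathy, x, y)
  seabed[is.na(seabed)] <- mean(config$depth_range)
  hab <- config$hab_profile[hod] +
    as.numeric(stats::filter(stats::rnorm(n, 0, config$hab_sd *
                                            sqrt(1 - config$hab_phi^2)),
                             config$hab_phi, "recursive",
                             init = stats::rnorm(1, 0, config$hab_sd)))
  depth <- pmin(pmax(seabed - hab, 0.5), seabed - 0.1)
  structure(list(fish_id = fish_id, release_time = config$t0,
                 release_reef = release_reef,
                 schedule = data.frame(reef_id = sched_r,
                                       t_start_day = sched_t,
                                       stringsAsFactors = FALSE),
                 fate = fate,
                 fate_days = n * dt / 86400,
                 emigration_days = emig_days,
                 traj = data.frame(t_sec = tsec, x = x, y = y,
                                   depth = depth)),
            class = "truth_bundle")
}

#' Simulate positioning-system observations of a truth trajectory
#'
#' Fix times are drawn with uniform inter-fix intervals; each fix is
#' the true position plus isotropic Gaussian error whose per-axis sd
#' interpolates between the centre and edge values with radial
#' distance. The emitted HPE score inverts the assumed linear
#' error-to-HPE relation, \code{hpe = (2 sqrt(2) s - b) / a}, times
#' lognormal noise, so a linear calibration is recoverable from the
#' output by construction. Sensor depth gets additive Gaussian noise.
#'
#' @param truth a \code{truth_bundle}.
#' @param config the \code{\link{sim_config}} used to generate it.
#' @param seed integer seed.
#' @return list with \code{fixes} (a \code{position_fixes} data frame)
#'   and \code{true_error} (per-fix \code{s_true}, \code{dx},
#'   \code{dy}, \code{error}).
#' @export
simulate_observations <- function(truth, config, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  tmax <- max(truth$traj$t_sec)
  n_guess <- ceiling(tmax / config$fix_interval[1L]) + 1L
  gaps <- stats::runif(n_guess, config$fix_interval[1L],
                       config$fix_interval[2L])
  ft <- cumsum(gaps)
  ft <- ft[ft <= tmax]
  idx <- pmax(1L, round(ft / config$dt_truth))
  s <- error_sd_at(config, truth$traj$x[idx], truth$traj$y[idx]) *
    exp(stats::rnorm(length(idx), 0, config$s_fix_sdlog))
  dx <- stats::rnorm(length(idx), 0, s)
  dy <- stats::rnorm(length(idx), 0, s)
  hpe <- pmax(0.01, (2 * sqrt(2) * s - config$hpe_b) / config$hpe_a) *
    exp(stats::rnorm(length(idx), 0, config$hpe_noise_sdlog))
  fixes <- data.frame(
    fish_id = truth$fish_id,
    t = truth$release_time + truth$traj$t_sec[idx],
    x = truth$traj$x[idx] + dx, y = truth$traj$y[idx] + dy,
    depth = truth$traj$depth[idx] +
      stats::rnorm(length(idx), 0, config$depth_sensor_sd),
    hpe = hpe, hpe_m = NA_real_, stringsAsFactors = FALSE)
  class(fixes) <- c("position_fixes", "data.frame")
  list(fixes = fixes,
       true_error = data.frame(s_true = s, dx = dx, dy = dy,
                               error = sqrt(dx^2 + dy^2)))
}

#' Simulate receiver self-positioning fixes for calibration
#'
#' Surveyed receivers are positioned by the same observation model as
#' fish, yielding per-fix deviations from their known coordinates --
#' the input to \code{\link{compute_2drms_bins}}.
#'
#' @param seascape from \code{\link{generate_seascape}}.
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed.
#' @param n_per fixes per surveyed receiver; default from config.
#' @return data frame \code{station_id}, \code{hpe}, \code{dx},
#'   \code{dy}.
#' @export
simulate_receiver_fixes <- function(seascape, config, seed,
                                    n_per = config$n_receiver_fixes) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  rc <- seascape$stations[seascape$stations$kind == "receiver" &
                            seascape$stations$surveyed, , drop = FALSE]
  n <- nrow(rc) * n_per
  s <- rep(error_sd_at(config, rc$x, rc$y), each = n_per) *
    exp(stats::rnorm(n, 0, config$s_fix_sdlog))
  data.frame(station_id = rep(rc$station_id, each = n_per),
             hpe = pmax(0.01, (2 * sqrt(2) * s - config$hpe_b) /
                          config$hpe_a) *
               exp(stats::rnorm(n, 0, config$hpe_noise_sdlog)),
             dx = stats::rnorm(n, 0, s), dy = stats::rnorm(n, 0, s),
             stringsAsFactors = FALSE)
}

#' Simulate a tagged cohort end to end
#'
#' Generates the seascape, receiver calibration fixes and, for each
#' fish, a truth bundle and its observed fix table. Truth trajectories
#' are thinned (default to 60 s) in the returned bundles to keep the
#' object small; observations are drawn from the full-resolution truth.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_fish cohort size.
#' @param truth_thin keep every this-many-seconds truth sample in the
#'   returned bundles.
#' @return list of class \code{telemetry_sim}: \code{seascape},
#'   \code{receiver_fixes}, \code{fixes} (all fish), \code{truth}
#'   (list of thinned bundles), \code{fates}, \code{releases},
#'   \code{config}.
#' @export
simulate_cohort <- function(config, n_fish, truth_thin = 60) {
  seascape <- generate_seascape(config)
  set.seed(config$seed + 1L)
  seeds <- sample.int(.Machine$integer.max - 1L, n_fish + 1L)
  receiver_fixes <- simulate_receiver_fixes(seascape, config,
                                            seed = seeds[n_fish + 1L])
  truth <- vector("list", n_fish)
  fix_list <- vector("list", n_fish)
  for (i in seq_len(n_fish)) {
    id <- sprintf("F%03d", i)
    tb <- simulate_fish(seascape, config, fish_id = id, seed = seeds[i])
    obs <- simulate_observations(tb, config, seed = seeds[i] + 1L)
    fix_list[[i]] <- obs$fixes
    keep <- c(seq(1L, nrow(tb$traj), by = max(1L, round(truth_thin /
                                                          config$dt_truth))),
              nrow(tb$traj))
    tb$traj <- tb$traj[unique(keep), , drop = FALSE]
    truth[[i]] <- tb
  }
  fixes <- do.call(rbind, fix_list)
  class(fixes) <- c("position_fixes", "data.frame")
  fates <- data.frame(
    fish_id = vapply(truth, `[[`, "", "fish_id"),
    fate = vapply(truth, `[[`, "", "fate"),
    fate_time = config$t0 + 86400 * vapply(truth, `[[`, 0, "fate_days"),
    stringsAsFactors = FALSE)
  releases <- data.frame(
    fish_id = fates$fish_id,
    release_reef = vapply(truth, `[[`, "", "release_reef"),
    release_time = config$t0, stringsAsFactors = FALSE)
  structure(list(seascape = seascape, receiver_fixes = receiver_fixes,
                 fixes = fixes, truth = truth, fates = fates,
                 releases = releases, config = config),
            class = "telemetry_sim")
}

#' True visit and switch log from a truth trajectory
#'
#' Applies the 20-m visit rule directly to the noise-free trajectory,
#' sampled at the given times (e.g. the observation schedule), with an
#' independent run-collapse: a switch is a transition between maximal
#' same-reef visiting runs with different reef ids. This is the oracle
#' against which pipeline-detected visits and switches are validated.
#'
#' @param truth a \code{truth_bundle} (full-resolution trajectory).
#' @param seascape the \code{seascape} it was simulated in.
#' @param times_sec sample times (s since release); default every
#'   truth sample.
#' @param visit_radius m; default 20.
#' @return list with \code{n_visits}, \code{n_switches},
#'   \code{reef_seq} (reef id per visiting run).
#' @export
true_switch_log <- function(truth, seascape, times_sec = NULL,
                            visit_radius = 20) {
  tr <- truth$traj
  if (!is.null(times_sec)) {
    idx <- findInterval(times_sec, tr$t_sec, all.inside = TRUE)
    tr <- tr[idx, , drop = FALSE]
  }
  reefs <- seascape$stations[seascape$stations$kind == "reef", ,
                             drop = FALSE]
  reefs <- reefs[order(reefs$station_id), , drop = FALSE]
  seq_ids <- character(0)
  prev <- NA_character_
  for (start in seq(1L, nrow(tr), by = 100000L)) {
    idx <- start:min(nrow(tr), start + 99999L)
    d2 <- outer(tr$x[idx], reefs$x, "-")^2 + outer(tr$y[idx], reefs$y, "-")^2
    j <- max.col(-d2, ties.method = "first")
    on <- d2[cbind(seq_along(idx), j)] <= visit_radius^2
    lab <- ifelse(on, reefs$station_id[j], NA_character_)
    for (v in lab) {
      if (!is.na(v) && (is.na(prev) || v != prev)) seq_ids <- c(seq_ids, v)
      prev <- v
    }
  }
  list(n_visits = length(seq_ids),
       n_switches = if (length(seq_ids) < 2L) 0L
                    else sum(seq_ids[-1L] != seq_ids[-length(seq_ids)]),
       reef_seq = seq_ids)
}

#' Mean nearest-neighbour spacing among reefs
#' @param seascape a \code{seascape}.
#' @return mean distance (m) from each reef to its nearest neighbour.
#' @export
mean_nn_reef_spacing <- function(seascape) {
  r <- seascape$stations[seascape$stations$kind == "reef", , drop = FALSE]
  d <- as.matrix(stats::dist(r[, c("x", "y")]))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}
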