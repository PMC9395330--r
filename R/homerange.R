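#' Segment a track into movement steps
#'
#' Consecutive fixes of the same fish become one movement step when
#' their time difference is positive and at most \code{max_delay}
#' seconds; larger gaps break the trajectory and contribute no step.
#'
#' @param fixes time-sorted, error-filtered \code{position_fixes}.
#' @param max_delay maximum delay (s) between positions retained in the
#'   movement model; default 1500.
#' @return data frame of steps: \code{fish_id}, \code{t1}, \code{t2},
#'   \code{dt} (s), \code{x1}, \code{y1}, \code{z1}, \code{x2},
#'   \code{y2}, \code{z2} (z = sensor depth, NA when absent) and
#'   \code{s1}, \code{s2}: per-axis endpoint error sd (m) derived from
#'   \code{hpe_m} as hpe_m / (2 sqrt 2) (0 when uncalibrated), used
#'   only when the density builder is asked to include endpoint error.
#' @export
segment_track <- function(fixes, max_delay = 1500) {
  out <- lapply(split(seq_len(nrow(fixes)), fixes$fish_id), function(idx) {
    fx <- fixes[idx, , drop = FALSE]
    fx <- fx[order(fx$t), , drop = FALSE]
    n <- nrow(fx)
    if (n < 2L) return(NULL)
    dt <- as.numeric(difftime(fx$t[-1L], fx$t[-n], units = "secs"))
    keep <- which(dt > 0 & dt <= max_delay)
    if (length(keep) == 0L) return(NULL)
    s <- ifelse(is.na(fx$hpe_m), 0, fx$hpe_m / (2 * sqrt(2)))
    data.frame(fish_id = fx$fish_id[1L],
               t1 = fx$t[keep], t2 = fx$t[keep + 1L], dt = dt[keep],
               x1 = fx$x[keep], y1 = fx$y[keep], z1 = fx$depth[keep],
               x2 = fx$x[keep + 1L], y2 = fx$y[keep + 1L],
               z2 = fx$depth[keep + 1L],
               s1 = s[keep], s2 = s[keep + 1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    warning("fewer than 2 usable fixes: no movement steps")
    out <- data.frame(fish_id = character(), t1 = as.POSIXct(character()),
                      t2 = as.POSIXct(character()), dt = numeric(),
                      x1 = numeric(), y1 = numeric(), z1 = numeric(),
                      x2 = numeric(), y2 = numeric(), z2 = numeric(),
                      s1 = numeric(), s2 = numeric())
  }
  rownames(out) <- NULL
  out
}

# Per-step subintegration resolution: at least 10 nodes, one per 30 s.
default_n_sub <- function(dt) pmax(10L, as.integer(ceiling(dt / 30)))

#' Brownian-bridge movement-based utilization density
#'
#' Builds a gridded utilization distribution from movement steps. Each
#' step is modelled as a Brownian bridge pinned at its observed
#' endpoints: at relative time \eqn{\alpha \in (0,1)} the animal's
#' location is normal with mean \eqn{(1-\alpha) p_i + \alpha p_{i+1}}
#' and per-axis variance \eqn{\alpha (1-\alpha) \Delta t_i \sigma^2}
#' (plus \eqn{(1-\alpha)^2 s_i^2 + \alpha^2 s_{i+1}^2} when endpoint
#' error is included). The bridge is integrated over \eqn{\alpha} by
#' midpoint sampling of \code{n_sub} equal subintervals, each step
#' weighted by its duration, with a bivariate-normal kernel in two
#' dimensions and a trivariate-normal kernel (vertical axis = absolute
#' depth, variance \code{sigma2_z}) in three. Kernels are truncated at
#' five standard deviations; per-axis variance is floored at
#' cellsize^2 / 12 so midpoint sampling near the endpoints cannot
#' produce sub-cell kernels. The grid is renormalized to total mass 1.
#'
#' @param steps data frame from \code{\link{segment_track}} (>= 1 row).
#' @param dims 2 or 3.
#' @param cellsize grid cell edge, m; default 1.
#' @param sigma2_move horizontal movement variance, m^2/s; default
#'   0.14 (mid-point of observed red snapper swim speeds).
#' @param sigma2_z vertical movement variance, m^2/s; defaults to
#'   \code{sigma2_move}.
#' @param grid optional grid specification, a list with \code{x0},
#'   \code{y0}, \code{nx}, \code{ny} (and \code{z0}, \code{nz} in 3-D);
#'   when NULL a grid covering all endpoints with a 5-sigma margin is
#'   built, origin snapped to whole meters.
#' @param n_sub number of alpha subintervals per step; default
#'   \code{max(10, ceiling(dt / 30))} per step.
#' @param use_endpoint_error include per-fix positional error in the
#'   bridge variance? Default FALSE.
#' @param trunc_sd kernel truncation radius in standard deviations;
#'   default 5 (an efficiency cutoff; raise it when validating against
#'   untruncated integration).
#' @param bathy optional \code{\link{bathy_grid}}; in 3-D, cells above
#'   the sea surface or below the local seabed are zeroed and the grid
#'   renormalized.
#' @return object of class \code{bb_ud}: list with \code{mass} (matrix
#'   nx x ny, or array nx x ny x nz, summing to 1), \code{x0},
#'   \code{y0}, \code{z0}, \code{cellsize}, \code{dims},
#'   \code{total_time} (s).
#' @export
bb_density <- function(steps, dims = 2, cellsize = 1, sigma2_move = 0.14,
                       sigma2_z = sigma2_move, grid = NULL, n_sub = NULL,
                       use_endpoint_error = FALSE, bathy = NULL,
                       trunc_sd = 5) {
  stopifnot(dims %in% c(2L, 3L))
  if (nrow(steps) == 0L) stop("no movement steps supplied")
  if (dims == 3L && anyNA(c(steps$z1, steps$z2)))
    stop("3-D density requires sensor depth on every step endpoint")
  s1 <- if (use_endpoint_error) steps$s1 else rep(0, nrow(steps))
  s2 <- if (use_endpoint_error) steps$s2 else rep(0, nrow(steps))
  # worst-case per-axis sd over alpha, for margins and truncation
  vmax <- 0.25 * steps$dt * max(sigma2_move, if (dims == 3L) sigma2_z else 0) +
    pmax(s1, s2)^2
  sd_max <- sqrt(max(vmax, cellsize^2 / 12))
  margin <- trunc_sd * sd_max
  xr <- range(steps$x1, steps$x2)
  yr <- range(steps$y1, steps$y2)
  zr <- if (dims == 3L) range(steps$z1, steps$z2) else c(0, 0)
  if (is.null(grid)) {
    x0 <- floor(xr[1L] - margin); y0 <- floor(yr[1L] - margin)
    z0 <- floor(zr[1L] - margin)
    grid <- list(x0 = x0, y0 = y0, z0 = z0,
                 nx = ceiling((xr[2L] + margin - x0) / cellsize),
                 ny = ceiling((yr[2L] + margin - y0) / cellsize),
                 nz = ceiling((zr[2L] + margin - z0) / cellsize))
  } else {
    need_x <- c(xr[1L] - margin, xr[2L] + margin)
    need_y <- c(yr[1L] - margin, yr[2L] + margin)
    if (grid$x0 > need_x[1L] || grid$x0 + grid$nx * cellsize < need_x[2L] ||
        grid$y0 > need_y[1L] || grid$y0 + grid$ny * cellsize < need_y[2L])
      stop("grid too small: need x in [", round(need_x[1L], 1), ", ",
           round(need_x[2L], 1), "], y in [", round(need_y[1L], 1), ", ",
           round(need_y[2L], 1), "] with the truncation margin")
  }
  xc <- grid$x0 + (seq_len(grid$nx) - 0.5) * cellsize
  yc <- grid$y0 + (seq_len(grid$ny) - 0.5) * cellsize
  zc <- if (dims == 3L) grid$z0 + (seq_len(grid$nz) - 0.5) * cellsize
  mass <- if (dims == 2L) matrix(0, grid$nx, grid$ny)
          else array(0, c(grid$nx, grid$ny, grid$nz))
  vfloor <- cellsize^2 / 12
  n_floored <- 0L
  # index window of cells within trunc_sd sd of mu along an axis
  win <- function(centers, c0, mu, sd, n) {
    lo <- max(1L, floor((mu - trunc_sd * sd - c0) / cellsize) + 1L)
    hi <- min(n, ceiling((mu + trunc_sd * sd - c0) / cellsize))
    if (lo > hi) integer(0) else lo:hi
  }
  for (i in seq_len(nrow(steps))) {
    dt_i <- steps$dt[i]
    ns <- if (is.null(n_sub)) default_n_sub(dt_i) else as.integer(n_sub)
    alpha <- (seq_len(ns) - 0.5) / ns
    w <- dt_i / ns
    v_bb <- alpha * (1 - alpha) * dt_i
    v_ep <- (1 - alpha)^2 * s1[i]^2 + alpha^2 * s2[i]^2
    vxy <- v_bb * sigma2_move + v_ep
    n_floored <- n_floored + sum(vxy < vfloor)
    vxy <- pmax(vxy, vfloor)
    vz <- pmax(v_bb * sigma2_z + v_ep, vfloor)
    mux <- (1 - alpha) * steps$x1[i] + alpha * steps$x2[i]
    muy <- (1 - alpha) * steps$y1[i] + alpha * steps$y2[i]
    if (dims == 3L) muz <- (1 - alpha) * steps$z1[i] + alpha * steps$z2[i]
    for (j in seq_len(ns)) {
      sdx <- sqrt(vxy[j])
      ix <- win(xc, grid$x0, mux[j], sdx, grid$nx)
      iy <- win(yc, grid$y0, muy[j], sdx, grid$ny)
      if (length(ix) == 0L || length(iy) == 0L) next
      px <- stats::dnorm(xc[ix], mux[j], sdx)
      py <- stats::dnorm(yc[iy], muy[j], sdx)
      if (dims == 2L) {
        mass[ix, iy] <- mass[ix, iy] + w * (px %o% py)
      } else {
        sdz <- sqrt(vz[j])
        iz <- win(zc, grid$z0, muz[j], sdz, grid$nz)
        if (length(iz) == 0L) next
        pz <- stats::dnorm(zc[iz], muz[j], sdz)
        pxy <- w * (px %o% py)
        for (k in seq_along(iz))
          mass[ix, iy, iz[k]] <- mass[ix, iy, iz[k]] + pxy * pz[k]
      }
    }
  }
  if (n_floored > 0L)
    message("bb_density: variance floored at cellsize^2/12 in ", n_floored,
            " subinterval(s)")
  if (dims == 3L) {
    # physical bounds: no mass above the surface or under the seabed
    above <- zc < 0
    if (any(above)) mass[, , above] <- 0
    if (!is.null(bathy)) {
      seabed <- matrix(bathy_depth_at(bathy, rep(xc, length(yc)),
                                      rep(yc, each = length(xc))),
                       grid$nx, grid$ny)
      for (k in seq_along(zc)) {
        blk <- !is.na(seabed) & zc[k] > seabed
        if (any(blk)) mass[, , k][blk] <- 0
      }
    }
  }
  tot <- sum(mass)
  if (tot <= 0) stop("utilization grid has zero mass (all kernels clipped)")
  structure(list(mass = mass / tot, x0 = grid$x0, y0 = grid$y0,
                 z0 = if (dims == 3L) grid$z0 else NA_real_,
                 cellsize = cellsize, dims = dims,
                 total_time = sum(steps$dt)),
            class = "bb_ud")
}

#' @export
print.bb_ud <- function(x, ...) {
  cat("Brownian-bridge utilization distribution (", x$dims, "-D): ",
      paste(dim(x$mass), collapse = " x "), " cells of ", x$cellsize,
      " m over ", signif(x$total_time / 3600, 4), " h of movement\n",
      sep = "")
  invisible(x)
}

#' Extract a probability contour (home range) from a utilization grid
#'
#' The home range at level p is the smallest set of grid cells holding
#' at least a fraction p of the probability mass: cells are sorted by
#' mass descending and the shortest prefix reaching the level is taken,
#' with all cells tied at the threshold mass included. Area (2-D) or
#' volume (3-D) is the cell count times the cell measure.
#'
#' @param ud a \code{bb_ud}.
#' @param level probability level in (0, 1); default 0.95.
#' @return object of class \code{home_range}: list with \code{level},
#'   \code{area} (m^2, 2-D) or \code{volume} (m^3, 3-D), \code{n_cells},
#'   \code{mass} (total mass inside, >= level), \code{cells} (integer
#'   indices into the grid), \code{dims}, \code{cellsize}.
#' @export
kde_contour <- function(ud, level = 0.95) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must lie strictly between 0 and 1")
  v <- as.vector(ud$mass)
  ord <- order(v, decreasing = TRUE)
  cum <- cumsum(v[ord])
  k <- which(cum >= level)[1L]
  thr <- v[ord[k]]
  cells <- which(v >= thr & v > 0)
  measure <- length(cells) * ud$cellsize^ud$dims
  structure(list(level = level,
                 area = if (ud$dims == 2L) measure else NA_real_,
                 volume = if (ud$dims == 3L) measure else NA_real_,
                 n_cells = length(cells), mass = sum(v[cells]),
                 cells = cells, dims = ud$dims, cellsize = ud$cellsize),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  m <- if (x$dims == 2L) paste0(x$area, " m^2") else paste0(x$volume, " m^3")
  cat(100 * x$level, "% home range: ", m, " (", x$n_cells, " cells, mass ",
      signif(x$mass, 5), ")\n", sep = "")
  invisible(x)
}

#' Home ranges over aligned time windows
#'
#' Partitions each fish's movement steps into clock-aligned UTC windows
#' (each step belongs to the window containing its start time), builds
#' the Brownian-bridge utilization density per window, and extracts the
#' home-range contour. Windows without steps yield no estimate.
#'
#' @param fixes error-filtered \code{position_fixes} (10-m filter for
#'   the standard analyses).
#' @param window \code{"hour"}, \code{"day"}, \code{"full"} (whole
#'   track), or a width in seconds.
#' @param dims 2 or 3.
#' @param level contour probability; default 0.95.
#' @param max_delay step gap limit, s; default 1500.
#' @param ... passed to \code{\link{bb_density}} (\code{cellsize},
#'   \code{sigma2_move}, \code{sigma2_z}, \code{bathy}, ...).
#' @return data frame: \code{fish_id}, \code{window_start} (POSIXct),
#'   \code{n_steps}, \code{hr} (area m^2 in 2-D, volume m^3 in 3-D).
#' @export
windowed_home_range <- function(fixes, window = "day", dims = 2,
                                level = 0.95, max_delay = 1500, ...) {
  steps <- segment_track(fixes, max_delay = max_delay)
  if (nrow(steps) == 0L)
    return(data.frame(fish_id = character(),
                      window_start = as.POSIXct(character()),
                      n_steps = integer(), hr = numeric()))
  width <- switch(as.character(window), hour = 3600, day = 86400,
                  full = Inf, as.numeric(window))
  if (is.na(width) || width <= 0) stop("bad window specification")
  t1s <- as.numeric(steps$t1)
  wstart <- if (is.infinite(width)) rep(min(t1s), nrow(steps))
            else floor(t1s / width) * width
  grp <- split(seq_len(nrow(steps)), list(steps$fish_id, wstart), drop = TRUE)
  rows <- lapply(grp, function(idx) {
    st <- steps[idx, , drop = FALSE]
    ud <- bb_density(st, dims = dims, ...)
    hr <- kde_contour(ud, level = level)
    data.frame(fish_id = st$fish_id[1L],
               window_start = as.POSIXct(
                 if (is.infinite(width)) min(as.numeric(st$t1))
                 else floor(as.numeric(st$t1[1L]) / width) * width,
                 origin = "1970-01-01", tz = "UTC"),
               n_steps = nrow(st),
               hr = if (dims == 2L) hr$area else hr$volume,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fish_id, out$window_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
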