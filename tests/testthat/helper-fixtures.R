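# shared fixture builders; everything is constructed in code

t0_utc <- as.POSIXct("2016-05-01 00:00:00", tz = "UTC")

# build a position_fixes data frame from offsets in seconds
make_fixes <- function(t_sec, x, y, fish_id = "F1", depth = NA_real_,
                       hpe = 1, hpe_m = NA_real_, t0 = t0_utc) {
  fx <- data.frame(fish_id = fish_id, t = t0 + t_sec, x = x, y = y,
                   depth = depth, hpe = hpe, hpe_m = hpe_m,
                   stringsAsFactors = FALSE)
  class(fx) <- c("position_fixes", "data.frame")
  fx
}

make_steps <- function(dt, x1, y1, x2, y2, z1 = NA_real_, z2 = NA_real_,
                       s1 = 0, s2 = 0, t0 = t0_utc) {
  starts <- t0 + c(0, cumsum(dt))[seq_along(dt)]
  data.frame(fish_id = "F1", t1 = starts, t2 = starts + dt, dt = dt,
             x1 = x1, y1 = y1, z1 = z1, x2 = x2, y2 = y2, z2 = z2,
             s1 = s1, s2 = s2, stringsAsFactors = FALSE)
}

# independent brute-force Brownian-bridge density: trapezoid integration
# over alpha with n_nodes nodes, no kernel truncation, same variance
# floor (cell^2 / 12) as the model definition
bb_oracle <- function(steps, grid, cellsize = 1, sigma2 = 0.14,
                      n_nodes = 1e4) {
  xc <- grid$x0 + (seq_len(grid$nx) - 0.5) * cellsize
  yc <- grid$y0 + (seq_len(grid$ny) - 0.5) * cellsize
  mass <- matrix(0, grid$nx, grid$ny)
  alpha <- seq(0, 1, length.out = n_nodes + 1L)
  w_tr <- c(0.5, rep(1, n_nodes - 1L), 0.5) / n_nodes
  vfloor <- cellsize^2 / 12
  for (i in seq_len(nrow(steps))) {
    v <- pmax(alpha * (1 - alpha) * steps$dt[i] * sigma2, vfloor)
    mux <- (1 - alpha) * steps$x1[i] + alpha * steps$x2[i]
    muy <- (1 - alpha) * steps$y1[i] + alpha * steps$y2[i]
    for (j in seq_along(alpha)) {
      px <- stats::dnorm(xc, mux[j], sqrt(v[j]))
      py <- stats::dnorm(yc, muy[j], sqrt(v[j]))
      mass <- mass + steps$dt[i] * w_tr[j] * (px %o% py)
    }
  }
  mass / sum(mass)
}

# grid second moments about a point
grid_moment2 <- function(ud, cx, cy) {
  xc <- ud$x0 + (seq_len(nrow(ud$mass)) - 0.5) * ud$cellsize
  yc <- ud$y0 + (seq_len(ncol(ud$mass)) - 0.5) * ud$cellsize
  c(x = sum(ud$mass * outer((xc - cx)^2, rep(1, length(yc)))),
    y = sum(ud$mass * outer(rep(1, length(xc)), (yc - cy)^2)))
}

# small planar bathymetry for reef-metric tests
flat_bathy <- function(depth = 30, n = 10, cellsize = 100, x0 = 0, y0 = 0) {
  bathy_grid(x0, y0, cellsize, matrix(depth, n, n))
}
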