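test_that("track segmentation breaks at the maximum delay", {
  fx <- make_fixes(c(0, 600, 1200, 1800), x = 1:4, y = 0)
  expect_equal(nrow(segment_track(fx)), 3L)

  # a 1501-s gap excludes exactly that pair
  fx2 <- make_fixes(c(0, 1501, 2101), x = 1:3, y = 0)
  st2 <- segment_track(fx2)
  expect_equal(nrow(st2), 1L)
  expect_equal(st2$x1, 2)

  # gaps 100, 2000, 100 on 4 fixes -> 2 steps
  fx3 <- make_fixes(c(0, 100, 2100, 2200), x = 1:4, y = 0)
  expect_equal(nrow(segment_track(fx3)), 2L)

  # boundary: exactly 1500 s is retained
  fx4 <- make_fixes(c(0, 1500), x = 1:2, y = 0)
  expect_equal(nrow(segment_track(fx4)), 1L)

  expect_warning(st5 <- segment_track(make_fixes(0, 1, 1)), "fewer than 2")
  expect_equal(nrow(st5), 0L)
})

test_that("utilization grids normalize and weight steps by duration", {
  st <- make_steps(dt = c(300, 300, 300), x1 = c(0, 10, 20),
                   y1 = c(0, 5, 0), x2 = c(10, 20, 30), y2 = c(5, 0, 5))
  ud <- bb_density(st)
  expect_s3_class(ud, "bb_ud")
  expect_equal(sum(ud$mass), 1, tolerance = 1e-6)
  expect_true(all(ud$mass >= 0))

  # two distant steps with dt 100 vs 900: mass splits 1:9 by time
  st2 <- make_steps(dt = c(100, 900), x1 = c(0, 500), y1 = 0,
                    x2 = c(0, 500), y2 = 0)
  ud2 <- bb_density(st2)
  xc <- ud2$x0 + (seq_len(nrow(ud2$mass)) - 0.5) * ud2$cellsize
  near1 <- sum(ud2$mass[abs(xc - 0) < 100, ])
  near2 <- sum(ud2$mass[abs(xc - 500) < 100, ])
  expect_equal(near2 / near1, 9, tolerance = 0.01)

  # an explicit grid that cannot hold the kernels errors out
  expect_error(
    bb_density(st, grid = list(x0 = 0, y0 = 0, nx = 5, ny = 5)),
    "grid too small")
})

test_that("stationary-step density matches its alpha-mixture by Monte Carlo", {
  # 0.5-m cells keep cell-centre quadrature error well below the
  # Monte-Carlo comparison tolerance
  cs <- 0.5
  st <- make_steps(dt = 1000, x1 = 100, y1 = 100, x2 = 100, y2 = 100)
  ud <- bb_density(st, cellsize = cs)
  xc <- ud$x0 + (seq_len(nrow(ud$mass)) - 0.5) * cs
  yc <- ud$y0 + (seq_len(ncol(ud$mass)) - 0.5) * cs
  r2 <- outer((xc - 100)^2, (yc - 100)^2, "+")

  # radial symmetry: x and y marginals coincide
  expect_equal(rowSums(ud$mass)[abs(xc - 100) < 15],
               colSums(ud$mass)[abs(yc - 100) < 15], tolerance = 1e-6,
               ignore_attr = TRUE)

  # Monte-Carlo draw from the same alpha-mixture (independent oracle)
  set.seed(42)
  n <- 1e6
  a <- runif(n)
  v <- pmax(a * (1 - a) * 1000 * 0.14, cs^2 / 12)
  mx <- rnorm(n, 0, sqrt(v)); my <- rnorm(n, 0, sqrt(v))
  rmc2 <- mx^2 + my^2
  for (r in c(3, 6, 10)) {
    expect_equal(sum(ud$mass[r2 <= r^2]), mean(rmc2 <= r^2),
                 tolerance = 0.01)
  }
})

test_that("contours take the smallest cell set holding the level", {
  ud <- structure(list(mass = matrix(c(0.5, 0.3, 0.15, 0.05), 2, 2),
                       x0 = 0, y0 = 0, z0 = NA, cellsize = 1, dims = 2L,
                       total_time = 1), class = "bb_ud")
  hr <- kde_contour(ud, 0.95)
  expect_equal(hr$n_cells, 3L)
  expect_equal(hr$mass, 0.95)
  expect_equal(hr$area, 3)

  # uniform mass over N cells -> ceil(0.95 N)
  udu <- structure(list(mass = matrix(1 / 100, 10, 10), x0 = 0, y0 = 0,
                        z0 = NA, cellsize = 2, dims = 2L, total_time = 1),
                   class = "bb_ud")
  hru <- kde_contour(udu, 0.95)
  expect_equal(hru$n_cells, 100L)   # all tied at the threshold mass
  hru2 <- kde_contour(udu, 0.9)
  expect_equal(hru2$n_cells, 100L)

  ud1 <- structure(list(mass = matrix(1, 1, 1), x0 = 0, y0 = 0, z0 = NA,
                        cellsize = 1, dims = 2L, total_time = 1),
                   class = "bb_ud")
  expect_equal(kde_contour(ud1, 0.95)$n_cells, 1L)

  expect_error(kde_contour(ud, 1.5), "level")
  expect_error(kde_contour(ud, 0), "level")
})

test_that("doubling the subintegration resolution leaves the area stable", {
  st <- make_steps(dt = c(300, 600), x1 = c(0, 15), y1 = c(0, 10),
                   x2 = c(15, 25), y2 = c(10, -5))
  a1 <- kde_contour(bb_density(st, n_sub = 20))$area
  a2 <- kde_contour(bb_density(st, n_sub = 40))$area
  expect_lt(abs(a2 - a1) / a1, 0.01)
})

test_that("windowed home ranges match the direct full-track estimate", {
  set.seed(13)
  n <- 40
  fx <- make_fixes(seq_len(n) * 300, x = cumsum(rnorm(n, 0, 5)),
                   y = cumsum(rnorm(n, 0, 5)))
  whr <- windowed_home_range(fx, window = "full")
  direct <- kde_contour(bb_density(segment_track(fx)))
  expect_equal(nrow(whr), 1L)
  expect_equal(whr$hr, direct$area)

  # hourly windows: steps are assigned by start time; windows with no
  # steps yield no row
  whr2 <- windowed_home_range(fx, window = "hour")
  expect_true(all(whr2$n_steps >= 1))
  expect_equal(sum(whr2$n_steps), nrow(segment_track(fx)))
  expect_true(all(as.numeric(whr2$window_start) %% 3600 == 0))
})

test_that("3-D utilization marginalizes onto the 2-D grid", {
  st <- make_steps(dt = c(300, 300), x1 = c(0, 10), y1 = c(0, 8),
                   x2 = c(10, 18), y2 = c(8, 2), z1 = c(20, 22),
                   z2 = c(22, 21))
  g2 <- list(x0 = -40, y0 = -40, nx = 100, ny = 90)
  g3 <- c(g2, list(z0 = -20, nz = 80))
  ud2 <- bb_density(st, dims = 2, grid = g2)
  ud3 <- bb_density(st, dims = 3, grid = g3)
  marg <- apply(ud3$mass, c(1, 2), sum)
  big <- ud2$mass > 1e-9
  expect_lt(max(abs(marg[big] - ud2$mass[big]) / ud2$mass[big]), 0.01)

  # 3-D contour reports volume
  hr3 <- kde_contour(ud3)
  expect_true(is.na(hr3$area))
  expect_equal(hr3$volume, hr3$n_cells)
  expect_gte(hr3$mass, 0.95)
})

test_that("3-D densities clip to the water column when bathymetry given", {
  st <- make_steps(dt = 300, x1 = 50, y1 = 50, x2 = 60, y2 = 50,
                   z1 = 28, z2 = 29)
  b <- flat_bathy(depth = 30, n = 2, cellsize = 100)
  ud <- bb_density(st, dims = 3, bathy = b)
  zc <- ud$z0 + (seq_len(dim(ud$mass)[3]) - 0.5) * ud$cellsize
  below <- zc > 30
  expect_equal(sum(ud$mass[, , below]), 0)
  expect_equal(sum(ud$mass), 1, tolerance = 1e-6)
})
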