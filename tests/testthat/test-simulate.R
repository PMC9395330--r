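small_cfg <- function(seed, ...) {
  args <- list(seed = seed, extent = 2000, n_reefs = 8,
               min_reef_spacing = 150, receiver_spacing = 600,
               horizon_days = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("seascapes respect reef spacing and feasibility limits", {
  cfg <- small_cfg(1)
  ss <- generate_seascape(cfg)
  r <- ss$stations[ss$stations$kind == "reef", ]
  expect_equal(nrow(r), 8L)
  d <- as.matrix(dist(r[, c("x", "y")]))
  diag(d) <- Inf
  expect_gte(min(d), 150)
  expect_true(all(ss$stations$surveyed[ss$stations$kind == "receiver"]))

  # single reef is fine
  ss1 <- generate_seascape(sim_config(seed = 2, n_reefs = 1))
  expect_equal(sum(ss1$stations$kind == "reef"), 1L)

  # infeasible packing errors out
  expect_error(generate_seascape(sim_config(seed = 3, extent = 500,
                                            n_reefs = 50,
                                            min_reef_spacing = 400,
                                            margin = 50)),
               "cannot place")
})

test_that("default seascapes reproduce the observed reef spacing scale", {
  sp <- vapply(1:5, function(s)
    mean_nn_reef_spacing(generate_seascape(sim_config(seed = s))), 0)
  expect_true(all(abs(sp - 350) / 350 < 0.2))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_cfg(4)
  ss <- generate_seascape(cfg)
  tb1 <- simulate_fish(ss, cfg, seed = 10)
  tb2 <- simulate_fish(ss, cfg, seed = 10)
  expect_identical(tb1, tb2)
  ob1 <- simulate_observations(tb1, cfg, seed = 11)
  ob2 <- simulate_observations(tb2, cfg, seed = 11)
  expect_identical(ob1, ob2)
  expect_false(identical(simulate_fish(ss, cfg, seed = 12)$traj, tb1$traj))
})

test_that("strong reef attraction keeps the fish on its reef", {
  # OU stationary sd = sigma_b / sqrt(2 beta) = 0.35 / sqrt(0.008) ~ 3.9 m
  cfg <- small_cfg(5, beta = 0.004, lambda_switch = 0, r_e = 0,
                   censor_rates = c(predation = 0), horizon_days = 1,
                   diel_mult = rep(1, 24))
  ss <- generate_seascape(cfg)
  tb <- simulate_fish(ss, cfg, seed = 20)
  r <- ss$stations[ss$stations$station_id == tb$release_reef, ]
  dist <- sqrt((tb$traj$x - r$x)^2 + (tb$traj$y - r$y)^2)
  expect_gte(mean(dist <= 20), 0.99)
  # empirical sd near the OU stationary prediction
  expect_equal(sd(tb$traj$x), 0.35 / sqrt(2 * 0.004), tolerance = 0.15)
})

test_that("emigration times are exponential with the configured rate", {
  cfg <- sim_config(seed = 6, lambda_switch = 0,
                    censor_rates = c(predation = 0), horizon_days = Inf)
  ss <- generate_seascape(cfg)
  reefs <- ss$stations[ss$stations$kind == "reef", ]
  set.seed(99)
  tt <- replicate(1000, reefrange:::draw_fish_events(
    cfg, reefs, reefs$station_id[1])$t_emig)
  expect_equal(mean(tt), 43 / log(2), tolerance = 0.05)
})

test_that("observations degrade truth as configured", {
  cfg <- small_cfg(7, err_sd_centre = 0, err_sd_edge = 0,
                   depth_sensor_sd = 0, horizon_days = 1)
  ss <- generate_seascape(cfg)
  tb <- simulate_fish(ss, cfg, seed = 30)
  obs <- simulate_observations(tb, cfg, seed = 31)
  idx <- round(as.numeric(obs$fixes$t - tb$release_time, units = "secs"))
  expect_equal(obs$fixes$x, tb$traj$x[idx])
  expect_equal(obs$fixes$depth, tb$traj$depth[idx])
  expect_true(all(obs$true_error$error == 0))
  # zero error collapses the 2DRMS bins onto zero: fitted slope ~ 0
  rf <- simulate_receiver_fixes(ss, cfg, seed = 32, n_per = 50)
  m <- fit_hpe_regression(compute_2drms_bins(rf, bin_width = 0.002))
  expect_equal(m$slope, 0)
  expect_equal(m$intercept, 0)

  # fix cadence respects the configured interval range
  gaps <- diff(as.numeric(obs$fixes$t))
  expect_true(all(gaps >= 59 & gaps <= 181))
})

test_that("positional error grows from array centre to edge", {
  cfg <- sim_config(seed = 8)
  s_centre <- reefrange:::error_sd_at(cfg, cfg$extent / 2, cfg$extent / 2)
  s_mid_edge <- reefrange:::error_sd_at(cfg, 0, cfg$extent / 2)
  s_corner <- reefrange:::error_sd_at(cfg, 0, 0)
  expect_equal(s_centre, 0.8)
  expect_equal(s_corner, 6.4)
  expect_true(s_centre < s_mid_edge && s_mid_edge < s_corner)

  # a simulated drift test sees lower error in the centre
  ss <- generate_seascape(cfg)
  set.seed(41)
  tow_t <- seq(0, 14000, by = 20)
  gps <- data.frame(t = cfg$t0 + tow_t,
                    x = seq(100, cfg$extent - 100, length.out = length(tow_t)),
                    y = cfg$extent / 2)
  s <- reefrange:::error_sd_at(cfg, gps$x, gps$y)
  vps <- data.frame(t = gps$t, x = gps$x + rnorm(nrow(gps), 0, s),
                    y = gps$y + rnorm(nrow(gps), 0, s))
  cx <- cfg$extent / 2
  res <- drift_test_error(vps, gps,
                          region = function(x, y)
                            ifelse(abs(x - cx) < cfg$extent / 4,
                                   "centre", "edge"))
  expect_lt(res$region_means["centre"], res$region_means["edge"])
})

test_that("cohort simulation wires truth, fixes, fates and releases", {
  cfg <- small_cfg(9, horizon_days = 1, n_receiver_fixes = 20)
  sim <- simulate_cohort(cfg, n_fish = 3)
  expect_equal(length(sim$truth), 3L)
  expect_equal(nrow(sim$fates), 3L)
  expect_equal(sort(unique(sim$fixes$fish_id)), sim$fates$fish_id)
  expect_true(all(sim$releases$release_reef %in%
                    sim$seascape$stations$station_id))
  expect_true(all(c("hpe", "dx", "dy") %in% names(sim$receiver_fixes)))
  # depths lie inside the water column
  expect_true(all(sim$fixes$depth > 0))
})

test_that("the truth-derived switch log matches a hand-built trajectory", {
  ss <- generate_seascape(small_cfg(10))
  reefs <- ss$stations[ss$stations$kind == "reef", ]
  a <- reefs[1, ]; b <- reefs[2, ]
  # sit at reef a, transit, sit at reef b, return to a
  traj <- data.frame(
    t_sec = 1:8,
    x = c(a$x, a$x + 5, (a$x + b$x) / 2, b$x, b$x + 3, (a$x + b$x) / 2,
          a$x, a$x),
    y = c(a$y, a$y, (a$y + b$y) / 2, b$y, b$y, (a$y + b$y) / 2, a$y, a$y),
    depth = 20)
  tb <- structure(list(fish_id = "T", traj = traj), class = "truth_bundle")
  log <- true_switch_log(tb, ss)
  expect_equal(log$reef_seq,
               c(a$station_id, b$station_id, a$station_id))
  expect_equal(log$n_switches, 2L)
})
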