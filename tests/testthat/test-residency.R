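mk_releases <- function(ids, reef = "R1")
  data.frame(fish_id = ids, release_reef = reef, release_time = t0_utc,
             stringsAsFactors = FALSE)

mk_fate <- function(id, fate, days)
  data.frame(fish_id = id, fate = fate, fate_time = t0_utc + days * 86400,
             stringsAsFactors = FALSE)

mk_visit <- function(id, reef, day)
  data.frame(fish_id = id, reef_id = reef, t_start = t0_utc + day * 86400,
             t_end = t0_utc + day * 86400 + 600, n_fixes = 3L,
             stringsAsFactors = FALSE)

test_that("residency records apply the event and censor rules", {
  visits <- rbind(mk_visit("A", "R1", 1), mk_visit("A", "P", 43),
                  mk_visit("B", "R1", 2), mk_visit("C", "R1", 1))
  fates <- rbind(mk_fate("A", "at_large", 100),
                 mk_fate("B", "predation", 10),
                 mk_fate("C", "at_large", 60))
  rec <- build_residency_records(visits, fates, mk_releases(c("A", "B", "C")))

  # A switched to reef P on day 43
  expect_equal(rec$duration[rec$fish_id == "A"], 43)
  expect_true(rec$event[rec$fish_id == "A"])
  # B predated without leaving: censored at day 10
  expect_equal(rec$duration[rec$fish_id == "B"], 10)
  expect_false(rec$event[rec$fish_id == "B"])
  # C stayed to study end: censored
  expect_false(rec$event[rec$fish_id == "C"])
  expect_equal(rec$duration[rec$fish_id == "C"], 60)

  # emigration fate is an event even with no reef switch
  rec2 <- build_residency_records(mk_visit("D", "R1", 1),
                                  mk_fate("D", "emigration", 20),
                                  mk_releases("D"))
  expect_true(rec2$event)
  expect_equal(rec2$duration, 20)

  # the 4-day screen drops early deaths
  rec3 <- build_residency_records(visits[0, ],
                                  mk_fate("E", "surface_mortality", 0.5),
                                  mk_releases("E"))
  expect_equal(nrow(rec3), 0L)

  expect_error(
    build_residency_records(visits, mk_fate("Z", "at_large", 10),
                            mk_releases("A")),
    "no release record")
})

test_that("Kaplan-Meier matches hand-worked examples", {
  # all events at 2, 4, 4, 7
  rec <- data.frame(fish_id = letters[1:4], duration = c(2, 4, 4, 7),
                    event = TRUE)
  km <- km_estimate(rec)
  expect_equal(km$time, c(2, 4, 7))
  expect_equal(km$surv, c(0.75, 0.25, 0))
  expect_equal(km$n_risk, c(4, 3, 1))

  # censoring: event 2, censored 3, event 4
  rec2 <- data.frame(fish_id = letters[1:3], duration = c(2, 3, 4),
                     event = c(TRUE, FALSE, TRUE))
  km2 <- km_estimate(rec2)
  expect_equal(km2$surv, c(2 / 3, 0))

  # all censored: curve identically 1 (no event rows), with a warning
  rec3 <- data.frame(fish_id = letters[1:3], duration = c(2, 3, 4),
                     event = FALSE)
  expect_warning(km3 <- km_estimate(rec3), "no departure")
  expect_equal(nrow(km3), 0L)
})

test_that("with no censoring the KM curve equals 1 - ECDF", {
  set.seed(21)
  d <- round(rexp(200, 1 / 30), 2)
  rec <- data.frame(fish_id = as.character(seq_along(d)), duration = d,
                    event = TRUE)
  km <- km_estimate(rec)
  F <- ecdf(d)
  expect_equal(km$surv, 1 - F(km$time))
})

test_that("KM curve and Greenwood SE agree with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(33)
  d <- rexp(150, 1 / 40)
  ev <- runif(150) > 0.3
  rec <- data.frame(fish_id = as.character(seq_along(d)), duration = d,
                    event = ev)
  km <- km_estimate(rec)
  sf <- summary(survival::survfit(
    survival::Surv(d, ev) ~ 1, conf.type = "log-log"))
  expect_equal(km$time, sf$time)
  expect_equal(km$surv, sf$surv, tolerance = 1e-12)
  expect_equal(km$se, sf$std.err, tolerance = 1e-8)
  ok <- sf$surv > 0 & sf$surv < 1
  expect_equal(km$lower[ok], sf$lower[ok], tolerance = 1e-8)
  expect_equal(km$upper[ok], sf$upper[ok], tolerance = 1e-8)
})

test_that("median residency uses the first time the curve reaches 0.5", {
  rec <- data.frame(fish_id = letters[1:4], duration = c(2, 4, 4, 7),
                    event = TRUE)
  med <- median_residency(km_estimate(rec))
  expect_equal(med$t50, 4)
  expect_true(med$reached)

  # exactly 0.5 counts (<= rule)
  rec2 <- data.frame(fish_id = letters[1:2], duration = c(2, 5),
                     event = TRUE)
  expect_equal(median_residency(km_estimate(rec2))$t50, 2)

  # curve never reaches 0.5
  rec3 <- data.frame(fish_id = letters[1:4], duration = c(2, 10, 10, 10),
                     event = c(TRUE, FALSE, FALSE, FALSE))
  med3 <- median_residency(km_estimate(rec3))
  expect_false(med3$reached)
  expect_true(is.na(med3$t50))
})

test_that("site-fidelity algebra is mutually consistent", {
  # definition: SF = 0.5 over 100 d gives t50 = 100
  expect_equal(convert_fidelity(sf = 0.5, t_sf = 100)$t50, 100)
  # SF 0.25 over a year: ln 0.25 = 2 ln 0.5
  expect_equal(convert_fidelity(sf = 0.25, t_sf = 365)$t50, 182.5)
  # independent evaluation of 365 * ln 0.5 / ln 0.8
  fp <- convert_fidelity(sf = 0.8, t_sf = 365)
  expect_equal(fp$t50, 365 * log(0.5) / log(0.8), tolerance = 1e-12)
  expect_equal(fp$t50, 1133.9, tolerance = 1e-4)
  expect_equal(fp$af, 0.8)

  # round trips to 1e-12
  for (sf in c(0.1, 0.37, 0.8, 0.99)) {
    t50 <- convert_fidelity(sf = sf, t_sf = 365)$t50
    expect_equal(convert_fidelity(t50 = t50, t_sf = 365)$sf, sf,
                 tolerance = 1e-12)
  }
  # internal consistency: S(t50) = 0.5 under Eq-style decay
  fp2 <- convert_fidelity(r_e = 0.02, t_sf = 365)
  expect_equal(exp(-fp2$r_e * fp2$t50), 0.5, tolerance = 1e-12)

  # degenerate and invalid inputs
  expect_equal(convert_fidelity(sf = 1, t_sf = 365)$t50, Inf)
  expect_error(convert_fidelity(sf = 0, t_sf = 365), "sf")
  expect_error(convert_fidelity(sf = -1, t_sf = 365), "sf")
  expect_error(convert_fidelity(), "exactly one")
  expect_error(convert_fidelity(sf = 0.5, t50 = 10), "exactly one")
})

test_that("KM recovers exponential emigration with censoring", {
  # median stays inside the Greenwood-based CI under 30% censoring
  set.seed(77)
  t50_true <- 43
  hits <- 0L
  for (r in 1:100) {
    d <- rexp(1000, log(2) / t50_true)
    cens <- rexp(1000, log(2) / t50_true * 0.43)  # ~30% censored
    rec <- data.frame(fish_id = as.character(1:1000),
                      duration = pmin(d, cens), event = d <= cens)
    med <- median_residency(km_estimate(rec))
    if (!is.na(med$ci_lower) && med$ci_lower <= t50_true &&
        med$ci_upper >= t50_true) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})
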