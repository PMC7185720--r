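test_that("the identity curve behaves like its analytic definition", {
  cv <- toy_curve(c(0, 6000), 0)
  d <- calibrate(2400, 30, cv)
  expect_equal(median_year(d), 2400)
  # file round trip through the published-curve dialect
  f <- withr::local_tempfile(fileext = ".14c")
  write_curve(cv, f)
  cv2 <- load_curve(f)
  d2 <- calibrate(2400, 30, cv2)
  expect_equal(d2$years, d$years)
  expect_equal(d2$mass, d$mass)
  expect_error(toy_curve(c(100, 100)), "empty")
})

test_that("synthetic landscapes have the advertised structure", {
  u <- synth_landscape(20, 20, "uniform", value = 0.7)
  expect_true(all(u$suitability == 0.7))
  expect_true(all(u$settleable))
  g <- synth_landscape(20, 30, "gradient")
  expect_true(all(diff(g$suitability[5, ]) > 0))   # monotone along columns
  expect_true(all(g$suitability >= 0 & g$suitability <= 1))
  s1 <- synth_landscape(40, 40, "smooth", seed = 5)
  s2 <- synth_landscape(40, 40, "smooth", seed = 5)
  expect_identical(s1$suitability, s2$suitability)
  expect_equal(range(s1$suitability), c(0, 1))
  s3 <- synth_landscape(40, 40, "smooth", seed = 6)
  expect_false(identical(s1$suitability, s3$suitability))
  expect_error(synth_landscape(5, 5, "uniform"), "10 x 10")
})

test_that("synthetic dates encode a constant-speed expansion", {
  cv <- identity_curve()
  spec <- synth_spec(speed = 2, start = 4000, n_sites = 25,
                     max_distance_km = 1500, lab_sigma = 0, seed = 51)
  d <- synth_dates(spec, cv)
  expect_equal(nrow(d), 25)
  expect_equal(d$dist_km[1], 0)                 # first site at the origin
  expect_equal(d$true_calbp, round(4000 - d$dist_km / 2))
  expect_equal(d$age_bp, d$true_calbp)          # identity curve, no noise
  expect_true(all(d$sigma >= 1))
  # distances on the sphere agree with the generating distances
  gc <- great_circle_km(cbind(d$lon, d$lat), spec$origin)
  expect_equal(gc, d$dist_km, tolerance = 1e-6)
  # reproducibility
  expect_identical(synth_dates(spec, cv), d)
  # running off the calendar range is caught
  bad <- synth_spec(speed = 0.5, start = 900, n_sites = 10,
                    max_distance_km = 1500, lab_sigma = 0, seed = 1)
  expect_error(synth_dates(bad, cv), "calendar range")
  expect_error(synth_spec(speed = -1), "speed")
  expect_error(synth_spec(start = 400), "start")
  expect_error(synth_spec(n_sites = 3), "5")
})

test_that("closed-form arrival rasters follow the wave formula", {
  g <- synth_landscape(50, 50, "uniform")
  arr <- synth_arrival(g, c(25, 25), 1, 3000)
  expect_equal(arr[25, 25], 3000)
  expect_equal(arr[25, 35], 3000 - 100)     # 10 cells = 100 km at 1 km/yr
  arr2 <- synth_arrival(g, c(25, 25), 2, 3000)
  expect_equal(3000 - arr2[25, 35], (3000 - arr[25, 35]) / 2)
  # unsettleable cells stay unreached
  m <- g$suitability; m[1, ] <- 0
  g2 <- suit_grid(m, threshold = 0.5)
  expect_true(all(is.na(synth_arrival(g2, c(25, 25), 1, 3000)[1, ])))
  expect_error(synth_arrival(g, c(25, 25), 0, 3000), "speed")
})

test_that("date tables sampled from an arrival raster recover its speed", {
  cv <- identity_curve()
  g <- synth_landscape(120, 120, "uniform", center = c(-60, -5))
  arr <- synth_arrival(g, c(60, 60), 1.5, 3500)
  d <- dates_from_arrival(arr, g, c(60, 60), n_sites = 40, sigma = 30,
                          seed = 71)
  expect_equal(nrow(d), 40)
  expect_true(all(diff(sort(d$dist_km)) >= 0))
  expect_true(all(abs(d$age_bp - (3500 - d$dist_km / 1.5)) <= 0.5))
  res <- bootstrap_regression(d, c(-60, -5), 100, cv, n_iter = 199, seed = 1)
  expect_equal(unname(res$speed["mean"]), 1.5, tolerance = 0.05)
  expect_error(dates_from_arrival(matrix(NA_real_, 120, 120), g, c(60, 60)),
               "fewer settled")
})

test_that("the full pipeline closes: dates -> regression -> simulation -> fitness", {
  # Constant-speed dates at the simulator's own wave speed for a small
  # catchment (about 0.75 km/yr on a uniform landscape), regression-recovered
  # start, then simulations with matched (10 km) and speed-distorting (30 km)
  # catchments scored against the same dates.
  cv <- identity_curve()
  spec <- synth_spec(origin = c(-60, -5), speed = 0.75, start = 3000,
                     n_sites = 40, max_distance_km = 700, lab_sigma = 60,
                     seed = 61)
  dates <- synth_dates(spec, cv)
  reg <- bootstrap_regression(dates, spec$origin, 100, cv, n_iter = 199,
                              seed = 3)
  start_est <- round(unname(reg$intercept["mean"]))
  expect_gt(start_est, 2700)

  g <- synth_landscape(150, 150, "uniform", center = spec$origin)
  origin_cell <- grid_locate(spec$origin[1], spec$origin[2], g)
  es <- build_eval_set(dates, spec$origin, 100, g, cv)

  p10 <- sim_params(k_star = 60, catchment_km = 10, fission_threshold = 150,
                    leap_km = 0, permanence = 20)
  p30 <- sim_params(k_star = 60, catchment_km = 30, fission_threshold = 150,
                    leap_km = 0, permanence = 20)
  f10 <- fitness_score(run_expansion(p10, g, origin_cell, start_est,
                                     seed = 62)$arrival, es)$score
  f30 <- fitness_score(run_expansion(p30, g, origin_cell, start_est,
                                     seed = 62)$arrival, es)$score
  expect_gte(f10, 0.3)
  # the wide catchment roughly triples the front speed: worse match
  expect_gt(f10, f30)
})
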