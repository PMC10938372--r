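test_that("town generation is deterministic and respects monitor separation", {
  t1 <- make_town(town_config(), seed = 1)
  t2 <- make_town(town_config(), seed = 1)
  expect_identical(t1, t2)
  t3 <- make_town(town_config(), seed = 2)
  expect_false(identical(t1$monitors, t3$monitors))

  m <- t1$monitors
  d <- as.matrix(dist(cbind(m$x, m$y)))
  diag(d) <- Inf
  expect_true(all(d >= 500))
  expect_true(all(m$x >= 0 & m$x <= t1$domain[1]))
  expect_true(all(m$y >= 0 & m$y <= t1$domain[2]))
  expect_setequal(m$station_id, as.character(1:8))
})

test_that("impossible separation requests fail after bounded retries", {
  cfg <- town_config(domain = c(1000, 1000), n_monitors = 8,
                     min_separation = 900)
  expect_error(make_town(cfg, seed = 1), "placement error")
})

test_that("meteorology honours zero-noise and zero-precipitation limits", {
  p0 <- met_params(blh_noise = 0, bld_noise = 0, precip_noise = 0,
                   wind_noise = 0, t_noise = 0, t_amp = 0, sp_noise = 0,
                   tcc_noise = 0, ssr_noise = 0, spatial_noise = 0)
  met <- simulate_met(5, seed = 1, params = p0)
  blh <- met$value[met$variable == "blh"]
  expect_true(all(blh == 600))
  u <- met$value[met$variable == "u10"]
  expect_true(all(u == 1.5))

  pdry <- met_params(p_wet = 0)
  dry <- simulate_met(20, seed = 2, params = pdry)
  expect_true(all(dry$value[dry$variable %in% c("tp", "mtpr")] == 0))
})

test_that("wet-day frequency matches the occurrence probability", {
  met <- simulate_met(2000, seed = 11, params = met_params(p_wet = 0.3))
  tp <- met$value[met$variable == "tp" & met$point == "C"]
  wet_frac <- mean(tp > 0)
  expect_lt(abs(wet_frac - 0.3), 0.03) # binomial 3-sigma at n = 2000
})

test_that("met tables are reproducible and structurally valid", {
  m1 <- simulate_met(10, seed = 5)
  m2 <- simulate_met(10, seed = 5)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 10 * 9 * 12)
  expect_true(all(m1$value[m1$variable == "blh"] > 0))
})

test_that("the PM field reduces to the background when sources are off", {
  cfg <- town_config(alpha = setNames(rep(0, 8), road_category_names()),
                     bg_amp = 0)
  town <- make_town(cfg, seed = 3)
  met <- simulate_met(10, seed = 4)
  sim <- simulate_pm(town, met, noise_sd = 0, seed = 5)
  bg <- sim$components$background
  f <- sim$truth_field(c(1000, 5000, 11000), c(500, 3000, 5500), "pm10")
  for (j in 1:3) expect_equal(f[, j], bg, tolerance = 1e-12)
})

test_that("doubling boundary-layer height halves the road term exactly", {
  cfg <- town_config(bg_amp = 0)
  town <- make_town(cfg, seed = 6)
  met1 <- simulate_met(6, seed = 7, params = met_params(
    blh_mean = 400, blh_noise = 0, bld_noise = 0, precip_noise = 0, p_wet = 0,
    wind_noise = 0, t_noise = 0, sp_noise = 0, tcc_noise = 0, ssr_noise = 0,
    spatial_noise = 0))
  met2 <- simulate_met(6, seed = 7, params = met_params(
    blh_mean = 800, blh_noise = 0, bld_noise = 0, precip_noise = 0, p_wet = 0,
    wind_noise = 0, t_noise = 0, sp_noise = 0, tcc_noise = 0, ssr_noise = 0,
    spatial_noise = 0))
  s1 <- simulate_pm(town, met1, noise_sd = 0, seed = 8)
  s2 <- simulate_pm(town, met2, noise_sd = 0, seed = 8)
  x <- town$monitors$x[1]; y <- town$monitors$y[1]
  b1 <- s1$components$background
  c1 <- s1$truth_field(x, y, "pm10")[, 1] - b1
  c2 <- s2$truth_field(x, y, "pm10")[, 1] - s2$components$background
  if (all(c1 == 0)) skip("monitor 1 has no road term in this layout")
  expect_equal(c2 / c1, rep(0.5, 6), tolerance = 1e-12)
})

test_that("monitor truth equals the field at monitor locations, exactly", {
  st <- tiny_study()
  sim <- st$sim
  m <- st$town$monitors
  for (size in c("pm1", "pm25", "pm10")) {
    f <- sim$truth_field(m$x, m$y, size)
    for (j in seq_len(nrow(m))) {
      expect_equal(sim$monitor_truth[[m$station_id[j]]][[size]], f[, j],
                   tolerance = 1e-12)
    }
  }
})

test_that("monitors near dense roads read higher than remote ones at zero noise", {
  # flat background so road proximity is the only spatial signal
  town <- make_town(town_config(bg_amp = 0), seed = 9)
  met <- simulate_met(30, seed = 10)
  sim <- simulate_pm(town, met, noise_sd = 0, seed = 11)
  road <- sim$components$road_term
  means <- vapply(sim$monitor_truth, function(ms) mean(ms$pm25), numeric(1))
  hi <- which.max(road); lo <- which.min(road)
  expect_gt(road[hi], road[lo])
  expect_gt(means[hi], means[lo])
  expect_equal(order(road), order(means))
})

test_that("size fractions are ordered and coarse mass is a small share", {
  st <- tiny_study()
  ms <- st$sim$monitor_truth[[1]]
  expect_true(all(ms$pm1 <= ms$pm25 & ms$pm25 <= ms$pm10))
  expect_lt(mean((ms$pm10 - ms$pm25) / ms$pm10), 0.10)
})

test_that("sensor distortion follows its stated form and is reproducible", {
  ms <- daily_series(20, pm25 = seq(2, 40, length.out = 20))
  ident <- distort_sensor(ms, params = list(a0 = 0, a1 = 1, a2 = 0,
                                            b1 = 0, noise_sd = 0), seed = 1)
  expect_equal(ident$pm25, ms$pm25, tolerance = 1e-12)

  quad <- distort_sensor(ms, params = list(a0 = 1, a1 = 0.5, a2 = 0.01,
                                           b1 = 0, noise_sd = 0), seed = 1)
  v <- ms$pm25[c(1, 10, 20)]
  expect_equal(quad$pm25[c(1, 10, 20)], 1 + 0.5 * v + 0.01 * v^2,
               tolerance = 1e-12)
  # strict convexity: the response at the midpoint input lies below the chord
  mid <- (quad$pm25[1] + quad$pm25[20]) / 2
  at_mid <- 1 + 0.5 * mean(v[c(1, 3)]) + 0.01 * mean(v[c(1, 3)])^2
  expect_lt(at_mid, mid)

  n1 <- distort_sensor(ms, seed = 33)
  n2 <- distort_sensor(ms, seed = 33)
  expect_identical(n1$pm25, n2$pm25)
})

test_that("a written town re-reads into consistent inputs", {
  st <- tiny_study()
  dir <- withr::local_tempdir()
  write_town(st$town, st$met, st$sim, dir)
  stations <- read_station_table(file.path(dir, "stations.csv"))
  expect_equal(nrow(stations), 8)
  ms <- read_monitor_csv(file.path(dir, "monitor_1.csv"), stations, "1")
  expect_equal(ms$pm25, st$sim$monitor_truth[["1"]]$pm25, tolerance = 1e-6)
  met <- read_met(file.path(dir, "met.csv"))
  expect_equal(nrow(met), nrow(st$met))
  manifest <- jsonlite::read_json(file.path(dir, "truth_manifest.json"))
  expect_equal(manifest$seed, st$town$seed)
})
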