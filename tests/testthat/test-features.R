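test_that("the default configuration yields exactly 151 uniquely named features", {
  nm <- feature_names(feature_config())
  expect_length(nm, 151)
  expect_equal(anyDuplicated(nm), 0)
})

test_that("feature blocks are individually switchable", {
  cfg <- feature_config(blocks = c(calendar = TRUE, doy = FALSE,
                                   position = TRUE, wind = FALSE, met = FALSE,
                                   network = TRUE, roads = TRUE))
  nm <- feature_names(cfg)
  expect_length(nm, 2 + 2 + 3 + 18 + 3 + 3 + 8)
  expect_false(any(grepl("^blh|^doy", nm)))
})

test_that("wind concordance distinguishes upwind from downwind", {
  # wind from due north; monitor due north of the point is upwind
  expect_equal(wind_concordance(0, u = 0, v = -1), 1L)
  # same wind, monitor due south: downwind
  expect_equal(wind_concordance(180, u = 0, v = -1), 0L)
  # 90-degree angular difference sits on the inclusive upwind boundary
  expect_equal(wind_concordance(90, u = 0, v = -1), 1L)
  # calm wind convention
  expect_equal(wind_concordance(45, u = 0, v = 0), 0L)
})

test_that("reversing the wind flips concordance except at the boundary", {
  set.seed(31)
  b <- runif(300, 0, 360)
  u <- rnorm(300); v <- rnorm(300)
  wfrom <- (atan2(-u, -v) * 180 / pi) %% 360
  diff <- abs(((wfrom - b + 180) %% 360) - 180)
  off_boundary <- abs(diff - 90) > 1e-6
  a <- wind_concordance(b, u, v)
  r <- wind_concordance(b, -u, -v)
  expect_true(all((a + r)[off_boundary] == 1))
})

test_that("nearest monitors order by distance with id tie-breaks", {
  cand <- tibble::tibble(
    station_id = c("5", "1", "3", "2", "4"),
    x = c(0, 100, 100, 100, 500), y = c(0, 0, 0, 0, 0)
  )
  nb <- nearest_monitors(c(0, 0), cand, k = 3, exclude = "5")
  expect_equal(nb$station_id, c("1", "2", "3")) # equidistant -> id order
  expect_equal(nb$distance, rep(100, 3))

  nb2 <- nearest_monitors(c(0, 0), cand, k = 3)
  expect_equal(nb2$station_id[1], "5") # colocated candidate wins
  expect_error(nearest_monitors(c(0, 0), cand[1:2, ], k = 3),
               "configuration error")
})

test_that("idw matches its closed form and the exact-hit rule", {
  expect_equal(idw(c(0, 6), c(1, 2)), 1.2)
  expect_equal(idw(c(3, 9, 12), c(50, 50, 50)), 8) # symmetry -> mean
  expect_equal(idw(c(5, 9), c(0, 800)), 5)          # exact hit
  expect_error(idw(numeric(0), numeric(0)), "value error")
})

test_that("idw agrees with a brute-force oracle on 1000 random triples", {
  set.seed(97)
  worst <- 0
  for (i in 1:1000) {
    v <- rnorm(3, 10, 4)
    d <- runif(3, 1.5, 5000)
    w <- 1 / d^2
    oracle <- sum(w * v) / sum(w)
    worst <- max(worst, abs(idw(v, d) - oracle))
  }
  expect_lt(worst, 1e-12)
})

test_that("rasterization conserves vertex counts and densities count windows", {
  sq <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  layers <- list(
    road_layer(list(sq(10, 10, 20, 20, 30, 30, 40, 40, 50, 50)), "A Road"),
    road_layer(list(sq(5000, 5000, 5010, 5010)), "Motorway")
  )
  r <- rasterize_roads(layers, resolution = 4)
  expect_equal(sum(r[["A Road"]]$n), 5)
  expect_equal(sum(r[["Motorway"]]$n), 2)
  expect_equal(sum(r[["B Road"]]$n), 0)

  d <- road_density(r, cbind(30, 30), window = 200)
  expect_equal(unname(d[1, "road_a_road"]), 5) # all five vertices inside
  expect_equal(unname(d[1, "road_motorway"]), 0)
  far <- road_density(r, cbind(30, 3000), window = 200)
  expect_equal(unname(far[1, "road_a_road"]), 0)
})

test_that("raster conservation holds on generated road networks", {
  st <- tiny_study()
  r <- st$raster
  for (cat_name in names(st$town$roads)) {
    nv <- sum(vapply(st$town$roads[[cat_name]]$lines, nrow, integer(1)))
    expect_equal(sum(r[[cat_name]]$n), nv)
  }
})

test_that("feature vectors have the contracted length, order and values", {
  st <- tiny_study()
  mons <- st$sim$monitor_truth
  fv <- build_feature_vector(c(3000, 2000), st$sim$dates[5], mons, st$met,
                             st$raster)
  expect_length(fv, 151)
  expect_identical(names(fv), feature_names(feature_config()))
  expect_true(all(is.finite(fv)))
  expect_equal(unname(fv["easting"]), 3000)

  # identical constant concentrations: average = idw = nearest, difference 0
  const_mons <- lapply(mons, function(ms) {
    out <- tibble::as_tibble(as.data.frame(ms))
    out$pm1 <- 4; out$pm25 <- 5; out$pm10 <- 6
    res <- monitor_series(out, attr(ms, "station_id"), attr(ms, "latitude"),
                          attr(ms, "longitude"), step = "day")
    attr(res, "x") <- attr(ms, "x"); attr(res, "y") <- attr(ms, "y")
    res
  })
  fv2 <- build_feature_vector(c(3000, 2000), st$sim$dates[5], const_mons,
                              st$met, st$raster)
  expect_equal(unname(fv2[c("avg_pm25", "idw_pm25", "nb1_pm25")]), rep(5, 3))
  expect_equal(unname(fv2[c("avgdiff_pm1", "avgdiff_pm25", "avgdiff_pm10")]),
               rep(0, 3))

  # co-located with a monitor: the exact-hit rule pins idw to its values
  m1 <- mons[[1]]
  fv3 <- build_feature_vector(c(attr(m1, "x"), attr(m1, "y")),
                              st$sim$dates[5], mons, st$met, st$raster)
  expect_equal(unname(fv3["idw_pm25"]), m1$pm25[5], tolerance = 1e-12)
})

test_that("feature order is stable across rows, calls and point sets", {
  st <- tiny_study()
  mons <- st$sim$monitor_truth
  pts <- tibble::tibble(point_id = c("a", "b"), x = c(1000, 9000),
                        y = c(1000, 5000))
  t1 <- build_feature_table(pts, st$sim$dates[1:5], mons, st$met, st$raster)
  t2 <- build_feature_table(pts[2:1, ], st$sim$dates[1:5], mons, st$met,
                            st$raster)
  expect_identical(attr(t1, "feature_names"), attr(t2, "feature_names"))
  expect_identical(attr(t1, "feature_names"), feature_names(feature_config()))
  a1 <- t1[t1$point_id == "a" & t1$date == st$sim$dates[2], ]
  a2 <- t2[t2$point_id == "a" & t2$date == st$sim$dates[2], ]
  expect_equal(as.data.frame(a1), as.data.frame(a2))
})

test_that("train tables exclude the target station from its own features", {
  st <- tiny_study()
  mons <- st$sim$monitor_truth
  split <- list(train = c("1", "3", "4", "5", "6"), eval = c("2", "7", "8"))
  tabs <- build_tables(mons, st$met, st$raster, split)
  expect_equal(nrow(tabs$train), 5 * length(st$sim$dates))
  expect_equal(nrow(tabs$eval), 3 * length(st$sim$dates))

  # train row for station 1: its own pm25 must not enter avg or neighbours
  r1 <- tabs$train[tabs$train$point_id == "1", ]
  d5 <- st$sim$dates[5]
  own <- mons[["1"]]$pm25[5]
  others <- vapply(split$train[-1], function(s) mons[[s]]$pm25[5], numeric(1))
  expect_equal(r1$avg_pm25[r1$date == d5], mean(others), tolerance = 1e-12)
  expect_false(any(abs(r1[r1$date == d5,
                          c("nb1_pm25", "nb2_pm25", "nb3_pm25")] - own) < 1e-9))
})

test_that("evaluation features are invariant to eval-station concentrations", {
  st <- tiny_study()
  mons <- st$sim$monitor_truth
  split <- list(train = c("1", "3", "4", "5", "6"), eval = c("2", "7", "8"))
  tabs <- build_tables(mons, st$met, st$raster, split)

  permuted <- mons
  for (s in split$eval) {
    out <- tibble::as_tibble(as.data.frame(mons[[s]]))
    set.seed(5)
    idx <- sample(nrow(out))
    out$pm1 <- out$pm1[idx]; out$pm25 <- out$pm25[idx]
    out$pm10 <- out$pm10[idx]
    res <- monitor_series(out, attr(mons[[s]], "station_id"),
                          attr(mons[[s]], "latitude"),
                          attr(mons[[s]], "longitude"), step = "day")
    attr(res, "x") <- attr(mons[[s]], "x"); attr(res, "y") <- attr(mons[[s]], "y")
    permuted[[s]] <- res
  }
  tabs2 <- build_tables(permuted, st$met, st$raster, split)
  fn <- attr(tabs$eval, "feature_names")
  expect_identical(as.matrix(tabs$eval[, fn]), as.matrix(tabs2$eval[, fn]))
  # the targets do change
  expect_false(identical(tabs$eval$pm25, tabs2$eval$pm25))

  expect_error(build_tables(mons, st$met, st$raster,
                            list(train = c("1", "2", "3", "4"), eval = "2")),
               "configuration error")
})
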