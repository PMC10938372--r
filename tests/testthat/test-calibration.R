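make_coloc <- function(n = 120, seed = 1, noise_sd = 0,
                       params = list(a0 = 2, a1 = 0.8, a2 = 0, b1 = 0.01,
                                     noise_sd = 0)) {
  params$noise_sd <- noise_sd
  set.seed(seed)
  truth <- exp(rnorm(n, log(10), 0.5))
  temperature <- runif(n, 2, 28)
  rh <- runif(n, 40, 98)
  noise <- if (noise_sd == 0) 0 else rnorm(n, 0, noise_sd)
  raw <- params$a0 + params$a1 * truth + params$a2 * truth^2 +
    params$b1 * rh * truth + noise
  list(truth = truth, raw = raw, temperature = temperature, rh = rh)
}

test_that("degree-2 expansion enumerates the nine polynomial terms", {
  z <- calibration_terms(1:5, 6:10, 11:15, degree = 2)
  expect_equal(ncol(z), 9)
  expect_setequal(colnames(z),
                  c("raw", "temp", "rh", "raw^2", "temp^2", "rh^2",
                    "raw*temp", "raw*rh", "temp*rh"))
  expect_equal(z[, "raw*rh"], (1:5) * (11:15))
  expect_equal(ncol(calibration_terms(1:5, 6:10, 11:15, degree = 1)), 3)
})

test_that("identity data recovers the identity at the weak-penalty end", {
  d <- make_coloc(n = 60, params = list(a0 = 0, a1 = 1, a2 = 0, b1 = 0,
                                        noise_sd = 0))
  m <- fit_calibration(d$truth, d$truth, d$temperature, d$rh, degree = 1,
                       penalty_grid = 1e-8)
  pred <- apply_calibration(m, d$truth, d$temperature, d$rh)
  expect_lt(max(abs(pred - d$truth)), 1e-6)
})

test_that("ridge at zero penalty and degree 1 coincides with least squares", {
  set.seed(21)
  n <- 20
  raw <- runif(n, 2, 30); temperature <- runif(n, 5, 25); rh <- runif(n, 40, 95)
  y <- 1.5 + 0.9 * raw - 0.1 * temperature + 0.02 * rh + rnorm(n, 0, 0.5)
  m <- suppressWarnings(fit_calibration(raw, y, temperature, rh, degree = 1,
                                        penalty_grid = 0, folds = 2))
  ols <- lm(y ~ raw + temperature + rh)
  pred <- apply_calibration(m, raw, temperature, rh)
  expect_equal(unname(pred), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("ridge shrinkage agrees with glmnet on standardized terms", {
  skip_if_not_installed("glmnet")
  d <- make_coloc(n = 200, seed = 4, noise_sd = 1)
  m <- fit_calibration(d$raw, d$truth, d$temperature, d$rh, degree = 2,
                       penalty_grid = 5)
  z <- calibration_terms(d$raw, d$temperature, d$rh, 2)
  zs <- scale(z)
  n <- nrow(zs)
  # glmnet states its ridge objective on the response standardized with the
  # 1/n variance, so lambda corresponds to (lambda_ours / n) * sd_n(y)
  sdy <- sqrt(sum((d$truth - mean(d$truth))^2) / n)
  g <- glmnet::glmnet(zs, d$truth, alpha = 0, lambda = 5 / n * sdy,
                      standardize = FALSE, intercept = TRUE,
                      thresh = 1e-14)
  ours <- m$coefficients[colnames(z)]
  theirs <- as.numeric(g$beta)
  expect_equal(unname(ours), theirs, tolerance = 1e-4)
})

test_that("training MSE is non-decreasing in the ridge penalty", {
  d <- make_coloc(n = 150, seed = 5, noise_sd = 1.5)
  grid <- 10^seq(-3, 3, by = 1)
  mses <- vapply(grid, function(lam) {
    m <- fit_calibration(d$raw, d$truth, d$temperature, d$rh, degree = 2,
                         penalty_grid = lam)
    mean((apply_calibration(m, d$raw, d$temperature, d$rh) - d$truth)^2)
  }, numeric(1))
  expect_true(all(diff(mses) >= -1e-9))
})

test_that("a quadratic + humidity distortion is inverted on held-out data", {
  d <- make_coloc(n = 240, seed = 6,
                  params = list(a0 = 2, a1 = 0.8, a2 = 0.004, b1 = 0.01,
                                noise_sd = 0))
  fit_idx <- 1:160; ho <- 161:240
  m <- fit_calibration(d$raw[fit_idx], d$truth[fit_idx],
                       d$temperature[fit_idx], d$rh[fit_idx], degree = 2)
  pred <- suppressWarnings(
    apply_calibration(m, d$raw[ho], d$temperature[ho], d$rh[ho]))
  expect_lt(sqrt(mean((pred - d$truth[ho])^2)), 0.01 * mean(d$truth))
  expect_gt(cor(pred, d$truth[ho]), 0.99)
})

test_that("calibration improves on raw readings over repeated noisy runs", {
  wins <- vapply(1:20, function(s) {
    coloc <- simulate_colocation(n = 150, seed = 700 + s)
    fit_idx <- 1:100; ho <- 101:150
    m <- fit_calibration(coloc$raw$pm25[fit_idx],
                         coloc$reference$pm25[fit_idx],
                         coloc$raw$temperature[fit_idx],
                         coloc$raw$relative_humidity[fit_idx])
    pred <- suppressWarnings(apply_calibration(
      m, coloc$raw$pm25[ho], coloc$raw$temperature[ho],
      coloc$raw$relative_humidity[ho]))
    truth <- coloc$reference$pm25[ho]
    rmse_cal <- sqrt(mean((pred - truth)^2))
    rmse_raw <- sqrt(mean((coloc$raw$pm25[ho] - truth)^2))
    rmse_cal - rmse_raw
  }, numeric(1))
  expect_lt(median(wins), 0)
})

test_that("degenerate and missing inputs are handled as flagged cases", {
  d <- make_coloc(n = 100, seed = 8, noise_sd = 0.5)
  const <- rep(7, 100)
  m <- fit_calibration(d$raw, const, d$temperature, d$rh, degree = 1)
  pred <- apply_calibration(m, d$raw, d$temperature, d$rh)
  expect_equal(pred, rep(7, 100), tolerance = 1e-6)
  expect_error(compute_metrics(const, pred), NA)
  expect_true(is.na(compute_metrics(const, pred)$r2))

  raw <- d$raw; temperature <- d$temperature
  temperature[3] <- NA
  expect_message(
    out <- apply_calibration(m, raw, temperature, d$rh),
    "flagged missing"
  )
  expect_true(is.na(out[3]))
  expect_false(anyNA(out[-3]))

  expect_error(fit_calibration(d$raw[1:15], d$truth[1:15],
                               d$temperature[1:15], d$rh[1:15], degree = 2),
               "data error")
  expect_warning(fit_calibration(d$raw[1:40], d$truth[1:40],
                                 d$temperature[1:40], d$rh[1:40], degree = 2),
                 "unstable")
})

test_that("calibration models survive JSON serialization", {
  d <- make_coloc(n = 120, seed = 9, noise_sd = 0.5)
  m <- fit_calibration(d$raw, d$truth, d$temperature, d$rh)
  f <- withr::local_tempfile(fileext = ".json")
  calibration_to_json(m, f)
  back <- calibration_from_json(f)
  p1 <- apply_calibration(m, d$raw, d$temperature, d$rh)
  p2 <- apply_calibration(back, d$raw, d$temperature, d$rh)
  expect_equal(p1, p2, tolerance = 1e-12)
})
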