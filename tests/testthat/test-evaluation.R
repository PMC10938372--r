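test_that("metrics hit their closed forms on canonical cases", {
  y <- c(3, 5, 8, 2)
  m <- compute_metrics(y, y)
  expect_equal(m$rmse, 0)
  expect_equal(m$smape, 0)
  expect_equal(m$r2, 1)
  expect_equal(m$pearson_r, 1)

  # |y - yhat| / ((|y|+|yhat|)/2) = 20/20 per pair -> 100%
  m2 <- compute_metrics(c(10, 10), c(30, 30))
  expect_equal(m2$smape, 100)

  y3 <- c(1, 4, 9, 3)
  m3 <- compute_metrics(y3, rep(mean(y3), 4))
  expect_equal(m3$r2, 0)
})

test_that("metric identities hold on random vectors", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    y <- rnorm(n, 10, 5)
    yhat <- y + rnorm(n, 0, 2)
    m <- compute_metrics(y, yhat)
    expect_equal(m$rmse^2, m$mse, tolerance = 1e-12)
    expect_lte(m$mae, m$rmse + 1e-12)
    # symmetry of SMAPE
    expect_equal(m$smape, compute_metrics(yhat, y)$smape, tolerance = 1e-12)
    # brute-force oracle
    expect_equal(m$mae, sum(abs(y - yhat)) / n, tolerance = 1e-12)
    expect_equal(m$mse, sum((y - yhat)^2) / n, tolerance = 1e-12)
    sm <- 0
    for (j in seq_len(n)) {
      d <- (abs(y[j]) + abs(yhat[j])) / 2
      sm <- sm + if (d == 0) 0 else abs(y[j] - yhat[j]) / d
    }
    expect_equal(m$smape, 100 * sm / n, tolerance = 1e-12)
    expect_equal(m$r2, 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
    expect_equal(m$pearson_r, cor(y, yhat), tolerance = 1e-12)
  }
})

test_that("degenerate metric inputs are flagged, not fabricated", {
  m <- compute_metrics(rep(4, 5), c(4, 4, 5, 4, 4))
  expect_true(m$degenerate)
  expect_true(is.na(m$r2) && is.na(m$pearson_r))
  expect_false(is.na(m$rmse))
  expect_error(compute_metrics(1, 1), "finite pairs")
  # 0/0 terms in SMAPE count as 0
  expect_equal(compute_metrics(c(0, 2), c(0, 2))$smape, 0)
})

test_that("weekly profiles reproduce group means and shape agreement", {
  dates <- seq(as.Date("2021-07-05"), by = "day", length.out = 28) # Mon start
  dow <- as.integer(format(dates, "%u")) - 1
  y <- ifelse(dow >= 5, 4, 10) # weekend dip
  wp <- weekly_profile(dates, y, y + 1)
  expect_equal(wp$profile$observed, ifelse(0:6 >= 5, 4, 10))
  expect_equal(wp$profile$predicted - wp$profile$observed, rep(1, 7))
  expect_equal(wp$shape_r, 1)

  flat <- weekly_profile(dates, rep(3, 28), rep(3, 28))
  expect_true(is.na(flat$shape_r))

  gap_y <- y; gap_y[dow == 2] <- NA
  wp2 <- weekly_profile(dates, gap_y, y)
  expect_true(2 %in% wp2$gaps)
  expect_error(weekly_profile(dates[1:6], y[1:6], y[1:6]), "two weeks")

  # repeated dates (several stations per day) group correctly
  d3 <- rep(dates[1:15], each = 3)
  dow3 <- as.integer(format(d3, "%u")) - 1
  y3 <- ifelse(dow3 >= 5, 4, 10) + rep(c(0, 1, 2), 15)
  wp3 <- weekly_profile(d3, y3, y3)
  oracle <- vapply(0:6, function(d) mean(y3[dow3 == d]), numeric(1))
  expect_equal(wp3$profile$observed, oracle)
})

test_that("OAT scores reproduce coefficient ratios exactly on a linear network", {
  W1 <- cbind(c(3, 1), c(-3, -1))
  mdl <- manual_mlp(
    weights = list(list(W = W1, b = c(0, 0)),
                   list(W = matrix(c(1, -1), 2, 1), b = 0)),
    feature_names = c("f1", "f2")
  )
  set.seed(8)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("f1", "f2")))
  rep_ <- oat_sensitivity(mdl, X, delta = 1)
  s <- setNames(rep_$score, rep_$feature)
  expect_equal(unname(s["f1"] / s["f2"]), 3, tolerance = 1e-12)
  expect_equal(rep_$feature[rep_$rank == 1], "f1")

  # with per-feature scales the ordering follows |coefficient| * sigma
  mdl2 <- manual_mlp(
    weights = list(list(W = W1, b = c(0, 0)),
                   list(W = matrix(c(1, -1), 2, 1), b = 0)),
    feature_names = c("f1", "f2"),
    scaler = list(centre = c(0, 0), scale = c(1, 10),
                  constant = c(FALSE, FALSE))
  )
  rep2 <- oat_sensitivity(mdl2, X, delta = 1)
  s2 <- setNames(rep2$score, rep2$feature)
  # prediction uses f/sigma, perturbation is delta*sigma: effect |c|*delta
  expect_equal(unname(s2["f1"] / s2["f2"]), 3, tolerance = 1e-12)
})

test_that("unused and constant features score zero in OAT", {
  W1 <- cbind(c(1, -1), c(0, 0)) # f2 has a pruned (all-zero) weight path
  mdl <- manual_mlp(
    weights = list(list(W = rbind(c(1, -1), c(0, 0)), b = c(0, 0)),
                   list(W = matrix(c(1, -1), 2, 1), b = 0)),
    feature_names = c("f1", "f2")
  )
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  rep_ <- oat_sensitivity(mdl, X)
  s <- setNames(rep_$score, rep_$feature)
  expect_equal(unname(s["f2"]), 0)
  expect_gt(unname(s["f1"]), 0)

  mdl3 <- manual_mlp(
    weights = list(list(W = rbind(c(1, -1), c(1, -1)), b = c(0, 0)),
                   list(W = matrix(c(1, -1), 2, 1), b = 0)),
    feature_names = c("f1", "f2"),
    scaler = list(centre = c(0, 0), scale = c(1, 1),
                  constant = c(FALSE, TRUE))
  )
  rep3 <- oat_sensitivity(mdl3, X)
  expect_equal(rep3$score[rep3$feature == "f2"], 0)
  expect_true(rep3$constant[rep3$feature == "f2"])
})
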