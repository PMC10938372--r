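#' Evaluation metrics for concentration predictions
#'
#' Computes MAE, MSE, RMSE, symmetric MAPE, the coefficient of determination
#' and Pearson's r over the finite (observed, predicted) pairs. SMAPE uses the
#' half-sum denominator, `(100/n) * sum(|yhat - y| / ((|y| + |yhat|) / 2))`,
#' bounded by 200%, with 0/0 terms defined as 0. R2 is `1 - SS_res / SS_tot`
#' against the observations (not a squared correlation). When the observations
#' have zero variance, r and R2 are undefined and returned as NA with a flag.
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @param size_class optional label carried into the report.
#' @return a `metrics_report` list: mae, mse, rmse, smape (%), r2, pearson_r,
#'   n, size_class, degenerate (TRUE when y is constant).
#' @export
compute_metrics <- function(y, yhat, size_class = NA_character_) {
  stopifnot(length(y) == length(yhat))
  ok <- is.finite(y) & is.finite(yhat)
  y <- y[ok]; yhat <- yhat[ok]
  n <- length(y)
  if (n < 2) stop("need >= 2 finite pairs")
  err <- yhat - y
  mae <- mean(abs(err))
  mse <- mean(err^2)
  denom <- (abs(y) + abs(yhat)) / 2
  terms <- ifelse(denom == 0, 0, abs(err) / denom)
  smape <- 100 * mean(terms)
  ss_tot <- sum((y - mean(y))^2)
  degenerate <- ss_tot == 0
  r2 <- if (degenerate) NA_real_ else 1 - sum(err^2) / ss_tot
  r <- if (degenerate || sd(yhat) == 0) NA_real_ else cor(y, yhat)
  structure(list(mae = mae, mse = mse, rmse = sqrt(mse), smape = smape,
                 r2 = r2, pearson_r = r, n = n, size_class = size_class,
                 degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report>%s n=%d  RMSE %.3f  SMAPE %.2f%%  R2 %s  r %s\n",
    if (is.na(x$size_class)) "" else paste0(" ", x$size_class),
    x$n, x$rmse, x$smape,
    ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2)),
    ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r))
  ))
  invisible(x)
}

#' Day-of-week profiles of observed and predicted series
#'
#' Groups both series by day of week (Monday = 0) with missing-aware means and
#' reports a shape-agreement statistic (Pearson r between the two 7-vectors).
#' Days of week with no data are flagged gaps.
#'
#' @param dates Date vector.
#' @param y observed values; `yhat` predictions, both aligned with `dates`.
#' @param yhat predicted values.
#' @return list with `profile` (tibble dow 0..6, observed, predicted, n),
#'   `shape_r` (NA when either profile is constant) and `gaps` (dows with no
#'   data).
#' @export
weekly_profile <- function(dates, y, yhat) {
  dates <- as.Date(dates)
  if (as.numeric(max(dates) - min(dates)) < 13) {
    stop("dates must span at least two weeks")
  }
  dw <- as.integer(format(dates, "%u")) - 1L
  grp_mean <- function(v, d) {
    vv <- v[dw == d]
    if (length(vv) == 0 || all(is.na(vv))) NA_real_ else mean(vv, na.rm = TRUE)
  }
  obs <- vapply(0:6, function(d) grp_mean(y, d), numeric(1))
  pre <- vapply(0:6, function(d) grp_mean(yhat, d), numeric(1))
  cnt <- vapply(0:6, function(d) sum(dw == d & !is.na(y)), integer(1))
  prof <- tibble::tibble(dow = 0:6, observed = obs, predicted = pre, n = cnt)
  gaps <- prof$dow[prof$n == 0]
  ok <- !is.na(prof$observed) & !is.na(prof$predicted)
  shape_r <- if (sum(ok) < 3 || sd(prof$observed[ok]) == 0 ||
                 sd(prof$predicted[ok]) == 0) {
    NA_real_
  } else {
    cor(prof$observed[ok], prof$predicted[ok])
  }
  list(profile = prof, shape_r = shape_r, gaps = gaps)
}

#' One-at-a-time sensitivity analysis
#'
#' Perturbs each feature in turn by `+/- delta` standard deviations (the
#' model's fit-time scale), holding the others fixed, and scores the feature by
#' the mean absolute prediction response over all rows and both perturbation
#' signs. Constant features (zero scale at fit time) score 0 and are flagged.
#' For a linear response the score equals `|coefficient| * delta * sigma`
#' exactly, so the ranking recovers the coefficient-magnitude ordering.
#'
#' @param model a `trained_mlp`.
#' @param table a `feature_table` (or matrix) satisfying the model contract.
#' @param delta perturbation size in feature standard deviations (default 1).
#' @return a `sensitivity_report` tibble: feature, score (ug/m3), rank
#'   (1 = most sensitive), constant flag; attribute `delta`.
#' @export
oat_sensitivity <- function(model, table, delta = 1.0) {
  fnames <- model$feature_names
  X <- if (is.matrix(table)) table[, fnames, drop = FALSE] else {
    .model_matrix_raw(model, table)
  }
  if (nrow(X) == 0) stop("table is empty")
  # OAT probes the network's local response, so perturbations act on the
  # standardized inputs directly, without the deployment range clamp
  Xs <- sweep(sweep(X, 2, model$scaler$centre), 2, model$scaler$scale, "/")
  base <- .predict_scaled(model, Xs)
  const <- model$scaler$constant
  if (is.null(const)) const <- rep(FALSE, length(fnames))
  scores <- numeric(length(fnames))
  for (j in seq_along(fnames)) {
    if (const[j]) next # zero fit-time variance: score 0, flagged
    Xp <- Xs; Xp[, j] <- Xs[, j] + delta
    Xm <- Xs; Xm[, j] <- Xs[, j] - delta
    up <- .predict_scaled(model, Xp)
    dn <- .predict_scaled(model, Xm)
    scores[j] <- mean((abs(up - base) + abs(dn - base)) / 2)
  }
  ord <- order(-scores, fnames)
  rank <- integer(length(scores))
  rank[ord] <- seq_along(scores)
  out <- tibble::tibble(feature = fnames, score = scores, rank = rank,
                        constant = unname(const))
  out <- out[order(out$rank), ]
  structure(out, class = c("sensitivity_report", class(out)), delta = delta)
}

# raw (unstandardized) feature matrix with the same contract enforcement
.model_matrix_raw <- function(object, table) {
  fnames <- object$feature_names
  have <- names(table)[names(table) %in% fnames]
  if (!identical(have, fnames)) {
    stop("contract error: feature names/order mismatch")
  }
  as.matrix(table[, fnames])
}
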