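#' Polynomial term expansion for calibration
#'
#' All monomials of total degree 1..`degree` in (raw PM, temperature, relative
#' humidity), including the pairwise/interaction terms; degree 2 yields the 9
#' terms raw, T, RH, raw^2, T^2, RH^2, raw*T, raw*RH, T*RH.
#'
#' @param raw,temperature,rh aligned numeric vectors.
#' @param degree maximum total degree (>= 1).
#' @return numeric matrix with one named column per term.
#' @export
calibration_terms <- function(raw, temperature, rh, degree = 2) {
  stopifnot(degree >= 1)
  vars <- list(raw = raw, temp = temperature, rh = rh)
  expo <- expand.grid(raw = 0:degree, temp = 0:degree, rh = 0:degree)
  expo <- expo[rowSums(expo) >= 1 & rowSums(expo) <= degree, , drop = FALSE]
  expo <- expo[order(rowSums(expo),
                     -expo$raw * 100 - expo$temp * 10 - expo$rh), ,
               drop = FALSE]
  cols <- lapply(seq_len(nrow(expo)), function(i) {
    raw^expo$raw[i] * temperature^expo$temp[i] * rh^expo$rh[i]
  })
  nm <- vapply(seq_len(nrow(expo)), function(i) {
    parts <- character(0)
    for (v in c("raw", "temp", "rh")) {
      e <- expo[[v]][i]
      if (e == 1) parts <- c(parts, v)
      if (e > 1) parts <- c(parts, paste0(v, "^", e))
    }
    paste(parts, collapse = "*")
  }, character(1))
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

# closed-form ridge on centred/standardized terms; intercept unpenalized
.ridge_fit <- function(Z, y, lambda) {
  p <- ncol(Z)
  beta <- solve(crossprod(Z) + diag(lambda, p), crossprod(Z, y))
  as.numeric(beta)
}

#' Fit a ridge polynomial calibration model
#'
#' Regresses reference concentrations on the degree-`degree` polynomial
#' expansion of (raw sensor PM, temperature, relative humidity). Terms are
#' standardised, the ridge penalty is chosen from `penalty_grid` by
#' cross-validated MSE over time-blocked (contiguous) folds — respecting the
#' autocorrelation of ambient series — and the model is refit on all complete
#' rows. Ties in CV score go to the smaller penalty.
#'
#' @param raw raw sensor readings (ug/m3).
#' @param reference co-located reference concentrations (ug/m3).
#' @param temperature degC; `rh` percent; all aligned with `raw`.
#' @param rh relative humidity (%).
#' @param degree polynomial total degree (default 2).
#' @param penalty_grid candidate ridge strengths (default 7 log-spaced values
#'   1e-3..1e3).
#' @param folds number of contiguous CV folds (default 5).
#' @param seed accepted for interface stability; the blocked folds are already
#'   deterministic.
#' @param size_class label of the PM size being calibrated.
#' @return a `calibration_model`: degree, chosen penalty, named coefficients
#'   (with intercept), per-term centre/scale, fit-time input ranges, CV table.
#' @export
fit_calibration <- function(raw, reference, temperature, rh, degree = 2,
                            penalty_grid = 10^seq(-3, 3, by = 1), folds = 5,
                            seed = NULL, size_class = "pm25") {
  ok <- complete.cases(raw, reference, temperature, rh)
  raw <- raw[ok]; reference <- reference[ok]
  temperature <- temperature[ok]; rh <- rh[ok]
  Z0 <- calibration_terms(raw, temperature, rh, degree)
  n <- nrow(Z0); p <- ncol(Z0)
  if (n < 2 * p + 2) {
    stop("data error: need >= ", 2 * p + 2, " complete rows for degree ",
         degree, " (have ", n, ")")
  }
  if (n < 10 * p) {
    warning("only ", n, " complete rows for ", p,
            " terms; the fit may be unstable (recommended >= ", 10 * p, ")")
  }
  centre <- colMeans(Z0)
  scale <- apply(Z0, 2, sd)
  if (any(!is.finite(scale))) stop("data error: non-finite term statistics")
  scale[scale == 0] <- 1
  Z <- sweep(sweep(Z0, 2, centre), 2, scale, "/")
  if (any(!is.finite(Z))) stop("data error: non-finite values after standardization")

  fold_id <- cut(seq_len(n), breaks = folds, labels = FALSE)
  cv_mse <- vapply(penalty_grid, function(lam) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      ybar <- mean(reference[tr])
      beta <- .ridge_fit(Z[tr, , drop = FALSE], reference[tr] - ybar, lam)
      pred <- Z[!tr, , drop = FALSE] %*% beta + ybar
      mean((reference[!tr] - pred)^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  lambda <- penalty_grid[which.min(cv_mse)]
  ybar <- mean(reference)
  beta <- .ridge_fit(Z, reference - ybar, lambda)
  coef <- setNames(c(ybar, beta), c("(Intercept)", colnames(Z0)))
  structure(list(
    degree = degree, penalty = lambda, coefficients = coef,
    centre = centre, scale = scale, size_class = size_class,
    input_range = list(raw = range(raw), temperature = range(temperature),
                       rh = range(rh)),
    cv = data.frame(penalty = penalty_grid, mse = cv_mse)
  ), class = "calibration_model")
}

#' Apply a calibration model to raw readings
#'
#' Rows with missing temperature or humidity where the raw value is present are
#' flagged missing. Negative corrected concentrations are floored at 0 and the
#' count reported. A warning is issued when inputs stray more than 20% of the
#' fit-time range outside it.
#'
#' @param model a [fit_calibration()] result.
#' @param raw,temperature,rh aligned input vectors.
#' @return corrected concentration vector (ug/m3).
#' @export
apply_calibration <- function(model, raw, temperature, rh) {
  n <- length(raw)
  out <- rep(NA_real_, n)
  ok <- !is.na(raw) & !is.na(temperature) & !is.na(rh)
  n_dropped <- sum(!is.na(raw) & !ok)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) flagged missing (no temperature/humidity)")
  }
  if (!any(ok)) return(out)
  for (v in c("raw", "temperature", "rh")) {
    rng <- model$input_range[[v]]
    span <- max(diff(rng), 1e-9)
    x <- switch(v, raw = raw, temperature = temperature, rh = rh)[ok]
    if (any(x < rng[1] - 0.2 * span | x > rng[2] + 0.2 * span)) {
      warning("`", v, "` extends > 20% beyond the calibration range")
    }
  }
  Z0 <- calibration_terms(raw[ok], temperature[ok], rh[ok], model$degree)
  Z <- sweep(sweep(Z0, 2, model$centre), 2, model$scale, "/")
  pred <- as.numeric(Z %*% model$coefficients[colnames(Z0)] +
                       model$coefficients["(Intercept)"])
  n_neg <- sum(pred < 0)
  if (n_neg > 0) message(n_neg, " negative corrected value(s) floored at 0")
  out[ok] <- pmax(0, pred)
  out
}

#' Calibrate all three PM sizes of a monitor series
#'
#' Fits one model per size class against a reference series and returns the
#' corrected series plus the models.
#'
#' @param raw_series a raw [monitor_series()].
#' @param reference_series the co-located reference [monitor_series()].
#' @param ... passed to [fit_calibration()].
#' @return list with `series` (corrected `monitor_series`) and `models` (named
#'   list of `calibration_model`).
#' @export
calibrate_monitor <- function(raw_series, reference_series, ...) {
  stopifnot(nrow(raw_series) == nrow(reference_series))
  out <- tibble::as_tibble(as.data.frame(raw_series))
  models <- list()
  for (size in c("pm1", "pm25", "pm10")) {
    models[[size]] <- fit_calibration(
      raw_series[[size]], reference_series[[size]],
      raw_series$temperature, raw_series$relative_humidity,
      size_class = size, ...
    )
    out[[size]] <- apply_calibration(
      models[[size]], raw_series[[size]],
      raw_series$temperature, raw_series$relative_humidity
    )
  }
  res <- monitor_series(out, attr(raw_series, "station_id"),
                        attr(raw_series, "latitude"),
                        attr(raw_series, "longitude"),
                        step = attr(raw_series, "step"))
  attr(res, "x") <- attr(raw_series, "x")
  attr(res, "y") <- attr(raw_series, "y")
  list(series = res, models = models)
}

#' Serialize a calibration model to JSON (and back)
#' @param model a `calibration_model`.
#' @param path output path.
#' @return `path` invisibly; `calibration_from_json` returns the model.
#' @export
calibration_to_json <- function(model, path) {
  out <- unclass(model)
  # named vectors must become JSON objects, not nameless arrays
  for (f in c("coefficients", "centre", "scale")) out[[f]] <- as.list(out[[f]])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname calibration_to_json
#' @export
calibration_from_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$coefficients <- unlist(m$coefficients)
  m$centre <- unlist(m$centre)
  m$scale <- unlist(m$scale)
  m$cv <- as.data.frame(m$cv)
  class(m) <- "calibration_model"
  m
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> %s: degree %d, %d terms, ridge penalty %.4g\n",
    x$size_class, x$degree, length(x$coefficients) - 1, x$penalty
  ))
  invisible(x)
}
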