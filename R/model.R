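#' Multilayer-perceptron specification
#'
#' The network used for each PM size: three hidden layers of 100, 100 and 10
#' rectifier units with dropout rates 0.2, 0.2 and 0, a linear scalar output,
#' mean-absolute-error loss, Adam optimisation, mini-batches of 24 rows and 20
#' epochs. All of it is configurable; the learning rate defaults to Adam's
#' conventional 1e-3.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param dropout_rates dropout probability per hidden layer, in [0, 1).
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size (the last incomplete batch is kept).
#' @param epochs training epochs.
#' @param seed integer seed for initialisation, batch order and dropout.
#' @return an `mlp_spec` list.
#' @export
mlp_spec <- function(hidden_sizes = c(100, 100, 10),
                     dropout_rates = c(0.2, 0.2, 0),
                     learning_rate = 1e-3, batch_size = 24, epochs = 20,
                     seed = 1) {
  stopifnot(length(hidden_sizes) == length(dropout_rates),
            all(hidden_sizes > 0), all(dropout_rates >= 0),
            all(dropout_rates < 1), batch_size >= 1, epochs >= 1)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 dropout_rates = dropout_rates,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "mlp_spec")
}

#' Split a feature table into training and validation rows by date
#'
#' The rows whose date falls in the final `frac` of the table's date range form
#' the validation set; the split is by date, never within a date.
#'
#' @param table a `feature_table`.
#' @param frac fraction of the date range held out (default 0.2).
#' @return list of two tables, `train` and `validation`.
#' @export
split_train_validation <- function(table, frac = 0.2) {
  dates <- as.Date(table$date)
  ud <- sort(unique(dates))
  if (length(ud) < 10) stop("data error: need >= 10 distinct dates to split")
  cut <- min(ud) + as.numeric(max(ud) - min(ud)) * (1 - frac)
  val <- dates > cut
  if (!any(val) || all(val)) stop("data error: degenerate validation split")
  list(train = table[!val, , drop = FALSE],
       validation = table[val, , drop = FALSE])
}

.relu <- function(z) pmax(z, 0)

.mlp_init <- function(input_dim, hidden_sizes) {
  dims <- c(input_dim, hidden_sizes, 1L)
  weights <- vector("list", length(dims) - 1)
  for (l in seq_along(weights)) {
    fan_in <- dims[l]
    weights[[l]] <- list(
      W = matrix(rnorm(fan_in * dims[l + 1], 0, sqrt(2 / fan_in)),
                 fan_in, dims[l + 1]),
      b = rep(0, dims[l + 1])
    )
  }
  weights
}

# forward pass; returns activations per layer (for backprop) or predictions
.mlp_forward <- function(X, weights, dropout = NULL) {
  L <- length(weights)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% weights[[l]]$W, 2, weights[[l]]$b, "+")
    if (l < L) {
      a <- .relu(z)
      if (!is.null(dropout) && dropout[l] > 0) {
        keep <- matrix(rbinom(length(a), 1, 1 - dropout[l]), nrow(a)) /
          (1 - dropout[l])
        a <- a * keep
      }
      acts[[l + 1]] <- a
    } else {
      acts[[l + 1]] <- z
    }
  }
  acts
}

#' Train the per-size multilayer perceptron
#'
#' Features are z-scored with training-set statistics (constant features get
#' unit scale); the target is standardised internally and back-transformed at
#' prediction time. Optimisation is Adam on the mean absolute error with a
#' seeded mini-batch order and inverted dropout active only during training.
#' The history records epoch-end MAE and MSE on the training and validation
#' tables, in original concentration units with dropout off. Runs are
#' bit-reproducible for a fixed seed on one platform.
#'
#' @param spec an [mlp_spec()].
#' @param train_table,validation_table `feature_table`s sharing feature names.
#' @param size target column: `"pm1"`, `"pm25"` or `"pm10"` (or any numeric
#'   column present in both tables).
#' @return a `trained_mlp`: spec, layer weights, bound feature names, feature
#'   and target scalers, size class and the per-epoch history.
#' @export
train_mlp <- function(spec, train_table, validation_table, size = "pm25") {
  fnames <- attr(train_table, "feature_names")
  if (!identical(fnames, attr(validation_table, "feature_names"))) {
    stop("contract error: train and validation feature names differ")
  }
  keep <- !is.na(train_table[[size]])
  X <- as.matrix(train_table[keep, fnames])
  y <- train_table[[size]][keep]
  keep_v <- !is.na(validation_table[[size]])
  Xv <- as.matrix(validation_table[keep_v, fnames])
  yv <- validation_table[[size]][keep_v]
  if (!all(is.finite(y))) stop("data error: non-finite targets")

  centre <- colMeans(X)
  scale <- apply(X, 2, sd)
  constant <- scale == 0 | !is.finite(scale)
  scale[constant] <- 1
  Xs <- sweep(sweep(X, 2, centre), 2, scale, "/")
  Xvs <- sweep(sweep(Xv, 2, centre), 2, scale, "/")
  y_centre <- mean(y)
  y_scale <- sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- max(abs(y_centre), 1)
  ys <- (y - y_centre) / y_scale

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  weights <- .mlp_init(length(fnames), spec$hidden_sizes)
  L <- length(weights)
  adam <- lapply(weights, function(w) list(
    mW = w$W * 0, vW = w$W * 0, mb = w$b * 0, vb = w$b * 0
  ))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(Xs)
  history <- data.frame(epoch = integer(0), train_mae = numeric(0),
                        train_mse = numeric(0), val_mae = numeric(0),
                        val_mse = numeric(0))
  for (epoch in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = spec$batch_size)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + spec$batch_size - 1, n)]
      Xb <- Xs[idx, , drop = FALSE]
      yb <- ys[idx]
      acts <- .mlp_forward(Xb, weights, dropout = spec$dropout_rates)
      yhat <- acts[[L + 1]][, 1]
      if (any(!is.finite(yhat))) {
        stop("non-finite loss in epoch ", epoch, ", batch starting at ", s0)
      }
      # MAE gradient
      delta <- matrix(sign(yhat - yb) / length(yb), ncol = 1)
      step <- step + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(weights[[l]]$W)) * (acts[[l]] > 0)
        }
        a <- adam[[l]]
        a$mW <- beta1 * a$mW + (1 - beta1) * gW
        a$vW <- beta2 * a$vW + (1 - beta2) * gW^2
        a$mb <- beta1 * a$mb + (1 - beta1) * gb
        a$vb <- beta2 * a$vb + (1 - beta2) * gb^2
        mWh <- a$mW / (1 - beta1^step); vWh <- a$vW / (1 - beta2^step)
        mbh <- a$mb / (1 - beta1^step); vbh <- a$vb / (1 - beta2^step)
        weights[[l]]$W <- weights[[l]]$W -
          spec$learning_rate * mWh / (sqrt(vWh) + eps)
        weights[[l]]$b <- weights[[l]]$b -
          spec$learning_rate * mbh / (sqrt(vbh) + eps)
        adam[[l]] <- a
      }
    }
    pt <- .mlp_forward(Xs, weights)[[L + 1]][, 1] * y_scale + y_centre
    pv <- .mlp_forward(Xvs, weights)[[L + 1]][, 1] * y_scale + y_centre
    history <- rbind(history, data.frame(
      epoch = epoch,
      train_mae = mean(abs(pt - y)), train_mse = mean((pt - y)^2),
      val_mae = mean(abs(pv - yv)), val_mse = mean((pv - yv)^2)
    ))
  }
  structure(list(
    spec = spec, weights = weights, feature_names = fnames,
    scaler = list(centre = centre, scale = scale, constant = constant,
                  zmin = apply(Xs, 2, min), zmax = apply(Xs, 2, max)),
    y_scaler = list(centre = y_centre, scale = y_scale),
    size_class = size, history = history
  ), class = "trained_mlp")
}

#' Assemble a multilayer perceptron from explicit weights
#'
#' Utility for analyses that need a network with known behaviour (for example
#' closed-form checks of the sensitivity analysis): the weights are supplied
#' directly instead of trained.
#'
#' @param weights list of layers, each `list(W = matrix, b = vector)`; the last
#'   layer must have one output column.
#' @param feature_names column names the model binds to.
#' @param scaler list(centre, scale) applied to features before the network;
#'   defaults to the identity.
#' @param y_scaler list(centre, scale) back-transform of the output; defaults
#'   to the identity.
#' @param size_class label for the target.
#' @return a `trained_mlp` with an empty history.
#' @export
manual_mlp <- function(weights, feature_names,
                       scaler = NULL, y_scaler = NULL, size_class = "pm25") {
  p <- length(feature_names)
  stopifnot(nrow(weights[[1]]$W) == p,
            ncol(weights[[length(weights)]]$W) == 1)
  if (is.null(scaler)) {
    scaler <- list(centre = rep(0, p), scale = rep(1, p),
                   constant = rep(FALSE, p))
  }
  if (is.null(scaler$constant)) scaler$constant <- rep(FALSE, p)
  if (is.null(y_scaler)) y_scaler <- list(centre = 0, scale = 1)
  structure(list(
    spec = NULL, weights = weights, feature_names = feature_names,
    scaler = scaler, y_scaler = y_scaler, size_class = size_class,
    history = data.frame()
  ), class = "trained_mlp")
}

# standardized feature matrix from a table, enforcing the name/order contract
.model_matrix <- function(object, table) {
  fnames <- object$feature_names
  have <- if (is.matrix(table)) colnames(table) else names(table)
  have <- have[have %in% fnames] # feature columns in the order supplied
  if (!identical(have, fnames)) {
    n <- min(length(have), length(fnames))
    div <- which(head(have, n) != head(fnames, n))[1]
    if (is.na(div)) div <- n + 1
    stop("contract error: feature names/order mismatch; first divergence at ",
         "position ", div, " (expected '",
         fnames[min(div, length(fnames))], "')")
  }
  X <- if (is.matrix(table)) table[, fnames, drop = FALSE] else
    as.matrix(table[, fnames])
  Xs <- sweep(sweep(X, 2, object$scaler$centre), 2, object$scaler$scale, "/")
  # features with zero training variance carry no information: the network
  # never saw them vary, so any new value is untrained extrapolation; hold
  # them at their training value
  if (!is.null(object$scaler$constant) && any(object$scaler$constant)) {
    Xs[, object$scaler$constant] <- 0
  }
  # outside the training envelope the rectifier tails extrapolate linearly
  # without support; saturate each feature at its fit-time range instead
  if (!is.null(object$scaler$zmin)) {
    Xs <- pmin(pmax(Xs, rep(object$scaler$zmin, each = nrow(Xs))),
               rep(object$scaler$zmax, each = nrow(Xs)))
  }
  Xs
}

#' Predict from a trained network
#'
#' Deterministic (dropout off); the feature names and order of `newdata` must
#' match the model's bound names exactly.
#'
#' @param object a `trained_mlp`.
#' @param newdata a `feature_table` or numeric matrix with the model's feature
#'   columns.
#' @param ... unused.
#' @return numeric vector of predictions (ug/m3), one per row.
#' @export
predict.trained_mlp <- function(object, newdata, ...) {
  n <- if (is.matrix(newdata)) nrow(newdata) else nrow(newdata)
  if (n == 0) return(numeric(0))
  Xs <- .model_matrix(object, newdata)
  .predict_scaled(object, Xs)
}

# forward pass on an already standardized (and possibly clamped) matrix
.predict_scaled <- function(object, Xs) {
  L <- length(object$weights)
  raw <- .mlp_forward(Xs, object$weights)[[L + 1]][, 1]
  raw * object$y_scaler$scale + object$y_scaler$centre
}

#' @export
print.trained_mlp <- function(x, ...) {
  arch <- paste(c(length(x$feature_names),
                  vapply(x$weights, function(w) ncol(w$W), integer(1))),
                collapse = " -> ")
  cat(sprintf("<trained_mlp> %s, target %s, %d epochs trained\n",
              arch, x$size_class, nrow(x$history)))
  invisible(x)
}
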