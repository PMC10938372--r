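#' Run the full synthetic study end to end
#'
#' Generates a town and its meteorology, simulates the latent PM field and the
#' monitor truth, distorts the monitors into raw sensor readings, calibrates
#' them back against the truth of a designated colocation monitor, builds
#' leakage-separated feature tables for a 5-train / 3-eval monitor split,
#' trains one network per requested PM size, evaluates it on the held-out
#' monitors, and produces daily plus period-average maps compared against the
#' truth field.
#'
#' @param seed master integer seed; all stage seeds derive from it.
#' @param days simulated days (default 180).
#' @param sizes PM size classes to model.
#' @param noise_sd day-level lognormal noise of the PM field.
#' @param sensor_params distortion parameters passed to [distort_sensor()].
#' @param grid_rows,grid_cols,grid_cell map geometry (defaults 10 x 20 at
#'   600 m).
#' @param epochs,batch_size,hidden_sizes,dropout_rates network settings
#'   (defaults per [mlp_spec()]).
#' @param config a [feature_config()].
#' @param calibrate logical; distort and re-calibrate the monitors (TRUE) or
#'   model the truth series directly.
#' @param eval_ids stations held out for evaluation (default "2", "7", "8",
#'   the network's mid-range, well-surrounded stations).
#' @return list with the town, met, simulation, calibrated monitors, feature
#'   tables, per-size models, held-out metrics, maps, truth comparison and
#'   summary numbers.
#' @export
run_synthetic_study <- function(seed = 1, days = 180,
                                sizes = c("pm1", "pm25", "pm10"),
                                noise_sd = 0.1,
                                sensor_params = list(a0 = 2, a1 = 0.8,
                                                     a2 = 0.004, b1 = 0.002,
                                                     noise_sd = 1),
                                grid_rows = 10, grid_cols = 20,
                                grid_cell = 600,
                                epochs = 20, batch_size = 24,
                                hidden_sizes = c(100, 100, 10),
                                dropout_rates = c(0.2, 0.2, 0),
                                config = feature_config(),
                                calibrate = TRUE,
                                eval_ids = c("2", "7", "8")) {
  seed <- as.integer(seed) %% 100000L
  town <- make_town(town_config(), seed = seed + 1L)
  met <- simulate_met(days, seed = seed + 2L)
  sim <- simulate_pm(town, met, noise_sd = noise_sd, seed = seed + 3L,
                     raster_res = config$raster_res, window = config$window)

  monitors <- sim$monitor_truth
  calib <- NULL
  if (calibrate) {
    raws <- lapply(seq_along(monitors), function(i) {
      distort_sensor(monitors[[i]], params = sensor_params,
                     seed = seed + 10L + i)
    })
    # colocation campaign spanning the ambient range; the fitted transfer
    # model is applied to every monitor's raw readings
    coloc <- simulate_colocation(n = 200, seed = seed + 9L,
                                 params = sensor_params)
    calib_fit <- calibrate_monitor(coloc$raw, coloc$reference)
    monitors <- lapply(raws, function(rs) {
      out <- tibble::as_tibble(as.data.frame(rs))
      for (size in c("pm1", "pm25", "pm10")) {
        out[[size]] <- apply_calibration(calib_fit$models[[size]], rs[[size]],
                                         rs$temperature, rs$relative_humidity)
      }
      res <- monitor_series(out, attr(rs, "station_id"),
                            attr(rs, "latitude"), attr(rs, "longitude"),
                            step = "day")
      attr(res, "x") <- attr(rs, "x")
      attr(res, "y") <- attr(rs, "y")
      res
    })
    calib <- list(models = calib_fit$models, raw = raws)
  }
  names(monitors) <- town$monitors$station_id
  train_ids <- setdiff(town$monitors$station_id, eval_ids)

  raster <- rasterize_roads(town$roads, resolution = config$raster_res)
  tabs <- build_tables(monitors, met, raster,
                       split = list(train = train_ids, eval = eval_ids),
                       config = config)
  sv <- split_train_validation(tabs$train)

  grid <- make_grid(c(0, 0), rows = grid_rows, cols = grid_cols,
                    cell = grid_cell)
  models <- list(); metrics <- list(); avg_maps <- list()
  truth_avg <- list(); predictions <- list()
  for (size in sizes) {
    spec <- mlp_spec(hidden_sizes = hidden_sizes,
                     dropout_rates = dropout_rates,
                     batch_size = batch_size, epochs = epochs,
                     seed = seed + 100L + match(size, c("pm1", "pm25", "pm10")))
    models[[size]] <- train_mlp(spec, sv$train, sv$validation, size = size)
    pred <- predict(models[[size]], tabs$eval)
    obs <- tabs$eval[[size]]
    metrics[[size]] <- compute_metrics(obs, pred, size_class = size)
    predictions[[size]] <- tibble::tibble(
      point_id = tabs$eval$point_id, date = tabs$eval$date,
      observed = obs, predicted = pred
    )
    daily <- predict_map(models[[size]], grid, sim$dates, monitors[train_ids],
                         met, raster, config)
    avg_maps[[size]] <- average_map(daily)
    truth_avg[[size]] <- colMeans(sim$truth_field(grid$x, grid$y, size))
  }

  # spatial benchmark: between-monitor SD of true period means, per size
  spatial_sd <- vapply(c("pm1", "pm25", "pm10"), function(size) {
    sd(vapply(sim$monitor_truth, function(ms) mean(ms[[size]]), numeric(1)))
  }, numeric(1))
  list(
    town = town, met = met, sim = sim, monitors = monitors,
    calibration = calib, split = list(train = train_ids, eval = eval_ids),
    tables = tabs, grid = grid, models = models, metrics = metrics,
    predictions = predictions, avg_maps = avg_maps, truth_avg = truth_avg,
    spatial_sd = spatial_sd
  )
}
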