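#' Persist a trained network as a directory of text artifacts
#'
#' Writes `spec.json`, `scaler.json`, `weights.json` and `history.csv` so a
#' model can be reloaded (numbers serialized at full double precision; the
#' text round trip is faithful to ~1e-13 relative).
#'
#' @param model a `trained_mlp`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_mlp <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(spec = unclass(model$spec), feature_names = model$feature_names,
         size_class = model$size_class),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    lapply(model$scaler, unname),
    file.path(dir, "scaler.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(y_scaler = model$y_scaler,
         layers = lapply(model$weights, function(w) {
           list(W = as.vector(w$W), dim = dim(w$W), b = w$b)
         })),
    file.path(dir, "weights.json"), auto_unbox = TRUE, digits = NA
  )
  write.csv(model$history, file.path(dir, "history.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_mlp
#' @param dir directory written by `save_mlp`.
#' @return `load_mlp` returns the reconstructed `trained_mlp`.
#' @export
load_mlp <- function(dir) {
  spec <- jsonlite::read_json(file.path(dir, "spec.json"),
                              simplifyVector = TRUE)
  scaler <- jsonlite::read_json(file.path(dir, "scaler.json"),
                                simplifyVector = TRUE)
  wj <- jsonlite::read_json(file.path(dir, "weights.json"),
                            simplifyVector = TRUE)
  fn <- spec$feature_names
  for (f in c("centre", "scale", "zmin", "zmax", "constant")) {
    if (!is.null(scaler[[f]])) names(scaler[[f]]) <- fn
  }
  weights <- lapply(seq_len(nrow(wj$layers)), function(i) {
    list(W = matrix(wj$layers$W[[i]], wj$layers$dim[[i]][1],
                    wj$layers$dim[[i]][2]),
         b = as.numeric(wj$layers$b[[i]]))
  })
  mspec <- if (length(spec$spec) > 0) {
    structure(spec$spec, class = "mlp_spec")
  } else NULL
  structure(list(
    spec = mspec, weights = weights, feature_names = fn, scaler = scaler,
    y_scaler = wj$y_scaler, size_class = spec$size_class,
    history = read.csv(file.path(dir, "history.csv"))
  ), class = "trained_mlp")
}

#' Write and read feature tables as CSV with a JSON sidecar
#'
#' The CSV holds `point_id`, `date`, the feature columns and the target
#' columns; the sidecar (same path with `.json` appended) records the ordered
#' feature names so the model contract survives the round trip.
#'
#' @param table a `feature_table`.
#' @param path CSV path.
#' @return `path`, invisibly; `read_feature_table` returns the table.
#' @export
write_feature_table <- function(table, path) {
  out <- as.data.frame(table)
  out$date <- format(out$date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(feature_names = attr(table, "feature_names")),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df$point_id <- as.character(df$point_id)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- tibble::as_tibble(df)
  structure(df, class = c("feature_table", class(df)),
            feature_names = side$feature_names)
}
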