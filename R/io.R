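# Plain-text persistence: neuron tables as CSV, rasters/drives as
# MatrixMarket with JSON metadata, events/protocols as JSON, parameters
# and configs as YAML. Write -> read is the identity on all fields.

#' Read and write neuron tables
#'
#' CSV with columns `id`, `x`, `y`, `z`, `hemisphere`, `ap`, `ml`
#' (micrometres; hemisphere in `L`/`R`).
#'
#' @param neurons Neuron table.
#' @param path File path.
#' @return `read_neurons()` returns the tibble; writers return the path
#'   invisibly.
#' @export
write_neurons <- function(neurons, path) {
  write.csv(neurons[, c("id", "x", "y", "z", "hemisphere", "ap", "ml")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_neurons
#' @export
read_neurons <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "x", "y", "z", "hemisphere", "ap", "ml")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("neuron table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  as_tibble(df)
}

#' Read and write spike rasters
#'
#' Counts are stored as a MatrixMarket sparse matrix (`.mtx`) with a JSON
#' sidecar (`<path>.json`) holding `frame_dt`, `t0` and a schema version.
#'
#' @param raster A [spike_raster()].
#' @param path Path to the `.mtx` file.
#' @return `read_raster()` returns the [spike_raster()].
#' @export
write_raster <- function(raster, path) {
  writeMM(raster$counts, path)
  meta <- list(schema = "tectalnp/raster/1", frame_dt = raster$frame_dt,
               t0 = raster$t0, dims = dim(raster$counts))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$schema, "tectalnp/raster/1")) {
    abort(sprintf("unsupported raster schema: %s", meta$schema %||% "<none>"))
  }
  counts <- readMM(path)
  spike_raster(counts, frame_dt = meta$frame_dt, t0 = meta$t0)
}

#' Read and write model parameters and configs as YAML
#' @param params A [model_params()] (or any named list).
#' @param path File path.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  do.call(model_params, yaml::read_yaml(path))
}

#' Read and write event tables as JSON
#' @param events Tibble of events.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  jsonlite::write_json(events, path, digits = NA)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Persist a dataset bundle to a directory
#'
#' Writes the neuron table (`neurons.csv`), raster (`raster.mtx` +
#' sidecar), events (`events.json`, if any) and parameters (`params.yaml`)
#' of a dataset into `dir`. `read_bundle()` restores them.
#'
#' @param dataset A [generate_dataset()] result (or a list with compatible
#'   elements).
#' @param dir Directory (created if needed).
#' @return `read_bundle()` returns a list with `neurons`, `raster`,
#'   `events`, `params`.
#' @export
write_bundle <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_neurons(dataset$neurons, file.path(dir, "neurons.csv"))
  write_raster(dataset$raster, file.path(dir, "raster.mtx"))
  if (!is.null(dataset$events)) {
    write_events(dataset$events, file.path(dir, "events.json"))
  }
  write_params(dataset$params, file.path(dir, "params.yaml"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  out <- list(
    neurons = read_neurons(file.path(dir, "neurons.csv")),
    raster = read_raster(file.path(dir, "raster.mtx")),
    params = read_params(file.path(dir, "params.yaml")))
  ev <- file.path(dir, "events.json")
  if (file.exists(ev)) out$events <- read_events(ev)
  out
}
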