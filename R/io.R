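# Plain-text serialization: PNG for images, JSON for feature sets and
# decoders (sparse index/value weights), CSV for matrices. Every JSON
# artifact embeds a format version tag and is verified on read.

FORMAT_VERSION <- "deeprecon/1"

#' Write an image as PNG
#'
#' Pixels are clipped to `[0, 255]` on export (optimization itself is
#' unconstrained).
#'
#' @param image H x W x 3 array.
#' @param path output file.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clip_image(image) / 255, target = path)
  invisible(path)
}

#' Read a PNG image to the `[0, 255]` scale
#'
#' @param path PNG file.
#' @return H x W x 3 array.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE] # drop alpha
  x * 255
}

check_version <- function(obj, path) {
  if (is.null(obj$version) || !identical(obj$version, FORMAT_VERSION))
    stop("file '", path, "' is not a recognized deeprecon artifact ",
         "(missing or mismatched version tag)", call. = FALSE)
}

read_json_checked <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("corrupted or unreadable JSON file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  check_version(obj, path)
  obj
}

#' Save / load a FeatureSet as JSON
#'
#' Full-precision values, one array per layer, with the provenance and a
#' format version tag; the round trip is lossless.
#'
#' @param fs a [feature_set()].
#' @param path file path.
#' @return `load_feature_set` returns the [feature_set()].
#' @export
save_feature_set <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  obj <- list(version = FORMAT_VERSION, type = "feature_set",
              provenance = attr(fs, "provenance"),
              layers = lapply(unclass(fs), identity))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_feature_set
#' @export
load_feature_set <- function(path) {
  obj <- read_json_checked(path)
  if (!identical(obj$type, "feature_set"))
    stop("'", path, "' does not contain a feature_set", call. = FALSE)
  feature_set(obj$layers, provenance = obj$provenance)
}

#' Save / load a layer decoder as JSON
#'
#' Weights are stored sparsely as voxel-index / value pairs per unit.
#' Loading reproduces identical predictions.
#'
#' @param decoder a `layer_decoder`.
#' @param path file path.
#' @return `load_layer_decoder` returns the `layer_decoder`.
#' @export
save_layer_decoder <- function(decoder, path) {
  stopifnot(inherits(decoder, "layer_decoder"))
  units <- lapply(seq_along(decoder$units), function(k) {
    u <- decoder$units[[k]]
    sel <- decoder$selections[[k]]
    nz <- which(u$weights != 0)
    list(voxels = sel$indices, sel_cor = sel$correlations,
         w_idx = nz, w_val = u$weights[nz], bias = u$bias,
         alpha = u$ard_precisions, converged = u$converged,
         noise_precision = u$noise_precision)
  })
  obj <- list(version = FORMAT_VERSION, type = "layer_decoder",
              layer = decoder$layer, n_voxels = decoder$n_voxels,
              n_units_total = decoder$n_units_total,
              unit_indices = decoder$unit_indices,
              train_mean = decoder$train_stats$mean,
              train_sd = decoder$train_stats$sd,
              units = units)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_layer_decoder
#' @export
load_layer_decoder <- function(path) {
  obj <- read_json_checked(path)
  if (!identical(obj$type, "layer_decoder"))
    stop("'", path, "' does not contain a layer_decoder", call. = FALSE)
  units <- vector("list", length(obj$units$bias))
  sels <- vector("list", length(units))
  as_num <- function(x) if (is.null(x)) numeric(0) else as.numeric(x)
  as_int <- function(x) if (is.null(x)) integer(0) else as.integer(x)
  for (k in seq_along(units)) {
    row <- lapply(obj$units, function(col) if (is.list(col)) col[[k]] else col[k])
    p <- length(as_int(row$voxels))
    w <- numeric(p)
    w[as_int(row$w_idx)] <- as_num(row$w_val)
    units[[k]] <- structure(list(weights = w, bias = as.numeric(row$bias),
                                 ard_precisions = as_num(row$alpha),
                                 converged = isTRUE(row$converged),
                                 noise_precision = as.numeric(row$noise_precision)),
                            class = "unit_decoder")
    sels[[k]] <- structure(list(indices = as_int(row$voxels),
                                correlations = as_num(row$sel_cor),
                                cap = NA_integer_),
                           class = "voxel_selection")
  }
  structure(list(layer = obj$layer, units = units, selections = sels,
                 unit_indices = as.integer(obj$unit_indices),
                 n_units_total = as.integer(obj$n_units_total),
                 n_voxels = as.integer(obj$n_voxels),
                 train_stats = list(mean = as.numeric(obj$train_mean),
                                    sd = as.numeric(obj$train_sd))),
            class = "layer_decoder")
}

#' Save / load a sample matrix as CSV
#'
#' First column `label`, remaining columns voxels.
#'
#' @param samples a [sample_matrix()].
#' @param path CSV file path.
#' @return `load_sample_matrix` returns the [sample_matrix()].
#' @export
save_sample_matrix <- function(samples, path) {
  stopifnot(inherits(samples, "sample_matrix"))
  df <- data.table::data.table(label = samples$labels)
  df <- cbind(df, data.table::as.data.table(samples$data))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname save_sample_matrix
#' @export
load_sample_matrix <- function(path) {
  df <- data.table::fread(path)
  if (!"label" %in% names(df))
    stop("'", path, "' is not a saved sample matrix (no label column)", call. = FALSE)
  labels <- as.character(df$label)
  sample_matrix(as.matrix(df[, -1, with = FALSE]), labels)
}

#' Save / load a run time series
#'
#' The voxel data go to `<prefix>_data.csv`, motion parameters to a plain
#' six-column text table `<prefix>_motion.txt`, and scan metadata to
#' `<prefix>_meta.json`.
#'
#' @param run a [run_timeseries()].
#' @param prefix path prefix (no extension).
#' @return `load_run_timeseries` returns the [run_timeseries()].
#' @export
save_run_timeseries <- function(run, prefix) {
  stopifnot(inherits(run, "run_timeseries"))
  data.table::fwrite(data.table::as.data.table(run$data),
                     paste0(prefix, "_data.csv"))
  utils::write.table(run$motion, paste0(prefix, "_motion.txt"),
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(version = FORMAT_VERSION, type = "run_meta",
                            tr_seconds = run$tr_seconds,
                            rest_prefix_seconds = run$rest_prefix_seconds),
                       paste0(prefix, "_meta.json"),
                       digits = I(17), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname save_run_timeseries
#' @export
load_run_timeseries <- function(prefix) {
  meta <- read_json_checked(paste0(prefix, "_meta.json"))
  data <- as.matrix(data.table::fread(paste0(prefix, "_data.csv")))
  motion <- as.matrix(utils::read.table(paste0(prefix, "_motion.txt")))
  run_timeseries(data, tr_seconds = meta$tr_seconds, motion = motion,
                 rest_prefix_seconds = meta$rest_prefix_seconds)
}

#' Write a stimulus set to PNG files plus a manifest CSV
#'
#' @param stimuli a `stimulus_set`.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV.
#' @export
write_stimulus_set <- function(stimuli, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(stimuli$labels))
  for (i in seq_along(stimuli$labels)) {
    files[i] <- file.path(dir, paste0(stimuli$labels[i], ".png"))
    write_image_png(stimuli$images[[i]], files[i])
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(label = stimuli$labels, family = stimuli$family,
                              file = basename(files)),
                   manifest, row.names = FALSE)
  manifest
}
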