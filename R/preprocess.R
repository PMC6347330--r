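# Block-design fMRI preprocessing: run-level voxel time series in, one
# sample per stimulus block out. The pipeline order is fixed:
# remove_nuisance -> normalize_to_rest -> despike -> average_blocks.
# Discarding the initial scanner-instability volumes is the caller's
# responsibility (the simulator simply does not produce them).

#' Construct a run-level voxel time series
#'
#' @param data volumes x voxels numeric matrix.
#' @param tr_seconds repetition time in seconds (2 for the reference
#'   protocol).
#' @param motion volumes x 6 matrix of rigid-body motion parameters; defaults
#'   to all-zero (no motion regressors beyond trend and intercept).
#' @param rest_prefix_seconds duration of the initial rest period used as the
#'   normalization baseline (24 s in the reference protocol).
#' @return object of class `run_timeseries`.
#' @export
run_timeseries <- function(data, tr_seconds = 2, motion = NULL,
                           rest_prefix_seconds = 24) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("time series contains non-finite values", call. = FALSE)
  if (is.null(motion)) motion <- matrix(0, nrow(data), 6L)
  motion <- as.matrix(motion)
  if (nrow(motion) != nrow(data) || ncol(motion) != 6L)
    stop("motion must be a volumes x 6 matrix aligned with the data", call. = FALSE)
  stopifnot(tr_seconds > 0, rest_prefix_seconds >= 0)
  structure(list(data = data, tr_seconds = tr_seconds, motion = motion,
                 rest_prefix_seconds = rest_prefix_seconds),
            class = "run_timeseries")
}

#' Construct a block design
#'
#' @param onsets,durations numeric vectors in seconds; onsets non-decreasing.
#' @param labels stimulus label per block.
#' @param shift_seconds hemodynamic shift applied before averaging (4 s,
#'   i.e. two volumes at TR 2, in the reference protocol).
#' @return object of class `block_design`.
#' @export
block_design <- function(onsets, durations, labels, shift_seconds = 4) {
  stopifnot(length(onsets) == length(durations),
            length(onsets) == length(labels))
  if (is.unsorted(onsets)) stop("block onsets must be non-decreasing", call. = FALSE)
  structure(list(onsets = as.numeric(onsets), durations = as.numeric(durations),
                 labels = as.character(labels),
                 shift_seconds = as.numeric(shift_seconds)),
            class = "block_design")
}

#' Construct a samples x voxels matrix with stimulus labels
#'
#' @param data samples x voxels numeric matrix.
#' @param labels character vector, one stimulus label per row.
#' @return object of class `sample_matrix`.
#' @export
sample_matrix <- function(data, labels) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("sample matrix contains non-finite values", call. = FALSE)
  if (nrow(data) != length(labels))
    stop("one label per sample row is required", call. = FALSE)
  structure(list(data = data, labels = as.character(labels)),
            class = "sample_matrix")
}

#' Regress nuisance signals out of each voxel
#'
#' Per voxel, removes the least-squares fit of an intercept, a linear trend
#' and the six motion parameters, keeping the residual. With the default
#' `keep_mean = TRUE` the voxel's mean amplitude is added back, so that the
#' subsequent rest-period normalization still has a positive baseline to
#' divide by; `keep_mean = FALSE` returns the raw residual (orthogonal to
#' every regressor, including the intercept).
#'
#' @param run a [run_timeseries()].
#' @param keep_mean retain each voxel's mean amplitude (default `TRUE`).
#' @return a nuisance-free `run_timeseries`.
#' @export
remove_nuisance <- function(run, keep_mean = TRUE) {
  stopifnot(inherits(run, "run_timeseries"))
  n <- nrow(run$data)
  if (n < 8L) stop("at least 8 volumes are required for nuisance regression", call. = FALSE)
  X <- cbind(intercept = 1, trend = seq_len(n), run$motion)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    # drop collinear columns (e.g. all-zero motion) rather than failing;
    # error only if trend/intercept themselves collide
    keep <- qrX$pivot[seq_len(qrX$rank)]
    if (!all(c(1L, 2L) %in% keep))
      stop("rank-deficient nuisance design: collinear regressors ",
           paste(colnames(X)[setdiff(1:2, keep)], collapse = ", "), call. = FALSE)
    X <- X[, sort(keep), drop = FALSE]
    qrX <- qr(X)
  }
  resid <- qr.resid(qrX, run$data)
  run$data <- if (keep_mean) sweep(resid, 2L, colMeans(run$data), "+") else resid
  run
}

#' Normalize voxel amplitudes to the initial rest period
#'
#' Expresses each voxel as percent signal change relative to its mean
#' amplitude over the initial rest prefix:
#' `100 * (x - m) / m`.
#'
#' @param run a [run_timeseries()] with `rest_prefix_seconds >= tr_seconds`.
#' @param percent if `FALSE`, return the plain ratio `x / m` instead of
#'   percent change.
#' @return a normalized `run_timeseries`.
#' @export
normalize_to_rest <- function(run, percent = TRUE) {
  stopifnot(inherits(run, "run_timeseries"))
  n_rest <- floor(run$rest_prefix_seconds / run$tr_seconds)
  if (n_rest < 1L)
    stop("rest prefix must cover at least one volume", call. = FALSE)
  m <- colMeans(run$data[seq_len(n_rest), , drop = FALSE])
  bad <- which(m <= 0)
  if (length(bad))
    stop("non-positive rest-period mean for voxel(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  run$data <- if (percent) 100 * sweep(sweep(run$data, 2L, m), 2L, m, "/")
    else sweep(run$data, 2L, m, "/")
  run
}

#' Clip extreme values voxel-wise
#'
#' Within the run, values beyond `mean +/- sd_limit * SD` of each voxel are
#' clipped to that boundary (the SD is computed once, on the input).
#' Zero-variance voxels pass through unchanged.
#'
#' @param run a [run_timeseries()].
#' @param sd_limit boundary in within-run standard deviations (default 3).
#' @return a despiked `run_timeseries`.
#' @export
despike <- function(run, sd_limit = 3) {
  stopifnot(inherits(run, "run_timeseries"), sd_limit > 0)
  if (nrow(run$data) < 2L) stop("at least 2 volumes are required", call. = FALSE)
  mu <- colMeans(run$data)
  sd_ <- apply(run$data, 2L, stats::sd)
  lo <- mu - sd_limit * sd_
  hi <- mu + sd_limit * sd_
  x <- run$data
  for (j in seq_len(ncol(x))) {
    if (sd_[j] == 0) next
    x[, j] <- pmin(pmax(x[, j], lo[j]), hi[j])
  }
  run$data <- x
  run
}

block_volume_indices <- function(run, design, i) {
  tr <- run$tr_seconds
  start_s <- design$onsets[i] + design$shift_seconds
  n_vol <- round(design$durations[i] / tr)
  first <- round(start_s / tr) + 1L # volume covering [start_s, start_s + tr)
  idx <- seq(first, length.out = n_vol)
  if (max(idx) > nrow(run$data) || min(idx) < 1L)
    stop("shifted window of block ", i, " ('", design$labels[i],
         "') falls outside the run", call. = FALSE)
  idx
}

#' Average volumes within hemodynamically shifted stimulus blocks
#'
#' Each sample is the mean of the volumes covering one stimulus block after
#' shifting by `shift_seconds` (rounded to whole volumes) to compensate for
#' hemodynamic delay: an 8-s block at TR 2 averages 4 volumes, a 12-s block
#' 6 volumes, a 16-s imagery block 8 volumes.
#'
#' @param run a [run_timeseries()].
#' @param design a [block_design()].
#' @return a [sample_matrix()], one row per block, labels preserved in
#'   block order.
#' @export
average_blocks <- function(run, design) {
  stopifnot(inherits(run, "run_timeseries"), inherits(design, "block_design"))
  n_blocks <- length(design$onsets)
  out <- matrix(0, n_blocks, ncol(run$data))
  for (i in seq_len(n_blocks)) {
    idx <- block_volume_indices(run, design, i)
    out[i, ] <- colMeans(run$data[idx, , drop = FALSE])
  }
  sample_matrix(out, design$labels)
}

#' Full run-to-samples preprocessing pipeline
#'
#' Applies, in order: nuisance regression, rest normalization, despiking,
#' and hemodynamically shifted block averaging.
#'
#' @param run a [run_timeseries()].
#' @param design a [block_design()].
#' @param sd_limit despiking boundary in SDs.
#' @param percent percent-signal-change normalization (see
#'   [normalize_to_rest()]).
#' @return a [sample_matrix()].
#' @export
preprocess_run <- function(run, design, sd_limit = 3, percent = TRUE) {
  run <- remove_nuisance(run)
  run <- normalize_to_rest(run, percent = percent)
  run <- despike(run, sd_limit = sd_limit)
  average_blocks(run, design)
}

#' Row-bind sample matrices from multiple runs
#'
#' @param ... `sample_matrix` objects.
#' @return a combined `sample_matrix`.
#' @export
bind_samples <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "sample_matrix"))
    xs <- xs[[1]]
  sample_matrix(do.call(rbind, lapply(xs, `[[`, "data")),
                unlist(lapply(xs, `[[`, "labels")))
}

#' Average rows of a sample matrix that share a stimulus label
#'
#' Trial averaging raises the signal-to-noise ratio of test samples before
#' feature decoding. Label order of first appearance is preserved.
#'
#' @param samples a [sample_matrix()].
#' @return a `sample_matrix` with one row per distinct label.
#' @export
average_trials <- function(samples) {
  stopifnot(inherits(samples, "sample_matrix"))
  labs <- unique(samples$labels)
  out <- t(vapply(labs, function(l) {
    colMeans(samples$data[samples$labels == l, , drop = FALSE])
  }, numeric(ncol(samples$data))))
  sample_matrix(out, labs)
}
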