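# Per-unit sparse linear feature decoding: each scalar feature unit of each
# network layer gets its own linear readout from voxel activity, trained
# with an automatic relevance determination (ARD) prior so that irrelevant
# voxels are pruned to exactly zero weight.

#' Select the voxels most correlated with a decoding target
#'
#' Ranks voxels by the absolute Pearson correlation between their training
#' activity and the target unit's feature values and keeps at most `cap`
#' (500 in the reference protocol). Ties are broken by lowest voxel index.
#'
#' @param X a [sample_matrix()] of training samples.
#' @param y_unit numeric vector of target feature values (one per sample).
#' @param cap maximum number of voxels to keep.
#' @param use_abs rank by `|r|` (default); `FALSE` ranks by signed `r`.
#' @return a list with `indices`, `correlations` (signed, in selection
#'   order) and `cap`, of class `voxel_selection`.
#' @export
select_voxels <- function(X, y_unit, cap = 500L, use_abs = TRUE) {
  stopifnot(inherits(X, "sample_matrix"))
  if (nrow(X$data) < 3L) stop("at least 3 samples are required", call. = FALSE)
  if (length(y_unit) != nrow(X$data))
    stop("target length must equal the sample count", call. = FALSE)
  if (stats::sd(y_unit) == 0) stop("constant target", call. = FALSE)
  r <- suppressWarnings(as.numeric(stats::cor(X$data, y_unit)))
  r[is.na(r)] <- 0 # constant voxels carry no signal
  score <- if (use_abs) abs(r) else r
  ord <- order(-score, seq_along(score)) # ties -> lowest index first
  keep <- ord[seq_len(min(cap, length(ord)))]
  structure(list(indices = keep, correlations = r[keep], cap = as.integer(cap)),
            class = "voxel_selection")
}

#' Fit one unit decoder by ARD sparse Bayesian linear regression
#'
#' Fits `y ~ w . x + b` under a Gaussian likelihood with an independent
#' zero-mean Gaussian prior per weight whose precision `alpha_i` is a free
#' hyperparameter (the ARD prior). Hyperparameters are optimized by
#' fixed-point evidence updates (effective degrees of freedom
#' `gamma_i = 1 - alpha_i * Sigma_ii`, `alpha_i <- gamma_i / mu_i^2`,
#' noise precision `<- (n - sum gamma) / ||y - X mu||^2`). Weights whose
#' precision exceeds `prune_threshold` are pruned to exactly zero and drop
#' out of subsequent updates.
#'
#' Columns are standardized internally; returned weights and bias are on the
#' original scale.
#'
#' @param X_sel samples x voxels numeric matrix (already voxel-selected).
#' @param y_unit numeric response vector.
#' @param max_iter maximum number of update sweeps.
#' @param tol convergence tolerance on the largest weight change.
#' @param prune_threshold precision above which a weight is pruned.
#' @return object of class `unit_decoder`: `weights` (dense numeric, pruned
#'   entries exactly zero), `bias`, `ard_precisions`, `converged`,
#'   `noise_precision`.
#' @export
fit_ard <- function(X_sel, y_unit, max_iter = 200L, tol = 1e-4,
                    prune_threshold = 1e8) {
  X_sel <- as.matrix(X_sel)
  y_unit <- as.numeric(y_unit)
  if (!all(is.finite(X_sel)) || !all(is.finite(y_unit)))
    stop("non-finite values in decoder training data", call. = FALSE)
  n <- nrow(X_sel); p <- ncol(X_sel)
  if (n < 2L) stop("at least 2 samples are required", call. = FALSE)
  if (length(y_unit) != n) stop("response length mismatch", call. = FALSE)

  xm <- colMeans(X_sel)
  xs <- apply(X_sel, 2L, stats::sd)
  xs[xs == 0] <- 1
  Z <- sweep(sweep(X_sel, 2L, xm), 2L, xs, "/")
  ym <- mean(y_unit)
  yc <- y_unit - ym

  out <- structure(list(weights = numeric(p), bias = ym,
                        ard_precisions = rep(Inf, p), converged = TRUE,
                        noise_precision = NA_real_),
                   class = "unit_decoder")
  if (stats::sd(y_unit) == 0) {
    out$bias <- ym
    return(out)
  }

  alpha <- rep(1, p)
  beta <- 1 / stats::var(yc)
  mu_full <- numeric(p)
  active <- seq_len(p)
  converged <- FALSE
  Zty <- crossprod(Z, yc)
  for (it in seq_len(max_iter)) {
    A <- active
    if (!length(A)) { converged <- TRUE; break }
    Za <- Z[, A, drop = FALSE]
    S_inv <- beta * crossprod(Za) + diag(alpha[A], nrow = length(A))
    Sig <- tryCatch(chol2inv(chol(S_inv)), error = function(e) solve(S_inv))
    mu <- as.numeric(beta * Sig %*% Zty[A])
    gam <- 1 - alpha[A] * diag(Sig)
    gam <- pmin(pmax(gam, 1e-12), 1)
    mu_new <- numeric(p); mu_new[A] <- mu
    delta <- max(abs(mu_new - mu_full))
    mu_full <- mu_new
    alpha[A] <- gam / pmax(mu^2, 1e-300)
    rss <- sum((yc - Za %*% mu)^2)
    beta <- max(n - sum(gam), 1e-6) / max(rss, 1e-12)
    active <- which(alpha < prune_threshold)
    if (delta < tol) { converged <- TRUE; break }
  }
  mu_full[alpha >= prune_threshold] <- 0

  w_orig <- mu_full / xs
  out$weights <- w_orig
  out$bias <- ym - sum(w_orig * xm)
  out$ard_precisions <- alpha
  out$converged <- converged
  out$noise_precision <- beta
  out
}

#' Train a full layer decoder
#'
#' One [fit_ard()] decoder per feature unit, each on its own
#' correlation-selected voxel subset. For desk-scale runs a seeded unit
#' subsample can be decoded instead of the full layer; the subsample is
#' recorded so downstream consumers (norm correction, reconstruction) use
#' matching unit indices.
#'
#' @param X a [sample_matrix()] of training voxel samples.
#' @param Y samples x units matrix of true feature values for one layer.
#' @param layer layer name.
#' @param voxel_cap maximum voxels per unit (see [select_voxels()]).
#' @param unit_subsample optional integer: decode only this many units,
#'   chosen deterministically from `subsample_seed`.
#' @param subsample_seed seed for the unit subsample.
#' @param max_iter,tol,prune_threshold passed to [fit_ard()].
#' @return object of class `layer_decoder` with fields `layer`, `units`
#'   (list of `unit_decoder`), `selections`, `unit_indices`, `n_units_total`,
#'   `train_stats` (per-unit mean/sd of the true training features).
#' @export
train_layer_decoder <- function(X, Y, layer, voxel_cap = 500L,
                                unit_subsample = NULL, subsample_seed = 1L,
                                max_iter = 200L, tol = 1e-4,
                                prune_threshold = 1e8) {
  stopifnot(inherits(X, "sample_matrix"))
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X$data))
    stop("feature matrix and voxel samples disagree on sample count", call. = FALSE)
  n_total <- ncol(Y)
  unit_idx <- seq_len(n_total)
  if (!is.null(unit_subsample) && unit_subsample < n_total) {
    unit_idx <- with_seed(derive_seed(subsample_seed, 17L),
                          sort(sample.int(n_total, unit_subsample)))
  }
  units <- vector("list", length(unit_idx))
  sels <- vector("list", length(unit_idx))
  for (k in seq_along(unit_idx)) {
    y <- Y[, unit_idx[k]]
    if (stats::sd(y) == 0) {
      # constant unit: intercept-only decoder
      sels[[k]] <- structure(list(indices = integer(0), correlations = numeric(0),
                                  cap = as.integer(voxel_cap)),
                             class = "voxel_selection")
      units[[k]] <- structure(list(weights = numeric(0), bias = mean(y),
                                   ard_precisions = numeric(0), converged = TRUE,
                                   noise_precision = NA_real_),
                              class = "unit_decoder")
      next
    }
    sel <- select_voxels(X, y, cap = voxel_cap)
    dec <- fit_ard(X$data[, sel$indices, drop = FALSE], y,
                   max_iter = max_iter, tol = tol,
                   prune_threshold = prune_threshold)
    sels[[k]] <- sel
    units[[k]] <- dec
  }
  structure(list(layer = layer, units = units, selections = sels,
                 unit_indices = unit_idx, n_units_total = n_total,
                 n_voxels = ncol(X$data),
                 train_stats = list(mean = colMeans(Y)[unit_idx],
                                    sd = apply(Y, 2L, stats::sd)[unit_idx])),
            class = "layer_decoder")
}

predict_layer <- function(decoder, data) {
  n <- nrow(data)
  out <- matrix(0, n, length(decoder$units))
  for (k in seq_along(decoder$units)) {
    u <- decoder$units[[k]]
    idx <- decoder$selections[[k]]$indices
    out[, k] <- if (length(idx))
      as.numeric(data[, idx, drop = FALSE] %*% u$weights + u$bias)
    else rep(u$bias, n)
  }
  out
}

#' Decode feature values for test samples
#'
#' Applies trained layer decoders to voxel samples. With
#' `average_trials = TRUE` (the reference protocol for test data), rows
#' sharing a stimulus label are averaged before prediction.
#'
#' @param decoders a single `layer_decoder` or list of them.
#' @param X_test a [sample_matrix()].
#' @param average_trials average same-label rows first (default `TRUE`).
#' @return object of class `decoded_features`: per-layer samples x units
#'   matrices, plus `labels` and provenance `"decoded"`.
#' @export
predict_features <- function(decoders, X_test, average_trials = TRUE) {
  if (inherits(decoders, "layer_decoder")) decoders <- list(decoders)
  stopifnot(inherits(X_test, "sample_matrix"))
  if (average_trials) X_test <- average_trials(X_test)
  layers <- list()
  for (d in decoders) {
    if (d$n_voxels != ncol(X_test$data))
      stop("voxel count (", ncol(X_test$data),
           ") differs from training (", d$n_voxels, ")", call. = FALSE)
    layers[[d$layer]] <- predict_layer(d, X_test$data)
  }
  structure(list(layers = layers, labels = X_test$labels,
                 unit_indices = lapply(decoders, `[[`, "unit_indices"),
                 provenance = "decoded"),
            class = "decoded_features")
}

#' @export
print.decoded_features <- function(x, ...) {
  cat("<decoded_features>", length(x$labels), "samples, provenance:",
      x$provenance, "\n")
  for (nm in names(x$layers))
    cat("  ", nm, ": ", ncol(x$layers[[nm]]), " units\n", sep = "")
  invisible(x)
}

#' Extract one sample's FeatureSet from decoded features
#'
#' @param decoded a `decoded_features` object.
#' @param label stimulus label of the sample to extract.
#' @return a [feature_set()].
#' @export
decoded_sample <- function(decoded, label) {
  i <- match(label, decoded$labels)
  if (is.na(i)) stop("no decoded sample labelled '", label, "'", call. = FALSE)
  vals <- lapply(decoded$layers, function(m) m[i, ])
  feature_set(vals, provenance = if (identical(decoded$provenance,
                                               "decoded_norm_corrected"))
    "decoded_norm_corrected" else "decoded")
}

#' Reference mean feature norms for norm correction
#'
#' Computes, per layer, the mean Euclidean norm of true feature vectors over
#' a reference image set (the reference protocol uses 10,000 independent
#' natural images; desk-scale runs use a smaller seeded synthetic set).
#'
#' @param images list of image arrays.
#' @param extractor a `dnn_extractor`.
#' @param layers character vector of layer names.
#' @param unit_indices optional named list (layer -> integer vector) when
#'   decoders cover a unit subsample; norms are then computed on the same
#'   subsample.
#' @return object of class `norm_correction`: named numeric `reference_norms`
#'   and a `source` description.
#' @export
compute_norm_correction <- function(images, extractor, layers,
                                    unit_indices = NULL) {
  norms <- matrix(0, length(images), length(layers),
                  dimnames = list(NULL, layers))
  for (i in seq_along(images)) {
    fs <- extract_features(images[[i]], extractor, layers)
    for (l in layers) {
      v <- fs[[l]]
      if (!is.null(unit_indices[[l]])) v <- v[unit_indices[[l]]]
      norms[i, l] <- sqrt(sum(v^2))
    }
  }
  ref <- colMeans(norms)
  if (any(ref <= 0)) stop("zero reference norm for layer(s): ",
                          paste(layers[ref <= 0], collapse = ", "), call. = FALSE)
  structure(list(reference_norms = ref,
                 source = sprintf("%d reference images", length(images))),
            class = "norm_correction")
}

#' Norm-correct decoded features
#'
#' Rescales each decoded layer vector by a single scalar so its Euclidean
#' norm matches the layer's reference mean norm, compensating for the
#' signal-to-noise difference between training and (trial-averaged) test
#' samples. Direction is unchanged.
#'
#' @param decoded a [feature_set()] or `decoded_features` object with
#'   provenance `"decoded"`.
#' @param correction a [compute_norm_correction()] result.
#' @return the same type as `decoded`, provenance
#'   `"decoded_norm_corrected"`.
#' @export
norm_correct <- function(decoded, correction) {
  stopifnot(inherits(correction, "norm_correction"))
  ref <- correction$reference_norms
  scale_vec <- function(v, l) {
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("zero-norm decoded vector in layer '", l, "'", call. = FALSE)
    v * (ref[[l]] / nv)
  }
  if (inherits(decoded, "feature_set")) {
    vals <- lapply(names(decoded), function(l) {
      if (is.null(ref[[l]]) || is.na(ref[[l]]))
        stop("no reference norm for layer '", l, "'", call. = FALSE)
      scale_vec(decoded[[l]], l)
    })
    names(vals) <- names(decoded)
    return(feature_set(vals, provenance = "decoded_norm_corrected"))
  }
  if (inherits(decoded, "decoded_features")) {
    for (l in names(decoded$layers)) {
      if (is.null(ref[[l]]) || is.na(ref[[l]]))
        stop("no reference norm for layer '", l, "'", call. = FALSE)
      m <- decoded$layers[[l]]
      for (i in seq_len(nrow(m))) m[i, ] <- scale_vec(m[i, ], l)
      decoded$layers[[l]] <- m
    }
    decoded$provenance <- "decoded_norm_corrected"
    return(decoded)
  }
  stop("unsupported input to norm_correct", call. = FALSE)
}

#' Feature decoding accuracy
#'
#' `mode = "per_unit"`: Pearson correlation between decoded and true values
#' of each unit across samples. `mode = "per_sample"`: per-sample correlation
#' across units, after z-normalizing both decoded and true test values with
#' per-unit means/SDs estimated from the *training* features (guards against
#' spuriously high correlations from baseline/scale differences across
#' units). Constant series yield `NA` and are excluded from averages.
#'
#' @param decoded,true_features samples x units matrices (matched).
#' @param mode `"per_unit"` or `"per_sample"`.
#' @param train_stats list with `mean` and `sd` per unit (required for
#'   `per_sample`).
#' @return data.frame: per unit (`unit`, `r`) or per sample (`sample`, `r`).
#' @export
decoding_accuracy <- function(decoded, true_features,
                              mode = c("per_unit", "per_sample"),
                              train_stats = NULL) {
  mode <- match.arg(mode)
  decoded <- as.matrix(decoded); true_features <- as.matrix(true_features)
  if (!all(dim(decoded) == dim(true_features)))
    stop("decoded and true feature matrices must have matching dimensions",
         call. = FALSE)
  if (mode == "per_unit") {
    r <- vapply(seq_len(ncol(decoded)), function(j)
      safe_cor(decoded[, j], true_features[, j]), numeric(1))
    return(data.frame(unit = seq_len(ncol(decoded)), r = r))
  }
  if (is.null(train_stats))
    stop("per_sample accuracy requires training mean/sd statistics", call. = FALSE)
  sdz <- train_stats$sd
  sdz[sdz == 0] <- 1
  zt <- sweep(sweep(true_features, 2L, train_stats$mean), 2L, sdz, "/")
  zd <- sweep(sweep(decoded, 2L, train_stats$mean), 2L, sdz, "/")
  r <- vapply(seq_len(nrow(decoded)), function(i)
    safe_cor(zd[i, ], zt[i, ]), numeric(1))
  data.frame(sample = seq_len(nrow(decoded)), r = r)
}

#' Raw versus absolute-value feature decodability of a conv layer
#'
#' Trains unit decoders twice -- once on raw feature values, once on their
#' absolute values -- then averages held-out per-unit decoding accuracy
#' within each convolution filter. fMRI signals are largely insensitive to
#' contrast polarity, so filters whose responses carry luminance sign are
#' expected to be better decoded after rectifying the target.
#'
#' @param X_train,X_test [sample_matrix()] voxel samples.
#' @param Y_train,Y_test samples x units true feature matrices for the layer
#'   (units in the package's channel-fastest flattening order).
#' @param n_filters number of convolution filters in the layer.
#' @param voxel_cap,max_iter passed to [train_layer_decoder()].
#' @param unit_subsample,subsample_seed optional seeded unit subsample.
#' @return data.frame, one row per filter present in the decoded unit set,
#'   columns `filter`, `acc_raw`, `acc_abs`, sorted ascending by `acc_raw`.
#' @export
abs_feature_comparison <- function(X_train, Y_train, X_test, Y_test,
                                   n_filters, voxel_cap = 500L,
                                   max_iter = 100L, unit_subsample = NULL,
                                   subsample_seed = 1L) {
  Y_train <- as.matrix(Y_train); Y_test <- as.matrix(Y_test)
  fit_eval <- function(Ytr, Yte) {
    dec <- train_layer_decoder(X_train, Ytr, layer = "conv_raw_abs",
                               voxel_cap = voxel_cap, max_iter = max_iter,
                               unit_subsample = unit_subsample,
                               subsample_seed = subsample_seed)
    pred <- predict_layer(dec, X_test$data)
    acc <- decoding_accuracy(pred, Yte[, dec$unit_indices, drop = FALSE],
                             mode = "per_unit")
    list(idx = dec$unit_indices, r = acc$r)
  }
  raw <- fit_eval(Y_train, Y_test)
  ab <- fit_eval(abs(Y_train), abs(Y_test))
  filt <- ((raw$idx - 1L) %% n_filters) + 1L
  agg <- function(r) tapply(r, filt, mean, na.rm = TRUE)
  out <- data.frame(filter = as.integer(names(agg(raw$r))),
                    acc_raw = as.numeric(agg(raw$r)),
                    acc_abs = as.numeric(agg(ab$r)))
  out[order(out$acc_raw), , drop = FALSE]
}
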