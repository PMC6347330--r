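# Image reconstruction by feature matching: find the image v* minimizing
#   0.5 * sum_l beta_l || Phi_l(v) - y_l ||^2
# over pixels, or over the latent code z of a generator network G with
# v = G(z). Phi_l are the extractor's pre-rectification layer outputs and
# y_l the (decoded) target features.

#' Layer weights balancing multi-layer contributions
#'
#' Sets each layer's weight to the inverse squared Euclidean norm of its
#' target feature vector, `beta_l = 1 / ||y_l||^2`, so every layer term
#' starts on a comparable scale.
#'
#' @param decoded a [feature_set()].
#' @param layers layer names; default all layers of `decoded`.
#' @return named numeric vector of weights.
#' @export
compute_layer_weights <- function(decoded, layers = names(decoded)) {
  w <- vapply(layers, function(l) {
    v <- decoded[[l]]
    if (is.null(v)) stop("layer '", l, "' missing from decoded features", call. = FALSE)
    n2 <- sum(v^2)
    if (n2 == 0) stop("zero-norm feature vector in layer '", l, "'", call. = FALSE)
    1 / n2
  }, numeric(1))
  names(w) <- layers
  w
}

#' Reconstruction configuration
#'
#' @param layers character vector of layer names to match.
#' @param layer_weights named numeric `beta_l` per layer; `NULL` means
#'   compute from the decoded features via [compute_layer_weights()].
#' @param optimizer `"lbfgs"` (default) or `"momentum_gd"`.
#' @param max_iter iteration budget (L-BFGS iterations or gradient steps).
#' @param initial_image an H x W x 3 array, or one of the presets `"mean"`
#'   (spatially uniform image at `mean_rgb`), `"zero"`, `"random"` (seeded
#'   uniform in `[0, 255]`).
#' @param mean_rgb length-3 RGB used by the `"mean"` preset; in the
#'   reference analysis this is the mean RGB of the natural-image corpus.
#' @param seed integer seed for the `"random"` preset.
#' @param snapshot_every store a snapshot of the best image every this many
#'   loss evaluations (0 = none).
#' @param momentum,step_size momentum coefficient and step size (on the
#'   normalized gradient by default) for `"momentum_gd"`.
#' @param normalize_gradient for `"momentum_gd"`, divide the gradient by its
#'   Euclidean norm before stepping (default `TRUE`; robust to the loss
#'   scale but converges only to within the step size). Set `FALSE` with an
#'   appropriately small `step_size` for asymptotically exact convergence,
#'   e.g. against closed-form solutions.
#' @param lbfgs_history number of L-BFGS correction pairs.
#' @param lbfgs_factr L-BFGS convergence factor (machine-precision
#'   multiples; smaller is stricter).
#' @return object of class `recon_config`.
#' @export
recon_config <- function(layers, layer_weights = NULL,
                         optimizer = c("lbfgs", "momentum_gd"),
                         max_iter = 500L, initial_image = "mean",
                         mean_rgb = c(128, 128, 128), seed = 1L,
                         snapshot_every = 0L, momentum = 0.9,
                         step_size = 1.0, normalize_gradient = TRUE,
                         lbfgs_history = 10L, lbfgs_factr = 1e3) {
  optimizer <- match.arg(optimizer)
  stopifnot(length(layers) >= 1L, max_iter >= 1L)
  if (!is.null(layer_weights)) {
    if (!all(layers %in% names(layer_weights)))
      stop("layer_weights must cover every layer in `layers`", call. = FALSE)
    if (any(layer_weights[layers] <= 0))
      stop("layer weights must be positive", call. = FALSE)
  }
  structure(list(layers = layers, layer_weights = layer_weights,
                 optimizer = optimizer, max_iter = as.integer(max_iter),
                 initial_image = initial_image, mean_rgb = mean_rgb,
                 seed = as.integer(seed),
                 snapshot_every = as.integer(snapshot_every),
                 momentum = momentum, step_size = step_size,
                 normalize_gradient = isTRUE(normalize_gradient),
                 lbfgs_history = as.integer(lbfgs_history),
                 lbfgs_factr = lbfgs_factr),
            class = "recon_config")
}

initial_image_from <- function(config, extractor) {
  dims <- extractor$arch$input
  ini <- config$initial_image
  if (is.array(ini)) {
    ini <- as_image_tensor(ini)
    if (!all(dim(ini) == dims)) ini <- resize_bilinear(ini, dims[1], dims[2])
    return(ini)
  }
  switch(as.character(ini),
         mean = {
           out <- array(0, dims)
           for (c in 1:3) out[, , c] <- config$mean_rgb[c]
           out
         },
         zero = array(0, dims),
         random = with_seed(derive_seed(config$seed, 5L),
                            array(stats::runif(prod(dims), 0, 255), dims)),
         stop("unknown initial image preset '", ini, "'", call. = FALSE))
}

#' Feature-matching loss and its pixel gradient
#'
#' Evaluates `0.5 * sum_l beta_l ||Phi_l(v) - y_l||^2` together with its
#' per-layer breakdown and the exact gradient with respect to the pixels
#' (computed by backpropagation through the extractor).
#'
#' @param image H x W x 3 array at the extractor's input size.
#' @param decoded a [feature_set()] of target features.
#' @param weights named `beta_l` vector (layers to include).
#' @param extractor a `dnn_extractor` with weights.
#' @param unit_indices optional named list (layer -> integer vector): match
#'   only this unit subsample of each layer (targets are then vectors over
#'   the subsample).
#' @return list with `value`, `per_layer`, `gradient` (H x W x 3 array).
#' @export
recon_loss <- function(image, decoded, weights, extractor,
                       unit_indices = NULL) {
  layers <- names(weights)
  missing_l <- setdiff(layers, names(decoded))
  if (length(missing_l))
    stop("decoded features missing layer(s): ",
         paste(missing_l, collapse = ", "), call. = FALSE)
  fwd <- net_forward(extractor, image, need = layers)
  uc <- unit_counts(extractor)
  per_layer <- numeric(length(layers)); names(per_layer) <- layers
  inj <- list()
  for (l in layers) {
    phi <- fwd$features[[l]]
    y <- decoded[[l]]
    if (!is.null(unit_indices[[l]])) {
      sub <- unit_indices[[l]]
      if (length(y) != length(sub))
        stop("target vector of layer '", l, "' does not match its unit subsample",
             call. = FALSE)
      d_full <- numeric(uc[[l]])
      d_sub <- phi[sub] - y
      d_full[sub] <- d_sub
      per_layer[l] <- 0.5 * weights[[l]] * sum(d_sub^2)
      inj[[l]] <- weights[[l]] * d_full
    } else {
      if (length(y) != length(phi))
        stop("target vector of layer '", l, "' has length ", length(y),
             ", expected ", length(phi), call. = FALSE)
      d <- phi - y
      per_layer[l] <- 0.5 * weights[[l]] * sum(d^2)
      inj[[l]] <- weights[[l]] * d
    }
  }
  grad <- net_backward(extractor, fwd, inj)
  list(value = sum(per_layer), per_layer = per_layer, gradient = grad)
}

# Shared optimization driver over a generic parameterization:
#   value_grad(par) -> list(value, gradient (vector), per_layer)
run_optimizer <- function(par0, value_grad, config, project = identity,
                          lower = -Inf, upper = Inf) {
  best <- list(value = Inf, par = par0, per_layer = NULL)
  trace <- numeric(0)
  snapshots <- list()
  n_eval <- 0L
  eval_cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(eval_cache$par) && identical(par, eval_cache$par))
      return(eval_cache$res)
    res <- value_grad(par)
    n_eval <<- n_eval + 1L
    trace[n_eval] <<- res$value
    if (is.finite(res$value) && res$value < best$value) {
      best <<- list(value = res$value, par = par, per_layer = res$per_layer)
      if (config$snapshot_every > 0L &&
          (length(snapshots) == 0L ||
           n_eval - attr(snapshots[[length(snapshots)]], "eval") >=
             config$snapshot_every))
        snapshots[[length(snapshots) + 1L]] <<-
          structure(list(par = par, value = res$value), eval = n_eval)
    }
    if (!is.finite(res$value))
      stop(structure(class = c("recon_divergence", "error", "condition"),
                     list(message = "optimization diverged to a non-finite loss",
                          call = NULL, trace = trace)))
    eval_cache$par <- par
    eval_cache$res <- res
    res
  }
  if (config$optimizer == "lbfgs") {
    fn <- function(p) evaluate(project(p))$value
    gr <- function(p) evaluate(project(p))$gradient
    stats::optim(par0, fn, gr, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = config$max_iter,
                                lmm = config$lbfgs_history,
                                factr = config$lbfgs_factr))
  } else {
    par <- par0
    vel <- numeric(length(par0))
    for (it in seq_len(config$max_iter)) {
      res <- evaluate(par)
      g <- res$gradient
      gn <- sqrt(sum(g^2))
      if (gn == 0) break
      step <- if (config$normalize_gradient) g / gn else g
      vel <- config$momentum * vel - config$step_size * step
      par <- project(par + vel)
    }
    evaluate(par)
  }
  list(best = best, trace = trace, snapshots = snapshots, n_eval = n_eval)
}

#' Reconstruct an image by optimizing pixels
#'
#' Iteratively updates the pixels of an initial image to minimize the
#' (multi-layer, weighted) feature-matching loss against the decoded
#' features. The best-loss iterate seen during optimization is returned, so
#' the final loss never exceeds the initial loss. Pixels are unconstrained
#' during optimization; clip with [clip_image()] on export.
#'
#' @param decoded a [feature_set()] covering `config$layers`.
#' @param extractor a `dnn_extractor` with weights.
#' @param config a [recon_config()].
#' @param unit_indices optional per-layer unit subsample (see
#'   [recon_loss()]).
#' @return object of class `recon_result`: `image`, `loss_trace`,
#'   `per_layer_loss`, `initial_loss`, `final_loss`, `snapshots`.
#' @export
reconstruct_pixel <- function(decoded, extractor, config,
                              unit_indices = NULL) {
  stopifnot(inherits(config, "recon_config"))
  weights <- config$layer_weights
  if (is.null(weights)) {
    weights <- compute_layer_weights(decoded, config$layers)
  } else weights <- weights[config$layers]
  x0 <- initial_image_from(config, extractor)
  dims <- dim(x0)
  vg <- function(par) {
    img <- array(par, dims)
    r <- recon_loss(img, decoded, weights, extractor, unit_indices)
    list(value = r$value, gradient = as.vector(r$gradient),
         per_layer = r$per_layer)
  }
  out <- run_optimizer(as.vector(x0), vg, config)
  structure(list(image = array(out$best$par, dims),
                 loss_trace = out$trace,
                 per_layer_loss = out$best$per_layer,
                 initial_loss = out$trace[1],
                 final_loss = out$best$value,
                 snapshots = lapply(out$snapshots, function(s)
                   list(image = array(s$par, dims), loss = s$value)),
                 latent = NULL, config = config),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat("<recon_result> loss:", format(x$initial_loss), "->",
      format(x$final_loss), "in", length(x$loss_trace), "evaluations\n")
  invisible(x)
}

#' Clip an image to the displayable [0, 255] range
#'
#' @param image numeric array.
#' @return clipped array.
#' @export
clip_image <- function(image) pmin(pmax(image, 0), 255)

# ---- generator handles -----------------------------------------------------

#' Identity generator
#'
#' Maps a latent vector directly to pixels (latent dimension equals the
#' pixel count); latent-space reconstruction through it is pixel-space
#' reconstruction with bounded variables.
#'
#' @param dims image dimensions `c(H, W, C)`.
#' @param bounds symmetric per-element latent bound; the identity latent is
#'   on the pixel scale, so the default allows the full `[0, 255]` range.
#' @return object of class `generator_handle`.
#' @export
identity_generator <- function(dims, bounds = 255) {
  dims <- as.integer(dims)
  structure(list(latent_dim = prod(dims), dims = dims,
                 forward = function(z) unflatten_hwc(z, dims),
                 backward = function(z, dimg) flatten_hwc(dimg),
                 bounds = rep(abs(bounds), prod(dims)),
                 source = "identity"),
            class = "generator_handle")
}

#' Seeded linear toy generator
#'
#' `G(z) = A z + c` reshaped to an image; a desk-scale stand-in exercising
#' the latent-space reconstruction path with a generator whose Jacobian is
#' known exactly.
#'
#' @param seed integer seed for the map.
#' @param latent_dim latent dimensionality.
#' @param dims output image dimensions `c(H, W, C)`.
#' @param bounds symmetric per-element latent bound (default 3, a typical
#'   scale for a unit-Gaussian latent).
#' @param offset scalar added to every output pixel (default 128, mid-gray).
#' @return object of class `generator_handle` with the dense map in `A`.
#' @export
toy_linear_generator <- function(seed, latent_dim, dims,
                                 bounds = 3, offset = 128) {
  dims <- as.integer(dims)
  n_pix <- prod(dims)
  A <- with_seed(derive_seed(seed, 11L),
                 matrix(stats::rnorm(n_pix * latent_dim,
                                     sd = 255 / sqrt(latent_dim)),
                        n_pix, latent_dim))
  structure(list(latent_dim = as.integer(latent_dim), dims = dims, A = A,
                 offset = offset,
                 forward = function(z)
                   unflatten_hwc(as.numeric(A %*% z) + offset, dims),
                 backward = function(z, dimg)
                   as.numeric(crossprod(A, flatten_hwc(dimg))),
                 bounds = rep(abs(bounds), latent_dim),
                 source = "toy_linear"),
            class = "generator_handle")
}

#' Reconstruct an image in a generator's latent space
#'
#' Optimizes the latent code `z` by gradient descent with momentum, starting
#' from the zero vector, so that the generated image `G(z)` matches the
#' decoded features; each element of `z` is clipped to its allowed range
#' after every step, and the reconstruction is `G(z*)`. Constraining the
#' solution to the generator's output manifold acts as a natural-image
#' prior.
#'
#' @param decoded a [feature_set()] covering `config$layers`.
#' @param extractor a `dnn_extractor` whose input size matches the
#'   generator's output.
#' @param generator a `generator_handle`.
#' @param config a [recon_config()]. With `"momentum_gd"` (the default and
#'   the reference protocol) each element of `z` is clipped to its range
#'   after every step; with `"lbfgs"` the range is enforced natively as box
#'   constraints.
#' @param unit_indices optional per-layer unit subsample.
#' @return a `recon_result`; `latent` holds `z*`.
#' @export
reconstruct_latent <- function(decoded, extractor, generator, config,
                               unit_indices = NULL) {
  stopifnot(inherits(config, "recon_config"),
            inherits(generator, "generator_handle"))
  if (!all(generator$dims == extractor$arch$input))
    stop("generator output size does not match the extractor input", call. = FALSE)
  weights <- config$layer_weights
  if (is.null(weights)) {
    weights <- compute_layer_weights(decoded, config$layers)
  } else weights <- weights[config$layers]
  bounds <- generator$bounds
  project <- function(z) pmin(pmax(z, -bounds), bounds)
  vg <- function(z) {
    img <- generator$forward(z)
    r <- recon_loss(img, decoded, weights, extractor, unit_indices)
    list(value = r$value, gradient = generator$backward(z, r$gradient),
         per_layer = r$per_layer)
  }
  z0 <- numeric(generator$latent_dim) # zero-vector initialization
  out <- run_optimizer(z0, vg, config, project = project,
                       lower = -bounds, upper = bounds)
  z_best <- out$best$par
  structure(list(image = generator$forward(z_best),
                 loss_trace = out$trace,
                 per_layer_loss = out$best$per_layer,
                 initial_loss = out$trace[1],
                 final_loss = out$best$value,
                 snapshots = lapply(out$snapshots, function(s)
                   list(image = generator$forward(s$par), loss = s$value)),
                 latent = z_best, config = config),
            class = "recon_result")
}
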