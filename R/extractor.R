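# ---- image tensors ---------------------------------------------------------

#' Validate and coerce an H x W x 3 image array
#'
#' Images are numeric arrays on the 8-bit intensity scale `[0, 255]`, with
#' dimensions height x width x channel (RGB). Grayscale matrices are expanded
#' to three identical channels.
#'
#' @param x numeric matrix or 3-d array.
#' @return a numeric H x W x 3 array.
#' @export
as_image_tensor <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("image must be an H x W x C array", call. = FALSE)
  if (!all(is.finite(x))) stop("image contains non-finite pixel values", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# Flatten an H x W x C array in row-major (height, width, channel-last)
# order: channel varies fastest, then width, then height. This order is the
# package-wide contract for serialized feature vectors.
flatten_hwc <- function(a) {
  if (is.null(dim(a))) return(as.numeric(a))
  as.vector(aperm(a, c(3L, 2L, 1L)))
}

unflatten_hwc <- function(v, dims) {
  aperm(array(v, dim = rev(dims)), c(3L, 2L, 1L))
}

#' Bilinear image resize
#'
#' @param image H x W x C numeric array.
#' @param height,width target size in pixels.
#' @return resized array.
#' @export
resize_bilinear <- function(image, height, width) {
  image <- as_image_tensor(image)
  d <- dim(image)
  if (d[1] == height && d[2] == width) return(image)
  map <- function(n_src, n_tgt) {
    # pixel-center alignment
    s <- (seq_len(n_tgt) - 0.5) * n_src / n_tgt + 0.5
    s <- pmin(pmax(s, 1), n_src)
    lo <- pmin(floor(s), n_src - 1L)
    list(lo = as.integer(lo), frac = s - lo)
  }
  my <- map(d[1], height); mx <- map(d[2], width)
  out <- array(0, dim = c(height, width, d[3]))
  for (ch in seq_len(d[3])) {
    a <- image[, , ch]
    top <- a[my$lo, mx$lo, drop = FALSE] * (1 - mx$frac[col(matrix(0, height, width))]) +
      a[my$lo, mx$lo + 1L, drop = FALSE] * mx$frac[col(matrix(0, height, width))]
    bot <- a[my$lo + 1L, mx$lo, drop = FALSE] * (1 - mx$frac[col(matrix(0, height, width))]) +
      a[my$lo + 1L, mx$lo + 1L, drop = FALSE] * mx$frac[col(matrix(0, height, width))]
    wy <- my$frac[row(matrix(0, height, width))]
    out[, , ch] <- top * (1 - wy) + bot * wy
  }
  out
}

# ---- feature sets ----------------------------------------------------------

#' Construct a FeatureSet
#'
#' A FeatureSet maps layer names to flattened pre-rectification feature
#' vectors, and records whether the values were computed from an image,
#' decoded from brain activity, or decoded and norm-corrected.
#'
#' @param values named list of numeric vectors, one per layer.
#' @param provenance one of `"computed"`, `"decoded"`,
#'   `"decoded_norm_corrected"`.
#' @return an object of class `feature_set`.
#' @export
feature_set <- function(values,
                        provenance = c("computed", "decoded",
                                       "decoded_norm_corrected")) {
  provenance <- match.arg(provenance)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("feature values must be a named list of layer vectors", call. = FALSE)
  for (nm in names(values)) {
    values[[nm]] <- as.numeric(values[[nm]])
    if (!all(is.finite(values[[nm]])))
      stop("non-finite feature values in layer '", nm, "'", call. = FALSE)
  }
  structure(values, class = "feature_set", provenance = provenance)
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> provenance:", attr(x, "provenance"), "\n")
  for (nm in names(x)) cat("  ", nm, ": ", length(x[[nm]]), " units\n", sep = "")
  invisible(x)
}

provenance <- function(fs) attr(fs, "provenance")

# ---- architecture specs ----------------------------------------------------

# A layer descriptor list: conv layers carry filters/kernel, fc layers carry
# units, pool layers halve the spatial grid (2x2, stride 2). Named (conv/fc)
# layers are the feature layers whose pre-rectification outputs are exposed.

#' Describe a small convolutional architecture
#'
#' @param input integer vector `c(height, width, channels)`.
#' @param layers list of layer descriptors; each is a list with `type`
#'   (`"conv"`, `"pool"`, `"fc"`) and, for conv, `name`, `filters`, `kernel`
#'   (odd), for fc, `name` and `units`.
#' @param rectify logical; `FALSE` builds a fully linear network (no
#'   rectifier; pooling, if present, is average pooling in both variants).
#' @return an architecture description (class `dnn_architecture`).
#' @export
dnn_architecture <- function(input, layers, rectify = TRUE) {
  stopifnot(length(input) == 3L, all(input >= 1))
  n_conv_blocks <- 0L; saw_fc <- FALSE; block <- 1L
  for (ly in layers) {
    if (!ly$type %in% c("conv", "pool", "fc"))
      stop("unknown layer type '", ly$type, "'", call. = FALSE)
    if (ly$type == "conv") {
      if (is.null(ly$filters) || ly$filters < 1L)
        stop("degenerate architecture: conv layer with zero filters", call. = FALSE)
      if (saw_fc) stop("conv layer after fc layer is not supported", call. = FALSE)
      n_conv_blocks <- max(n_conv_blocks, block)
    }
    if (ly$type == "pool") block <- block + 1L
    if (ly$type == "fc") {
      if (is.null(ly$units) || ly$units < 1L)
        stop("degenerate architecture: fc layer with zero units", call. = FALSE)
      saw_fc <- TRUE
    }
  }
  structure(list(input = as.integer(input), layers = layers, rectify = rectify),
            class = "dnn_architecture")
}

#' Default toy architecture used throughout tests and simulations
#'
#' Two convolutional blocks and two fully connected layers on a 16 x 16 x 3
#' input: large enough that multi-layer combination is meaningful, small
#' enough that reconstruction runs in seconds on one CPU.
#'
#' @param input input dimensions `c(H, W, C)`; H and W must be multiples of 4.
#' @param filters integer filters for the two conv blocks.
#' @param fc_units integer unit counts for the two fc layers.
#' @param rectify logical; `FALSE` gives a fully linear network.
#' @param pool logical; `FALSE` omits pooling layers (spatial size is then
#'   preserved throughout the conv stack).
#' @return a `dnn_architecture`.
#' @export
toy_architecture <- function(input = c(16L, 16L, 3L), filters = c(8L, 16L),
                             fc_units = c(64L, 10L), rectify = TRUE,
                             pool = TRUE) {
  layers <- list()
  for (b in seq_along(filters)) {
    layers[[length(layers) + 1L]] <-
      list(type = "conv", name = sprintf("conv%d_1", b),
           filters = as.integer(filters[b]), kernel = 3L)
    if (pool) layers[[length(layers) + 1L]] <- list(type = "pool")
  }
  for (j in seq_along(fc_units)) {
    layers[[length(layers) + 1L]] <-
      list(type = "fc", name = sprintf("fc%d", j + 5L),
           units = as.integer(fc_units[j]))
  }
  dnn_architecture(input = input, layers = layers, rectify = rectify)
}

#' The 19-layer reference architecture
#'
#' Sixteen 3x3 same-padding convolutional layers in five blocks
#' (64-64 / 128-128 / 256x4 / 512x4 / 512x4), each block followed by 2x2 max
#' pooling, then fully connected layers fc6 (4096), fc7 (4096) and fc8
#' (1000), for a 224 x 224 x 3 input. Only the architecture (shapes, layer
#' groups) ships with the package; unit counts are derived by shape
#' propagation. Feature extraction requires externally supplied pre-trained
#' weights.
#'
#' @return a `dnn_architecture`.
#' @export
reference_architecture <- function() {
  blocks <- list(c(64L, 64L), c(128L, 128L),
                 c(256L, 256L, 256L, 256L),
                 c(512L, 512L, 512L, 512L),
                 c(512L, 512L, 512L, 512L))
  layers <- list()
  for (b in seq_along(blocks)) {
    for (i in seq_along(blocks[[b]])) {
      layers[[length(layers) + 1L]] <-
        list(type = "conv", name = sprintf("conv%d_%d", b, i),
             filters = blocks[[b]][i], kernel = 3L)
    }
    layers[[length(layers) + 1L]] <- list(type = "pool")
  }
  layers <- c(layers,
              list(list(type = "fc", name = "fc6", units = 4096L),
                   list(type = "fc", name = "fc7", units = 4096L),
                   list(type = "fc", name = "fc8", units = 1000L)))
  dnn_architecture(input = c(224L, 224L, 3L), layers = layers)
}

# Propagate shapes through an architecture. Returns, per layer, the input
# and output dimensions, plus per named layer the flattened unit count and
# (for conv) the filter count used for filter-wise grouping.
propagate_shapes <- function(arch) {
  cur <- arch$input          # c(H, W, C) or scalar length for fc stages
  spatial <- TRUE
  shapes <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$type == "conv") {
      if (!spatial) stop("conv layer on non-spatial input", call. = FALSE)
      out <- c(cur[1], cur[2], ly$filters)
    } else if (ly$type == "pool") {
      if (!spatial) stop("pool layer on non-spatial input", call. = FALSE)
      if (cur[1] %% 2L != 0L || cur[2] %% 2L != 0L)
        stop("pooling requires even spatial dimensions", call. = FALSE)
      out <- c(cur[1] %/% 2L, cur[2] %/% 2L, cur[3])
    } else { # fc
      out <- ly$units
      spatial_in <- spatial
      spatial <- FALSE
      shapes[[i]] <- list(input = cur, output = out, spatial_input = spatial_in)
      cur <- out
      next
    }
    shapes[[i]] <- list(input = cur, output = out, spatial_input = spatial)
    cur <- out
  }
  shapes
}

# Assign the DNN1..DNN8 layer groups: conv blocks (delimited by pooling
# layers) are DNN1..DNN5, fully connected layers are DNN6..DNN8.
layer_groups <- function(arch) {
  block <- 1L; fc_i <- 6L
  groups <- character(0)
  for (ly in arch$layers) {
    if (ly$type == "conv") groups[ly$name] <- paste0("DNN", block)
    if (ly$type == "pool") block <- block + 1L
    if (ly$type == "fc") { groups[ly$name] <- paste0("DNN", fc_i); fc_i <- fc_i + 1L }
  }
  groups
}

# ---- extractor handles -----------------------------------------------------

new_extractor <- function(arch, weights, variant, weights_source) {
  shapes <- propagate_shapes(arch)
  structure(list(arch = arch, weights = weights, variant = variant,
                 weights_source = weights_source, shapes = shapes,
                 groups = layer_groups(arch)),
            class = "dnn_extractor")
}

#' Build a seeded toy feature extractor
#'
#' Draws He-scaled Gaussian weights deterministically from `seed` for the
#' given architecture. Biases are zero, so a linear-mode toy network is an
#' exactly linear map of the pixels.
#'
#' @param seed integer seed; the same seed always yields the same extractor.
#' @param arch a [dnn_architecture()]; default [toy_architecture()].
#' @return an object of class `dnn_extractor` with `variant = "standard"`.
#' @export
build_toy_extractor <- function(seed, arch = toy_architecture()) {
  stopifnot(inherits(arch, "dnn_architecture"))
  shapes <- propagate_shapes(arch)
  weights <- with_seed(as.integer(seed), {
    lapply(seq_along(arch$layers), function(i) {
      ly <- arch$layers[[i]]
      if (ly$type == "conv") {
        cin <- shapes[[i]]$input[3]
        k <- ly$kernel
        sd <- sqrt(2 / (k * k * cin))
        list(kernel = array(stats::rnorm(k * k * cin * ly$filters, sd = sd),
                            dim = c(k, k, cin, ly$filters)),
             bias = rep(0, ly$filters))
      } else if (ly$type == "fc") {
        nin <- prod(shapes[[i]]$input)
        sd <- sqrt(2 / nin)
        list(weight = matrix(stats::rnorm(ly$units * nin, sd = sd),
                             nrow = ly$units, ncol = nin),
             bias = rep(0, ly$units))
      } else NULL
    })
  })
  new_extractor(arch, weights, variant = "standard", weights_source = "toy_seeded")
}

#' Reference extractor handle (architecture only)
#'
#' Carries the 19-layer reference architecture for shape arithmetic
#' ([unit_counts()], layer groups). Feature extraction errors unless weights
#' are attached, since pre-trained weights do not ship with the package.
#'
#' @return a `dnn_extractor` with `weights_source = "architecture_only"`.
#' @export
reference_extractor <- function() {
  new_extractor(reference_architecture(), weights = NULL,
                variant = "standard", weights_source = "architecture_only")
}

#' @export
print.dnn_extractor <- function(x, ...) {
  cat("<dnn_extractor> variant:", x$variant,
      " weights:", x$weights_source, "\n")
  uc <- unit_counts(x)
  for (nm in names(uc))
    cat(sprintf("  %-10s %-6s %d units\n", nm, x$groups[[nm]], uc[[nm]]))
  invisible(x)
}

#' Layer names of an extractor
#'
#' @param extractor a `dnn_extractor`.
#' @param groups optional character vector of layer groups (e.g.
#'   `c("DNN1","DNN2")`) to restrict to.
#' @return character vector of named (conv/fc) layers, in network order.
#' @export
layer_names <- function(extractor, groups = NULL) {
  nms <- names(extractor$groups)
  if (!is.null(groups)) nms <- nms[extractor$groups[nms] %in% groups]
  nms
}

#' Unit counts per named layer
#'
#' Counts are computed from the propagated output shapes of the architecture
#' (height x width x filters for conv layers, unit count for fc layers), not
#' stored constants.
#'
#' @param extractor a `dnn_extractor`.
#' @return named integer vector, one entry per named layer.
#' @export
unit_counts <- function(extractor) {
  stopifnot(inherits(extractor, "dnn_extractor"))
  out <- integer(0)
  for (i in seq_along(extractor$arch$layers)) {
    ly <- extractor$arch$layers[[i]]
    if (!is.null(ly$name))
      out[ly$name] <- as.integer(prod(extractor$shapes[[i]]$output))
  }
  out
}

#' Number of convolution filters of a named conv layer
#'
#' Used to group a conv layer's flattened units by filter (the unit index
#' modulo the filter count, given the channel-fastest flattening order).
#'
#' @param extractor a `dnn_extractor`.
#' @param layer a conv layer name.
#' @return integer filter count.
#' @export
n_filters <- function(extractor, layer) {
  i <- layer_index(extractor, layer)
  ly <- extractor$arch$layers[[i]]
  if (ly$type != "conv") stop("layer '", layer, "' is not convolutional", call. = FALSE)
  ly$filters
}

layer_index <- function(extractor, layer) {
  for (i in seq_along(extractor$arch$layers)) {
    nm <- extractor$arch$layers[[i]]$name
    if (!is.null(nm) && nm == layer) return(i)
  }
  stop("unknown layer name '", layer, "'", call. = FALSE)
}

#' Imagery-variant extractor
#'
#' Replaces max pooling by average pooling and the rectifier by a leaky
#' rectifier with negative slope 0.2, keeping weights and all layer shapes
#' unchanged. Used when the decoded content is mental imagery rather than a
#' seen stimulus.
#'
#' @param extractor a standard-variant `dnn_extractor`.
#' @return the imagery-variant `dnn_extractor`.
#' @export
make_imagery_variant <- function(extractor) {
  stopifnot(inherits(extractor, "dnn_extractor"))
  if (extractor$variant == "imagery")
    stop("extractor is already the imagery variant", call. = FALSE)
  extractor$variant <- "imagery"
  extractor
}

# ---- forward / backward ----------------------------------------------------

rectifier <- function(x, variant) {
  if (variant == "imagery") ifelse(x > 0, x, 0.2 * x) else pmax(x, 0)
}
rectifier_grad <- function(pre, variant) {
  if (variant == "imagery") ifelse(pre > 0, 1, 0.2) else (pre > 0) * 1
}

conv_matrices <- function(kernel) {
  d <- dim(kernel) # k, k, Cin, F
  matrix(aperm(kernel, c(3L, 2L, 1L, 4L)), nrow = d[1] * d[2] * d[3], ncol = d[4])
}

im2col <- function(a, k) {
  d <- dim(a); H <- d[1]; W <- d[2]; C <- d[3]
  p <- (k - 1L) %/% 2L
  apad <- array(0, dim = c(H + 2L * p, W + 2L * p, C))
  apad[p + seq_len(H), p + seq_len(W), ] <- a
  P <- matrix(0, nrow = H * W, ncol = k * k * C)
  b <- 0L
  for (i1 in seq_len(k)) {
    for (i2 in seq_len(k)) {
      slab <- apad[i1 - 1L + seq_len(H), i2 - 1L + seq_len(W), , drop = FALSE]
      dim(slab) <- c(H * W, C)
      P[, b * C + seq_len(C)] <- slab
      b <- b + 1L
    }
  }
  P
}

col2im <- function(dP, dims, k) {
  H <- dims[1]; W <- dims[2]; C <- dims[3]
  p <- (k - 1L) %/% 2L
  dpad <- array(0, dim = c(H + 2L * p, W + 2L * p, C))
  b <- 0L
  for (i1 in seq_len(k)) {
    for (i2 in seq_len(k)) {
      slab <- dP[, b * C + seq_len(C), drop = FALSE]
      dim(slab) <- c(H, W, C)
      dpad[i1 - 1L + seq_len(H), i2 - 1L + seq_len(W), ] <-
        array(dpad[i1 - 1L + seq_len(H), i2 - 1L + seq_len(W), ,
                   drop = FALSE], c(H, W, C)) + slab
      b <- b + 1L
    }
  }
  dpad[p + seq_len(H), p + seq_len(W), , drop = FALSE]
}

pool_forward <- function(a, type) {
  d <- dim(a); H <- d[1]; W <- d[2]; C <- d[3]
  i1 <- seq(1L, H, by = 2L); i2 <- seq(2L, H, by = 2L)
  j1 <- seq(1L, W, by = 2L); j2 <- seq(2L, W, by = 2L)
  s <- array(0, dim = c(H %/% 2L, W %/% 2L, C, 4L))
  s[, , , 1L] <- a[i1, j1, , drop = FALSE]
  s[, , , 2L] <- a[i2, j1, , drop = FALSE]
  s[, , , 3L] <- a[i1, j2, , drop = FALSE]
  s[, , , 4L] <- a[i2, j2, , drop = FALSE]
  slab <- function(q) array(s[, , , q], dim = dim(s)[1:3])
  if (type == "avg") {
    list(out = (slab(1L) + slab(2L) + slab(3L) + slab(4L)) / 4, which = NULL)
  } else {
    out <- pmax(slab(1L), slab(2L), slab(3L), slab(4L))
    # lowest window position attaining the max wins ties (deterministic)
    wh <- array(4L, dim = dim(out))
    for (q in 3:1) wh[slab(q) == out] <- q
    list(out = out, which = wh)
  }
}

pool_backward <- function(dout, dims, type, which) {
  H <- dims[1]; W <- dims[2]; C <- dims[3]
  da <- array(0, dim = dims)
  i1 <- seq(1L, H, by = 2L); i2 <- seq(2L, H, by = 2L)
  j1 <- seq(1L, W, by = 2L); j2 <- seq(2L, W, by = 2L)
  if (type == "avg") {
    q <- dout / 4
    da[i1, j1, ] <- q; da[i2, j1, ] <- q; da[i1, j2, ] <- q; da[i2, j2, ] <- q
  } else {
    da[i1, j1, ] <- dout * (which == 1L)
    da[i2, j1, ] <- dout * (which == 2L)
    da[i1, j2, ] <- dout * (which == 3L)
    da[i2, j2, ] <- dout * (which == 4L)
  }
  da
}

pool_type <- function(extractor) if (extractor$variant == "imagery") "avg" else "max"

# Forward pass caching everything needed for the backward pass, up to the
# deepest requested named layer.
net_forward <- function(extractor, image, need = NULL) {
  if (extractor$weights_source == "architecture_only")
    stop("extractor has no weights loaded (architecture-only handle)", call. = FALSE)
  arch <- extractor$arch
  named <- names(extractor$groups)
  if (is.null(need)) need <- named
  unknown <- setdiff(need, named)
  if (length(unknown))
    stop("unknown layer name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  idx_needed <- vapply(need, function(nm) layer_index(extractor, nm), integer(1))
  i_max <- max(idx_needed)
  a <- image
  cache <- vector("list", i_max)
  features <- list()
  ptype <- pool_type(extractor)
  for (i in seq_len(i_max)) {
    ly <- arch$layers[[i]]
    if (ly$type == "conv") {
      P <- im2col(a, ly$kernel)
      K <- conv_matrices(extractor$weights[[i]]$kernel)
      pre <- P %*% K
      pre <- sweep(pre, 2L, extractor$weights[[i]]$bias, "+")
      dim(pre) <- extractor$shapes[[i]]$output
      cache[[i]] <- list(type = "conv", input_dims = dim(a), pre = pre)
      if (ly$name %in% need) features[[ly$name]] <- flatten_hwc(pre)
      a <- if (arch$rectify) rectifier(pre, extractor$variant) else pre
    } else if (ly$type == "pool") {
      pf <- pool_forward(a, ptype)
      cache[[i]] <- list(type = "pool", input_dims = dim(a), which = pf$which)
      a <- pf$out
    } else { # fc
      xin <- flatten_hwc(a)
      pre <- as.numeric(extractor$weights[[i]]$weight %*% xin +
                          extractor$weights[[i]]$bias)
      cache[[i]] <- list(type = "fc", input_dims = dim(a), pre = pre)
      if (ly$name %in% need) features[[ly$name]] <- pre
      a <- if (arch$rectify) rectifier(pre, extractor$variant) else pre
    }
  }
  list(features = features, cache = cache, i_max = i_max)
}

# Backward pass: `injections` is a named list (layer -> flattened gradient
# with respect to that layer's pre-rectification output); returns the
# gradient with respect to the input image.
net_backward <- function(extractor, fwd, injections) {
  arch <- extractor$arch
  cache <- fwd$cache
  i_max <- fwd$i_max
  ptype <- pool_type(extractor)
  da <- NULL # gradient wrt rectified output of current layer (NULL = zero)
  for (i in seq(i_max, 1L)) {
    ly <- arch$layers[[i]]
    cc <- cache[[i]]
    if (ly$type == "pool") {
      if (is.null(da)) next
      da <- pool_backward(da, cc$input_dims, ptype, cc$which)
    } else {
      pre <- cc$pre
      dpre <- if (is.null(da)) {
        if (is.null(dim(pre))) numeric(length(pre)) else array(0, dim = dim(pre))
      } else if (arch$rectify) {
        rectifier_grad(pre, extractor$variant) * da
      } else da
      if (!is.null(ly$name) && !is.null(injections[[ly$name]])) {
        inj <- injections[[ly$name]]
        dpre <- if (ly$type == "conv") dpre + unflatten_hwc(inj, dim(pre))
          else dpre + inj
      }
      if (ly$type == "conv") {
        K <- conv_matrices(extractor$weights[[i]]$kernel)
        dmat <- dpre; dim(dmat) <- c(prod(dim(pre)[1:2]), dim(pre)[3])
        dP <- dmat %*% t(K)
        da <- col2im(dP, cc$input_dims, ly$kernel)
      } else { # fc
        dx <- as.numeric(crossprod(extractor$weights[[i]]$weight, dpre))
        da <- if (length(cc$input_dims) == 3L) unflatten_hwc(dx, cc$input_dims)
          else dx
      }
    }
  }
  if (is.null(da)) da <- array(0, dim = extractor$arch$input)
  da
}

#' Extract pre-rectification features from an image
#'
#' Runs the extractor forward and returns the flattened pre-rectification
#' outputs of the requested named layers. The image is resized (bilinear) to
#' the extractor's input size if needed.
#'
#' @param image an H x W x 3 array on the `[0, 255]` scale.
#' @param extractor a `dnn_extractor` with weights.
#' @param layers character vector of layer names; default all named layers.
#' @return a [feature_set()] with provenance `"computed"`.
#' @export
extract_features <- function(image, extractor, layers = NULL) {
  stopifnot(inherits(extractor, "dnn_extractor"))
  image <- as_image_tensor(image)
  din <- extractor$arch$input
  if (!all(dim(image) == din))
    image <- resize_bilinear(image, din[1], din[2])
  if (is.null(layers)) layers <- layer_names(extractor)
  fwd <- net_forward(extractor, image, need = layers)
  feature_set(fwd$features[layers], provenance = "computed")
}

#' Layer table of an extractor
#'
#' @param extractor a `dnn_extractor`.
#' @return data.frame with columns `name`, `group`, `unit_count`.
#' @export
layer_specs <- function(extractor) {
  uc <- unit_counts(extractor)
  data.frame(name = names(uc), group = unname(extractor$groups[names(uc)]),
             unit_count = unname(uc), stringsAsFactors = FALSE)
}
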