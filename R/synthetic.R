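# Synthetic-data stack: stimulus image generators (colored shapes, letters,
# procedural natural-like textures), a linear voxel encoding model of true
# network features, and a block-design run simulator. Together these let
# the whole decode-and-reconstruct pipeline run, and be tested, without
# scanner data: voxel responses are generated as a noisy linear readout of
# true layer features, so the decoders' linearity assumption holds by
# construction.

#' Rec. 709 relative luminance
#'
#' @param rgb length-3 vector or H x W x 3 array on the `[0, 255]` scale.
#' @return relative luminance in `[0, 1]` (scalar or matrix).
#' @export
relative_luminance <- function(rgb) {
  w <- c(0.2126, 0.7152, 0.0722)
  if (is.array(rgb) && length(dim(rgb)) == 3L)
    return((rgb[, , 1] * w[1] + rgb[, , 2] * w[2] + rgb[, , 3] * w[3]) / 255)
  sum(rgb * w) / 255
}

#' The 8-color stimulus palette
#'
#' Red, green, blue, cyan, magenta, yellow, white and black. The six
#' chromatic colors are luminance-matched: each is the pure hue scaled so
#' its Rec. 709 relative luminance equals that of full-intensity blue (the
#' dimmest achievable pure hue, hence the common ceiling). White and black
#' are exempt.
#'
#' @return named list of length-3 RGB vectors.
#' @export
stimulus_palette <- function() {
  w <- c(0.2126, 0.7152, 0.0722)
  target <- w[3] # luminance of (0, 0, 255)
  hues <- list(red = c(1, 0, 0), green = c(0, 1, 0), blue = c(0, 0, 1),
               cyan = c(0, 1, 1), magenta = c(1, 0, 1), yellow = c(1, 1, 0))
  cols <- lapply(hues, function(h) 255 * h * target / sum(w * h))
  c(cols, list(white = c(255, 255, 255), black = c(0, 0, 0)))
}

shape_mask <- function(shape, size) {
  m <- matrix(FALSE, size, size)
  g <- seq_len(size) / size # normalized pixel centers (upper bound)
  within <- function(v, lo, hi) v > lo & v <= hi
  r <- row(m) / size; c_ <- col(m) / size
  thick <- 0.2
  switch(shape,
    square = within(r, 0.25, 0.75) & within(c_, 0.25, 0.75),
    plus = (within(r, 0.5 - thick / 2, 0.5 + thick / 2) & within(c_, 0.15, 0.85)) |
           (within(c_, 0.5 - thick / 2, 0.5 + thick / 2) & within(r, 0.15, 0.85)),
    tee = (within(r, 0.15, 0.15 + thick) & within(c_, 0.15, 0.85)) |
          (within(c_, 0.5 - thick / 2, 0.5 + thick / 2) & within(r, 0.15, 0.85)),
    ell = (within(c_, 0.15, 0.15 + thick) & within(r, 0.15, 0.85)) |
          (within(r, 0.85 - thick, 0.85) & within(c_, 0.15, 0.85)),
    diamond = abs(r - 0.5) + abs(c_ - 0.5) <= 0.3,
    stop("unknown shape '", shape, "'", call. = FALSE))
}

flat_image <- function(size, rgb) {
  out <- array(0, c(size, size, 3L))
  for (ch in 1:3) out[, , ch] <- rgb[ch]
  out
}

paint_mask <- function(image, mask, rgb) {
  for (ch in 1:3) {
    pl <- image[, , ch]
    pl[mask] <- rgb[ch]
    image[, , ch] <- pl
  }
  image
}

#' Generate the colored artificial-shape stimulus set
#'
#' Five parametric shapes (square, plus, tee, ell, diamond) in each of the
#' eight palette colors on a neutral mid-gray background: 40 stimuli.
#'
#' @param size image side in pixels (>= 32).
#' @param background background gray level (default 128).
#' @return object of class `stimulus_set` (family
#'   `"artificial_shape"`): named list `images`, character `labels`.
#' @export
make_shape_stimuli <- function(size = 32L, background = 128) {
  if (size < 32L) stop("shape stimuli require size >= 32 pixels", call. = FALSE)
  pal <- stimulus_palette()
  shapes <- c("square", "plus", "tee", "ell", "diamond")
  images <- list()
  for (sh in shapes) {
    mask <- shape_mask(sh, size)
    for (cn in names(pal)) {
      lab <- paste(sh, cn, sep = "_")
      images[[lab]] <- paint_mask(flat_image(size, rep(background, 3)),
                                  mask, pal[[cn]])
    }
  }
  structure(list(images = images, labels = names(images),
                 family = "artificial_shape",
                 shapes = shapes, colors = names(pal)),
            class = "stimulus_set")
}

# 5 x 7 bitmap glyphs for the letter stimuli ("#" = ink).
letter_glyphs <- function() {
  list(
    A = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
    C = c(".####", "#....", "#....", "#....", "#....", "#....", ".####"),
    E = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
    I = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "#####"),
    N = c("#...#", "##..#", "##..#", "#.#.#", "#..##", "#..##", "#...#"),
    O = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
    R = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
    S = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
    T = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
    U = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."))
}

#' Generate the alphabetical-letter stimulus set
#'
#' The ten letters A, C, E, I, N, O, R, S, T, U rendered from a bundled
#' 5 x 7 bitmap font, black ink on a white background.
#'
#' @param size image side in pixels (>= 32).
#' @return object of class `stimulus_set` (family `"alphabetical_letter"`).
#' @export
make_letter_stimuli <- function(size = 32L) {
  if (size < 32L) stop("letter stimuli require size >= 32 pixels", call. = FALSE)
  glyphs <- letter_glyphs()
  wanted <- c("A", "C", "E", "I", "N", "O", "R", "S", "T", "U")
  missing_g <- setdiff(wanted, names(glyphs))
  if (length(missing_g))
    stop("glyph(s) missing from the bundled font: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  # glyph occupies the central 70% of the canvas, nearest-neighbor scaled
  margin <- round(size * 0.15)
  gh <- size - 2L * margin
  images <- list()
  for (L in wanted) {
    bm <- do.call(rbind, lapply(glyphs[[L]], function(s)
      strsplit(s, "")[[1]] == "#"))
    rows <- bm[pmin(nrow(bm), ceiling(seq_len(gh) * nrow(bm) / gh)),
               pmin(ncol(bm), ceiling(seq_len(gh) * ncol(bm) / gh)),
               drop = FALSE]
    img <- flat_image(size, c(255, 255, 255))
    full <- matrix(FALSE, size, size)
    full[margin + seq_len(gh), margin + seq_len(gh)] <- rows
    images[[L]] <- paint_mask(img, full, c(0, 0, 0))
  }
  structure(list(images = images, labels = wanted,
                 family = "alphabetical_letter"),
            class = "stimulus_set")
}

#' Generate procedural natural-like stimuli
#'
#' Smooth colored textures built from seeded low-frequency cosine gratings
#' plus Gaussian blobs, rescaled to span `[0, 255]`. They emulate the
#' spatial-frequency falloff of photographs without shipping copyrighted
#' images; they contain no objects or semantics.
#'
#' @param n number of images.
#' @param size image side in pixels.
#' @param seed integer seed (same seed, same set).
#' @return object of class `stimulus_set` (family `"natural_like"`).
#' @export
make_natural_stimuli <- function(n, size = 32L, seed = 1L) {
  images <- with_seed(derive_seed(seed, 23L), {
    lapply(seq_len(n), function(i) {
      img <- array(0, c(size, size, 3L))
      r <- row(matrix(0, size, size)) / size
      c_ <- col(matrix(0, size, size)) / size
      for (ch in 1:3) {
        pl <- matrix(0, size, size)
        for (k in 1:4) { # low-frequency gratings
          fx <- stats::runif(1, 0.5, 3); fy <- stats::runif(1, 0.5, 3)
          ph <- stats::runif(1, 0, 2 * pi)
          pl <- pl + stats::rnorm(1, sd = 1 / k) *
            cos(2 * pi * (fx * r + fy * c_) + ph)
        }
        for (k in 1:3) { # blobs
          cx <- stats::runif(1); cy <- stats::runif(1)
          s2 <- stats::runif(1, 0.01, 0.08)
          pl <- pl + stats::rnorm(1, sd = 0.8) *
            exp(-((r - cx)^2 + (c_ - cy)^2) / (2 * s2))
        }
        img[, , ch] <- pl
      }
      rng <- range(img)
      if (diff(rng) == 0) img[] <- 128 else
        img <- (img - rng[1]) / diff(rng) * 255
      img
    })
  })
  names(images) <- sprintf("nat_%03d", seq_len(n))
  structure(list(images = images, labels = names(images),
                 family = "natural_like"),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("<stimulus_set>", x$family, "-", length(x$images), "images\n")
  invisible(x)
}

#' Seeded linear voxel encoding model
#'
#' Each voxel responds as a sparse linear combination of true feature
#' values of the encoded layer(s) plus Gaussian noise: `x = W f + eps`.
#'
#' @param n_voxels number of voxels.
#' @param feature_dim length of the encoded feature vector.
#' @param layers layer name(s) the features come from.
#' @param nonzeros_per_voxel how many features drive each voxel.
#' @param noise_sd noise standard deviation (response units).
#' @param seed integer seed.
#' @param unit_indices optional integer vector: the encoded features are
#'   this subsample of the layer's units.
#' @return object of class `encoding_model` with the voxels x features
#'   weight matrix in `weights`.
#' @export
make_encoding_model <- function(n_voxels, feature_dim, layers,
                                nonzeros_per_voxel = 12L, noise_sd = 0,
                                seed = 1L, unit_indices = NULL) {
  stopifnot(n_voxels >= 1L, feature_dim >= 1L, noise_sd >= 0)
  k <- min(nonzeros_per_voxel, feature_dim)
  W <- with_seed(derive_seed(seed, 31L), {
    W <- matrix(0, n_voxels, feature_dim)
    for (v in seq_len(n_voxels)) {
      idx <- sample.int(feature_dim, k)
      W[v, idx] <- stats::rnorm(k)
    }
    W
  })
  structure(list(weights = W, noise_sd = noise_sd, layers = layers,
                 unit_indices = unit_indices, seed = as.integer(seed)),
            class = "encoding_model")
}

#' Feature matrix of a stimulus set
#'
#' @param stimuli a `stimulus_set`.
#' @param extractor a `dnn_extractor`.
#' @param layer layer name.
#' @param unit_indices optional unit subsample.
#' @return images x units numeric matrix (rows follow `stimuli$labels`).
#' @export
stimulus_features <- function(stimuli, extractor, layer, unit_indices = NULL) {
  out <- t(vapply(stimuli$images, function(img) {
    v <- extract_features(img, extractor, layer)[[layer]]
    if (!is.null(unit_indices)) v[unit_indices] else v
  }, numeric(if (is.null(unit_indices)) unit_counts(extractor)[[layer]]
             else length(unit_indices))))
  rownames(out) <- stimuli$labels
  out
}

#' Simulate voxel responses to a stimulus set
#'
#' Each sample is `W f(image) + eps` with `eps ~ N(0, noise_sd)` drawn
#' independently per sample (so repeats of a stimulus carry independent
#' noise).
#'
#' @param stimuli a `stimulus_set`.
#' @param extractor a `dnn_extractor`.
#' @param model an [make_encoding_model()] result.
#' @param repeats presentations per stimulus.
#' @param seed integer seed for the noise.
#' @return a [sample_matrix()] with one row per presentation.
#' @export
simulate_voxel_responses <- function(stimuli, extractor, model, repeats = 1L,
                                     seed = 1L) {
  stopifnot(inherits(model, "encoding_model"))
  layer <- model$layers[[1]]
  Fmat <- stimulus_features(stimuli, extractor, layer, model$unit_indices)
  if (ncol(Fmat) != ncol(model$weights))
    stop("encoding model expects ", ncol(model$weights),
         " features but the extractor produced ", ncol(Fmat), call. = FALSE)
  clean <- Fmat %*% t(model$weights) # images x voxels
  n_img <- nrow(clean)
  data <- with_seed(derive_seed(seed, 41L), {
    out <- matrix(0, n_img * repeats, ncol(clean))
    for (r in seq_len(repeats)) {
      noise <- if (model$noise_sd > 0)
        matrix(stats::rnorm(length(clean), sd = model$noise_sd),
               nrow(clean), ncol(clean))
      else 0
      out[(r - 1L) * n_img + seq_len(n_img), ] <- clean + noise
    }
    out
  })
  sample_matrix(data, rep(stimuli$labels, times = repeats))
}

#' Simulate a block-design fMRI run
#'
#' Builds a voxel x time series around a 24-s rest prefix: a boxcar per
#' stimulus block (delayed by the design's hemodynamic shift) scales the
#' baseline by the encoded sample amplitudes (interpreted as percent signal
#' change), on top of a linear drift, motion-correlated nuisance signals,
#' and white noise.
#'
#' @param design a [block_design()]; block windows (plus shift) must fit in
#'   the run.
#' @param amplitudes blocks x voxels matrix of percent-signal-change
#'   amplitudes.
#' @param tr_seconds repetition time (default 2).
#' @param baseline baseline amplitude (default 100, so percent units are
#'   literal).
#' @param drift_amplitude total linear drift over the run, in baseline
#'   units.
#' @param motion_amplitude scale of the random-walk motion parameters and
#'   of their coupling into voxel amplitudes.
#' @param noise_sd white-noise SD in baseline units.
#' @param rest_prefix_seconds leading rest duration (default 24).
#' @param rest_suffix_seconds trailing rest (default 8).
#' @param seed integer seed.
#' @return a [run_timeseries()] (with the generated motion parameters).
#' @export
simulate_run <- function(design, amplitudes, tr_seconds = 2, baseline = 100,
                         drift_amplitude = 0, motion_amplitude = 0,
                         noise_sd = 0, rest_prefix_seconds = 24,
                         rest_suffix_seconds = 8, seed = 1L) {
  stopifnot(inherits(design, "block_design"))
  amplitudes <- as.matrix(amplitudes)
  n_blocks <- length(design$onsets)
  if (nrow(amplitudes) != n_blocks)
    stop("one amplitude row per block is required", call. = FALSE)
  ends <- design$onsets + design$durations
  if (any(design$onsets[-1] < ends[-n_blocks]))
    stop("overlapping stimulus blocks", call. = FALSE)
  if (any(design$onsets < rest_prefix_seconds))
    stop("blocks must start after the rest prefix", call. = FALSE)
  total_s <- max(ends) + design$shift_seconds + rest_suffix_seconds
  n_vol <- ceiling(total_s / tr_seconds)
  n_vox <- ncol(amplitudes)
  t_mid <- (seq_len(n_vol) - 0.5) * tr_seconds

  pct <- matrix(0, n_vol, n_vox) # percent modulation per volume
  for (i in seq_len(n_blocks)) {
    on <- design$onsets[i] + design$shift_seconds
    off <- on + design$durations[i]
    idx <- which(t_mid > on & t_mid < off)
    pct[idx, ] <- matrix(amplitudes[i, ], length(idx), n_vox, byrow = TRUE)
  }
  out <- with_seed(derive_seed(seed, 53L), {
    data <- baseline * (1 + pct / 100)
    if (drift_amplitude != 0) {
      slope <- stats::runif(n_vox, 0.5, 1.5) * drift_amplitude
      data <- data + outer(seq_len(n_vol) / n_vol, slope)
    }
    motion <- matrix(0, n_vol, 6L)
    if (motion_amplitude > 0) {
      # respiration-coupled oscillation plus scan-to-scan jitter: the motion
      # of a head-restrained subject, spectrally distinct from the slow
      # block-design signal
      tsec <- t_mid
      for (j in 1:6) {
        f <- stats::runif(1, 0.15, 0.35) # Hz
        ph <- stats::runif(1, 0, 2 * pi)
        motion[, j] <- motion_amplitude *
          (sin(2 * pi * f * tsec + ph) +
             stats::rnorm(n_vol, sd = 0.3))
      }
      coupling <- matrix(stats::rnorm(6L * n_vox), 6L, n_vox)
      data <- data + motion %*% coupling
    }
    if (noise_sd > 0)
      data <- data + matrix(stats::rnorm(n_vol * n_vox, sd = noise_sd),
                            n_vol, n_vox)
    list(data = data, motion = motion)
  })
  run_timeseries(out$data, tr_seconds = tr_seconds, motion = out$motion,
                 rest_prefix_seconds = rest_prefix_seconds)
}
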