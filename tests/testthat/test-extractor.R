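test_that("unit counts of the 19-layer reference architecture are derived from shapes", {
  ref <- reference_extractor()
  uc <- unit_counts(ref)
  expect_length(uc, 19L)
  expect_equal(unname(uc[c("conv1_1", "conv1_2")]), c(3211264L, 3211264L))
  expect_equal(unname(uc[c("conv2_1", "conv2_2")]), rep(1605632L, 2))
  expect_equal(unname(uc[paste0("conv3_", 1:4)]), rep(802816L, 4))
  expect_equal(unname(uc[paste0("conv4_", 1:4)]), rep(401408L, 4))
  expect_equal(unname(uc[paste0("conv5_", 1:4)]), rep(100352L, 4))
  expect_equal(unname(uc[c("fc6", "fc7", "fc8")]), c(4096L, 4096L, 1000L))
  # layer-group bookkeeping
  expect_equal(unname(ref$groups[c("conv1_1", "conv5_4", "fc6", "fc8")]),
               c("DNN1", "DNN5", "DNN6", "DNN8"))
  # counts for a toy net: 16x16 input, 8 same-padding filters -> 16*16*8
  toy <- build_toy_extractor(1, toy_architecture(input = c(16L, 16L, 3L),
                                                 filters = c(8L, 4L),
                                                 fc_units = c(12L, 5L),
                                                 pool = FALSE))
  expect_equal(unname(unit_counts(toy)["conv1_1"]), 2048L)
})

test_that("feature extraction is deterministic and validates its inputs", {
  ex <- tiny_extractor()
  img <- random_image(c(8, 8, 3), 11)
  f1 <- extract_features(img, ex)
  f2 <- extract_features(img, ex)
  expect_identical(f1, f2)
  expect_equal(attr(f1, "provenance"), "computed")
  expect_error(extract_features(img, ex, layers = "conv9_9"), "conv9_9")
  bad <- img; bad[1, 1, 1] <- NA
  expect_error(extract_features(bad, ex), "non-finite")
  expect_error(extract_features(img, reference_extractor()), "weights")
})

test_that("a 1x1 identity-kernel convolution reproduces the input channel", {
  arch <- dnn_architecture(input = c(6L, 6L, 3L),
                           layers = list(list(type = "conv", name = "conv1_1",
                                              filters = 1L, kernel = 1L)))
  ex <- build_toy_extractor(1, arch)
  ex$weights[[1]]$kernel[] <- 0
  ex$weights[[1]]$kernel[1, 1, 1, 1] <- 1 # pass channel 1 through
  img <- random_image(c(6, 6, 3), 3)
  got <- extract_features(img, ex, "conv1_1")[["conv1_1"]]
  # channel-fastest flattening of a single-filter map = h-major pixel order
  expect_equal(got, as.vector(t(img[, , 1])))
})

test_that("seeded toy extractors are reproducible and seed-sensitive", {
  img <- random_image(c(8, 8, 3), 2)
  a <- extract_features(img, tiny_extractor(4))
  b <- extract_features(img, tiny_extractor(4))
  c <- extract_features(img, tiny_extractor(5))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a[["conv1_1"]], c[["conv1_1"]])))
  expect_error(toy_architecture(filters = c(0L, 4L)), "zero filters")
})

test_that("a linear-mode extractor is an affine map (dense-matrix oracle)", {
  ex <- linear_extractor(size = 6L)
  lin <- probe_linear_map(ex)
  img <- random_image(lin$dims, 8)
  fs <- extract_features(img, ex)
  got <- unlist(fs, use.names = FALSE)
  expect_equal(got, as.numeric(lin$M %*% as.vector(img) + lin$d),
               tolerance = 1e-10)
})

test_that("backpropagated gradients match central finite differences", {
  for (ex in list(tiny_extractor(3), make_imagery_variant(tiny_extractor(3)))) {
    img <- random_image(c(8, 8, 3), 13)
    fs <- extract_features(img, ex)
    set.seed(21)
    y <- lapply(unclass(fs), function(v) v + rnorm(length(v)))
    w <- stats::setNames(rep(1, length(y)), names(y))
    loss_at <- function(im) {
      f <- extract_features(im, ex)
      sum(vapply(names(y), function(nm) 0.5 * sum((f[[nm]] - y[[nm]])^2),
                 numeric(1)))
    }
    g <- recon_loss(img, feature_set(y, "decoded"), w, ex)$gradient
    set.seed(31)
    pick <- cbind(sample(8, 20, TRUE), sample(8, 20, TRUE), sample(3, 20, TRUE))
    h <- 1e-3
    for (t in seq_len(nrow(pick))) {
      up <- img; up[pick[t, 1], pick[t, 2], pick[t, 3]] <- up[pick[t, 1], pick[t, 2], pick[t, 3]] + h
      dn <- img; dn[pick[t, 1], pick[t, 2], pick[t, 3]] <- dn[pick[t, 1], pick[t, 2], pick[t, 3]] - h
      fd <- (loss_at(up) - loss_at(dn)) / (2 * h)
      expect_equal(g[pick[t, 1], pick[t, 2], pick[t, 3]], fd,
                   tolerance = 1e-4)
    }
  }
})

test_that("imagery variant swaps pooling and rectifier but preserves shapes", {
  ex <- tiny_extractor(6)
  im <- make_imagery_variant(ex)
  expect_identical(unit_counts(ex), unit_counts(im))
  expect_error(make_imagery_variant(im), "already")
  # leaky rectifier: negative slope 0.2
  expect_equal(deeprecon:::rectifier(-1, "imagery"), -0.2)
  expect_equal(deeprecon:::rectifier(-1, "standard"), 0)
  # average pooling over window [1, 3, x, x]
  a <- array(0, c(2, 2, 1)); a[, , 1] <- matrix(c(1, 3, 2, 2), 2, 2)
  expect_equal(as.numeric(deeprecon:::pool_forward(a, "avg")$out), 2)
  expect_equal(as.numeric(deeprecon:::pool_forward(a, "max")$out), 3)
})

test_that("imagery and standard variants agree on constant non-negative maps", {
  # 1x1 kernels on a constant image give spatially constant pre-pooling
  # activations (no padding border); with absolute kernels they are also
  # non-negative, so average pooling equals max pooling and the leaky
  # rectifier is the identity: the variants must coincide exactly
  arch <- dnn_architecture(input = c(8L, 8L, 3L), layers = list(
    list(type = "conv", name = "conv1_1", filters = 4L, kernel = 1L),
    list(type = "pool"),
    list(type = "conv", name = "conv2_1", filters = 6L, kernel = 1L),
    list(type = "pool"),
    list(type = "fc", name = "fc6", units = 12L)))
  ex <- build_toy_extractor(9, arch)
  for (i in seq_along(ex$weights))
    if (!is.null(ex$weights[[i]])) {
      if (!is.null(ex$weights[[i]]$kernel))
        ex$weights[[i]]$kernel <- abs(ex$weights[[i]]$kernel)
      if (!is.null(ex$weights[[i]]$weight))
        ex$weights[[i]]$weight <- abs(ex$weights[[i]]$weight)
    }
  img <- array(100, c(8, 8, 3))
  fs_std <- extract_features(img, ex)
  fs_img <- extract_features(img, make_imagery_variant(ex))
  for (nm in names(fs_std))
    expect_equal(fs_std[[nm]], fs_img[[nm]], tolerance = 1e-12)
})

test_that("bilinear resize preserves constants and hits the input contract", {
  img <- array(37.5, c(10, 14, 3))
  out <- resize_bilinear(img, 8, 8)
  expect_equal(dim(out), c(8L, 8L, 3L))
  expect_true(all(abs(out - 37.5) < 1e-9))
  # extraction auto-resizes
  ex <- tiny_extractor()
  expect_silent(extract_features(array(10, c(12, 12, 3)), ex, "conv1_1"))
})
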