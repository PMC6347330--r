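test_that("voxel selection ranks by absolute training correlation", {
  # 3 voxels with correlations ~ [0.9, 0.1, 0.5], cap 2 -> voxels 1 and 3
  set.seed(1)
  y <- rnorm(60)
  X <- cbind(0.9 * y + 0.44 * rnorm(60),
             0.1 * y + 0.99 * rnorm(60),
             0.5 * y + 0.87 * rnorm(60))
  sel <- select_voxels(sample_matrix(X, as.character(1:60)), y, cap = 2)
  expect_setequal(sel$indices, c(1L, 3L))
  # fewer voxels than the cap: all selected
  sel_all <- select_voxels(sample_matrix(X, as.character(1:60)), y, cap = 500)
  expect_length(sel_all$indices, 3L)
  # brute-force correlation-scan oracle on seeded data
  set.seed(2)
  Xb <- matrix(rnorm(50 * 120), 50, 120)
  yb <- rnorm(50)
  selb <- select_voxels(sample_matrix(Xb, as.character(1:50)), yb, cap = 20)
  oracle <- order(-abs(as.numeric(cor(Xb, yb))), seq_len(120))[1:20]
  expect_identical(selb$indices, oracle)
  expect_error(select_voxels(sample_matrix(Xb, as.character(1:50)),
                             rep(1, 50)), "constant target")
  # negatively correlated voxels are informative and selected under |r|
  Xn <- cbind(-y, rnorm(60))
  seln <- select_voxels(sample_matrix(Xn, as.character(1:60)), y, cap = 1)
  expect_identical(seln$indices, 1L)
})

test_that("ARD regression recovers sparse supports and prunes exactly", {
  set.seed(11)
  X <- matrix(rnorm(200 * 50), 200, 50)
  w <- numeric(50); sup <- c(3, 10, 22, 37, 48)
  w[sup] <- c(1.5, -2, 1, 0.8, -1.2)
  y <- as.numeric(X %*% w + rnorm(200, sd = 0.1))
  fit <- fit_ard(X, y)
  expect_true(fit$converged)
  expect_true(all(fit$ard_precisions > 0))
  # pruned weights are exactly zero
  expect_true(all(fit$weights[fit$ard_precisions >= 1e8] == 0))
  # >= 90% of absolute weight mass on the true support
  expect_gt(sum(abs(fit$weights[sup])) / sum(abs(fit$weights)), 0.9)
  # support-restricted weights close to the restricted-OLS oracle
  ols <- lm.fit(cbind(1, X[, sup]), y)$coefficients[-1]
  expect_lt(sqrt(mean((fit$weights[sup] - ols)^2)), 0.1)
})

test_that("ARD handles degenerate and noiseless targets", {
  set.seed(12)
  X <- matrix(rnorm(80 * 10), 80, 10)
  # all-zero target: fully pruned, zero bias
  f0 <- fit_ard(X, rep(0, 80))
  expect_equal(f0$weights, rep(0, 10))
  expect_equal(f0$bias, 0)
  # noiseless y = 2 * x_7: perfect held-out prediction
  y <- 2 * X[, 7]
  fit <- fit_ard(X, y)
  Xnew <- matrix(rnorm(40 * 10), 40, 10)
  pred <- as.numeric(Xnew %*% fit$weights + fit$bias)
  expect_equal(cor(pred, 2 * Xnew[, 7]), 1.0, tolerance = 1e-6)
  expect_error(fit_ard(X, c(NA, rep(0, 79))), "non-finite")
})

test_that("ARD weights are equivariant under voxel permutation", {
  set.seed(13)
  X <- matrix(rnorm(100 * 30), 100, 30)
  y <- as.numeric(X[, c(4, 9)] %*% c(1, -1) + rnorm(100, sd = 0.2))
  fit <- fit_ard(X, y)
  perm <- sample(30)
  fit_p <- fit_ard(X[, perm], y)
  expect_equal(fit_p$weights[order(perm)], fit$weights, tolerance = 1e-8)
})

test_that("prediction applies trial averaging before the linear readout", {
  # hand-built decoder: w = [1, 0], b = 1 applied to x = [2, 5] -> 3
  dec <- structure(list(
    layer = "conv1_1",
    units = list(structure(list(weights = c(1, 0), bias = 1,
                                ard_precisions = c(1, 1), converged = TRUE,
                                noise_precision = 1), class = "unit_decoder")),
    selections = list(structure(list(indices = c(1L, 2L),
                                     correlations = c(1, 0), cap = 500L),
                                class = "voxel_selection")),
    unit_indices = 1L, n_units_total = 1L, n_voxels = 2L,
    train_stats = list(mean = 0, sd = 1)), class = "layer_decoder")
  one <- predict_features(dec, sample_matrix(matrix(c(2, 5), 1), "s1"),
                          average_trials = FALSE)
  expect_equal(as.numeric(one$layers$conv1_1), 3)
  # 24 identical repeats average to the same prediction
  reps <- sample_matrix(matrix(rep(c(2, 5), each = 24), 24), rep("s1", 24))
  expect_equal(as.numeric(predict_features(dec, reps)$layers$conv1_1), 3)
  # seeded multi-trial set equals prediction on hand-averaged rows
  set.seed(3)
  X <- matrix(rnorm(30 * 2), 30, 2)
  labs <- rep(sprintf("s%d", 1:10), 3)
  got <- predict_features(dec, sample_matrix(X, labs))
  manual <- t(vapply(sprintf("s%d", 1:10), function(l)
    colMeans(X[labs == l, , drop = FALSE]), numeric(2)))
  expect_equal(as.numeric(got$layers$conv1_1),
               as.numeric(manual %*% c(1, 0) + 1))
  expect_identical(got$labels, sprintf("s%d", 1:10))
  # voxel-count mismatch errors
  expect_error(predict_features(dec, sample_matrix(matrix(1, 1, 3), "s1")),
               "voxel count")
})

test_that("norm correction rescales layer vectors to the reference norm", {
  nc <- structure(list(reference_norms = c(conv1_1 = 10), source = "test"),
                  class = "norm_correction")
  fs <- feature_set(list(conv1_1 = c(3, 4)), "decoded")
  out <- norm_correct(fs, nc)
  expect_equal(out[["conv1_1"]], c(6, 8))
  expect_equal(attr(out, "provenance"), "decoded_norm_corrected")
  # already at the reference norm: unchanged
  at_ref <- feature_set(list(conv1_1 = c(6, 8)), "decoded")
  expect_equal(norm_correct(at_ref, nc)[["conv1_1"]], c(6, 8))
  # property: output norm equals the reference norm to 1e-9
  for (s in 1:5) {
    set.seed(s)
    v <- rnorm(64)
    o <- norm_correct(feature_set(list(conv1_1 = v), "decoded"), nc)
    expect_equal(sqrt(sum(o[["conv1_1"]]^2)), 10, tolerance = 1e-9)
  }
  expect_error(norm_correct(feature_set(list(conv1_1 = c(0, 0)), "decoded"),
                            nc), "zero-norm")
})

test_that("decoding accuracy matches the direct Pearson formula", {
  set.seed(4)
  true <- matrix(rnorm(20 * 6), 20, 6)
  dec <- true + matrix(rnorm(120, sd = 0.5), 20, 6)
  acc <- decoding_accuracy(dec, true, mode = "per_unit")
  for (j in 1:6)
    expect_equal(acc$r[j],
                 sum(scale(dec[, j]) * scale(true[, j])) / 19)
  # perfect and sign-flipped decoding
  expect_equal(decoding_accuracy(true, true)$r, rep(1, 6))
  expect_equal(decoding_accuracy(-true, true)$r, rep(-1, 6))
  # constant unit reported as missing, excluded from averages
  dec2 <- dec; dec2[, 2] <- 5
  acc2 <- decoding_accuracy(dec2, true)
  expect_true(is.na(acc2$r[2]))
  expect_false(any(is.na(acc2$r[-2])))
})

test_that("per-sample accuracy z-normalizes with training statistics", {
  set.seed(6)
  n <- 12; p <- 40
  true <- matrix(rnorm(n * p, mean = 50, sd = 4), n, p)
  dec <- true + matrix(rnorm(n * p, sd = 2), n, p)
  ts <- list(mean = rnorm(p, 50), sd = runif(p, 2, 6))
  acc <- decoding_accuracy(dec, true, mode = "per_sample", train_stats = ts)
  # oracle: z-normalize both with the training stats and correlate rows
  zt <- sweep(sweep(true, 2, ts$mean), 2, ts$sd, "/")
  zd <- sweep(sweep(dec, 2, ts$mean), 2, ts$sd, "/")
  for (i in 1:n) expect_equal(acc$r[i], cor(zd[i, ], zt[i, ]))
  expect_error(decoding_accuracy(dec, true, mode = "per_sample"),
               "training")
})

test_that("sign-invariant voxel encoding favors absolute-value targets", {
  # voxels respond to |f| only, as fMRI is insensitive to contrast
  # polarity: decoding |f| must beat decoding the raw signed f
  set.seed(7)
  n_tr <- 150; n_te <- 40; n_units <- 24; n_filters <- 4; n_vox <- 60
  F_tr <- matrix(rnorm(n_tr * n_units), n_tr, n_units)
  F_te <- matrix(rnorm(n_te * n_units), n_te, n_units)
  W <- matrix(rnorm(n_vox * n_units, sd = 0.5), n_vox, n_units)
  X_tr <- sample_matrix(abs(F_tr) %*% t(W) + matrix(rnorm(n_tr * n_vox, sd = 0.1), n_tr),
                        sprintf("t%03d", 1:n_tr))
  X_te <- sample_matrix(abs(F_te) %*% t(W) + matrix(rnorm(n_te * n_vox, sd = 0.1), n_te),
                        sprintf("e%03d", 1:n_te))
  tab <- abs_feature_comparison(X_tr, F_tr, X_te, F_te,
                                n_filters = n_filters, voxel_cap = 40,
                                max_iter = 40)
  expect_equal(nrow(tab), n_filters)
  expect_named(tab, c("filter", "acc_raw", "acc_abs"))
  expect_false(is.unsorted(tab$acc_raw)) # ascending by raw accuracy
  expect_gt(mean(tab$acc_abs), mean(tab$acc_raw) + 0.3)
  # all-non-negative targets: raw and absolute coincide
  F2_tr <- abs(F_tr); F2_te <- abs(F_te)
  tab2 <- abs_feature_comparison(X_tr, F2_tr, X_te, F2_te,
                                 n_filters = n_filters, voxel_cap = 40,
                                 max_iter = 40)
  expect_equal(tab2$acc_raw, tab2$acc_abs, tolerance = 1e-9)
})

test_that("high-SNR end-to-end decoding is accurate and norm correction preserves cosine identification", {
  ex <- build_toy_extractor(31, toy_architecture(input = c(8L, 8L, 3L),
                                                 filters = c(4L, 4L),
                                                 fc_units = c(16L, 8L)))
  tr <- make_natural_stimuli(120, size = 8, seed = 41)
  te <- make_natural_stimuli(20, size = 8, seed = 42)
  sub <- 1:120
  em <- make_encoding_model(150, 120, "conv1_1", seed = 43,
                            unit_indices = sub)
  clean <- simulate_voxel_responses(tr, ex, em, seed = 44)
  em$noise_sd <- 0.05 * mean(apply(clean$data, 2, sd))
  Xtr <- simulate_voxel_responses(tr, ex, em, seed = 44)
  Xte <- simulate_voxel_responses(te, ex, em, repeats = 2, seed = 45)
  Ftr <- stimulus_features(tr, ex, "conv1_1", sub)
  Fte <- stimulus_features(te, ex, "conv1_1", sub)
  dec <- train_layer_decoder(Xtr, Ftr, "conv1_1", voxel_cap = 60,
                             max_iter = 30)
  pred <- predict_features(dec, Xte)
  acc <- decoding_accuracy(pred$layers$conv1_1, Fte, mode = "per_unit")
  expect_gt(mean(acc$r, na.rm = TRUE), 0.8)
  # cosine-similarity identification is invariant to per-sample rescaling,
  # hence to norm correction
  cosine_id <- function(M) {
    sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    vapply(seq_len(nrow(M)), function(i) {
      s <- vapply(seq_len(nrow(M)), function(j) sim(M[i, ], Fte[j, ]),
                  numeric(1))
      sum(s[-i] < s[i]) + 0.5 * sum(s[-i] == s[i])
    }, numeric(1))
  }
  ref_imgs <- make_natural_stimuli(30, size = 8, seed = 46)$images
  nc <- compute_norm_correction(ref_imgs, ex, "conv1_1",
                                list(conv1_1 = sub))
  pred_nc <- norm_correct(pred, nc)
  expect_equal(cosine_id(pred_nc$layers$conv1_1),
               cosine_id(pred$layers$conv1_1))
})
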