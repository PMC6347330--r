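# Orchestration: a single seeded configuration drives simulate ->
# preprocess -> train-decoders -> decode -> norm-correct -> reconstruct ->
# evaluate, writing every artifact (with checksums) under one output
# directory.

#' Default pipeline configuration
#'
#' Desk-scale defaults: 12 x 12 procedural stimuli, a two-block toy
#' extractor, 500 voxels encoding a 500-unit subsample of conv1_1, runs of
#' 44 eight-second blocks at TR 2 with drift, respiration-like motion and
#' scanner noise, ARD decoders on 100 selected voxels, and L-BFGS pixel
#' reconstruction.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param out_dir output directory.
#' @return a named list (class `pipeline_config`), YAML-serializable.
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = "deeprecon_out") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stimuli = list(n_train = 220L, n_test = 40L, size = 12L,
                   test_repeats = 3L),
    extractor = list(filters = c(8L, 16L), fc_units = c(32L, 10L)),
    encoding = list(n_voxels = 500L, nonzeros_per_voxel = 12L,
                    noise_sd_factor = 0.1),
    runs = list(blocks_per_run = 44L, block_seconds = 8, tr_seconds = 2,
                amplitude_percent_sd = 2, drift_amplitude = 5,
                motion_amplitude = 0.5, noise_sd = 0.3),
    decoding = list(layer = "conv1_1", unit_subsample = 500L,
                    voxel_cap = 100L, max_iter = 30L),
    norm_correction = list(n_reference = 100L),
    recon = list(optimizer = "lbfgs", max_iter = 200L,
                 initial_image = "mean"),
    verbose = TRUE
  ), class = "pipeline_config")
}

#' Load / save a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param config a `pipeline_config`.
#' @return `load_pipeline_config` returns the config.
#' @export
load_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  for (nm in names(cfg)) {
    base[[nm]] <- if (is.list(cfg[[nm]]) && is.list(base[[nm]]))
      utils::modifyList(base[[nm]], cfg[[nm]]) else cfg[[nm]]
  }
  base
}

#' @rdname load_pipeline_config
#' @export
save_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipe_log <- function(config, stage, ...) {
  if (isTRUE(config$verbose))
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste0(...)))
}

# Split n block indices into runs of at most `per_run`.
chunk_runs <- function(n, per_run) {
  split(seq_len(n), ceiling(seq_len(n) / per_run))
}

# Turn encoded samples into simulated runs and preprocess them back into a
# sample matrix. Amplitudes are rescaled so clean responses sit at a
# realistic percent-signal-change scale.
samples_through_scanner <- function(samples, scale, runs_cfg, seed,
                                    design_shift = 4) {
  n <- nrow(samples$data)
  out <- list()
  chunks <- chunk_runs(n, runs_cfg$blocks_per_run)
  for (ci in seq_along(chunks)) {
    idx <- chunks[[ci]]
    onsets <- 24 + seq(0, by = runs_cfg$block_seconds,
                       length.out = length(idx))
    des <- block_design(onsets, rep(runs_cfg$block_seconds, length(idx)),
                        samples$labels[idx], shift_seconds = design_shift)
    run <- simulate_run(des, samples$data[idx, , drop = FALSE] * scale,
                        tr_seconds = runs_cfg$tr_seconds,
                        drift_amplitude = runs_cfg$drift_amplitude,
                        motion_amplitude = runs_cfg$motion_amplitude,
                        noise_sd = runs_cfg$noise_sd,
                        seed = derive_seed(seed, 700 + ci))
    out[[ci]] <- preprocess_run(run, des)
  }
  bind_samples(out)
}

#' Run the full simulate-to-evaluate pipeline
#'
#' Executes, in order: stimulus simulation, voxel-response encoding, run
#' synthesis and preprocessing, decoder training, feature decoding with
#' trial averaging, norm correction, pixel reconstruction, and pairwise
#' identification. Every artifact is written under `config$out_dir`
#' together with the resolved configuration and a checksum manifest; all
#' randomness derives from `config$seed`.
#'
#' @param config a [default_pipeline_config()]-style list.
#' @return (invisibly) a list with the `manifest` data.frame
#'   (`file`, `md5`), the `identification` result, and the per-unit
#'   decoding accuracy data.frame.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stage <- "validate"
  res <- tryCatch({
    save_pipeline_config(config, file.path(config$out_dir, "config.yaml"))

    stage <- "simulate"
    pipe_log(config, stage, "generating stimuli and voxel responses")
    ex <- build_toy_extractor(derive_seed(seed, 1),
                              toy_architecture(input = c(config$stimuli$size,
                                                         config$stimuli$size, 3L),
                                               filters = config$extractor$filters,
                                               fc_units = config$extractor$fc_units))
    train <- make_natural_stimuli(config$stimuli$n_train,
                                  size = config$stimuli$size,
                                  seed = derive_seed(seed, 2))
    test <- make_natural_stimuli(config$stimuli$n_test,
                                 size = config$stimuli$size,
                                 seed = derive_seed(seed, 3))
    write_stimulus_set(train, file.path(config$out_dir, "stimuli_train"))
    write_stimulus_set(test, file.path(config$out_dir, "stimuli_test"))

    layer <- config$decoding$layer
    n_units <- unit_counts(ex)[[layer]]
    sub <- if (config$decoding$unit_subsample < n_units)
      with_seed(derive_seed(seed, 4),
                sort(sample.int(n_units, config$decoding$unit_subsample)))
    else seq_len(n_units)
    em <- make_encoding_model(config$encoding$n_voxels, length(sub), layer,
                              config$encoding$nonzeros_per_voxel,
                              seed = derive_seed(seed, 5), unit_indices = sub)
    clean <- simulate_voxel_responses(train, ex, em,
                                      seed = derive_seed(seed, 6))
    clean_sd <- mean(apply(clean$data, 2L, stats::sd))
    em$noise_sd <- config$encoding$noise_sd_factor * clean_sd
    X_train_raw <- simulate_voxel_responses(train, ex, em,
                                            seed = derive_seed(seed, 6))
    X_test_raw <- simulate_voxel_responses(test, ex, em,
                                           repeats = config$stimuli$test_repeats,
                                           seed = derive_seed(seed, 7))

    stage <- "preprocess"
    pipe_log(config, stage, "synthesizing and preprocessing runs")
    scale <- config$runs$amplitude_percent_sd / clean_sd
    X_train <- samples_through_scanner(X_train_raw, scale, config$runs,
                                       derive_seed(seed, 8))
    X_test <- samples_through_scanner(X_test_raw, scale, config$runs,
                                      derive_seed(seed, 9))
    save_sample_matrix(X_train, file.path(config$out_dir, "samples_train.csv"))
    save_sample_matrix(X_test, file.path(config$out_dir, "samples_test.csv"))

    stage <- "train-decoders"
    pipe_log(config, stage, sprintf("ARD decoders for %d units of %s",
                                    length(sub), layer))
    F_train <- stimulus_features(train, ex, layer, sub)
    decoder <- train_layer_decoder(X_train, F_train, layer,
                                   voxel_cap = config$decoding$voxel_cap,
                                   max_iter = config$decoding$max_iter)
    decoder$unit_indices <- sub
    save_layer_decoder(decoder, file.path(config$out_dir, "decoder.json"))

    stage <- "decode"
    pipe_log(config, stage, "predicting test features (trial-averaged)")
    decoded <- predict_features(decoder, X_test, average_trials = TRUE)

    stage <- "norm-correct"
    ref <- make_natural_stimuli(config$norm_correction$n_reference,
                                size = config$stimuli$size,
                                seed = derive_seed(seed, 10))
    nc <- compute_norm_correction(ref$images, ex, layer,
                                  stats::setNames(list(sub), layer))
    decoded <- norm_correct(decoded, nc)

    stage <- "reconstruct"
    pipe_log(config, stage, sprintf("%d images by %s", length(test$labels),
                                    config$recon$optimizer))
    rcfg <- recon_config(layers = layer,
                         optimizer = config$recon$optimizer,
                         max_iter = config$recon$max_iter,
                         initial_image = config$recon$initial_image,
                         seed = derive_seed(seed, 11))
    rec_dir <- file.path(config$out_dir, "reconstructions")
    dir.create(rec_dir, showWarnings = FALSE)
    recons <- vector("list", length(test$labels))
    losses <- data.frame()
    for (i in seq_along(test$labels)) {
      fs <- decoded_sample(decoded, test$labels[i])
      r <- reconstruct_pixel(fs, ex, rcfg,
                             unit_indices = stats::setNames(list(sub), layer))
      recons[[i]] <- r$image
      write_image_png(r$image, file.path(rec_dir,
                                         paste0(test$labels[i], ".png")))
      losses <- rbind(losses,
                      data.frame(label = test$labels[i],
                                 eval = seq_along(r$loss_trace),
                                 loss = r$loss_trace))
    }
    utils::write.table(losses, file.path(config$out_dir, "loss_trace.tsv"),
                       sep = "\t", row.names = FALSE)

    stage <- "evaluate"
    ident <- pairwise_identification(recons, test$images)
    F_test <- stimulus_features(test, ex, layer, sub)
    acc <- decoding_accuracy(decoded$layers[[layer]], F_test,
                             mode = "per_unit")
    utils::write.csv(ident$per_image,
                     file.path(config$out_dir, "identification.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(version = FORMAT_VERSION, type = "summary",
                              pooled_percent_correct = ident$pooled_percent,
                              n_comparisons = ident$n_comparisons,
                              mean_decoding_r = mean(acc$r, na.rm = TRUE)),
                         file.path(config$out_dir, "summary.json"),
                         digits = I(17), auto_unbox = TRUE)
    pipe_log(config, stage,
             sprintf("identification %.1f%% over %d comparisons",
                     ident$pooled_percent, ident$n_comparisons))
    list(identification = ident, decoding_accuracy = acc)
  }, error = function(e) {
    # persist a partial manifest so a failed run is inspectable
    files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
    manifest <- data.frame(file = files, md5 = unname(tools::md5sum(files)))
    utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                     row.names = FALSE)
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  files <- setdiff(list.files(config$out_dir, recursive = TRUE,
                              full.names = TRUE),
                   file.path(config$out_dir, "manifest.csv"))
  manifest <- data.frame(file = sub(paste0("^", config$out_dir, "/?"), "",
                                    files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(c(list(manifest = manifest), res))
}

#' End-to-end encoding-noise sweep
#'
#' The package's desk-scale analogue of the reported accuracy tables: for
#' each encoding-noise level (as a multiple of the clean voxel-response SD)
#' it trains ARD decoders on simulated training responses, decodes
#' trial-averaged held-out responses, norm-corrects, reconstructs every
#' test image by L-BFGS, and scores pairwise identification.
#'
#' @param seed master seed.
#' @param noise_factors numeric vector of encoding-noise multiples of the
#'   clean response SD.
#' @param n_train,n_test training/test image counts.
#' @param size stimulus side in pixels.
#' @param unit_subsample decoded unit subsample of the target layer.
#' @param n_voxels simulated voxel count.
#' @param test_repeats presentations per test stimulus (trial-averaged).
#' @return data.frame with one row per noise level: `noise_factor`,
#'   `identification_percent`, `mean_decoding_r`.
#' @export
end_to_end_experiment <- function(seed = 1L, noise_factors = c(0.1, 1, 5, 25),
                                  n_train = 220L, n_test = 40L, size = 12L,
                                  unit_subsample = 500L, n_voxels = 500L,
                                  test_repeats = 3L) {
  arch <- toy_architecture(input = c(size, size, 3L))
  ex <- build_toy_extractor(derive_seed(seed, 101), arch)
  layer <- "conv1_1"
  train <- make_natural_stimuli(n_train, size = size,
                                seed = derive_seed(seed, 102))
  test <- make_natural_stimuli(n_test, size = size,
                               seed = derive_seed(seed, 103))
  n_units <- unit_counts(ex)[[layer]]
  sub <- if (unit_subsample < n_units)
    with_seed(derive_seed(seed, 104), sort(sample.int(n_units, unit_subsample)))
  else seq_len(n_units)
  em0 <- make_encoding_model(n_voxels, length(sub), layer,
                             seed = derive_seed(seed, 105),
                             unit_indices = sub)
  clean <- simulate_voxel_responses(train, ex, em0,
                                    seed = derive_seed(seed, 106))
  clean_sd <- mean(apply(clean$data, 2L, stats::sd))
  F_train <- stimulus_features(train, ex, layer, sub)
  F_test <- stimulus_features(test, ex, layer, sub)
  ref <- make_natural_stimuli(100L, size = size, seed = derive_seed(seed, 107))
  nc <- compute_norm_correction(ref$images, ex, layer,
                                stats::setNames(list(sub), layer))
  rcfg <- recon_config(layers = layer, max_iter = 200L,
                       initial_image = "mean")
  out <- data.frame()
  for (nf in noise_factors) {
    em <- em0
    em$noise_sd <- nf * clean_sd
    X_train <- simulate_voxel_responses(train, ex, em,
                                        seed = derive_seed(seed, 106))
    X_test <- simulate_voxel_responses(test, ex, em, repeats = test_repeats,
                                       seed = derive_seed(seed, 108))
    dec <- train_layer_decoder(X_train, F_train, layer, voxel_cap = 100L,
                               max_iter = 30L)
    decoded <- norm_correct(predict_features(dec, X_test), nc)
    recons <- lapply(test$labels, function(l)
      reconstruct_pixel(decoded_sample(decoded, l), ex, rcfg,
                        unit_indices = stats::setNames(list(sub), layer))$image)
    ident <- pairwise_identification(recons, test$images)
    acc <- decoding_accuracy(decoded$layers[[layer]], F_test,
                             mode = "per_unit")
    out <- rbind(out, data.frame(noise_factor = nf,
                                 identification_percent = ident$pooled_percent,
                                 mean_decoding_r = mean(acc$r, na.rm = TRUE)))
  }
  out
}

#' Multi-layer self-inversion experiment
#'
#' Reconstructs seeded target images from their *true* multi-layer features
#' (no brain data in the loop), the regime in which combining all layers is
#' expected to produce near-complete reconstructions. Reports the pixel
#' correlation between each reconstruction and its target.
#'
#' @param seed master seed.
#' @param n_images number of seeded target images.
#' @param size image side in pixels.
#' @param max_iter L-BFGS iteration budget per image.
#' @return data.frame with `image`, `pixel_r`, `final_loss`.
#' @export
self_inversion_experiment <- function(seed = 1L, n_images = 10L, size = 16L,
                                      max_iter = 500L) {
  ex <- build_toy_extractor(derive_seed(seed, 201),
                            toy_architecture(input = c(size, size, 3L)))
  targets <- make_natural_stimuli(n_images, size = size,
                                  seed = derive_seed(seed, 202))
  cfg <- recon_config(layers = layer_names(ex), max_iter = max_iter,
                      initial_image = "mean")
  out <- data.frame()
  for (i in seq_len(n_images)) {
    tgt <- targets$images[[i]]
    fs <- extract_features(tgt, ex)
    r <- reconstruct_pixel(fs, ex, cfg)
    out <- rbind(out, data.frame(image = i,
                                 pixel_r = pixel_correlation(r$image, tgt),
                                 final_loss = r$final_loss))
  }
  out
}
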