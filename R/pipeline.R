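# Configuration handling and the end-to-end pipeline entry points
# (simulate -> features -> evaluate / train / predict), also exposed through
# the command-line wrapper in inst/cli/riemgait.

#' Default pipeline configuration
#'
#' Nested configuration with the published defaults: metric weights
#' `lambda = 0.1`, `mu = 0.2`, 40 training epochs with gradient threshold
#' 0.01, 150 frames per aligned cycle, stratified 5-fold cross-validation
#' repeated 10 times. Generator settings mirror a small mocap study
#' (7 subjects x 20 cycles).
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    preprocess = list(reference_joint = "lankle", target_frames = 150L,
                      min_period = 5L, max_lag_fraction = 0.5),
    hierarchy = list(scheme = "figure", window_length = NULL,
                     n_windows = 7L),
    metric = list(mu = 0.2, lambda = 0.1, zeta = 1, p = NULL,
                  max_epochs = 40L, grad_threshold = 0.01, n_targets = 3L,
                  k_classify = 3L, learning_rate = 1e-3),
    cv = list(folds = 5L, repeats = 10L, seed = 1L),
    simulate = list(n_subjects = 7L, cycles_per_subject = 20L,
                    frames_per_cycle = 40L, frame_rate = 40,
                    between_subject_spread = 1, within_subject_noise = 0.02,
                    bone_length_spread = 0.05, periods_per_sequence = 4L,
                    skeleton = "cmu19", seed = 1L),
    log_level = "info"
  )
}

check_known_keys <- function(cfg, ref, path = "") {
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad))
    rg_stop(paste0("unknown config key: ", path, bad[1]), "config")
  for (k in names(cfg))
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      check_known_keys(as.list(cfg[[k]]), ref[[k]], paste0(path, k, "."))
  invisible(TRUE)
}

#' Build a full pipeline configuration from overrides
#'
#' Merges user overrides into [default_pipeline_config()], rejecting any key
#' the schema does not know.
#'
#' @param overrides nested list of settings to change.
#' @return merged configuration list.
#' @export
pipeline_config <- function(overrides = list()) {
  ref <- default_pipeline_config()
  check_known_keys(overrides, ref)
  utils::modifyList(ref, overrides, keep.null = TRUE)
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return merged configuration list (unknown keys rejected).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) rg_stop(paste("no such file:", path), "io")
  ov <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
        else jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(ov %||% list())
}

rg_log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}

#' Simulate a dataset to disk
#'
#' Writes one position CSV (+ JSON sidecar) per sequence, the skeleton JSON,
#' and a manifest with labels, files, and the full configuration echo.
#'
#' @param out_dir output directory (created if missing).
#' @param config pipeline configuration (see [pipeline_config()]).
#' @return the manifest list, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = pipeline_config()) {
  check_known_keys(config, default_pipeline_config())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_cfg <- do.call(gait_sim_config, config$simulate)
  ds <- generate_dataset(sim_cfg)
  write_skeleton_json(ds$skeleton, file.path(out_dir, "skeleton.json"))
  files <- character(0)
  for (i in seq_along(ds$sequences)) {
    f <- paste0(ds$sequences[[i]]$sequence_id, ".csv")
    write_position_csv(ds$sequences[[i]], ds$skeleton, file.path(out_dir, f))
    files <- c(files, f)
  }
  manifest <- list(schema = "riemgait-dataset-1", files = files,
                   labels = ds$labels, seed = sim_cfg$seed,
                   config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  rg_log(config, "simulated %d sequences into %s", length(files), out_dir)
  invisible(manifest)
}

# Serialize aligned cycles to one wide CSV (cycle, frame, bone xyz columns).
write_cycles_csv <- function(cycles, path) {
  nb <- dim(cycles[[1]]$dirs)[2]
  bn <- paste0("b", seq_len(nb))
  rows <- lapply(seq_along(cycles), function(i) {
    d <- cycles[[i]]$dirs
    nf <- dim(d)[1]
    flat <- matrix(NA_real_, nf, 3 * nb)
    for (b in seq_len(nb)) flat[, (3 * b - 2):(3 * b)] <- d[, b, ]
    data.frame(cycle = i - 1L, frame = 0:(nf - 1), flat)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("cycle", "frame",
                 paste(rep(bn, each = 3), c("x", "y", "z"), sep = "_"))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_cycles_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nb <- (ncol(df) - 2L) / 3L
  lapply(sort(unique(df$cycle)), function(ci) {
    sub <- df[df$cycle == ci, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    dirs <- array(NA_real_, c(nrow(sub), nb, 3))
    for (b in seq_len(nb))
      dirs[, b, ] <- as.matrix(sub[, (3 * b):(3 * b + 2)])
    # re-normalize against CSV rounding
    nrm <- sqrt(dirs[, , 1]^2 + dirs[, , 2]^2 + dirs[, , 3]^2)
    for (k in 1:3) dirs[, , k] <- dirs[, , k] / nrm
    pose_sequence(dirs, sequence_id = sprintf("cycle%03d", ci))
  })
}

#' Extract, align, and featurize a dataset
#'
#' For every sequence in `input_dir`: converts positions to bone directions,
#' segments gait cycles by ankle-speed autocorrelation, and keeps the first
#' complete cycle as that sequence's sample. All samples are then aligned to
#' `preprocess$target_frames` on the manifold, the Riemannian mean motion
#' sequence is computed over all aligned samples, and the geodesic feature
#' matrix `G(s)` plus the hierarchical covariance descriptor `C(s)` are
#' written per sample. The aligned cycles themselves are also serialized so
#' that evaluation can recompute fold-local mean sequences (see
#' [evaluate_cycles()]); the serialized `G`/`C` use the all-data mean.
#'
#' @param input_dir dataset directory written by [cmd_simulate()] (or in the
#'   same layout).
#' @param out_dir output directory for feature files.
#' @param config pipeline configuration.
#' @return invisibly, a list with the feature matrices and labels.
#' @export
cmd_features <- function(input_dir, out_dir, config = pipeline_config()) {
  check_known_keys(config, default_pipeline_config())
  mf_path <- file.path(input_dir, "manifest.json")
  if (!file.exists(mf_path)) rg_stop(paste("no manifest in", input_dir), "io")
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  skeleton <- read_skeleton_json(file.path(input_dir, "skeleton.json"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pp <- config$preprocess
  cycles <- list()
  labels <- character(0)
  ids <- character(0)
  for (i in seq_along(manifest$files)) {
    f <- manifest$files[i]
    sq <- tryCatch(
      read_position_csv(file.path(input_dir, f), skeleton),
      riemgait_error = function(e) rg_stop(
        sprintf("while reading '%s': %s", f, conditionMessage(e)),
        "format"))
    ps <- to_pose_sequence(sq, skeleton)
    cs <- tryCatch(
      extract_cycles(ps, sq, pp$reference_joint, pp$min_period,
                     pp$max_lag_fraction),
      riemgait_error = function(e) rg_stop(
        sprintf("while segmenting '%s': %s", f, conditionMessage(e)),
        "preprocess"))
    cycles[[length(cycles) + 1L]] <- cs$cycles[[1L]]
    labels <- c(labels, sq$subject_label)
    ids <- c(ids, sq$sequence_id)
  }
  aligned <- align_cycles(cycles, pp$target_frames)
  ms <- compute_mean_sequence(aligned)
  hy <- config$hierarchy
  G <- t(vapply(aligned, function(cy)
    flatten_features(geometric_features(cy, ms)),
    numeric(prod(dim(ms$mean_poses)[1:2]))))
  Cd <- do.call(rbind, lapply(aligned, function(cy)
    temporal_hierarchy(geometric_features(cy, ms), hy$scheme,
                       hy$window_length, hy$n_windows)$flattened))
  write_cycles_csv(aligned, file.path(out_dir, "cycles.csv"))
  write_mean_sequence_csv(ms, bone_names(skeleton),
                          file.path(out_dir, "mean_sequence.csv"))
  utils::write.csv(G, file.path(out_dir, "spatial.csv"), row.names = FALSE)
  utils::write.csv(Cd, file.path(out_dir, "temporal.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(schema = "riemgait-features-1", labels = labels,
         sequence_ids = ids, config = config),
    file.path(out_dir, "features_meta.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  rg_log(config, "featurized %d samples into %s", length(labels), out_dir)
  invisible(list(spatial = G, temporal = Cd, labels = labels,
                 mean_sequence = ms, cycles = aligned))
}

read_features_dir <- function(features_dir) {
  meta_path <- file.path(features_dir, "features_meta.json")
  if (!file.exists(meta_path))
    rg_stop(paste("no features in", features_dir), "io")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  list(
    meta = meta,
    labels = as.character(meta$labels),
    spatial = as.matrix(utils::read.csv(
      file.path(features_dir, "spatial.csv"))),
    temporal = as.matrix(utils::read.csv(
      file.path(features_dir, "temporal.csv"))),
    cycles = read_cycles_csv(file.path(features_dir, "cycles.csv")))
}

#' Evaluate recognition accuracy by repeated stratified cross-validation
#'
#' Runs [evaluate_cycles()] (fold-local mean sequences; the default) or
#' [cross_validate()] on the serialized all-data features
#' (`leaky_mean = TRUE`) for each requested feature mode, and writes a JSON
#' report.
#'
#' @param features_dir directory written by [cmd_features()].
#' @param config pipeline configuration.
#' @param modes feature modes to evaluate (subset of `"spatial"`,
#'   `"temporal"`, `"fused"`).
#' @param leaky_mean use the serialized all-data mean-sequence features.
#' @param report_path optional output path for the JSON report.
#' @return the report list.
#' @export
cmd_evaluate <- function(features_dir, config = pipeline_config(),
                         modes = c("spatial", "temporal", "fused"),
                         leaky_mean = FALSE, report_path = NULL) {
  check_known_keys(config, default_pipeline_config())
  fts <- read_features_dir(features_dir)
  cv <- config$cv
  hy <- config$hierarchy
  results <- list()
  for (mode in modes) {
    res <- if (leaky_mean)
      cross_validate(fts$spatial, fts$temporal, fts$labels, mode,
                     cv$folds, cv$repeats, cv$seed, config$metric)
    else
      evaluate_cycles(fts$cycles, fts$labels, mode, cv$folds, cv$repeats,
                      cv$seed, config$metric, scheme = hy$scheme)
    rg_log(config, "mode %-8s mean accuracy %.4f", mode, res$mean_accuracy)
    results[[mode]] <- list(
      mean_accuracy = res$mean_accuracy,
      repeat_means = res$repeat_means,
      fold_accuracies = res$fold_accuracies,
      confusion = res$confusion)
  }
  report <- list(schema = "riemgait-report-1", modes = results,
                 n_samples = length(fts$labels),
                 n_classes = length(unique(fts$labels)),
                 leaky_mean = leaky_mean, config = config)
  if (!is.null(report_path))
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  report
}

#' Train a recognition model on a full feature set
#'
#' Estimates kernel bandwidths on all samples, builds the fused (or single
#' mode) kernel columns, trains the KLMNN metric, and serializes everything
#' a later [cmd_predict()] needs: the transform, training feature matrices,
#' bandwidths, labels, the mean sequence, and the configuration.
#'
#' @param features_dir directory written by [cmd_features()].
#' @param model_path output JSON path.
#' @param config pipeline configuration.
#' @param mode feature mode (default `"fused"`).
#' @return the model bundle, invisibly.
#' @export
cmd_train <- function(features_dir, model_path, config = pipeline_config(),
                      mode = "fused") {
  mode <- match.arg(mode, c("fused", "spatial", "temporal"))
  fts <- read_features_dir(features_dir)
  bundle <- list(schema = "riemgait-model-1", mode = mode,
                 labels = fts$labels, config = config)
  cols <- NULL
  if (mode %in% c("spatial", "fused")) {
    bundle$bw_spatial <- estimate_bandwidth(fts$spatial)
    bundle$spatial <- fts$spatial
    cols <- rbf_kernel(fts$spatial, bundle$bw_spatial)$values
  }
  if (mode %in% c("temporal", "fused")) {
    bundle$bw_temporal <- estimate_bandwidth(fts$temporal)
    bundle$temporal <- fts$temporal
    kt <- rbf_kernel(fts$temporal, bundle$bw_temporal)$values
    cols <- if (is.null(cols)) kt else cols * kt
  }
  model <- train_metric(cols, fts$labels, config$metric)
  bundle$L <- model$L
  bundle$loss_history <- model$loss_history
  bundle$mean_sequence_csv <- file.path(features_dir, "mean_sequence.csv")
  jsonlite::write_json(bundle, model_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  rg_log(config, "trained %s model on %d samples -> %s", mode,
         length(fts$labels), model_path)
  invisible(bundle)
}

#' Predict labels for a query feature set
#'
#' Featurizes the query samples against the stored training bandwidths and
#' kernel basis and classifies them under the stored transform. The query
#' features must have been produced with the same mean sequence as the
#' training run (point `cmd_features` at features built from the training
#' mean, or re-featurize query cycles against `mean_sequence.csv` from the
#' training features directory).
#'
#' @param model_path JSON written by [cmd_train()].
#' @param features_dir query features directory ([cmd_features()] layout).
#' @param config pipeline configuration.
#' @return character vector of predicted labels.
#' @export
cmd_predict <- function(model_path, features_dir,
                        config = pipeline_config()) {
  if (!file.exists(model_path)) rg_stop("no such model file", "io")
  b <- jsonlite::read_json(model_path, simplifyVector = TRUE)
  if (!identical(b$schema, "riemgait-model-1"))
    rg_stop("unrecognized model schema", "format")
  fts <- read_features_dir(features_dir)
  cols_tr <- NULL; cols_te <- NULL
  if (b$mode %in% c("spatial", "fused")) {
    tr <- as.matrix(b$spatial)
    cols_tr <- rbf_kernel(tr, b$bw_spatial)$values
    cols_te <- rbf_cross_kernel(tr, fts$spatial, b$bw_spatial)
  }
  if (b$mode %in% c("temporal", "fused")) {
    tr <- as.matrix(b$temporal)
    kt <- rbf_kernel(tr, b$bw_temporal)$values
    kte <- rbf_cross_kernel(tr, fts$temporal, b$bw_temporal)
    if (is.null(cols_tr)) { cols_tr <- kt; cols_te <- kte }
    else { cols_tr <- cols_tr * kt; cols_te <- cols_te * kte }
  }
  cfg <- utils::modifyList(default_metric_config(),
                           config$metric %||% list())
  model <- structure(list(L = as.matrix(b$L), p = nrow(as.matrix(b$L)),
                          config = cfg, columns = cols_tr,
                          labels = as.character(b$labels)),
                     class = "rg_metric_model")
  classify_knn(model, cols_te)
}
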