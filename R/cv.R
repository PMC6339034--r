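# Stratified, repeated cross-validation of the kernel-metric classifier.

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals its samples across folds, so
#' fold class proportions differ from the global ones by at most one sample.
#'
#' @param labels class labels.
#' @param n_folds number of folds.
#' @param seed RNG seed for the shuffle.
#' @return integer vector of fold ids in `1..n_folds`.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < n_folds))
    rg_stop(sprintf("every class needs >= %d samples for %d folds",
                    n_folds, n_folds), "argument")
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

# One fold of the kernel-metric pipeline on precomputed descriptor matrices.
# spatial/temporal: n x d matrices (rows = samples); either may be NULL when
# the mode does not use it. Returns predicted labels for the test rows.
run_fold <- function(spatial, temporal, labels, train, test, mode, config) {
  cols_tr <- NULL
  cols_te <- NULL
  if (mode %in% c("spatial", "fused")) {
    bw_s <- estimate_bandwidth(spatial[train, , drop = FALSE])
    ks_tr <- rbf_kernel(spatial[train, , drop = FALSE], bw_s, "spatial")$values
    ks_te <- rbf_cross_kernel(spatial[train, , drop = FALSE],
                              spatial[test, , drop = FALSE], bw_s)
    cols_tr <- ks_tr; cols_te <- ks_te
  }
  if (mode %in% c("temporal", "fused")) {
    bw_t <- estimate_bandwidth(temporal[train, , drop = FALSE])
    kt_tr <- rbf_kernel(temporal[train, , drop = FALSE], bw_t,
                        "temporal")$values
    kt_te <- rbf_cross_kernel(temporal[train, , drop = FALSE],
                              temporal[test, , drop = FALSE], bw_t)
    if (is.null(cols_tr)) {
      cols_tr <- kt_tr; cols_te <- kt_te
    } else {
      cols_tr <- cols_tr * kt_tr; cols_te <- cols_te * kt_te
    }
  }
  model <- train_metric(cols_tr, labels[train], config)
  classify_knn(model, cols_te)
}

#' Repeated stratified cross-validation of the kernel-metric classifier
#'
#' Splits the samples into stratified folds, and per fold estimates kernel
#' bandwidths and trains the metric on the training portion only; test
#' samples enter as cross-kernel columns against the training basis (no
#' train/test leakage). Repeated with distinct shuffle seeds.
#'
#' @param spatial `n x dG` matrix of flattened geodesic features `G(s)`
#'   (rows = samples); may be `NULL` for `mode = "temporal"`.
#' @param temporal `n x dC` matrix of flattened covariance descriptors
#'   `C(s)`; may be `NULL` for `mode = "spatial"`.
#' @param labels length-`n` class labels.
#' @param mode `"fused"` (default), `"spatial"`, or `"temporal"`.
#' @param n_folds folds (default 5).
#' @param n_repeats repetitions with different shuffles (default 10).
#' @param seed base seed; repeat `r` uses `seed + r - 1`.
#' @param config metric configuration passed to [train_metric()].
#' @return list with `mean_accuracy` (grand mean over all fold accuracies),
#'   `repeat_means`, `fold_accuracies` (`n_repeats x n_folds`),
#'   `confusion` (summed over everything), `mode`.
#' @export
cross_validate <- function(spatial, temporal, labels, mode = "fused",
                           n_folds = 5L, n_repeats = 10L, seed = 1L,
                           config = list()) {
  mode <- match.arg(mode, c("fused", "spatial", "temporal"))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    rg_stop("need at least two classes", "argument")
  if (mode %in% c("spatial", "fused") && is.null(spatial))
    rg_stop("spatial features required for this mode", "argument")
  if (mode %in% c("temporal", "fused") && is.null(temporal))
    rg_stop("temporal features required for this mode", "argument")
  cls <- sort(unique(labels))
  acc <- matrix(NA_real_, n_repeats, n_folds)
  conf <- matrix(0L, length(cls), length(cls), dimnames = list(cls, cls))
  for (r in seq_len(n_repeats)) {
    folds <- stratified_folds(labels, n_folds, seed + r - 1L)
    for (k in seq_len(n_folds)) {
      test <- which(folds == k)
      train <- which(folds != k)
      pred <- run_fold(spatial, temporal, labels, train, test, mode, config)
      acc[r, k] <- mean(pred == labels[test])
      for (q in seq_along(test))
        conf[labels[test[q]], pred[q]] <- conf[labels[test[q]], pred[q]] + 1L
    }
  }
  list(mean_accuracy = mean(acc), repeat_means = rowMeans(acc),
       fold_accuracies = acc, confusion = conf, mode = mode)
}

#' Cross-validate from aligned cycles with fold-local mean sequences
#'
#' Like [cross_validate()], but recomputes the Riemannian mean motion
#' sequence (and hence all geodesic and covariance features) from the
#' training folds only, so no test information leaks into the reference the
#' features are measured against. `leaky_mean = TRUE` restores the simpler
#' variant where one mean sequence is computed from all cycles up front.
#'
#' @param cycles list of aligned `rg_pose_seq` (equal `F` and `B`).
#' @param labels class labels, one per cycle.
#' @param mode,n_folds,n_repeats,seed,config as in [cross_validate()].
#' @param scheme covariance hierarchy scheme (see [temporal_hierarchy()]).
#' @param leaky_mean compute the mean sequence once from all data
#'   (default `FALSE`).
#' @return as [cross_validate()].
#' @export
evaluate_cycles <- function(cycles, labels, mode = "fused", n_folds = 5L,
                            n_repeats = 10L, seed = 1L, config = list(),
                            scheme = "figure", leaky_mean = FALSE) {
  mode <- match.arg(mode, c("fused", "spatial", "temporal"))
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2L) rg_stop("need at least two classes", "argument")
  feats_for <- function(idx_mean) {
    ms <- compute_mean_sequence(cycles[idx_mean])
    G <- t(vapply(cycles, function(cy)
      flatten_features(geometric_features(cy, ms)),
      numeric(prod(dim(ms$mean_poses)[1:2]))))
    Cd <- t(vapply(cycles, function(cy)
      temporal_hierarchy(geometric_features(cy, ms), scheme)$flattened,
      numeric(length(temporal_hierarchy(
        geometric_features(cycles[[1]], ms), scheme)$flattened))))
    list(G = G, C = Cd)
  }
  if (leaky_mean) {
    fts <- feats_for(seq_along(cycles))
    return(cross_validate(fts$G, fts$C, labels, mode, n_folds, n_repeats,
                          seed, config))
  }
  acc <- matrix(NA_real_, n_repeats, n_folds)
  conf <- matrix(0L, length(cls), length(cls), dimnames = list(cls, cls))
  for (r in seq_len(n_repeats)) {
    folds <- stratified_folds(labels, n_folds, seed + r - 1L)
    for (k in seq_len(n_folds)) {
      test <- which(folds == k)
      train <- which(folds != k)
      fts <- feats_for(train)
      pred <- run_fold(fts$G, fts$C, labels, train, test, mode, config)
      acc[r, k] <- mean(pred == labels[test])
      for (q in seq_along(test))
        conf[labels[test[q]], pred[q]] <- conf[labels[test[q]], pred[q]] + 1L
    }
  }
  list(mean_accuracy = mean(acc), repeat_means = rowMeans(acc),
       fold_accuracies = acc, confusion = conf, mode = mode)
}
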