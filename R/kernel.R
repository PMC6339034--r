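# RBF kernels over feature vectors and their Hadamard fusion.

as_feature_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  as.matrix(x)
}

#' Estimate an RBF bandwidth from training features
#'
#' The bandwidth is the mean Euclidean distance over all unordered distinct
#' pairs of training vectors — the convention used for both the spatial
#' (`delta`) and temporal (`beta`) kernels.
#'
#' @param feature_vectors matrix with one sample per row (or list of
#'   vectors).
#' @return positive scalar.
#' @export
estimate_bandwidth <- function(feature_vectors) {
  X <- as_feature_matrix(feature_vectors)
  if (nrow(X) < 2L) rg_stop("need at least two vectors", "argument")
  bw <- mean(stats::dist(X))
  if (bw <= 0)
    rg_stop("all feature vectors identical: bandwidth is zero",
            "degenerate_bandwidth")
  bw
}

#' RBF kernel matrix
#'
#' `k(i, j) = exp(-||x_i - x_j||^2 / (2 * bandwidth^2))`: symmetric, unit
#' diagonal, positive semidefinite.
#'
#' @param feature_vectors matrix with one sample per row (or list).
#' @param bandwidth positive scalar (`delta` or `beta`).
#' @param feature_tag label recorded on the result, e.g. "spatial".
#' @return an object of class `rg_kernel` with `values` (`N x N`),
#'   `bandwidth`, `feature_tag`.
#' @export
rbf_kernel <- function(feature_vectors, bandwidth, feature_tag = "spatial") {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    rg_stop("bandwidth must be a positive scalar", "argument")
  X <- as_feature_matrix(feature_vectors)
  d2 <- as.matrix(stats::dist(X))^2
  K <- exp(-d2 / (2 * bandwidth^2))
  dimnames(K) <- NULL
  structure(list(values = K, bandwidth = bandwidth,
                 feature_tag = feature_tag),
            class = "rg_kernel")
}

#' Cross RBF kernel between query and training features
#'
#' `k(q, n) = exp(-||q - x_n||^2 / (2 * bandwidth^2))` against the training
#' rows; column `q` of the result is the out-of-sample feature vector of
#' query `q` in the training kernel basis.
#'
#' @param train_vectors,query_vectors matrices, one sample per row.
#' @param bandwidth the training bandwidth.
#' @return `N_train x N_query` matrix.
#' @export
rbf_cross_kernel <- function(train_vectors, query_vectors, bandwidth) {
  if (bandwidth <= 0) rg_stop("bandwidth must be positive", "argument")
  A <- as_feature_matrix(train_vectors)
  B <- as_feature_matrix(query_vectors)
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * bandwidth^2))
}

#' Fuse two kernels by the Hadamard product
#'
#' Entrywise multiplication of the spatial and temporal kernel matrices; the
#' Schur product theorem guarantees the fusion stays positive semidefinite.
#' Column `n` of the fused matrix is sample `n`'s fused feature vector.
#'
#' @param ks,kt `rg_kernel` objects (or bare matrices) of matching size.
#' @return an `rg_kernel` with `feature_tag = "fused"`.
#' @export
fuse_kernels <- function(ks, kt) {
  Ks <- if (inherits(ks, "rg_kernel")) ks$values else ks
  Kt <- if (inherits(kt, "rg_kernel")) kt$values else kt
  if (!all(dim(Ks) == dim(Kt)))
    rg_stop("kernel sizes differ", "argument")
  structure(list(values = Ks * Kt, bandwidth = NA_real_,
                 feature_tag = "fused"),
            class = "rg_kernel")
}
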