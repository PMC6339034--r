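# Kernelized large-margin nearest neighbour (KLMNN): loss, exact gradient,
# LDA initialization, gradient-descent training with backtracking line
# search, and k-NN classification under the learned metric.
#
# Convention: `columns` is a d x n matrix, one sample per column (for kernel
# features d = N, the number of training samples, so L is p x N).

pairwise_sqdist <- function(P) {
  # P: p x n projected samples; returns n x n squared Euclidean distances
  g <- colSums(P^2)
  d2 <- outer(g, rep(1, length(g))) + outer(rep(1, length(g)), g) -
    2 * crossprod(P)
  pmax(d2, 0)
}

check_klmnn_args <- function(mu, lambda, zeta) {
  if (!is.numeric(mu) || mu < 0 || mu > 1)
    rg_stop("mu must lie in [0, 1]", "argument")
  if (!is.numeric(lambda) || lambda < 0)
    rg_stop("lambda must be >= 0", "argument")
  if (!is.numeric(zeta) || zeta < 0)
    rg_stop("zeta must be >= 0", "argument")
}

check_triplet_sets <- function(labels, targets, impostors) {
  for (i in seq_along(labels)) {
    if (length(targets[[i]]) &&
        any(labels[targets[[i]]] != labels[i]))
      rg_stop("target neighbour with a different label", "argument")
    if (length(impostors[[i]]) &&
        any(labels[impostors[[i]]] == labels[i]))
      rg_stop("impostor with the same label", "argument")
  }
}

#' Squared distance under a learned transform
#'
#' `D(k_i, k_j) = ||L (k_i - k_j)||^2`, the squared Euclidean distance after
#' projection by the learned low-rank transform.
#'
#' @param L `p x d` transform.
#' @param ki,kj feature vectors of length `d`.
#' @return non-negative scalar.
#' @export
learned_distance <- function(L, ki, kj) {
  if (length(ki) != ncol(L) || length(kj) != ncol(L))
    rg_stop("vector length does not match ncol(L)", "argument")
  sum((L %*% (ki - kj))^2)
}

#' KLMNN loss
#'
#' The large-margin loss over kernel feature columns:
#' `mu * sum(hinge(D(i,j) - D(l,i) + zeta))` over triplets (i, target j,
#' impostor l), plus `(1 - mu) * sum(D(i,j))` over target pairs, plus
#' `lambda * ||L'L - I||_F`. The push term drives impostors at least `zeta`
#' further away than any target neighbour; the pull term keeps target
#' neighbours close; the penalty keeps the metric near-orthonormal.
#'
#' @param L `p x d` transform.
#' @param columns `d x n` matrix, one sample per column.
#' @param labels length-`n` class labels.
#' @param targets list: `targets[[i]]` are sample `i`'s target-neighbour
#'   indices (same label).
#' @param impostors list: `impostors[[i]]` are the differently-labelled
#'   candidate indices for sample `i` (hinge inactivity excludes distant
#'   ones automatically).
#' @param mu push/pull weight in `[0, 1]`.
#' @param lambda penalty weight, `>= 0`.
#' @param zeta hinge margin, `>= 0`.
#' @return scalar loss.
#' @export
klmnn_loss <- function(L, columns, labels, targets, impostors,
                       mu = 0.2, lambda = 0.1, zeta = 1) {
  check_klmnn_args(mu, lambda, zeta)
  check_triplet_sets(labels, targets, impostors)
  D <- pairwise_sqdist(L %*% columns)
  pull <- 0
  push <- 0
  for (i in seq_along(labels)) {
    tj <- targets[[i]]
    if (!length(tj)) next
    pull <- pull + sum(D[i, tj])
    il <- impostors[[i]]
    if (length(il))
      for (j in tj)
        push <- push + sum(pmax(D[i, j] - D[il, i] + zeta, 0))
  }
  A <- crossprod(L) - diag(ncol(L))
  mu * push + (1 - mu) * pull + lambda * sqrt(sum(A^2))
}

#' Exact gradient of the KLMNN loss
#'
#' Differentiates [klmnn_loss()] exactly: active triplets (positive hinge)
#' contribute `2 L (M_ij - M_il)` weighted by `mu`, target pairs contribute
#' `2 L M_ij` weighted by `1 - mu` (with `M_ab` the outer product of the
#' column difference), and the Frobenius penalty contributes
#' `lambda * 2 L (L'L - I) / ||L'L - I||_F` (zero subgradient when the
#' penalty vanishes). Note the published gradient formula for this loss
#' omits the `mu`/`1 - mu` weights and the hinge indicator; the exact
#' derivative is used here so the optimizer descends the stated loss
#' (validated against finite differences in the test suite).
#'
#' @inheritParams klmnn_loss
#' @return `p x d` gradient matrix.
#' @export
klmnn_gradient <- function(L, columns, labels, targets, impostors,
                           mu = 0.2, lambda = 0.1, zeta = 1) {
  check_klmnn_args(mu, lambda, zeta)
  check_triplet_sets(labels, targets, impostors)
  n <- length(labels)
  D <- pairwise_sqdist(L %*% columns)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    tj <- targets[[i]]
    if (!length(tj)) next
    W[i, tj] <- W[i, tj] + (1 - mu)
    il <- impostors[[i]]
    if (length(il)) {
      for (j in tj) {
        act <- il[D[i, j] - D[il, i] + zeta > 0]
        if (length(act)) {
          W[i, j] <- W[i, j] + mu * length(act)
          W[i, act] <- W[i, act] - mu
        }
      }
    }
  }
  # sum_ij W_ij (x_i - x_j)(x_i - x_j)' = X Lap X'
  r <- rowSums(W); cs <- colSums(W)
  lap <- diag(r + cs, n) - W - t(W)
  S <- columns %*% lap %*% t(columns)
  grad <- 2 * (L %*% S)
  A <- crossprod(L) - diag(ncol(L))
  nA <- sqrt(sum(A^2))
  if (nA > 0) grad <- grad + lambda * 2 * (L %*% A) / nA
  grad
}

#' Default target neighbours
#'
#' For each sample, its `k` nearest same-class neighbours under plain
#' Euclidean distance in column space; fixed before training, as in standard
#' LMNN.
#'
#' @param columns `d x n` matrix.
#' @param labels class labels.
#' @param k neighbours per sample.
#' @return list of integer index vectors.
#' @export
select_targets <- function(columns, labels, k = 3L) {
  D <- pairwise_sqdist(columns)
  lapply(seq_along(labels), function(i) {
    same <- setdiff(which(labels == labels[i]), i)
    same[order(D[i, same])][seq_len(min(k, length(same)))]
  })
}

#' LDA initialization of the transform
#'
#' The first `min(p, C - 1)` rows span the linear discriminant directions of
#' the labelled columns (generalized eigenvectors of the between/within
#' scatter, within-scatter ridge-regularized); remaining rows are principal
#' components of the feature matrix orthonormalized against the LDA rows.
#' All rows are orthonormal.
#'
#' @param columns `d x n` matrix, one sample per column.
#' @param labels class labels (`>= 2` classes).
#' @param p number of rows (`<= d`).
#' @return `p x d` matrix with orthonormal rows.
#' @export
lda_init <- function(columns, labels, p) {
  X <- as.matrix(columns)
  d <- nrow(X); n <- ncol(X)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2L) rg_stop("need at least two classes", "argument")
  if (p > d) rg_stop("p must not exceed the feature dimension", "argument")
  mu_all <- rowMeans(X)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (cl in cls) {
    idx <- which(labels == cl)
    mu_c <- rowMeans(X[, idx, drop = FALSE])
    Xc <- X[, idx, drop = FALSE] - mu_c
    Sw <- Sw + tcrossprod(Xc)
    Sb <- Sb + length(idx) * tcrossprod(mu_c - mu_all)
  }
  eps <- 1e-6 * mean(diag(Sw)) + 1e-12
  M <- solve(Sw + diag(eps, d), Sb)
  ei <- eigen(M)
  ord <- order(Re(ei$values), decreasing = TRUE)
  n_lda <- min(p, length(cls) - 1L)
  V <- Re(ei$vectors[, ord[seq_len(n_lda)], drop = FALSE])
  # candidate directions: LDA, then PCA of the samples, then canonical basis
  pcs <- stats::prcomp(t(X), center = TRUE)$rotation
  cand <- cbind(V, pcs, diag(d))
  basis <- matrix(0, d, 0)
  for (k in seq_len(ncol(cand))) {
    v <- cand[, k]
    if (ncol(basis)) v <- v - basis %*% crossprod(basis, v)
    nv <- vnorm(v)
    if (nv > 1e-8) basis <- cbind(basis, v / nv)
    if (ncol(basis) == p) break
  }
  if (ncol(basis) < p)
    rg_stop("could not build an orthonormal initialization of rank p",
            "argument")
  t(basis)
}

default_metric_config <- function(n = NULL) {
  list(mu = 0.2, lambda = 0.1, zeta = 1, p = NULL,
       max_epochs = 40L, grad_threshold = 0.01,
       n_targets = 3L, k_classify = 3L, learning_rate = 1e-3)
}

#' Train the KLMNN metric
#'
#' Gradient descent on [klmnn_loss()] from the LDA initialization, with a
#' backtracking line search (start at `learning_rate`, halve on loss
#' increase, accept on decrease) so the recorded loss history is
#' non-increasing. Training stops at `max_epochs`, when the gradient
#' Frobenius norm falls below `grad_threshold`, or when the line search can
#' no longer decrease the loss.
#'
#' @param columns `d x n` training matrix, one sample per column (kernel
#'   feature columns in the full pipeline).
#' @param labels length-`n` class labels; every class needs at least
#'   `n_targets + 1` samples.
#' @param config list overriding defaults: `mu` (0.2), `lambda` (0.1),
#'   `zeta` (1), `p` (defaults to `d`), `max_epochs` (40),
#'   `grad_threshold` (0.01), `n_targets` (3), `k_classify` (3),
#'   `learning_rate` (1e-3).
#' @return an object of class `rg_metric_model` with `L`, `p`, `config`,
#'   `columns`, `labels`, `loss_history`, `grad_norms`, `converged`.
#' @export
train_metric <- function(columns, labels, config = list()) {
  cfg <- utils::modifyList(default_metric_config(), config)
  X <- as.matrix(columns)
  labels <- as.character(labels)
  n <- ncol(X)
  if (length(labels) != n) rg_stop("one label per column required", "argument")
  tab <- table(labels)
  if (length(tab) < 2L) rg_stop("need at least two classes", "argument")
  if (any(tab < cfg$n_targets + 1L))
    rg_stop(sprintf("every class needs >= %d samples", cfg$n_targets + 1L),
            "argument")
  check_klmnn_args(cfg$mu, cfg$lambda, cfg$zeta)
  p <- as.integer(cfg$p %||% nrow(X))
  targets <- select_targets(X, labels, cfg$n_targets)
  impostors <- lapply(seq_len(n), function(i) which(labels != labels[i]))
  L <- lda_init(X, labels, p)
  loss <- klmnn_loss(L, X, labels, targets, impostors,
                     cfg$mu, cfg$lambda, cfg$zeta)
  history <- loss
  gnorms <- numeric(0)
  converged <- FALSE
  for (epoch in seq_len(cfg$max_epochs)) {
    grad <- klmnn_gradient(L, X, labels, targets, impostors,
                           cfg$mu, cfg$lambda, cfg$zeta)
    gn <- sqrt(sum(grad^2))
    gnorms <- c(gnorms, gn)
    if (gn < cfg$grad_threshold) { converged <- TRUE; break }
    step <- cfg$learning_rate
    accepted <- FALSE
    for (half in 1:50) {
      if (step <= 0) break
      L2 <- L - step * grad
      loss2 <- klmnn_loss(L2, X, labels, targets, impostors,
                          cfg$mu, cfg$lambda, cfg$zeta)
      if (loss2 < loss) {
        L <- L2; loss <- loss2; accepted <- TRUE; break
      }
      step <- step / 2
    }
    history <- c(history, loss)
    if (!accepted) break   # line search stalled: local minimum along -grad
  }
  structure(list(L = L, p = p, config = cfg, columns = X, labels = labels,
                 targets = targets, loss_history = history,
                 grad_norms = gnorms, converged = converged),
            class = "rg_metric_model")
}

#' @export
print.rg_metric_model <- function(x, ...) {
  cat(sprintf(
    "<rg_metric_model> p=%d, n=%d, %d classes; loss %.4g -> %.4g (%s)\n",
    x$p, ncol(x$columns), length(unique(x$labels)),
    x$loss_history[1], x$loss_history[length(x$loss_history)],
    if (x$converged) "gradient converged" else "epoch/step limit"))
  invisible(x)
}

#' Classify queries by k-NN under the learned metric
#'
#' Majority vote among the `k_classify` nearest training columns under
#' [learned_distance()]; vote ties are broken by the smallest summed
#' distance, then by label sort order.
#'
#' @param model a trained `rg_metric_model`.
#' @param query_columns `d x m` matrix of query feature columns built
#'   against the same training basis.
#' @return character vector of `m` predicted labels.
#' @export
classify_knn <- function(model, query_columns) {
  if (!inherits(model, "rg_metric_model"))
    rg_stop("model is not a trained rg_metric_model", "state")
  Q <- as.matrix(query_columns)
  if (nrow(Q) != ncol(model$L))
    rg_stop("query dimension does not match the model", "argument")
  k <- model$config$k_classify
  PT <- model$L %*% model$columns
  PQ <- model$L %*% Q
  d2 <- outer(colSums(PT^2), rep(1, ncol(PQ))) +
    outer(rep(1, ncol(PT)), colSums(PQ^2)) - 2 * crossprod(PT, PQ)
  d2 <- pmax(d2, 0)
  vapply(seq_len(ncol(Q)), function(q) {
    ord <- order(d2[, q])[seq_len(min(k, ncol(PT)))]
    votes <- model$labels[ord]
    tab <- table(votes)
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1L) {
      sums <- vapply(best, function(b) sum(d2[ord[votes == b], q]),
                     numeric(1))
      best <- best[sums == min(sums)]
    }
    sort(best)[1]
  }, character(1))
}
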