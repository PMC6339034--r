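# RBF kernels, fusion, KLMNN loss/gradient/training, k-NN classification,
# cross-validation

test_that("estimate_bandwidth is the mean pairwise distance", {
  expect_equal(estimate_bandwidth(rbind(c(0, 0), c(3, 0))), 3)
  expect_equal(estimate_bandwidth(matrix(c(0, 1, 2), 3, 1)), 4 / 3)
  expect_error(estimate_bandwidth(matrix(1, 1, 2)),
               class = "riemgait_error_argument")
  expect_error(estimate_bandwidth(matrix(1, 4, 2)),
               class = "riemgait_error_degenerate_bandwidth")
})

test_that("rbf_kernel has unit diagonal and the right decay", {
  X <- rbind(c(0, 0), c(2 * sqrt(2), 0), c(1, 1))
  K <- rbf_kernel(X, bandwidth = 2)
  expect_equal(diag(K$values), rep(1, 3))
  expect_equal(K$values[1, 2], exp(-1))        # distance = bandwidth * sqrt(2)
  expect_equal(K$values, t(K$values))
  expect_error(rbf_kernel(X, 0), class = "riemgait_error_argument")
})

test_that("fuse_kernels multiplies entrywise and stays PSD", {
  Kt <- matrix(c(1, .4, .4, 1), 2, 2)
  expect_equal(fuse_kernels(matrix(1, 2, 2), Kt)$values, Kt)
  expect_equal(fuse_kernels(matrix(.5, 2, 2), matrix(.4, 2, 2))$values,
               matrix(.2, 2, 2))
  set.seed(20)
  for (rep in 1:100) {
    A <- matrix(rnorm(8 * 3), 8, 3)
    B <- matrix(rnorm(8 * 4), 8, 4)
    Kf <- fuse_kernels(rbf_kernel(A, estimate_bandwidth(A)),
                       rbf_kernel(B, estimate_bandwidth(B)))
    expect_gt(min(eigen(Kf$values, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-8)
  }
  expect_error(fuse_kernels(matrix(1, 2, 2), matrix(1, 3, 3)),
               class = "riemgait_error_argument")
})

test_that("learned_distance is the squared norm of the projected difference", {
  ki <- c(1, 2, 3); kj <- c(0, 1, 1)
  expect_equal(learned_distance(diag(3), ki, ki), 0)
  expect_equal(learned_distance(diag(3), ki, kj), sum((ki - kj)^2))
  expect_equal(learned_distance(2 * diag(3), ki, kj), 4 * sum((ki - kj)^2))
  expect_error(learned_distance(diag(2), ki, kj),
               class = "riemgait_error_argument")
})

test_that("klmnn_loss matches hand evaluation", {
  # 1-D samples {0, 1, 10}, labels {a, a, b}; target pair (1,2); impostor 3
  X <- matrix(c(0, 1, 10), 1, 3)
  labels <- c("a", "a", "b")
  targets <- list(2L, 1L, integer(0))
  imps <- list(3L, 3L, integer(0))
  L <- matrix(1, 1, 1)
  # pull = 0.8 * (1 + 1); push hinges: (1 - 100 + 1, 1 - 81 + 1) both <= 0
  expect_equal(klmnn_loss(L, X, labels, targets, imps, mu = 0.2,
                          lambda = 0, zeta = 1), 0.8 * 2)
  # coincident samples, zero margin: every term vanishes at L = I
  Xc <- matrix(1, 2, 4)
  lc <- c("a", "a", "b", "b")
  tc <- list(2L, 1L, 4L, 3L)
  ic <- list(3:4, 3:4, 1:2, 1:2)
  expect_equal(klmnn_loss(diag(2), Xc, lc, tc, ic, 0.2, 0, 0), 0)
  # single sample: only the penalty survives
  L1 <- matrix(c(1, 2), 1, 2)
  pen <- sqrt(sum((crossprod(L1) - diag(2))^2))
  expect_equal(klmnn_loss(L1, matrix(c(1, 1), 2, 1), "a", list(integer(0)),
                          list(integer(0)), 0.2, 0.7, 1), 0.7 * pen)
  expect_error(klmnn_loss(L, X, labels, targets, imps, mu = 2),
               class = "riemgait_error_argument")
  expect_error(klmnn_loss(L, X, labels, list(3L, 1L, integer(0)), imps),
               class = "riemgait_error_argument")  # target label mismatch
})

test_that("klmnn_gradient matches central finite differences", {
  set.seed(23)
  for (rep in 1:3) {
    n <- 4 + rep; d <- 4; p <- 2
    X <- matrix(rnorm(d * n), d, n)
    labels <- rep(c("a", "b"), length.out = n)
    targets <- select_targets(X, labels, 1)
    imps <- lapply(seq_len(n), function(i) which(labels != labels[i]))
    L <- matrix(rnorm(p * d) * 0.6, p, d)
    g <- klmnn_gradient(L, X, labels, targets, imps, 0.2, 0.1, 1)
    h <- 1e-6
    fd <- matrix(0, p, d)
    for (i in seq_len(p)) for (j in seq_len(d)) {
      Lp <- L; Lp[i, j] <- Lp[i, j] + h
      Lm <- L; Lm[i, j] <- Lm[i, j] - h
      fd[i, j] <- (klmnn_loss(Lp, X, labels, targets, imps, 0.2, 0.1, 1) -
                     klmnn_loss(Lm, X, labels, targets, imps, 0.2, 0.1, 1)) /
        (2 * h)
    }
    expect_lt(max(abs(g - fd) / (abs(fd) + 1e-6)), 1e-5)
  }
  # coincident samples at L = I with p = d: exact minimum, zero gradient
  Xc <- matrix(1, 2, 4)
  lc <- c("a", "a", "b", "b")
  g0 <- klmnn_gradient(diag(2), Xc, lc, list(2L, 1L, 4L, 3L),
                       list(3:4, 3:4, 1:2, 1:2), 0.2, 0, 0)
  expect_equal(g0, matrix(0, 2, 2))
})

test_that("lda_init recovers discriminant directions with orthonormal rows", {
  set.seed(25)
  n <- 40
  X <- cbind(matrix(rnorm(2 * n, sd = 0.3), 2, n) + c(5, 0),
             matrix(rnorm(2 * n, sd = 0.3), 2, n) + c(-5, 0))
  labels <- rep(c("a", "b"), each = n)
  L <- lda_init(X, labels, 1)
  ang <- acos(min(1, abs(sum(L * c(1, 0)) / sqrt(sum(L^2)))))
  expect_lt(ang, 5 * pi / 180)          # within 5 degrees of the mean gap
  L2 <- lda_init(X, labels, 2)
  expect_equal(tcrossprod(L2), diag(2), tolerance = 1e-8)
  set.seed(26)
  Xr <- matrix(rnorm(6 * 12), 6, 12)
  lr <- rep(c("a", "b", "c"), each = 4)
  L3 <- lda_init(Xr, lr, 5)
  expect_equal(tcrossprod(L3), diag(5), tolerance = 1e-8)
  expect_error(lda_init(Xr, rep("a", 12), 2),
               class = "riemgait_error_argument")
})

make_separable <- function(seed = 30, n_per = 10, C = 3, d = 6, gap = 20) {
  set.seed(seed)
  centers <- matrix(rnorm(d * C), d, C) * gap
  X <- NULL; labels <- character(0)
  for (c_ in seq_len(C)) {
    X <- cbind(X, centers[, c_] + matrix(rnorm(d * n_per, sd = 0.5), d))
    labels <- c(labels, rep(letters[c_], n_per))
  }
  list(X = X, labels = labels)
}

test_that("train_metric descends monotonically and fits separable data", {
  sep <- make_separable()
  model <- train_metric(sep$X, sep$labels, list(p = 4))
  expect_true(all(diff(model$loss_history) <= 1e-12))
  pred <- classify_knn(model, sep$X)
  expect_equal(mean(pred == sep$labels), 1)
  # zero learning rate: line search can never accept, L stays at the init
  frozen <- train_metric(sep$X, sep$labels, list(p = 4, learning_rate = 0))
  expect_equal(frozen$L, lda_init(sep$X, sep$labels, 4))
  expect_error(train_metric(sep$X, rep("a", length(sep$labels))),
               class = "riemgait_error_argument")
})

test_that("monotone loss holds on random instances", {
  set.seed(41)
  for (rep in 1:20) {
    n <- 12; d <- 5
    X <- matrix(rnorm(d * n), d, n)
    labels <- rep(c("a", "b"), each = 6)
    m <- train_metric(X, labels, list(p = 3, max_epochs = 15, n_targets = 2))
    expect_true(all(diff(m$loss_history) <= 1e-12))
  }
})

test_that("classify_knn votes with deterministic tie-breaking", {
  X <- matrix(c(0, 0, 5), 1, 3)
  m <- train_metric(cbind(X, X + 0.01), rep(c("a", "a", "b"), 2),
                    list(p = 1, max_epochs = 1, n_targets = 1,
                         learning_rate = 0))
  expect_equal(classify_knn(m, matrix(0, 1, 1)), "a")
  # two coincident training points, different labels, k = 2: label order
  m2 <- structure(list(L = matrix(1, 1, 1), p = 1,
                       config = utils::modifyList(
                         riemgait:::default_metric_config(),
                         list(k_classify = 2L)),
                       columns = matrix(c(1, 1), 1, 2),
                       labels = c("z", "b")),
                  class = "rg_metric_model")
  expect_equal(classify_knn(m2, matrix(1, 1, 1)), "b")
  expect_error(classify_knn(list(), matrix(1, 1, 1)),
               class = "riemgait_error_state")
})

test_that("stratified_folds balances classes and covers every sample", {
  labels <- rep(c("a", "b", "c"), times = c(10, 15, 20))
  f <- stratified_folds(labels, 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  for (k in 1:5) {
    expect_equal(sum(labels[f == k] == "a"), 2)
    expect_equal(sum(labels[f == k] == "b"), 3)
    expect_equal(sum(labels[f == k] == "c"), 4)
  }
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 10)), 5),
               class = "riemgait_error_argument")
})

test_that("cross_validate is honest, deterministic, and fits separable data", {
  sep <- make_separable(seed = 44, n_per = 10, C = 3, d = 5, gap = 30)
  S <- t(sep$X)
  Tm <- t(sep$X) + 0.1
  res <- cross_validate(S, Tm, sep$labels, "fused", n_folds = 5,
                        n_repeats = 2, seed = 7,
                        config = list(p = 10, max_epochs = 5))
  expect_equal(res$mean_accuracy, 1)
  expect_equal(dim(res$fold_accuracies), c(2L, 5L))
  expect_equal(sum(res$confusion), 2 * length(sep$labels))
  res2 <- cross_validate(S, Tm, sep$labels, "fused", n_folds = 5,
                         n_repeats = 2, seed = 7,
                         config = list(p = 10, max_epochs = 5))
  expect_identical(res, res2)                        # same seed, same result
  expect_error(cross_validate(S, Tm, rep("a", 30), "fused"),
               class = "riemgait_error_argument")
})

test_that("label permutation destroys cross-validated signal", {
  sep <- make_separable(seed = 50, n_per = 10, C = 4, d = 5, gap = 25)
  perm <- withr::with_seed(8, sample(sep$labels))
  res <- cross_validate(t(sep$X), t(sep$X), perm, "fused", n_folds = 5,
                        n_repeats = 2, seed = 9,
                        config = list(p = 8, max_epochs = 5))
  expect_lt(abs(res$mean_accuracy - 0.25), 0.15)
})
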