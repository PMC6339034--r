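# Aligned Riemannian mean motion sequence, geodesic spatial features, and
# the temporal hierarchy of covariance descriptors.

#' Compute the aligned Riemannian mean motion sequence
#'
#' For every frame `f` and bone `b`, the Karcher mean of that bone's
#' directions across all aligned cycles is computed by iterated tangent-space
#' averaging, giving one mean pose per frame. All cycles must share the same
#' frame count and bone count (align them first).
#'
#' @param aligned_cycles list of `rg_pose_seq` with identical dimensions.
#' @param grad_tol,step_size,max_iter Karcher iteration controls
#'   (see [karcher_mean()]).
#' @return an object of class `rg_mean_seq`: `mean_poses` (`F x B x 3`),
#'   and `convergence` (list of `F x B` matrices `grad_norm`, `iterations`).
#' @export
compute_mean_sequence <- function(aligned_cycles, grad_tol = 1e-6,
                                  step_size = 1, max_iter = 100L) {
  if (!length(aligned_cycles)) rg_stop("no cycles", "argument")
  dims <- vapply(aligned_cycles, function(c) dim(c$dirs)[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    rg_stop("cycles differ in frame or bone count", "argument")
  nf <- dims[1, 1]; nb <- dims[2, 1]; ns <- length(aligned_cycles)
  mp <- array(NA_real_, c(nf, nb, 3))
  gn <- matrix(NA_real_, nf, nb)
  it <- matrix(NA_integer_, nf, nb)
  pts <- matrix(NA_real_, ns, 3)
  for (f in seq_len(nf)) for (b in seq_len(nb)) {
    for (s in seq_len(ns)) pts[s, ] <- aligned_cycles[[s]]$dirs[f, b, ]
    m <- tryCatch(
      karcher_mean(pts, grad_tol, step_size, max_iter),
      riemgait_error = function(e) rg_stop(sprintf(
        "Karcher mean failed at frame %d, bone %d: %s",
        f - 1L, b, conditionMessage(e)), "convergence"))
    mp[f, b, ] <- m
    gn[f, b] <- attr(m, "grad_norm")
    it[f, b] <- attr(m, "iterations")
  }
  structure(list(mean_poses = mp,
                 convergence = list(grad_norm = gn, iterations = it)),
            class = "rg_mean_seq")
}

#' @export
print.rg_mean_seq <- function(x, ...) {
  d <- dim(x$mean_poses)
  cat(sprintf(
    "<rg_mean_seq> %d frames x %d bones; max final ||v|| = %.2e\n",
    d[1], d[2], max(x$convergence$grad_norm)))
  invisible(x)
}

#' Geodesic spatial features of a cycle against the mean sequence
#'
#' `G[f, b]` is the great-circle distance (radians) between the cycle's bone
#' direction and the corresponding mean-sequence direction, i.e. how far this
#' individual's pose deviates from the population mean pose at that instant.
#'
#' @param cycle an `rg_pose_seq` with the same `F` and `B` as `mean_seq`.
#' @param mean_seq an `rg_mean_seq`.
#' @return an object of class `rg_geom_features` with `G` (`F x B` matrix,
#'   entries in `[0, pi]`).
#' @export
geometric_features <- function(cycle, mean_seq) {
  d1 <- dim(cycle$dirs); d2 <- dim(mean_seq$mean_poses)
  if (!all(d1 == d2))
    rg_stop("cycle and mean sequence dimensions differ", "argument")
  prod <- cycle$dirs * mean_seq$mean_poses
  G <- acos(clamp1(prod[, , 1] + prod[, , 2] + prod[, , 3]))
  G <- matrix(G, d1[1], d1[2])
  structure(list(G = G), class = "rg_geom_features")
}

#' Flatten a geodesic feature matrix to the vector G(s)
#'
#' Row-major by frame: all bones of frame 0, then frame 1, and so on;
#' length `F * B`.
#'
#' @param feats an `rg_geom_features` (or a bare `F x B` matrix).
#' @return numeric vector of length `F * B`.
#' @export
flatten_features <- function(feats) {
  G <- if (inherits(feats, "rg_geom_features")) feats$G else feats
  as.vector(t(G))
}

#' Covariance of geodesic features over a frame window
#'
#' Sample covariance (denominator `n - 1`) of the rows of `G` in the
#' half-open 0-based frame window `[f1, f2)`; a `B x B` symmetric positive
#' semidefinite matrix describing how bone deviations co-vary over the
#' window.
#'
#' @param feats an `rg_geom_features` or `F x B` matrix.
#' @param f1,f2 window bounds, 0-based half-open; `f2 - f1 >= 2`.
#' @return `B x B` covariance matrix.
#' @export
covariance_window <- function(feats, f1, f2) {
  G <- if (inherits(feats, "rg_geom_features")) feats$G else feats
  f1 <- as.integer(f1); f2 <- as.integer(f2)
  if (f2 - f1 < 2L)
    rg_stop("window must contain at least 2 frames", "window_too_small")
  if (f1 < 0L || f2 > nrow(G))
    rg_stop("window out of range", "argument")
  C <- stats::cov(G[(f1 + 1L):f2, , drop = FALSE])
  (C + t(C)) / 2
}

# Window table for a hierarchy scheme: two-column 0-based half-open ranges.
hierarchy_windows <- function(n_frames, scheme = c("figure", "paper_dim",
                                                   "custom"),
                              window_length = NULL, n_windows = 7L) {
  scheme <- match.arg(scheme)
  w <- as.integer(window_length %||% floor(n_frames / 4))
  n_windows <- as.integer(n_windows)
  if (n_frames < 8L)
    rg_stop("need at least 8 frames for the default hierarchy", "argument")
  if (w < 2L || w > n_frames)
    rg_stop("second-level window length out of range", "argument")
  starts <- floor((0:(n_windows - 1L)) * (n_frames - w) / (n_windows - 1L))
  second <- cbind(start = as.integer(starts), end = as.integer(starts + w))
  if (scheme == "paper_dim") second
  else rbind(c(0L, n_frames), second)
}

#' Temporal hierarchy of covariance descriptors
#'
#' Builds the two-level overlapping window scheme and one covariance matrix
#' per window, then concatenates the upper triangles (including diagonals,
#' row-major) into a single descriptor vector. The default `"figure"` scheme
#' is one top-level window over all `F` frames plus seven second-level
#' windows of length `floor(F/4)` whose starts are evenly spaced so that
#' together they cover the whole sequence (8 matrices). The `"paper_dim"`
#' scheme drops the top level, giving 7 matrices and descriptor length
#' `7 * B * (B + 1) / 2`.
#'
#' @param feats an `rg_geom_features` or `F x B` matrix.
#' @param scheme `"figure"` (default), `"paper_dim"`, or `"custom"`.
#' @param window_length second-level window length (default `floor(F/4)`).
#' @param n_windows number of second-level windows (default 7).
#' @return an object of class `rg_cov_descriptor`: `windows` (0-based
#'   half-open ranges), `matrices` (list of `B x B`), `flattened`
#'   (length `W * B * (B + 1) / 2`).
#' @export
temporal_hierarchy <- function(feats, scheme = "figure",
                               window_length = NULL, n_windows = 7L) {
  G <- if (inherits(feats, "rg_geom_features")) feats$G else feats
  wins <- hierarchy_windows(nrow(G), scheme, window_length, n_windows)
  mats <- lapply(seq_len(nrow(wins)), function(k)
    covariance_window(G, wins[k, 1], wins[k, 2]))
  nb <- ncol(G)
  flat <- unlist(lapply(mats, function(M)
    unlist(lapply(seq_len(nb), function(i) M[i, i:nb]))))
  structure(list(windows = wins, matrices = mats, flattened = flat),
            class = "rg_cov_descriptor")
}

#' @export
print.rg_cov_descriptor <- function(x, ...) {
  cat(sprintf("<rg_cov_descriptor> %d windows, descriptor length %d\n",
              nrow(x$windows), length(x$flattened)))
  invisible(x)
}

#' Serialize a mean sequence to the wide CSV layout
#'
#' Writes unit bone-direction components in the position-CSV layout (bone
#' names in place of joint names) for inspection; [read_mean_sequence_csv()]
#' restores the object (without convergence diagnostics).
#'
#' @param mean_seq an `rg_mean_seq`.
#' @param names character vector of bone names (length `B`).
#' @param path output path.
#' @return `path` invisibly, or the restored `rg_mean_seq`.
#' @export
write_mean_sequence_csv <- function(mean_seq, names, path) {
  mp <- mean_seq$mean_poses
  nf <- dim(mp)[1]; nb <- dim(mp)[2]
  if (length(names) != nb) rg_stop("need one name per bone", "argument")
  flat <- matrix(NA_real_, nf, 3 * nb)
  for (b in seq_len(nb)) flat[, (3 * b - 2):(3 * b)] <- mp[, b, ]
  df <- data.frame(frame = 0:(nf - 1), flat, check.names = FALSE)
  names(df) <- c("frame", paste(rep(names, each = 3),
                                c("x", "y", "z"), sep = "_"))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mean_sequence_csv
#' @export
read_mean_sequence_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nb <- (ncol(df) - 1L) / 3L
  nf <- nrow(df)
  mp <- array(NA_real_, c(nf, nb, 3))
  for (b in seq_len(nb)) mp[, b, ] <- as.matrix(df[, (3 * b - 1):(3 * b + 1)])
  structure(list(mean_poses = mp,
                 convergence = list(grad_norm = matrix(0, nf, nb),
                                    iterations = matrix(0L, nf, nb))),
            class = "rg_mean_seq")
}
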