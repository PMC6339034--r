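# Geometry of the unit 2-sphere and its product: log/exp maps, geodesic
# distance, Karcher means, slerp, and conversion of joint positions to
# bone-direction pose sequences.

check_unit <- function(v, what = "point") {
  if (abs(vnorm(v) - 1) > 1e-9)
    rg_stop(paste(what, "is not unit norm"), "argument")
  invisible(v)
}

#' Logarithm map on the unit 2-sphere
#'
#' Maps `point` into the tangent plane at `base` along their connecting
#' geodesic: the returned vector is orthogonal to `base` and its Euclidean
#' norm equals the geodesic angle between the two points.
#'
#' @param base,point unit 3-vectors.
#' @return a 3-vector in the tangent plane of `base`.
#' @seealso [sphere_exp()] for the inverse map.
#' @export
sphere_log <- function(base, point) {
  check_unit(base, "base"); check_unit(point, "point")
  d <- clamp1(sum(base * point))
  theta <- acos(d)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (theta > pi - 1e-6)
    rg_stop("log map undefined for (near-)antipodal points", "undefined_log")
  (theta / sin(theta)) * (point - d * base)
}

#' Exponential map on the unit 2-sphere
#'
#' Walks from `base` along the geodesic with initial direction `tangent` for
#' arc length `||tangent||` and returns the unit end point.
#'
#' @param base unit 3-vector.
#' @param tangent 3-vector orthogonal to `base` (tolerance 1e-6).
#' @return unit 3-vector at geodesic distance `||tangent||` from `base`.
#' @export
sphere_exp <- function(base, tangent) {
  check_unit(base, "base")
  if (abs(sum(base * tangent)) > 1e-6)
    rg_stop("tangent is not orthogonal to base", "invalid_tangent")
  nt <- vnorm(tangent)
  if (nt < 1e-14) return(base)
  out <- cos(nt) * base + sin(nt) * (tangent / nt)
  out / vnorm(out)
}

#' Geodesic distance between two unit vectors
#'
#' Great-circle arc length `acos(<x, m>)` with the inner product clamped to
#' `[-1, 1]`; the value lies in `[0, pi]` and equals the norm of
#' `sphere_log(m, x)` away from the antipode.
#'
#' @param x,m unit 3-vectors.
#' @return arc length in radians.
#' @export
geodesic_distance <- function(x, m) {
  check_unit(x, "x"); check_unit(m, "m")
  acos(clamp1(sum(x * m)))
}

# Vectorized logs of the rows of `points` (n x 3) about unit vector m.
# Returns n x 3 tangent rows; rows at the base map to zero.
sphere_log_rows <- function(m, points) {
  d <- clamp1(as.vector(points %*% m))
  theta <- acos(d)
  if (any(theta > pi - 1e-6))
    rg_stop("log map undefined for (near-)antipodal points", "undefined_log")
  fac <- ifelse(theta < 1e-12, 0, theta / sin(theta))
  fac * (points - outer(d, m))
}

#' Karcher (Fréchet) mean of points on the sphere
#'
#' Iterated tangent-space averaging: from the current estimate `m`, the mean
#' tangent `v = mean(log_m(x_s))` is computed and `m` is moved to
#' `exp_m(step_size * v)` until `||v|| <= grad_tol`. Uniqueness requires the
#' points to lie in an open hemisphere.
#'
#' @param points numeric matrix, one unit 3-vector per row (a single vector
#'   is accepted).
#' @param grad_tol convergence tolerance on the mean-tangent norm
#'   (default 1e-6).
#' @param step_size Riemannian gradient step (default 1, the classical
#'   Karcher iteration; contractive within a hemisphere).
#' @param max_iter iteration cap (default 100).
#' @return unit 3-vector with attributes `iterations` and `grad_norm`.
#' @export
karcher_mean <- function(points, grad_tol = 1e-6, step_size = 1,
                         max_iter = 100L) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  if (nrow(points) == 0L) rg_stop("empty point set", "argument")
  nr <- sqrt(rowSums(points^2))
  if (any(abs(nr - 1) > 1e-9))
    rg_stop("points must be unit vectors", "argument")
  m <- points[1, ]
  for (it in 0:max_iter) {
    v <- colMeans(sphere_log_rows(m, points))
    nv <- vnorm(v)
    if (nv <= grad_tol) {
      attr(m, "iterations") <- it
      attr(m, "grad_norm") <- nv
      return(m)
    }
    if (it == max_iter) break
    m <- sphere_exp(m, step_size * v)
  }
  rg_stop(sprintf(
    "Karcher mean did not converge in %d iterations (||v|| = %.3g)",
    max_iter, nv), "convergence")
}

#' Equally spaced points along a sphere geodesic
#'
#' Returns `n_intermediate` points strictly between `x_f` and `x_w` on their
#' connecting geodesic, splitting it into `n_intermediate + 1` equal arcs
#' (the manifold analogue of cutting the tangent vector into equal parts).
#'
#' @param x_f,x_w unit 3-vectors, not antipodal.
#' @param n_intermediate number of interior points (>= 0).
#' @return matrix `n_intermediate x 3` of unit vectors.
#' @export
geodesic_interpolate <- function(x_f, x_w, n_intermediate) {
  n_intermediate <- as.integer(n_intermediate)
  if (n_intermediate < 0L) rg_stop("n_intermediate must be >= 0", "argument")
  if (n_intermediate == 0L) return(matrix(numeric(0), 0, 3))
  v <- sphere_log(x_f, x_w)
  t(vapply(seq_len(n_intermediate),
           function(k) sphere_exp(x_f, v * k / (n_intermediate + 1)),
           numeric(3)))
}

# Slerp x_f -> x_w at parameter t in [0, 1]; exact endpoints at t = 0, 1.
slerp <- function(x_f, x_w, t) {
  if (t == 0) return(x_f)
  if (t == 1) return(x_w)
  sphere_exp(x_f, t * sphere_log(x_f, x_w))
}

#' Convert joint positions to a bone-direction pose sequence
#'
#' Each bone's state in each frame is the unit vector from parent joint to
#' child joint, a point on the 2-sphere; a pose is the tuple of all bone
#' directions (a point on the product manifold S^2 x ... x S^2). Bone
#' lengths, and hence static skeleton size, are discarded.
#'
#' @param seq an `rg_joint_seq`.
#' @param skeleton its `rg_skeleton`.
#' @return an object of class `rg_pose_seq` with `dirs` (`F x B x 3`),
#'   `frame_rate`, `subject_label`, `sequence_id`.
#' @export
to_pose_sequence <- function(seq, skeleton, ...) {
  pos <- seq$positions
  nf <- dim(pos)[1]
  bones <- skeleton$bones
  nb <- nrow(bones)
  dirs <- array(NA_real_, c(nf, nb, 3))
  for (b in seq_len(nb)) {
    d <- pos[, bones[b, 2], , drop = FALSE] - pos[, bones[b, 1], , drop = FALSE]
    d <- matrix(d, nrow = nf)
    len <- sqrt(rowSums(d^2))
    if (any(len < 1e-9)) {
      f <- which(len < 1e-9)[1]
      rg_stop(sprintf("degenerate bone '%s' at frame %d (length %.3g)",
                      bone_names(skeleton)[b], f - 1L, len[f]),
              "degenerate_bone")
    }
    dirs[, b, ] <- d / len
  }
  pose_sequence(dirs, seq$frame_rate, seq$subject_label, seq$sequence_id)
}

#' Construct a pose sequence from bone directions
#'
#' @param dirs numeric `F x B x 3` array of unit bone directions.
#' @param frame_rate frames per second.
#' @param subject_label,sequence_id metadata.
#' @return an `rg_pose_seq`.
#' @export
pose_sequence <- function(dirs, frame_rate = 1, subject_label = "unknown",
                          sequence_id = "seq") {
  if (length(dim(dirs)) != 3L || dim(dirs)[3] != 3L)
    rg_stop("dirs must be an F x B x 3 array", "argument")
  nrm <- sqrt(apply(dirs^2, c(1, 2), sum))
  if (any(abs(nrm - 1) > 1e-9))
    rg_stop("bone directions must be unit vectors", "argument")
  structure(
    list(dirs = dirs, frame_rate = frame_rate,
         subject_label = as.character(subject_label),
         sequence_id = as.character(sequence_id)),
    class = "rg_pose_seq"
  )
}

#' @export
print.rg_pose_seq <- function(x, ...) {
  d <- dim(x$dirs)
  cat(sprintf("<rg_pose_seq> '%s' subject=%s: %d frames x %d bones\n",
              x$sequence_id, x$subject_label, d[1], d[2]))
  invisible(x)
}

# Replace the frame axis of a pose sequence, keeping metadata.
pose_slice <- function(ps, frames) {
  pose_sequence(ps$dirs[frames, , , drop = FALSE], ps$frame_rate,
                ps$subject_label, ps$sequence_id)
}

#' Uniformly resample a pose sequence on the manifold
#'
#' Maps `target_F` equally spaced time points onto the source frame axis and
#' interpolates between neighbouring frames along per-bone geodesics; when
#' `target_F` equals the source length the sequence is returned unchanged.
#'
#' @param ps an `rg_pose_seq`.
#' @param target_F desired frame count (>= 2).
#' @return an `rg_pose_seq` with exactly `target_F` frames.
#' @export
resample_pose_sequence <- function(ps, target_F) {
  nf <- dim(ps$dirs)[1]
  nb <- dim(ps$dirs)[2]
  target_F <- as.integer(target_F)
  if (target_F < 2L) rg_stop("target_F must be >= 2", "argument")
  if (target_F == nf) return(ps)
  u <- seq(0, nf - 1, length.out = target_F)
  i0 <- pmin(floor(u), nf - 2)
  tt <- u - i0
  out <- array(NA_real_, c(target_F, nb, 3))
  for (f in seq_len(target_F)) {
    a <- i0[f] + 1
    for (b in seq_len(nb))
      out[f, b, ] <- slerp(ps$dirs[a, b, ], ps$dirs[a + 1, b, ], tt[f])
  }
  pose_sequence(out, ps$frame_rate, ps$subject_label, ps$sequence_id)
}
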