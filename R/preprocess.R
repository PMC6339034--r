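# Cycle segmentation via speed autocorrelation and manifold alignment of
# cycles to a common length.

#' Per-frame speed of one joint
#'
#' The speed series is the frame-to-frame Euclidean displacement of the joint
#' scaled by the frame rate, i.e. units of length per second; it has
#' `F - 1` entries.
#'
#' @param seq an `rg_joint_seq`.
#' @param joint joint name.
#' @return numeric vector of length `F - 1`.
#' @export
joint_speed <- function(seq, joint) {
  j <- match(joint, dimnames(seq$positions)[[2]])
  if (is.na(j)) rg_stop(paste("unknown joint:", joint), "argument")
  p <- seq$positions[, j, , drop = FALSE]
  nf <- dim(p)[1]
  d <- matrix(p[-1, 1, ] - p[-nf, 1, ], nrow = nf - 1)
  sqrt(rowSums(d^2)) * seq$frame_rate
}

#' Speed autocorrelation profile
#'
#' Raw (uncentred) autocorrelation of a speed series:
#' `R(lag) = mean(v[i] * v[i + lag])` over the `n - lag` available products,
#' for lags `0 .. max_lag`. The profile of a periodic speed signal peaks at
#' lags equal to multiples of the locomotion period.
#'
#' @param speeds numeric speed series (length `n = F - 1`).
#' @param max_lag largest lag; must leave at least two products
#'   (`max_lag <= n - 2`).
#' @param source_joint optional joint name recorded in the result.
#' @return an object of class `rg_autocorr` with fields `coefficients`
#'   (length `max_lag + 1`, lag 0 first), `lags`, `source_joint`,
#'   `n_speed_samples`.
#' @export
speed_autocorrelation <- function(speeds, max_lag, source_joint = NA) {
  n <- length(speeds)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L || max_lag > n - 2L)
    rg_stop(sprintf("max_lag must be in [0, %d]", n - 2L), "argument")
  r <- vapply(0:max_lag, function(lag) {
    k <- n - lag
    sum(speeds[seq_len(k)] * speeds[seq_len(k) + lag]) / k
  }, numeric(1))
  structure(list(coefficients = r, lags = 0:max_lag,
                 source_joint = source_joint, n_speed_samples = n),
            class = "rg_autocorr")
}

#' Detect the locomotion period from an autocorrelation profile
#'
#' Finds local maxima of the profile at lags `>= min_lag` that exceed the
#' profile median (skipping the trivial lag-0 peak). Peak heights are
#' measured above the profile median and tapered by `(n - lag) / n` (the
#' biased-estimator weighting, which counters the variance inflation of the
#' unbiased `1/(F - 1 - lag)` normalization at long lags). Every peak lag
#' `q` is then scored by the mean tapered height found near its multiples
#' `q, 2q, 3q, ...` (zero where no peak lies within tolerance): the true
#' period attains the top score because all its multiples are strong,
#' harmonic sub-periods (e.g. from the rectified swing/stance structure of
#' joint speeds) are dragged down by their weak intermediate peaks, and
#' among near-ties (within 10%) the smallest lag wins so whole multiples of
#' the period are not preferred over the period itself.
#'
#' @param profile an `rg_autocorr`.
#' @param min_lag smallest admissible period in frames (default 5).
#' @return period in frames (integer).
#' @export
detect_period <- function(profile, min_lag = 5L) {
  r <- profile$coefficients
  lags <- profile$lags
  n <- length(r)
  if (n < 3L) rg_stop("profile too short for a local maximum", "no_periodicity")
  interior <- 2:(n - 1)
  is_peak <- r[interior] > r[interior - 1] & r[interior] >= r[interior + 1]
  cand <- interior[is_peak]
  cand <- cand[lags[cand] >= min_lag & r[cand] > stats::median(r)]
  if (!length(cand))
    rg_stop("no periodic peak in autocorrelation profile", "no_periodicity")
  nsamp <- profile$n_speed_samples
  peak_lag <- lags[cand]
  peak_adj <- (r[cand] - stats::median(r)) * (nsamp - peak_lag) / nsamp
  keep <- peak_adj > 0
  peak_lag <- peak_lag[keep]
  peak_adj <- peak_adj[keep]
  if (!length(peak_lag))
    rg_stop("no periodic peak in autocorrelation profile", "no_periodicity")
  max_lag <- lags[n]
  comb_score <- function(q) {
    ks <- seq_len(max(1L, floor(max_lag / q)))
    mean(vapply(ks, function(k) {
      tol <- max(2, 0.1 * k * q)
      hit <- abs(peak_lag - k * q) <= tol
      if (any(hit)) max(peak_adj[hit]) else 0
    }, numeric(1)))
  }
  scores <- vapply(peak_lag, comb_score, numeric(1))
  as.integer(min(peak_lag[scores >= 0.9 * max(scores)]))
}

#' Extract locomotion cycles from a sequence
#'
#' Detects the stride period from the reference joint's speed
#' autocorrelation, then cuts the pose sequence at successive speed minima
#' spaced approximately one period apart (speed minima of the ankle/toe
#' approximate ground contact). Trailing partial cycles are dropped.
#'
#' @param pose_seq the `rg_pose_seq` to segment.
#' @param raw_seq the matching `rg_joint_seq` (for joint speeds).
#' @param reference_joint joint driving segmentation, typically an ankle or
#'   toe.
#' @param min_period smallest admissible period in frames (default 5).
#' @param max_lag_fraction fraction of the speed series length used as the
#'   autocorrelation max lag (default 0.5).
#' @return an object of class `rg_cycle_set`: `cycles` (list of
#'   `rg_pose_seq`), `boundaries` (matrix of 0-based half-open frame ranges
#'   into the source), `detected_period` (frames).
#' @export
extract_cycles <- function(pose_seq, raw_seq, reference_joint,
                           min_period = 5L, max_lag_fraction = 0.5) {
  v <- joint_speed(raw_seq, reference_joint)
  n <- length(v)
  max_lag <- min(n - 2L, as.integer(floor(n * max_lag_fraction)))
  if (max_lag < min_period)
    rg_stop("sequence too short for period detection", "too_short")
  # light smoothing suppresses differentiated per-frame jitter, which
  # otherwise dominates the speed series (the autocorrelation's purpose is
  # robustness to such stochastic fluctuation, smoothing just helps it)
  vdet <- as.vector(stats::filter(v, rep(1 / 5, 5), sides = 2))
  vdet[is.na(vdet)] <- v[is.na(vdet)]
  prof <- speed_autocorrelation(vdet, max_lag, reference_joint)
  period <- detect_period(prof, min_lag = min_period)
  nf <- dim(pose_seq$dirs)[1]
  if (nf < 2L * period)
    rg_stop(sprintf(
      "sequence (%d frames) shorter than two periods (period %d)",
      nf, period), "too_short")
  # cut at speed minima (~ ground contact); work on a lightly smoothed
  # series so flat stance phases do not let the minima drift
  kw <- max(3L, as.integer(round(period / 8)))
  kern <- rep(1 / kw, kw)
  vs <- as.vector(stats::filter(v, kern, sides = 2))
  vs[is.na(vs)] <- v[is.na(vs)]
  loc_min <- which(diff(sign(diff(vs))) > 0) + 1L
  next_cut <- function(prev) {
    lo <- prev + as.integer(floor(0.8 * period))
    hi <- prev + as.integer(ceiling(1.2 * period))
    if (hi > n) return(NA_integer_)
    cand <- loc_min[loc_min >= lo & loc_min <= hi]
    if (length(cand)) cand[which.min(abs(cand - (prev + period)))]
    else (lo:hi)[which.min(vs[lo:hi])]
  }
  cuts <- which.min(vs[seq_len(period)])
  repeat {
    nc <- next_cut(cuts[length(cuts)])
    if (is.na(nc)) break
    cuts <- c(cuts, nc)
  }
  if (length(cuts) < 2L)
    rg_stop("could not place two cycle boundaries", "too_short")
  b0 <- cuts[-length(cuts)]
  b1 <- cuts[-1]
  len <- b1 - b0
  keep <- abs(len - period) <= 0.2 * period
  b0 <- b0[keep]; b1 <- b1[keep]
  if (!length(b0)) rg_stop("no complete cycle found", "too_short")
  cycles <- lapply(seq_along(b0), function(k) {
    ps <- pose_slice(pose_seq, b0[k]:(b1[k] - 1L))
    ps$sequence_id <- sprintf("%s#c%d", pose_seq$sequence_id, k)
    ps
  })
  structure(list(cycles = cycles,
                 boundaries = cbind(start = b0 - 1L, end = b1 - 1L),
                 detected_period = period),
            class = "rg_cycle_set")
}

#' @export
print.rg_cycle_set <- function(x, ...) {
  cat(sprintf("<rg_cycle_set> %d cycles, detected period %d frames\n",
              length(x$cycles), x$detected_period))
  invisible(x)
}

# Frame-to-frame cost between two pose sequences: summed per-bone geodesic
# distance. a, b: F x B x 3 arrays. Returns Fa x Fb matrix.
pose_cost_matrix <- function(a, b) {
  fa <- dim(a)[1]; fb <- dim(b)[1]; nb <- dim(a)[2]
  cost <- matrix(0, fa, fb)
  for (bn in seq_len(nb)) {
    dots <- clamp1(tcrossprod(matrix(a[, bn, ], fa), matrix(b[, bn, ], fb)))
    cost <- cost + acos(dots)
  }
  cost
}

# Classic DTW with steps (1,1), (1,0), (0,1); returns the warping path as a
# two-column matrix of (row, col) indices from (1,1) to (n, m).
dtw_path <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  acc <- matrix(Inf, n + 1, m + 1)
  acc[1, 1] <- 0
  for (i in seq_len(n))
    for (j in seq_len(m))
      acc[i + 1, j + 1] <- cost[i, j] +
        min(acc[i, j], acc[i, j + 1], acc[i + 1, j])
  i <- n; j <- m
  path <- list(c(n, m))
  while (i > 1 || j > 1) {
    opts <- c(if (i > 1 && j > 1) acc[i, j] else Inf,
              if (i > 1) acc[i, j + 1] else Inf,
              if (j > 1) acc[i + 1, j] else Inf)
    mv <- which.min(opts)
    if (mv == 1) { i <- i - 1; j <- j - 1 }
    else if (mv == 2) i <- i - 1
    else j <- j - 1
    path[[length(path) + 1L]] <- c(i, j)
  }
  do.call(rbind, rev(path))
}

# Replace runs of duplicated frames (introduced by warping) with geodesic
# interpolation between the nearest distinct anchor frames, per bone.
repair_duplicates <- function(dirs) {
  nf <- dim(dirs)[1]; nb <- dim(dirs)[2]
  same <- vapply(2:nf, function(f)
    max(abs(dirs[f, , ] - dirs[f - 1, , ])) < 1e-12, logical(1))
  if (!any(same)) return(dirs)
  anchors <- c(1L, which(!same) + 1L)       # first frame of each distinct run
  if (length(anchors) < 2L) return(dirs)    # fully constant input: leave as is
  # place anchors at run starts; ensure last frame is an anchor position
  pos <- anchors
  vals <- anchors
  if (pos[length(pos)] != nf) {
    pos[length(pos)] <- nf                  # stretch final run to the end
  }
  out <- array(NA_real_, dim(dirs))
  out[1, , ] <- dirs[1, , ]
  for (k in seq_len(length(pos) - 1L)) {
    a <- pos[k]; b <- pos[k + 1L]
    out[a, , ] <- dirs[vals[k], , ]
    out[b, , ] <- dirs[vals[k + 1L], , ]
    gap <- b - a - 1L
    if (gap > 0L)
      for (bn in seq_len(nb))
        out[(a + 1):(b - 1), bn, ] <- geodesic_interpolate(
          dirs[vals[k], bn, ], dirs[vals[k + 1L], bn, ], gap)
  }
  out
}

#' Align locomotion cycles to a common length on the manifold
#'
#' Implements the alignment stage: cycles are uniformly resampled to pick a
#' medoid reference (smallest summed per-frame, per-bone geodesic distance to
#' the others), each cycle is warped onto the reference by dynamic time
#' warping with frame cost equal to the summed bone geodesic distances,
#' frames duplicated by the warp are repaired by geodesic interpolation (to
#' keep the trajectory continuous and smooth), and the result is uniformly
#' resampled on the manifold to exactly `target_F` frames.
#'
#' @param cycles list of `rg_pose_seq`, each at least 4 frames.
#' @param target_F common output length (default 150 frames).
#' @return list of `rg_pose_seq`, each exactly `target_F` frames.
#' @export
align_cycles <- function(cycles, target_F = 150L) {
  if (!length(cycles)) rg_stop("no cycles to align", "argument")
  if (any(vapply(cycles, function(c) dim(c$dirs)[1], numeric(1)) < 4))
    rg_stop("every cycle must have at least 4 frames", "argument")
  target_F <- as.integer(target_F)
  res <- lapply(cycles, resample_pose_sequence, target_F = target_F)
  n <- length(res)
  ref_idx <- 1L
  if (n > 1L) {
    framewise_dist <- function(a, b) {
      ab <- a * b
      sum(acos(clamp1(ab[, , 1] + ab[, , 2] + ab[, , 3])))
    }
    dsum <- numeric(n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- framewise_dist(res[[i]]$dirs, res[[j]]$dirs)
      dsum[i] <- dsum[i] + d
      dsum[j] <- dsum[j] + d
    }
    ref_idx <- which.min(dsum)
  }
  ref <- res[[ref_idx]]$dirs
  lapply(seq_len(n), function(i) {
    cyc <- cycles[[i]]
    path <- dtw_path(pose_cost_matrix(cyc$dirs, ref))
    if (!nrow(path)) rg_stop("degenerate warping path", "alignment")
    # one source frame per reference frame: last match along the path
    src <- integer(target_F)
    for (r in seq_len(nrow(path))) src[path[r, 2]] <- path[r, 1]
    warped <- cyc$dirs[src, , , drop = FALSE]
    warped <- repair_duplicates(warped)
    out <- pose_sequence(warped, cyc$frame_rate, cyc$subject_label,
                         cyc$sequence_id)
    resample_pose_sequence(out, target_F)
  })
}
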