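# Shared fixtures and independent oracles used across the test files.

# n random unit vectors, optionally confined near a pole (open hemisphere)
rand_sphere <- function(n, hemisphere = FALSE) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m <- m / sqrt(rowSums(m^2))
  if (hemisphere) m[, 3] <- abs(m[, 3]) + 0.3
  m / sqrt(rowSums(m^2))
}

# Brute-force Karcher mean oracle: coarse grid over S2, then Nelder-Mead
# refinement in spherical coordinates. Independent of the package iteration.
brute_karcher <- function(points) {
  obj <- function(ang) {
    m <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
    sum(acos(pmin(1, pmax(-1, points %*% m)))^2)
  }
  grid <- expand.grid(theta = seq(0.01, pi - 0.01, length.out = 60),
                      phi = seq(-pi, pi, length.out = 120))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  a <- opt$par
  c(sin(a[1]) * cos(a[2]), sin(a[1]) * sin(a[2]), cos(a[1]))
}

# Textbook two-pass covariance oracle
two_pass_cov <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  S <- matrix(0, ncol(X), ncol(X))
  for (i in seq_len(n)) S <- S + tcrossprod(X[i, ] - mu)
  S / (n - 1)
}

# A 3-joint chain skeleton for small I/O tests
chain_skeleton <- function() {
  skeleton_definition(c("root", "mid", "tip"), c(NA, 1, 2))
}

# Small deterministic walking dataset: cycles already extracted and aligned.
# Cached per (seed, n_subjects, per_subject) within a test run.
local({
  cache <- new.env(parent = emptyenv())
  make_aligned_dataset <<- function(seed = 1, n_subjects = 4,
                                    per_subject = 6, skeleton = "mid9",
                                    frames_per_cycle = 40, target_F = 40,
                                    ...) {
    key <- paste(seed, n_subjects, per_subject, skeleton,
                 frames_per_cycle, target_F, ...)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- gait_sim_config(n_subjects = n_subjects,
                           cycles_per_subject = per_subject,
                           frames_per_cycle = frames_per_cycle,
                           skeleton = skeleton, seed = seed, ...)
    ds <- generate_dataset(cfg)
    cycles <- lapply(seq_along(ds$sequences), function(i) {
      sq <- ds$sequences[[i]]
      extract_cycles(to_pose_sequence(sq, ds$skeleton), sq,
                     "lankle")$cycles[[1]]
    })
    out <- list(aligned = align_cycles(cycles, target_F),
                labels = ds$labels, dataset = ds)
    cache[[key]] <- out
    out
  }
})

expect_unit_dirs <- function(ps, tol = 1e-9) {
  nrm <- sqrt(apply(ps$dirs^2, c(1, 2), sum))
  expect_lt(max(abs(nrm - 1)), tol)
}
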