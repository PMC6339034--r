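# mean motion sequence, geodesic features, covariance hierarchy

random_pose_set <- function(S, F_, B, seed = 1, spread = 0.15) {
  set.seed(seed)
  base <- rand_sphere(F_ * B, hemisphere = TRUE)
  lapply(seq_len(S), function(s) {
    dirs <- array(NA_real_, c(F_, B, 3))
    k <- 0
    for (f in seq_len(F_)) for (b in seq_len(B)) {
      k <- k + 1
      t <- rnorm(3); bb <- base[k, ]
      t <- t - sum(t * bb) * bb
      t <- t / sqrt(sum(t^2)) * runif(1, 0, spread)
      dirs[f, b, ] <- sphere_exp(bb, t)
    }
    pose_sequence(dirs, 30, sprintf("s%d", s), sprintf("seq%d", s))
  })
}

test_that("compute_mean_sequence reduces to exact cases", {
  one <- random_pose_set(1, 4, 3, seed = 5)
  ms <- compute_mean_sequence(one)
  expect_equal(ms$mean_poses, one[[1]]$dirs, tolerance = 1e-12)
  # mirror-symmetric pair about the pole -> pole everywhere
  F_ <- 3; B <- 2
  a <- array(NA_real_, c(F_, B, 3)); b <- a
  set.seed(6)
  for (f in 1:F_) for (bn in 1:B) {
    v <- c(rnorm(2) * 0.3, 0)
    a[f, bn, ] <- sphere_exp(c(0, 0, 1), v)
    b[f, bn, ] <- sphere_exp(c(0, 0, 1), -v)
  }
  ms2 <- compute_mean_sequence(list(pose_sequence(a), pose_sequence(b)))
  expect_lt(max(abs(ms2$mean_poses[, , 1:2])), 1e-6)
  expect_error(compute_mean_sequence(list(pose_sequence(a),
                                          pose_sequence(a[1:2, , , drop = FALSE]))),
               class = "riemgait_error_argument")
})

test_that("compute_mean_sequence matches the per-entry brute-force oracle", {
  cycles <- random_pose_set(3, 10, 4, seed = 9)
  ms <- compute_mean_sequence(cycles)
  set.seed(10)
  for (probe in 1:6) {            # spot-check random (frame, bone) entries
    f <- sample(10, 1); b <- sample(4, 1)
    pts <- t(sapply(cycles, function(cy) cy$dirs[f, b, ]))
    expect_lt(geodesic_distance(ms$mean_poses[f, b, ], brute_karcher(pts)),
              2e-3)
  }
})

test_that("geometric_features computes geodesic distances to the mean", {
  cycles <- random_pose_set(2, 6, 3, seed = 12)
  ms <- compute_mean_sequence(cycles)
  self <- geometric_features(
    structure(list(dirs = ms$mean_poses), class = "rg_pose_seq"), ms)
  expect_equal(self$G, matrix(0, 6, 3), tolerance = 1e-7)
  g <- geometric_features(cycles[[1]], ms)
  for (f in 1:6) for (b in 1:3)
    expect_lt(abs(g$G[f, b] -
                    acos(sum(cycles[[1]]$dirs[f, b, ] * ms$mean_poses[f, b, ]))),
              1e-9)
  # antipodal entry
  flipped <- cycles[[1]]$dirs
  flipped[2, 1, ] <- -ms$mean_poses[2, 1, ]
  g2 <- geometric_features(pose_sequence(flipped), ms)
  expect_equal(g2$G[2, 1], pi)
  expect_equal(flatten_features(g), as.vector(t(g$G)))
})

test_that("covariance_window equals the unbiased sample covariance", {
  expect_equal(covariance_window(matrix(c(0, 2), 2, 1), 0, 2)[1, 1], 2.0)
  Gc <- matrix(1.3, 10, 4)
  expect_equal(covariance_window(Gc, 2, 8), matrix(0, 4, 4))
  set.seed(14)
  G <- matrix(runif(20 * 5, 0, pi), 20, 5)
  expect_lt(max(abs(covariance_window(G, 0, 20) - two_pass_cov(G))), 1e-10)
  expect_lt(max(abs(covariance_window(G, 3, 11) -
                      two_pass_cov(G[4:11, ]))), 1e-10)
  expect_error(covariance_window(G, 4, 5),
               class = "riemgait_error_window_too_small")
})

test_that("temporal_hierarchy builds the documented window schemes", {
  set.seed(15)
  G <- matrix(runif(150 * 3, 0, pi), 150, 3)
  d <- temporal_hierarchy(G)                         # figure scheme
  expect_equal(nrow(d$windows), 8L)
  expect_equal(d$windows[1, ], c(start = 0L, end = 150L))
  starts <- floor((0:6) * (150 - 37) / 6)
  expect_equal(d$windows[-1, "start"], as.integer(starts),
               ignore_attr = TRUE)
  expect_true(all(d$windows[-1, "end"] - d$windows[-1, "start"] == 37L))
  expect_length(d$flattened, 8 * 3 * 4 / 2)
  # second-level windows jointly cover [0, F)
  covered <- rep(FALSE, 150)
  for (k in 2:8) covered[(d$windows[k, 1] + 1):d$windows[k, 2]] <- TRUE
  expect_true(all(covered))
  d2 <- temporal_hierarchy(G, scheme = "paper_dim")
  expect_equal(nrow(d2$windows), 7L)
  expect_length(d2$flattened, 7 * 3 * 4 / 2)         # printed dimension
  for (M in c(d$matrices, d2$matrices)) {
    expect_lt(max(abs(M - t(M))), 1e-10)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
  expect_error(temporal_hierarchy(G[1:6, ]), class = "riemgait_error_argument")
})

test_that("descriptors are blind to per-subject bone lengths", {
  cfg_a <- gait_sim_config(n_subjects = 2, cycles_per_subject = 1,
                           between_subject_spread = 0,
                           within_subject_noise = 0,
                           bone_length_spread = 0.2, skeleton = "toy6",
                           seed = 33)
  styles <- sample_subjects(cfg_a)
  expect_false(isTRUE(all.equal(styles[[1]]$lengths, styles[[2]]$lengths)))
  sk <- default_skeleton("toy6")
  # same angle dynamics + same trial seed, different bone lengths
  s1 <- simulate_sequence(styles[[1]], 2, cfg_a, seed = 5)
  s2 <- simulate_sequence(styles[[2]], 2, cfg_a, seed = 5)
  p1 <- to_pose_sequence(s1, sk)
  p2 <- to_pose_sequence(s2, sk)
  expect_equal(p1$dirs, p2$dirs, tolerance = 1e-10)
  # reference mean from a different trial so G is far from the acos() branch
  # point at zero distance
  ref <- to_pose_sequence(simulate_sequence(styles[[1]], 2, cfg_a, seed = 8),
                          sk)
  ms <- compute_mean_sequence(list(ref))
  g1 <- geometric_features(p1, ms)
  g2 <- geometric_features(p2, ms)
  expect_equal(g1$G, g2$G, tolerance = 1e-10)
  expect_equal(temporal_hierarchy(g1$G, window_length = 20)$flattened,
               temporal_hierarchy(g2$G, window_length = 20)$flattened,
               tolerance = 1e-10)
})
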