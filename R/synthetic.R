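# Synthetic locomotion generator: subject-specific joint-angle oscillations
# driven through a forward-kinematic chain, so every pipeline stage can be
# exercised on data with known ground truth (period, identity signal).

rot3 <- function(axis, a) {
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

# Template: joints, tree, rest offsets (y-up, z-forward, x-left), per-joint
# rotation axis and oscillation parameters (radians). Amplitudes roughly
# follow sagittal gait kinematics: hips ~0.5 rad, knees ~0.6 rad with a
# strong second harmonic, ankles ~0.3 rad, arms counter-swinging.
skeleton_template <- function(name = c("cmu19", "mid9", "toy6")) {
  name <- match.arg(name)
  row <- function(joint, parent, off, len, axis, mean, amp, phase,
                  h_amp, h_phase)
    data.frame(joint = joint, parent = parent,
               ox = off[1], oy = off[2], oz = off[3], len = len,
               axis = axis, mean = mean, amp = amp, phase = phase,
               h_amp = h_amp, h_phase = h_phase,
               stringsAsFactors = FALSE)
  legs <- function(parent_l, parent_r) rbind(
    row("lhip", parent_l, c(0.12, -0.03, 0), 0.12, "x", 0.0, 0.50, 0,
        0.15, pi / 2),
    row("lknee", "lhip", c(0, -1, 0), 0.45, "x", 0.25, 0.60, -pi / 2,
        0.18, 0.0),
    row("lankle", "lknee", c(0, -1, 0), 0.45, "x", -0.10, 0.30, pi / 4,
        0.10, 0.6),
    row("rhip", parent_r, c(-0.12, -0.03, 0), 0.12, "x", 0.0, 0.50, pi,
        0.15, pi / 2 + pi),
    row("rknee", "rhip", c(0, -1, 0), 0.45, "x", 0.25, 0.60, pi / 2,
        0.18, 0.0),
    row("rankle", "rknee", c(0, -1, 0), 0.45, "x", -0.10, 0.30,
        pi + pi / 4, 0.10, 0.6 + pi))
  tpl <- switch(name,
    toy6 = rbind(
      row("root", NA, c(0, 1, 0), 1.0, "x", 0, 0.03, 0, 0.02, 0),
      legs("root", "root")[1:5, ]),
    mid9 = rbind(
      row("root", NA, c(0, 1, 0), 1.0, "x", 0, 0.03, 0, 0.02, 0),
      row("spine", "root", c(0, 1, 0), 0.35, "x", 0, 0.05, pi, 0.03, 0),
      row("head", "spine", c(0, 1, 0), 0.25, "x", 0, 0.04, 0, 0.02, 0),
      legs("root", "root")),
    cmu19 = rbind(
      row("root", NA, c(0, 1, 0), 1.0, "x", 0, 0.03, 0, 0.02, 0),
      row("spine", "root", c(0, 1, 0), 0.20, "x", 0, 0.05, pi, 0.03, 0),
      row("chest", "spine", c(0, 1, 0), 0.20, "x", 0, 0.04, pi, 0.02, 0),
      row("neck", "chest", c(0, 1, 0), 0.15, "x", 0, 0.03, 0, 0.02, 0),
      row("head", "neck", c(0, 1, 0), 0.15, "x", 0, 0.03, 0, 0.02, 0),
      row("lshoulder", "chest", c(1, 0, 0), 0.20, "x", 0, 0.35, pi,
          0.06, 0.2),
      row("lelbow", "lshoulder", c(0, -1, 0), 0.30, "x", 0.30, 0.25, pi,
          0.05, 0.0),
      row("lwrist", "lelbow", c(0, -1, 0), 0.25, "x", 0.10, 0.15, pi,
          0.04, 0.0),
      row("rshoulder", "chest", c(-1, 0, 0), 0.20, "x", 0, 0.35, 0,
          0.06, 0.2 + pi),
      row("relbow", "rshoulder", c(0, -1, 0), 0.30, "x", 0.30, 0.25, 0,
          0.05, pi),
      row("rwrist", "relbow", c(0, -1, 0), 0.25, "x", 0.10, 0.15, 0,
          0.04, pi),
      legs("root", "root"),
      row("ltoe", "lankle", c(0, -0.3, 1), 0.15, "x", 0.0, 0.20,
          pi / 2, 0.08, 0.0),
      row("rtoe", "rankle", c(0, -0.3, 1), 0.15, "x", 0.0, 0.20,
          pi + pi / 2, 0.08, pi)))
  # normalize offset directions
  nrm <- sqrt(tpl$ox^2 + tpl$oy^2 + tpl$oz^2)
  tpl$ox <- tpl$ox / nrm; tpl$oy <- tpl$oy / nrm; tpl$oz <- tpl$oz / nrm
  tpl
}

#' Built-in generator skeletons
#'
#' `"cmu19"` is a 19-joint/18-bone full-body skeleton at the scale of
#' optical mocap databases; `"mid9"` (9 joints) and `"toy6"` (6 joints) are
#' reduced legs-plus-torso skeletons for fast tests. The ankle reference
#' joint for cycle extraction is `"lankle"` in all of them.
#'
#' @param name skeleton name.
#' @return an `rg_skeleton`.
#' @export
default_skeleton <- function(name = "cmu19") {
  tpl <- skeleton_template(name)
  skeleton_definition(tpl$joint, match(tpl$parent, tpl$joint))
}

#' Synthetic gait simulation configuration
#'
#' The stated world of the generator: per-subject oscillation styles around
#' a shared gait template, rigid forward-kinematic chains, and per-frame
#' angle jitter within subjects.
#'
#' @param n_subjects number of individuals (default 7, the scale of a small
#'   mocap identification study).
#' @param cycles_per_subject sequences (= one retained gait cycle each) per
#'   subject (default 20).
#' @param frames_per_cycle nominal stride period in frames (default 40).
#' @param frame_rate frames per second (default 40, one stride per second).
#' @param between_subject_spread dispersion of style parameters around the
#'   template; 0 makes all subjects' angle dynamics identical (default 1).
#' @param within_subject_noise per-frame joint-angle jitter, radians
#'   (default 0.02).
#' @param bone_length_spread log-normal dispersion of per-subject bone
#'   lengths, independent of the angle styles (default 0.05).
#' @param periods_per_sequence strides simulated per sequence (default 4,
#'   enough for robust period detection).
#' @param skeleton generator skeleton name (see [default_skeleton()]).
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated config list of class `rg_sim_config`.
#' @export
gait_sim_config <- function(n_subjects = 7L, cycles_per_subject = 20L,
                            frames_per_cycle = 40L, frame_rate = 40,
                            between_subject_spread = 1,
                            within_subject_noise = 0.02,
                            bone_length_spread = 0.05,
                            periods_per_sequence = 4L,
                            skeleton = "cmu19", seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              cycles_per_subject = as.integer(cycles_per_subject),
              frames_per_cycle = as.integer(frames_per_cycle),
              frame_rate = frame_rate,
              between_subject_spread = between_subject_spread,
              within_subject_noise = within_subject_noise,
              bone_length_spread = bone_length_spread,
              periods_per_sequence = as.integer(periods_per_sequence),
              skeleton = skeleton, seed = as.integer(seed))
  counts <- c(cfg$n_subjects, cfg$cycles_per_subject, cfg$frames_per_cycle,
              cfg$periods_per_sequence)
  if (any(counts < 1L)) rg_stop("all counts must be >= 1", "argument")
  if (cfg$frames_per_cycle < 10L)
    rg_stop("frames_per_cycle must be >= 10", "argument")
  if (cfg$within_subject_noise < 0 || cfg$between_subject_spread < 0 ||
      cfg$bone_length_spread < 0)
    rg_stop("spreads and noise must be >= 0", "argument")
  if (cfg$frame_rate <= 0) rg_stop("frame_rate must be positive", "argument")
  skeleton_template(cfg$skeleton)   # validates the name
  structure(cfg, class = "rg_sim_config")
}

#' Draw subject-specific gait styles
#'
#' Each subject's style perturbs the template: amplitude and second-harmonic
#' multipliers (log-normal), phase shifts and posture offsets (normal), a
#' stride-period factor, and per-bone length multipliers. All dispersions
#' except bone length scale with `between_subject_spread`, so spread 0 gives
#' identical angle dynamics across subjects. Deterministic given the config
#' seed.
#'
#' @param config an `rg_sim_config`.
#' @return list of style lists (class `rg_subject_style`).
#' @export
sample_subjects <- function(config) {
  tpl <- skeleton_template(config$skeleton)
  nj <- nrow(tpl)
  sp <- config$between_subject_spread
  with_seed(derive_seed(config$seed, 1L), {
    lapply(seq_len(config$n_subjects), function(s) {
      period <- max(10L, as.integer(round(
        config$frames_per_cycle *
          min(1.4, max(0.7, 1 + 0.10 * sp * stats::rnorm(1))))))
      structure(list(
        subject_id = sprintf("subj%02d", s),
        amp = tpl$amp * exp(0.30 * sp * stats::rnorm(nj)),
        phase = tpl$phase + 0.25 * sp * stats::rnorm(nj),
        mean = tpl$mean + 0.10 * sp * stats::rnorm(nj),
        h_amp = tpl$h_amp * exp(0.50 * sp * stats::rnorm(nj)),
        h_phase = tpl$h_phase + 0.50 * sp * stats::rnorm(nj),
        period = period,
        lengths = tpl$len * exp(config$bone_length_spread *
                                  stats::rnorm(nj))),
        class = "rg_subject_style")
    })
  })
}

# Forward kinematics: theta is F x J (radians); returns F x J x 3 positions.
fk_positions <- function(tpl, lengths, theta, root_path) {
  nf <- nrow(theta); nj <- nrow(tpl)
  parent <- match(tpl$parent, tpl$joint)
  offs <- cbind(tpl$ox, tpl$oy, tpl$oz) * lengths
  pos <- array(0, c(nf, nj, 3))
  for (f in seq_len(nf)) {
    grot <- vector("list", nj)
    for (j in seq_len(nj)) {
      rloc <- rot3(tpl$axis[j], theta[f, j])
      p <- parent[j]
      if (is.na(p)) {
        pos[f, j, ] <- root_path[f, ] + offs[j, ]
        grot[[j]] <- rloc
      } else {
        pos[f, j, ] <- pos[f, p, ] + as.vector(grot[[p]] %*% offs[j, ])
        grot[[j]] <- grot[[p]] %*% rloc
      }
    }
  }
  pos
}

#' Simulate one locomotion sequence for a subject style
#'
#' Joint angles follow `mean + amp * sin(2*pi*t/T + phase) +
#' h_amp * sin(4*pi*t/T + h_phase) + noise` with the style's stride period
#' `T`, driven through the rigid forward-kinematic chain; the root
#' translates forward at constant speed with a small double-frequency
#' vertical bob. A random trial phase makes repeated trials of one subject
#' distinct. Bit-identical for identical `(style, config, seed)`.
#'
#' @param style an `rg_subject_style`.
#' @param n_cycles strides to simulate.
#' @param config the `rg_sim_config`.
#' @param seed per-sequence seed (trial phase + noise stream).
#' @param sequence_id sequence name.
#' @return an `rg_joint_seq` of `n_cycles * frames_per_cycle` frames.
#' @export
simulate_sequence <- function(style, n_cycles, config, seed = 1L,
                              sequence_id = "sim") {
  tpl <- skeleton_template(config$skeleton)
  nj <- nrow(tpl)
  nf <- as.integer(n_cycles) * config$frames_per_cycle
  T_ <- style$period
  with_seed(seed, {
    t0 <- stats::runif(1, 0, T_)
    tt <- (0:(nf - 1)) + t0
    theta <- matrix(NA_real_, nf, nj)
    for (j in seq_len(nj))
      theta[, j] <- style$mean[j] +
        style$amp[j] * sin(2 * pi * tt / T_ + style$phase[j]) +
        style$h_amp[j] * sin(4 * pi * tt / T_ + style$h_phase[j])
    if (config$within_subject_noise > 0)
      theta <- theta + matrix(
        stats::rnorm(nf * nj, sd = config$within_subject_noise), nf, nj)
    root_path <- cbind(0,
                       0.02 * sin(4 * pi * tt / T_),
                       0.03 * (0:(nf - 1)))
    pos <- fk_positions(tpl, style$lengths, theta, root_path)
    sk <- default_skeleton(config$skeleton)
    joint_sequence(pos, sk, config$frame_rate, style$subject_id, sequence_id)
  })
}

#' Generate a labelled synthetic gait dataset
#'
#' `n_subjects * cycles_per_subject` sequences, each
#' `periods_per_sequence` strides long, with per-sequence seeds derived
#' deterministically from the config seed.
#'
#' @param config an `rg_sim_config`.
#' @return list with `sequences` (list of `rg_joint_seq`), `labels`
#'   (character), `skeleton` (`rg_skeleton`), `styles`, `config`.
#' @export
generate_dataset <- function(config) {
  styles <- sample_subjects(config)
  sequences <- list()
  labels <- character(0)
  for (s in seq_len(config$n_subjects)) {
    for (k in seq_len(config$cycles_per_subject)) {
      sid <- sprintf("%s_t%03d", styles[[s]]$subject_id, k)
      sq <- simulate_sequence(styles[[s]], config$periods_per_sequence,
                              config, derive_seed(config$seed, s * 1000L + k),
                              sid)
      sequences[[length(sequences) + 1L]] <- sq
      labels <- c(labels, styles[[s]]$subject_id)
    }
  }
  list(sequences = sequences, labels = labels,
       skeleton = default_skeleton(config$skeleton),
       styles = styles, config = config)
}
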