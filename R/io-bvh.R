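# Minimal BVH reader: HIERARCHY/MOTION, position/rotation Euler channels only.
#
# Conventions: right-handed, y-up; rotations are in degrees and applied in the
# channel order listed for each joint; a child's OFFSET is rotated by its
# parent's accumulated (global) rotation. End Sites become leaf joints named
# "<parent>_end". Anything outside this subset raises an error rather than
# guessing.

rot_axis <- function(axis, deg) {
  a <- deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    X = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    Y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    Z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

bvh_tokens <- function(path) {
  txt <- readLines(path, warn = FALSE)
  toks <- unlist(strsplit(paste(txt, collapse = "\n"), "[ \t\r\n]+"))
  toks[nzchar(toks)]
}

#' Read a BVH motion-capture file
#'
#' Parses the supported BVH subset (see Details) and runs forward kinematics
#' over the per-frame Euler rotations to produce world joint positions.
#'
#' @details Channels must be among `Xposition`/`Yposition`/`Zposition` and
#' `Xrotation`/`Yrotation`/`Zrotation`; rotations are applied in the order the
#' channels are listed. With all rotations zero, each joint's position is the
#' cumulative sum of OFFSETs (plus root translation). The frame rate is
#' `1 / Frame Time`.
#'
#' @param path BVH file path.
#' @param subject_label,sequence_id metadata attached to the returned
#'   sequence (BVH itself carries none).
#' @return a list with elements `skeleton` (`rg_skeleton`) and
#'   `sequence` (`rg_joint_seq`).
#' @export
read_bvh <- function(path, subject_label = "unknown",
                     sequence_id = NULL) {
  if (!file.exists(path)) rg_stop(paste("no such file:", path), "io")
  toks <- bvh_tokens(path)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[i] else NA_character_
  nxt <- function() {
    if (i > length(toks)) rg_stop("unexpected end of BVH file", "format")
    t <- toks[i]; i <<- i + 1L; t
  }
  expect <- function(what) {
    t <- nxt()
    if (!identical(t, what))
      rg_stop(sprintf("expected '%s', got '%s'", what, t), "format")
  }
  num <- function() {
    v <- suppressWarnings(as.numeric(nxt()))
    if (is.na(v)) rg_stop("expected a number in BVH", "format")
    v
  }

  joints <- character()
  parents <- integer()
  offsets <- list()
  channels <- list()   # per joint: character vector (possibly empty)

  allowed <- c("Xposition", "Yposition", "Zposition",
               "Xrotation", "Yrotation", "Zrotation")

  parse_joint <- function(parent, name) {
    joints[[length(joints) + 1L]] <<- name
    parents[[length(parents) + 1L]] <<- parent
    id <- length(joints)
    expect("{")
    expect("OFFSET")
    offsets[[id]] <<- c(num(), num(), num())
    channels[[id]] <<- character()
    if (identical(peek(), "CHANNELS")) {
      nxt()
      nch <- num()
      ch <- vapply(seq_len(nch), function(k) nxt(), character(1))
      bad <- setdiff(ch, allowed)
      if (length(bad))
        rg_stop(paste("unsupported channel:", bad[1]), "unsupported")
      channels[[id]] <<- ch
    }
    repeat {
      t <- peek()
      if (identical(t, "JOINT")) {
        nxt(); parse_joint(id, nxt())
      } else if (identical(t, "End")) {
        nxt(); expect("Site")
        joints[[length(joints) + 1L]] <<- paste0(name, "_end")
        parents[[length(parents) + 1L]] <<- id
        eid <- length(joints)
        expect("{"); expect("OFFSET")
        offsets[[eid]] <<- c(num(), num(), num())
        channels[[eid]] <<- character()
        expect("}")
      } else if (identical(t, "}")) {
        nxt(); break
      } else {
        rg_stop(paste("unexpected token in HIERARCHY:", t), "format")
      }
    }
  }

  expect("HIERARCHY")
  expect("ROOT")
  parse_joint(NA_integer_, nxt())
  expect("MOTION")
  expect("Frames:")
  nframes <- num()
  expect("Frame")
  expect("Time:")
  ft <- num()
  if (ft <= 0) rg_stop("Frame Time must be positive", "format")
  nchan_total <- sum(lengths(channels))
  vals <- suppressWarnings(as.numeric(toks[i:length(toks)]))
  if (length(toks) < i || anyNA(vals))
    rg_stop("non-numeric data in MOTION section", "format")
  if (length(vals) != nframes * nchan_total)
    rg_stop(sprintf(
      "MOTION has %d values; header implies %d (%d frames x %d channels)",
      length(vals), nframes * nchan_total, nframes, nchan_total), "format")
  motion <- matrix(vals, nrow = nframes, byrow = TRUE)

  nj <- length(joints)
  chan_start <- cumsum(c(0L, lengths(channels)))[seq_len(nj)]
  pos <- array(0, c(nframes, nj, 3))
  for (f in seq_len(nframes)) {
    gpos <- matrix(0, nj, 3)
    grot <- vector("list", nj)
    for (j in seq_len(nj)) {
      ch <- channels[[j]]
      trans <- c(0, 0, 0)
      rloc <- diag(3)
      if (length(ch)) {
        v <- motion[f, (chan_start[j] + 1):(chan_start[j] + length(ch))]
        for (k in seq_along(ch)) {
          cn <- ch[k]
          ax <- substr(cn, 1, 1)
          if (grepl("position$", cn)) {
            trans[match(ax, c("X", "Y", "Z"))] <- v[k]
          } else {
            rloc <- rloc %*% rot_axis(ax, v[k])
          }
        }
      }
      p <- parents[j]
      if (is.na(p)) {
        gpos[j, ] <- offsets[[j]] + trans
        grot[[j]] <- rloc
      } else {
        gpos[j, ] <- gpos[p, ] + as.vector(grot[[p]] %*% offsets[[j]])
        grot[[j]] <- grot[[p]] %*% rloc
      }
    }
    pos[f, , ] <- gpos
  }

  sk <- skeleton_definition(joints, parents)
  sq <- joint_sequence(pos, sk, 1 / ft, subject_label,
                       sequence_id %||% sub("\\.bvh$", "", basename(path)))
  list(skeleton = sk, sequence = sq)
}
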