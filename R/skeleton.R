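# Skeleton definitions and joint-trajectory containers.

#' Define a skeleton as a rooted kinematic tree
#'
#' A skeleton is an ordered set of named joints with a parent index per joint;
#' the single root has parent `NA`. Bones are the (parent, child) pairs along
#' the tree, ordered by child joint, so a `J`-joint skeleton has `J - 1` bones.
#'
#' @param joint_names character vector of unique joint identifiers.
#' @param parent_index integer vector, same length; `parent_index[j]` is the
#'   index of joint `j`'s parent, `NA` for the root.
#' @return An object of class `rg_skeleton` with elements `joints`, `parents`
#'   and `bones` (a `(J-1) x 2` integer matrix of parent/child joint indices).
#' @examples
#' sk <- skeleton_definition(c("root", "hip", "knee"), c(NA, 1, 2))
#' sk$bones
#' @export
skeleton_definition <- function(joint_names, parent_index) {
  joint_names <- as.character(joint_names)
  parent_index <- as.integer(parent_index)
  n <- length(joint_names)
  if (n < 2L) rg_stop("skeleton needs at least two joints", "argument")
  if (length(parent_index) != n)
    rg_stop("parent_index length must match joint_names", "argument")
  if (anyDuplicated(joint_names))
    rg_stop("duplicate joint names", "argument")
  roots <- which(is.na(parent_index))
  if (length(roots) != 1L)
    rg_stop(sprintf("skeleton must have exactly one root, found %d",
                    length(roots)), "argument")
  ok <- is.na(parent_index) | (parent_index >= 1L & parent_index <= n)
  if (!all(ok)) rg_stop("parent index out of range", "argument")
  # every non-root joint must reach the root without cycles
  for (j in seq_len(n)) {
    seen <- logical(n)
    cur <- j
    while (!is.na(parent_index[cur])) {
      if (seen[cur]) rg_stop("parent links contain a cycle", "argument")
      seen[cur] <- TRUE
      cur <- parent_index[cur]
    }
    if (cur != roots) rg_stop("joint not reachable from root", "argument")
  }
  children <- which(!is.na(parent_index))
  bones <- cbind(parent = parent_index[children], child = children)
  structure(
    list(joints = joint_names, parents = parent_index, bones = bones),
    class = "rg_skeleton"
  )
}

#' @export
print.rg_skeleton <- function(x, ...) {
  cat(sprintf("<rg_skeleton> %d joints, %d bones; root: %s\n",
              length(x$joints), nrow(x$bones),
              x$joints[is.na(x$parents)]))
  invisible(x)
}

#' Names of the bones of a skeleton
#'
#' Bone `b` is named `<parent>.<child>`.
#' @param skeleton an `rg_skeleton`.
#' @return character vector of length `J - 1`.
#' @export
bone_names <- function(skeleton) {
  paste(skeleton$joints[skeleton$bones[, 1]],
        skeleton$joints[skeleton$bones[, 2]], sep = ".")
}

#' Construct a joint-trajectory sequence
#'
#' Wraps an `F x J x 3` array of joint positions with its acquisition
#' metadata after validation against a skeleton.
#'
#' @param positions numeric array `F x J x 3` (any consistent length unit).
#' @param skeleton the `rg_skeleton` the columns refer to.
#' @param frame_rate frames per second, positive.
#' @param subject_label class label of the individual (coerced to character).
#' @param sequence_id unique sequence name.
#' @return An object of class `rg_joint_seq`.
#' @export
joint_sequence <- function(positions, skeleton, frame_rate,
                           subject_label = "unknown",
                           sequence_id = "seq") {
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L)
    rg_stop("positions must be an F x J x 3 array", "argument")
  if (dim(positions)[1] < 2L)
    rg_stop("need at least 2 frames", "argument")
  if (dim(positions)[2] != length(skeleton$joints))
    rg_stop(sprintf("positions have %d joints, skeleton has %d",
                    dim(positions)[2], length(skeleton$joints)), "argument")
  if (!all(is.finite(positions)))
    rg_stop("non-finite coordinate in positions", "argument")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    rg_stop("frame_rate must be a positive scalar", "argument")
  dimnames(positions) <- list(NULL, skeleton$joints, c("x", "y", "z"))
  structure(
    list(positions = positions, frame_rate = frame_rate,
         subject_label = as.character(subject_label),
         sequence_id = as.character(sequence_id)),
    class = "rg_joint_seq"
  )
}

#' @export
print.rg_joint_seq <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<rg_joint_seq> '%s' subject=%s: %d frames x %d joints @ %g fps\n",
              x$sequence_id, x$subject_label, d[1], d[2], x$frame_rate))
  invisible(x)
}

#' Write / read a skeleton definition as JSON
#'
#' The on-disk form is `{"joints": [...], "parents": [...]}` with `null`
#' marking the root's parent and 1-based indices otherwise.
#'
#' @param skeleton an `rg_skeleton`.
#' @param path file path.
#' @return `read_skeleton_json` returns an `rg_skeleton`;
#'   `write_skeleton_json` returns `path` invisibly.
#' @export
write_skeleton_json <- function(skeleton, path) {
  parents <- as.list(skeleton$parents)
  parents[is.na(skeleton$parents)] <- list(NULL)
  jsonlite::write_json(list(joints = skeleton$joints, parents = parents),
                       path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_skeleton_json
#' @export
read_skeleton_json <- function(path) {
  if (!file.exists(path)) rg_stop(paste("no such file:", path), "io")
  doc <- jsonlite::read_json(path)
  parents <- vapply(doc$parents,
                    function(p) if (is.null(p)) NA_integer_ else as.integer(p),
                    integer(1))
  skeleton_definition(unlist(doc$joints), parents)
}
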