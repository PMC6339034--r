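# Wide-layout position CSV with JSON sidecar metadata.
#
# Layout: header `frame,<joint>_x,<joint>_y,<joint>_z,...` with joints in
# skeleton order; one row per frame; the frame column is 0-based. A sidecar
# `<path minus .csv>.meta.json` carries {"subject": ..., "frame_rate": ...,
# "sequence_id": ...}.

sidecar_path <- function(path) {
  paste0(sub("\\.csv$", "", path), ".meta.json")
}

expected_header <- function(skeleton) {
  c("frame", paste(rep(skeleton$joints, each = 3),
                   c("x", "y", "z"), sep = "_"))
}

#' Read a joint-position CSV into a trajectory sequence
#'
#' Expects the wide layout documented in [write_position_csv()]; columns are
#' validated against the skeleton and metadata is taken from the sidecar JSON
#' when present (frame rate defaults to 1 fps otherwise).
#'
#' @param path CSV file path.
#' @param skeleton the `rg_skeleton` the file must match.
#' @return an `rg_joint_seq`.
#' @export
read_position_csv <- function(path, skeleton) {
  if (!file.exists(path)) rg_stop(paste("no such file:", path), "io")
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character"),
    error = function(e) rg_stop(paste("cannot parse", path), "format"))
  want <- expected_header(skeleton)
  missing <- setdiff(want, names(df))
  if (length(missing))
    rg_stop(paste0("missing column(s): ", paste(missing, collapse = ", ")),
            "format")
  extra <- setdiff(names(df), want)
  if (length(extra))
    rg_stop(paste0("unexpected column(s): ", paste(extra, collapse = ", ")),
            "format")
  num <- suppressWarnings(
    vapply(df[want[-1]], as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    rg_stop(sprintf("non-numeric value at data row %d, column '%s'",
                    bad[1], want[-1][bad[2]]), "parse")
  }
  nf <- nrow(df)
  nj <- length(skeleton$joints)
  pos <- array(NA_real_, c(nf, nj, 3))
  for (j in seq_len(nj)) pos[, j, ] <- num[, (3 * j - 2):(3 * j)]
  meta <- list(subject = "unknown", frame_rate = 1,
               sequence_id = sub("\\.csv$", "", basename(path)))
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    m <- jsonlite::read_json(sp)
    meta$subject <- m$subject %||% meta$subject
    meta$frame_rate <- m$frame_rate %||% meta$frame_rate
    meta$sequence_id <- m$sequence_id %||% meta$sequence_id
  }
  joint_sequence(pos, skeleton, meta$frame_rate, meta$subject,
                 meta$sequence_id)
}

#' Write a joint-position CSV (wide layout)
#'
#' Emits `1 + 3J` columns (`frame` then xyz per joint in skeleton order), one
#' row per frame, the frame index 0-based, plus a JSON sidecar with the
#' subject label, frame rate and sequence id. Coordinates survive a
#' write/read round trip to better than 1e-12.
#'
#' @param seq an `rg_joint_seq`.
#' @param skeleton its `rg_skeleton`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_position_csv <- function(seq, skeleton, path) {
  pos <- seq$positions
  nf <- dim(pos)[1]
  nj <- dim(pos)[2]
  flat <- matrix(NA_real_, nf, 3 * nj)
  for (j in seq_len(nj)) flat[, (3 * j - 2):(3 * j)] <- pos[, j, ]
  df <- data.frame(frame = 0:(nf - 1), flat, check.names = FALSE)
  names(df) <- expected_header(skeleton)
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) rg_stop(paste("cannot write", path), "io")
  jsonlite::write_json(
    list(subject = seq$subject_label, frame_rate = seq$frame_rate,
         sequence_id = seq$sequence_id),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
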