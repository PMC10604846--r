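#' Skeleton sequences
#'
#' A `skeleton_sequence` holds per-frame 3-D joint positions for a
#' `joint_set`. Coordinates are in meters in a right-handed frame with
#' x = lateral, y = vertical (up) and z = walking direction.
#'
#' @param joints a `joint_set`.
#' @param positions numeric array of dimension T x N x 3 (frames x
#'   joints x xyz), meters.
#' @param fps frames per second (positive real).
#' @param timestamps optional numeric vector of per-frame times in
#'   seconds; when absent, uniform sampling at `fps` is assumed.
#' @return an object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(joints, positions, fps, timestamps = NULL) {
  stopifnot(inherits(joints, "joint_set"))
  positions <- as.array(positions)
  d <- dim(positions)
  if (length(d) != 3L || d[3] != 3L) {
    stop("positions must be a T x N x 3 array")
  }
  if (d[1] < 1L) stop("skeleton_sequence: T must be >= 1")
  if (d[2] != n_joints(joints)) {
    stop("positions has ", d[2], " joints but joint set has ",
         n_joints(joints))
  }
  if (!all(is.finite(positions))) {
    bad <- which(!is.finite(positions), arr.ind = TRUE)
    stop("non-finite coordinate at frame ", bad[1, 1],
         ", joint ", joints$names[bad[1, 2]])
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("fps must be a positive scalar")
  }
  if (!is.null(timestamps)) {
    timestamps <- as.numeric(timestamps)
    if (length(timestamps) != d[1]) {
      stop("timestamps length must equal number of frames")
    }
  }
  structure(
    list(joints = joints, positions = positions, fps = fps,
         timestamps = timestamps),
    class = "skeleton_sequence"
  )
}

#' Number of frames in a skeleton sequence
#' @param seq a `skeleton_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) dim(seq$positions)[1]

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat("<skeleton_sequence> ", n_frames(x), " frames x ",
      n_joints(x$joints), " joints @ ", x$fps, " fps\n", sep = "")
  invisible(x)
}

#' Per-frame positions of a joint addressed by role
#' @param seq a `skeleton_sequence`.
#' @param role joint role, e.g. `"ANKLE_L"`.
#' @return T x 3 numeric matrix.
#' @export
joint_track <- function(seq, role) {
  idx <- joint_index(seq$joints, role)
  m <- seq$positions[, idx, , drop = FALSE]
  dim(m) <- c(dim(seq$positions)[1], 3L)
  m
}

#' Load a skeleton sequence from disk
#'
#' Two dialects are supported. Delimited text: UTF-8 CSV with header
#' `frame,joint,x,y,z`, one row per joint per frame (long form). JSON:
#' an object with fields `fps`, `joints` (names, in order) and `frames`
#' (list of N x 3 coordinate arrays), plus optional `timestamps`.
#'
#' @param path input file; `.json` extension selects the JSON dialect.
#' @param joints a `joint_set` giving the expected joints and their
#'   order in the returned sequence.
#' @return a `skeleton_sequence` with frames sorted ascending.
#' @export
load_skeleton_sequence <- function(path, joints = default_joint_set()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(obj$fps) || is.null(obj$joints) || is.null(obj$frames)) {
      stop("JSON skeleton file must contain fps, joints, frames")
    }
    file_joints <- as.character(obj$joints)
    unknown <- setdiff(joints$names, file_joints)
    if (length(unknown) > 0L) {
      stop("missing joints in file: ", paste(unknown, collapse = ", "))
    }
    fr <- obj$frames
    if (is.list(fr)) fr <- simplify2array(fr)  # (N, 3, T) when listed
    if (length(dim(fr)) != 3L) stop("malformed frames array")
    reorder <- match(joints$names, file_joints)
    pos <- if (dim(fr)[1] == length(file_joints) && dim(fr)[2] == 3L) {
      aperm(fr[reorder, , , drop = FALSE], c(3L, 1L, 2L))
    } else {                                    # simplified to (T, N, 3)
      fr[, reorder, , drop = FALSE]
    }
    ts <- if (!is.null(obj$timestamps)) as.numeric(obj$timestamps) else NULL
    return(skeleton_sequence(joints, pos, as.numeric(obj$fps), ts))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("frame", "joint", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("delimited skeleton file must have columns frame,joint,x,y,z")
  }
  unknown <- setdiff(unique(df$joint), joints$names)
  if (length(unknown) > 0L) {
    stop("unknown joint name(s) in file: ", paste(unknown, collapse = ", "))
  }
  frames <- sort(unique(df$frame))
  T_ <- length(frames)
  N <- n_joints(joints)
  pos <- array(NA_real_, dim = c(T_, N, 3L))
  fi <- match(df$frame, frames)
  ji <- match(df$joint, joints$names)
  pos[cbind(fi, ji, 1L)] <- df$x
  pos[cbind(fi, ji, 2L)] <- df$y
  pos[cbind(fi, ji, 3L)] <- df$z
  na <- which(is.na(pos), arr.ind = TRUE)
  if (nrow(na) > 0L) {
    stop("missing or non-finite coordinate at frame ", frames[na[1, 1]],
         ", joint ", joints$names[na[1, 2]])
  }
  # fps rides along as a commented header line: "# fps: <value>"
  fps <- 30
  hdr <- grep("^# fps:", readLines(path, n = 2L), value = TRUE)
  if (length(hdr) > 0L) fps <- as.numeric(sub("^# fps:", "", hdr[1]))
  skeleton_sequence(joints, pos, fps)
}

#' Save a skeleton sequence to disk
#'
#' Writes the dialect matching the file extension: `.json` for JSON,
#' anything else for long-form CSV (with the fps recorded on a leading
#' comment line).
#'
#' @param seq a `skeleton_sequence`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
save_skeleton_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    T_ <- n_frames(seq)
    frames <- lapply(seq_len(T_), function(t) {
      m <- seq$positions[t, , , drop = FALSE]
      dim(m) <- dim(seq$positions)[2:3]
      m
    })
    obj <- list(fps = seq$fps, joints = seq$joints$names, frames = frames)
    if (!is.null(seq$timestamps)) obj$timestamps <- seq$timestamps
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  T_ <- n_frames(seq)
  N <- n_joints(seq$joints)
  df <- data.frame(
    frame = rep(seq_len(T_) - 1L, each = N),
    joint = rep(seq$joints$names, times = T_),
    x = as.vector(t(seq$positions[, , 1])),
    y = as.vector(t(seq$positions[, , 2])),
    z = as.vector(t(seq$positions[, , 3]))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fps: ", format(seq$fps, digits = 17)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rigid transforms
#'
#' @param rotation 3 x 3 orthonormal rotation matrix (determinant +1).
#' @param translation length-3 numeric translation, meters.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation is not orthonormal")
  }
  if (abs(det(rotation) - 1) > 1e-6) {
    stop("rotation determinant must be +1 (got ", det(rotation), ")")
  }
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  Rt <- t(tf$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% tf$translation))
}

#' Apply sensor-to-world calibration
#'
#' Maps every joint position p to R p + t, the rigid transform that
#' carries sensor coordinates into the calibrated (marker) frame.
#'
#' @param seq a `skeleton_sequence`.
#' @param tf a `rigid_transform`.
#' @return the transformed `skeleton_sequence` (fps unchanged).
#' @export
apply_calibration <- function(seq, tf) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (!inherits(tf, "rigid_transform")) {
    tf <- rigid_transform(tf$rotation, tf$translation)  # re-validate
  }
  d <- dim(seq$positions)
  flat <- matrix(seq$positions, ncol = 3L)      # (T*N) x 3
  out <- flat %*% t(tf$rotation)
  out <- sweep(out, 2L, tf$translation, "+")
  dim(out) <- d
  seq$positions <- out
  seq
}

#' Mirror a sequence left-to-right
#'
#' Negates the lateral (x) coordinate of every joint and swaps each
#' left-side joint with its right-side counterpart, producing the
#' laterally reflected gait.
#'
#' @param seq a `skeleton_sequence` whose joint set has complete
#'   left/right pairs.
#' @return the mirrored `skeleton_sequence`.
#' @export
mirror_sequence <- function(seq) {
  js <- seq$joints
  if (nrow(js$lr_pairs) == 0L) stop("joint set has no left/right pairs")
  li <- match(js$lr_pairs[, 1], js$names)
  ri <- match(js$lr_pairs[, 2], js$names)
  if (anyNA(li) || anyNA(ri)) stop("unpaired lateral joint in joint set")
  pos <- seq$positions
  pos[, , 1] <- -pos[, , 1]
  perm <- seq_len(n_joints(js))
  perm[li] <- ri
  perm[ri] <- li
  seq$positions <- pos[, perm, , drop = FALSE]
  seq
}

#' Extract a fixed window from the end of a sequence
#'
#' Drops the last `tail_drop` frames (typically noisy because the
#' walker is too close to the sensor) and keeps the `window` frames
#' immediately preceding them, i.e. frames
#' `[T - tail_drop - window, T - tail_drop)` in 0-based half-open
#' indexing.
#'
#' @param seq a `skeleton_sequence` with at least `window + tail_drop`
#'   frames.
#' @param window positive number of frames to keep.
#' @param tail_drop nonnegative number of trailing frames to discard.
#' @return the windowed `skeleton_sequence` (length exactly `window`).
#' @export
window_sequence <- function(seq, window, tail_drop = 0L) {
  stopifnot(window >= 1L, tail_drop >= 0L)
  T_ <- n_frames(seq)
  if (T_ < window + tail_drop) {
    stop("sequence too short: need at least ", window + tail_drop,
         " frames, have ", T_)
  }
  keep <- (T_ - tail_drop - window + 1L):(T_ - tail_drop)
  seq$positions <- seq$positions[keep, , , drop = FALSE]
  if (!is.null(seq$timestamps)) seq$timestamps <- seq$timestamps[keep]
  seq
}
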