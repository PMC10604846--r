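#' Joint bending and link angles
#'
#' Two families of per-frame angles are extracted from a skeleton
#' sequence. A *bending angle* is the interior angle at a joint
#' (vertex) between the two limb segments meeting there, computed by
#' the law of cosines from the three squared side lengths. A *link
#' angle* is the angle between a limb-segment vector and one of the
#' coordinate axes (its direction cosine). Both are reported in
#' degrees in [0, 180].
#'
#' @name angle_features
NULL

.deg <- 180 / pi
.degenerate_eps <- 1e-8  # meters; below this a limb vector is degenerate

#' Define a bending angle
#' @param alpha vertex joint role.
#' @param beta,gamma roles of the two joints connected to the vertex.
#' @return a `bending_angle_def`.
#' @export
bending_angle_def <- function(alpha, beta, gamma) {
  if (length(unique(c(alpha, beta, gamma))) != 3L) {
    stop("bending angle requires three distinct joints")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "bending_angle_def")
}

#' Define a link (limb segment)
#' @param name link identifier (thigh_L, shank_R, trunk, ...).
#' @param m distal joint role (vector head).
#' @param n proximal joint role (vector tail).
#' @param axes axes the link angle is measured against, subset of
#'   `c("x","y","z")`.
#' @return a `link_def`.
#' @export
link_def <- function(name, m, n, axes = c("x", "y", "z")) {
  if (m == n) stop("link endpoints must differ")
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)
  if (length(axes) == 0L) stop("axes must be nonempty")
  structure(list(name = name, m = m, n = n, axes = axes),
            class = "link_def")
}

#' Per-frame bending angle at a joint
#'
#' The angle at vertex `alpha` between the segments to `beta` and
#' `gamma`, via the law of cosines over the triangle
#' (alpha, beta, gamma); the cosine is clamped to [-1, 1] before the
#' arccos so collinear geometry cannot produce NaN.
#'
#' @param seq a `skeleton_sequence`.
#' @param def a `bending_angle_def`.
#' @return numeric vector of length T, degrees in [0, 180].
#' @export
bending_angle <- function(seq, def) {
  a <- joint_track(seq, def$alpha)
  b <- joint_track(seq, def$beta)
  g <- joint_track(seq, def$gamma)
  ab <- b - a
  ag <- g - a
  d_ab2 <- rowSums(ab^2)
  d_ag2 <- rowSums(ag^2)
  d_bg2 <- rowSums((g - b)^2)
  bad <- which(d_ab2 < .degenerate_eps^2 | d_ag2 < .degenerate_eps^2)
  if (length(bad) > 0L) {
    stop("degenerate limb vector at frame ", bad[1],
         " for bending angle at ", def$alpha)
  }
  cosv <- (d_ab2 + d_ag2 - d_bg2) / (2 * sqrt(d_ab2) * sqrt(d_ag2))
  acos(pmin(1, pmax(-1, cosv))) * .deg
}

#' Per-frame link angle about a coordinate axis
#'
#' The angle between the link vector (m - n) and the unit axis
#' `axis`, i.e. the arccos of the link's direction cosine.
#'
#' @param seq a `skeleton_sequence`.
#' @param link a `link_def`.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @return numeric vector of length T, degrees in [0, 180].
#' @export
link_angle <- function(seq, link, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  m <- joint_track(seq, link$m)
  n <- joint_track(seq, link$n)
  v <- m - n
  nrm <- sqrt(rowSums(v^2))
  bad <- which(nrm < .degenerate_eps)
  if (length(bad) > 0L) {
    stop("zero-length link ", link$name, " at frame ", bad[1])
  }
  comp <- v[, match(axis, c("x", "y", "z"))]
  acos(pmin(1, pmax(-1, comp / nrm))) * .deg
}

#' Default 25-angle configuration
#'
#' Six bending angles (left/right hip, knee, ankle) plus the six limb
#' links (thigh, shank, foot on each side) measured about all three
#' axes (18 link angles) plus the trunk link measured about the
#' lateral (x) axis only, for 25 angles in total. The trunk link is
#' restricted to a single axis so the default dimension is exactly 25;
#' pass a custom configuration to change the set.
#'
#' @return a list with elements `bending` (list of
#'   `bending_angle_def`) and `links` (list of `link_def`).
#' @export
default_angle_config <- function() {
  bending <- list(
    hip_L   = bending_angle_def("HIP_L",   "PELVIS", "KNEE_L"),
    hip_R   = bending_angle_def("HIP_R",   "PELVIS", "KNEE_R"),
    knee_L  = bending_angle_def("KNEE_L",  "HIP_L",  "ANKLE_L"),
    knee_R  = bending_angle_def("KNEE_R",  "HIP_R",  "ANKLE_R"),
    ankle_L = bending_angle_def("ANKLE_L", "KNEE_L", "FOOT_L"),
    ankle_R = bending_angle_def("ANKLE_R", "KNEE_R", "FOOT_R")
  )
  links <- list(
    link_def("thigh_L", "KNEE_L",  "HIP_L"),
    link_def("thigh_R", "KNEE_R",  "HIP_R"),
    link_def("shank_L", "ANKLE_L", "KNEE_L"),
    link_def("shank_R", "ANKLE_R", "KNEE_R"),
    link_def("foot_L",  "FOOT_L",  "ANKLE_L"),
    link_def("foot_R",  "FOOT_R",  "ANKLE_R"),
    link_def("trunk",   "HEAD",    "PELVIS", axes = "x")
  )
  list(bending = bending, links = links)
}

#' Extract the full per-frame angle matrix
#'
#' Assembles all configured bending and link angles into a T x A
#' matrix (default A = 25) whose column order is: bending angles in
#' configuration order, then for each link its angles about x, y, z
#' (restricted to the link's configured axes).
#'
#' @param seq a `skeleton_sequence`.
#' @param config an angle configuration as returned by
#'   [default_angle_config()].
#' @return an `angle_sequence`: T x A numeric matrix (degrees) with
#'   labeled columns, plus attribute `fps`.
#' @export
extract_angle_matrix <- function(seq, config = default_angle_config()) {
  cols <- list()
  for (nm in names(config$bending)) {
    val <- tryCatch(bending_angle(seq, config$bending[[nm]]),
                    error = function(e) {
                      stop("column bend_", nm, ": ", conditionMessage(e))
                    })
    cols[[paste0("bend_", nm)]] <- val
  }
  for (link in config$links) {
    for (ax in link$axes) {
      lbl <- paste0("link_", link$name, "_", ax)
      val <- tryCatch(link_angle(seq, link, ax),
                      error = function(e) {
                        stop("column ", lbl, ": ", conditionMessage(e))
                      })
      cols[[lbl]] <- val
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  attr(m, "fps") <- seq$fps
  class(m) <- c("angle_sequence", class(m))
  m
}

#' Number of angles produced by a configuration
#' @param config an angle configuration.
#' @return integer angle count.
#' @export
n_angles <- function(config = default_angle_config()) {
  length(config$bending) +
    sum(vapply(config$links, function(l) length(l$axes), integer(1)))
}
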