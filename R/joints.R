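#' Joint sets
#'
#' A `joint_set` names the joints of a skeleton, maps semantic roles
#' (PELVIS, HEAD, HIP_L, ...) to joint names, and lists the bones
#' (parent-child pairs) connecting them. All downstream code addresses
#' joints through roles, so alternative marker sets only need a new
#' role mapping.
#'
#' @param names ordered character vector of joint identifiers.
#' @param roles named character vector mapping semantic roles to joint
#'   names. The roles `PELVIS`, `HEAD`, `HIP_L`, `HIP_R`, `KNEE_L`,
#'   `KNEE_R`, `ANKLE_L`, `ANKLE_R`, `FOOT_L`, `FOOT_R` are required.
#' @param bones two-column character matrix of (parent, child) joint
#'   names.
#' @param lr_pairs two-column character matrix pairing each left-side
#'   joint with its right-side counterpart.
#' @return an object of class `joint_set`.
#' @export
joint_set <- function(names, roles, bones, lr_pairs) {
  required <- c("PELVIS", "HEAD", "HIP_L", "HIP_R", "KNEE_L", "KNEE_R",
                "ANKLE_L", "ANKLE_R", "FOOT_L", "FOOT_R")
  missing_roles <- setdiff(required, base::names(roles))
  if (length(missing_roles) > 0L) {
    stop("joint_set: missing required roles: ",
         paste(missing_roles, collapse = ", "))
  }
  bad <- setdiff(unname(roles), names)
  if (length(bad) > 0L) {
    stop("joint_set: role targets not in joint names: ",
         paste(bad, collapse = ", "))
  }
  bones <- as.matrix(bones)
  if (ncol(bones) != 2L) stop("joint_set: bones must have two columns")
  bad <- setdiff(as.vector(bones), names)
  if (length(bad) > 0L) {
    stop("joint_set: bone endpoints not in joint names: ",
         paste(bad, collapse = ", "))
  }
  lr_pairs <- as.matrix(lr_pairs)
  bad <- setdiff(as.vector(lr_pairs), names)
  if (length(bad) > 0L) {
    stop("joint_set: left/right pair members not in joint names: ",
         paste(bad, collapse = ", "))
  }
  # left/right roles must come in pairs
  role_names <- base::names(roles)
  lefts <- grep("_L$", role_names, value = TRUE)
  for (l in lefts) {
    r <- sub("_L$", "_R", l)
    if (!(r %in% role_names)) {
      stop("joint_set: role ", l, " has no matching ", r)
    }
  }
  structure(
    list(names = as.character(names), roles = roles,
         bones = bones, lr_pairs = lr_pairs),
    class = "joint_set"
  )
}

#' Number of joints in a joint set
#' @param joints a `joint_set`.
#' @return integer joint count.
#' @export
n_joints <- function(joints) length(joints$names)

#' Resolve a semantic role to a joint index
#' @param joints a `joint_set`.
#' @param role role identifier, e.g. `"KNEE_L"`.
#' @return integer column index of the joint.
#' @export
joint_index <- function(joints, role) {
  nm <- joints$roles[[role]]
  if (is.null(nm)) stop("unknown joint role: ", role)
  match(nm, joints$names)
}

#' Default 19-joint walking skeleton
#'
#' A lower-plus-upper-body subset of the Azure Kinect 32-joint model:
#' the spine chain (pelvis, navel, chest, neck, head), both arms
#' (shoulder, elbow, wrist) and both legs (hip, knee, ankle, foot).
#' This is the minimal set that supports every bending angle, link
#' angle and gait parameter computed by the package.
#'
#' @return a `joint_set` with 19 joints.
#' @export
default_joint_set <- function() {
  nm <- c("PELVIS", "SPINE_NAVEL", "SPINE_CHEST", "NECK", "HEAD",
          "SHOULDER_LEFT", "ELBOW_LEFT", "WRIST_LEFT",
          "SHOULDER_RIGHT", "ELBOW_RIGHT", "WRIST_RIGHT",
          "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT", "FOOT_LEFT",
          "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT", "FOOT_RIGHT")
  roles <- c(
    PELVIS = "PELVIS", SPINE = "SPINE_CHEST", HEAD = "HEAD",
    SHOULDER_L = "SHOULDER_LEFT", SHOULDER_R = "SHOULDER_RIGHT",
    ELBOW_L = "ELBOW_LEFT", ELBOW_R = "ELBOW_RIGHT",
    WRIST_L = "WRIST_LEFT", WRIST_R = "WRIST_RIGHT",
    HIP_L = "HIP_LEFT", HIP_R = "HIP_RIGHT",
    KNEE_L = "KNEE_LEFT", KNEE_R = "KNEE_RIGHT",
    ANKLE_L = "ANKLE_LEFT", ANKLE_R = "ANKLE_RIGHT",
    FOOT_L = "FOOT_LEFT", FOOT_R = "FOOT_RIGHT"
  )
  bones <- rbind(
    c("PELVIS", "SPINE_NAVEL"),
    c("SPINE_NAVEL", "SPINE_CHEST"),
    c("SPINE_CHEST", "NECK"),
    c("NECK", "HEAD"),
    c("SPINE_CHEST", "SHOULDER_LEFT"),
    c("SHOULDER_LEFT", "ELBOW_LEFT"),
    c("ELBOW_LEFT", "WRIST_LEFT"),
    c("SPINE_CHEST", "SHOULDER_RIGHT"),
    c("SHOULDER_RIGHT", "ELBOW_RIGHT"),
    c("ELBOW_RIGHT", "WRIST_RIGHT"),
    c("PELVIS", "HIP_LEFT"),
    c("HIP_LEFT", "KNEE_LEFT"),
    c("KNEE_LEFT", "ANKLE_LEFT"),
    c("ANKLE_LEFT", "FOOT_LEFT"),
    c("PELVIS", "HIP_RIGHT"),
    c("HIP_RIGHT", "KNEE_RIGHT"),
    c("KNEE_RIGHT", "ANKLE_RIGHT"),
    c("ANKLE_RIGHT", "FOOT_RIGHT")
  )
  lr_pairs <- rbind(
    c("SHOULDER_LEFT", "SHOULDER_RIGHT"),
    c("ELBOW_LEFT", "ELBOW_RIGHT"),
    c("WRIST_LEFT", "WRIST_RIGHT"),
    c("HIP_LEFT", "HIP_RIGHT"),
    c("KNEE_LEFT", "KNEE_RIGHT"),
    c("ANKLE_LEFT", "ANKLE_RIGHT"),
    c("FOOT_LEFT", "FOOT_RIGHT")
  )
  joint_set(nm, roles, bones, lr_pairs)
}
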