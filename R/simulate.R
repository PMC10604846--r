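#' Parametric pathological-gait simulator
#'
#' A phase-driven kinematic walking model. Feet alternate between a
#' planted stance phase and a smooth swing that carries the foot to
#' its next placement; the pelvis advances at the commanded speed and
#' vaults over the planted leg (its height follows the near-extended
#' stance limb), the knee is placed by two-link inverse kinematics
#' between hip and ankle, and the trunk and arms ride on top with
#' style-dependent lean. Each gait class perturbs this template in the
#' clinically characteristic way; ground-truth events and commanded
#' parameters are returned with every walk, so the feature pipeline
#' can be validated against known values.
#'
#' @name synthetic_gait
NULL

.gait_classes <- c("normal", "antalgic", "steppage", "lurching",
                   "stiff_legged", "trendelenburg")

#' Gait style definition
#'
#' Returns the perturbation parameter set for one gait class. All
#' defaults can be overridden through `...`. Class signatures:
#' antalgic = shortened stance and step on the affected side;
#' steppage = high foot lift with dropped foot; lurching = posterior
#' trunk-lean pulse around affected heel strike; stiff-legged =
#' near-extended knee with lateral circumduction in swing;
#' Trendelenburg = contralateral pelvic drop plus lateral trunk lean
#' over affected stance; vestibular-like = irregular timing, lateral
#' sway and wandering heading.
#'
#' @param class gait class name.
#' @param affected_side `"L"` or `"R"` for unilateral patterns.
#' @param ... named overrides of individual style parameters.
#' @return a `gait_style` list.
#' @export
gait_style <- function(class = c(.gait_classes, "vestibular_like"),
                       affected_side = "L", ...) {
  class <- match.arg(class)
  s <- list(
    name = class, affected_side = affected_side,
    stance_frac = c(L = 0.60, R = 0.60),   # fraction of cycle in stance
    step_len = c(L = 0.55, R = 0.55),      # m, foot separation at strike
    foot_lift = c(L = 0.05, R = 0.05),     # m, swing clearance
    foot_drop = c(L = 10, R = 10),         # deg, swing foot pitch
    ext_frac = c(L = 0.98, R = 0.98),      # stance-leg extension fraction
    circumduct = c(L = 0, R = 0),          # 0/1, stiff-swing circumduction
    load_ramp = c(L = 0.3, R = 0.3),       # stance fraction to take load
    trunk_lat_amp = 2,                     # deg, lateral lean amplitude
    trunk_lat_pulse = FALSE,               # pulse during affected stance?
    trunk_post_amp = 0,                    # deg, posterior lean pulse
    pelvic_drop_amp = 0,                   # deg, contralateral hip drop
    sway_amp = 0.02,                       # m, lateral pelvis sway
    heading_noise = 0,                     # m, lateral random-walk scale
    timing_jitter = 0,                     # sd of log cycle duration
    step_noise = 0,                        # sd of per-step placement, m
    step_width = 0.12                      # m, lateral lane separation
  )
  a <- affected_side
  switch(class,
    normal = {},
    antalgic = {
      s$stance_frac[a] <- 0.45
      s$step_len[a] <- 0.40
    },
    steppage = {
      s$foot_lift[a] <- 0.18
      s$foot_drop[a] <- 45
    },
    lurching = {
      s$trunk_post_amp <- 15
    },
    stiff_legged = {
      s$ext_frac[a] <- 0.995
      s$foot_lift[a] <- 0.02
      s$circumduct[a] <- 1
      s$load_ramp[a] <- 0.02   # extended knee takes load immediately
    },
    trendelenburg = {
      s$pelvic_drop_amp <- 10
      s$trunk_lat_amp <- 12
      s$trunk_lat_pulse <- TRUE
    },
    vestibular_like = {
      s$sway_amp <- 0.06
      s$heading_noise <- 0.05
      s$timing_jitter <- 0.08
      s$step_noise <- 0.04
      s$step_len[] <- 0.45
      s$trunk_lat_amp <- 5
    }
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(s)) stop("unknown style parameter: ", nm)
    if (length(dots[[nm]]) == length(s[[nm]])) {
      s[[nm]][] <- dots[[nm]]
    } else {
      s[[nm]] <- dots[[nm]]
    }
  }
  structure(s, class = "gait_style")
}

#' Subject body profile
#'
#' Draws reproducible per-subject anthropometry: segment lengths
#' scaled by a common body-size factor, a preferred gait-cycle
#' duration and a step-length multiplier.
#'
#' @param subject_id identifier string.
#' @param seed integer seed controlling the draw.
#' @return a `subject_profile` list of segment lengths (m) and timing.
#' @export
subject_profile <- function(subject_id, seed) {
  rng <- .new_rng(seed)
  scale <- max(0.85, min(1.15, 1 + 0.04 * rng$norm(1)))
  structure(list(
    subject_id = as.character(subject_id),
    scale = scale,
    l_thigh = 0.45 * scale,
    l_shank = 0.42 * scale,   # knee to ankle
    l_foot = 0.20 * scale,    # ankle to tiptoe
    l_trunk = 0.58 * scale,   # pelvis to head
    w_pelvis = 0.24 * scale,
    w_shoulder = 0.20 * scale,
    l_upper_arm = 0.30 * scale,
    l_forearm = 0.27 * scale,
    ankle_h = 0.08 * scale,
    cycle_duration = 1.0 + 0.2 * rng$unif(1),   # s
    step_scale = max(0.8, min(1.2, 1 + 0.05 * rng$norm(1)))
  ), class = "subject_profile")
}

# Private counter-based RNG helper: isolates simulator draws from the
# global RNG stream so dataset generation is reproducible regardless
# of the caller's RNG state.
.new_rng <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed %% 2147483647L)
  draw <- function(n, fn) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(env$state)
    out <- fn(n)
    env$state <- as.integer(stats::runif(1, 1, 2147483646))
    out
  }
  list(
    unif = function(n = 1) draw(n, stats::runif),
    norm = function(n = 1) draw(n, stats::rnorm),
    int = function(n, max) draw(n, function(k) sample.int(max, k,
                                                          replace = TRUE))
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Rotation matrices about the coordinate axes (degrees).
.rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
.rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Smooth 0->1->0 bump over u in [0,1].
.bump <- function(u) sin(pi * pmin(1, pmax(0, u)))^2

#' Simulate one walk
#'
#' @param style a `gait_style`.
#' @param subject a `subject_profile`.
#' @param n_frames number of frames to generate.
#' @param fps frames per second.
#' @param seed integer seed for this walk's random draws.
#' @param noise_sd isotropic Gaussian position noise, meters.
#' @param joints the `joint_set` to emit (default 19-joint set).
#' @return a list with `sequence` (a `skeleton_sequence`) and
#'   `ground_truth` (events as frame indices, commanded parameters,
#'   and a `warning` field when fewer than two full cycles fit).
#' @export
simulate_walk <- function(style, subject, n_frames = 100, fps = 30,
                          seed = 1, noise_sd = 0.003,
                          joints = default_joint_set()) {
  stopifnot(inherits(style, "gait_style"), inherits(subject, "subject_profile"))
  rng <- .new_rng(seed)
  p <- subject
  tau <- p$cycle_duration
  step <- style$step_len * p$step_scale
  stride <- sum(step)
  d <- style$stance_frac
  dur <- (n_frames - 1) / fps
  t <- (seq_len(n_frames) - 1) / fps
  t0 <- rng$unif(1) * tau          # start mid-cycle
  s <- t + t0

  # Cycle-duration schedule (timing jitter) and the global phase Phi.
  n_cycles_max <- ceiling((dur + 2 * tau) / (tau * 0.8)) + 4L
  jit <- if (style$timing_jitter > 0) {
    exp(style$timing_jitter * rng$norm(n_cycles_max))
  } else rep(1, n_cycles_max)
  tau_k <- tau * jit
  knots_t <- c(0, cumsum(tau_k))
  knots_phi <- 0:(length(knots_t) - 1)
  phi <- stats::approx(knots_t, knots_phi, xout = s, rule = 2)$y
  inv_phi <- function(ph) stats::approx(knots_phi, knots_t, xout = ph,
                                        rule = 2)$y

  # Foot placements: side S strikes at Phi = k (+ 0.5 for right), landing
  # step_S/2 ahead of the pelvis, so foot separation at strike = step_S.
  k_max <- length(knots_t) - 1L
  ks_all <- -1:k_max                 # cycle -1 covers the pre-start stance
  place <- function(side_offset, lead) {
    z <- stride * (ks_all + side_offset) + lead
    if (style$step_noise > 0) z <- z + style$step_noise * rng$norm(length(z))
    z
  }
  zP_L <- place(0, step["L"] / 2)
  zP_R <- place(0.5, step["R"] / 2)

  # Lateral heading drift (vestibular-like wandering), smooth random walk.
  drift <- if (style$heading_noise > 0) {
    w <- cumsum(rng$norm(n_frames)) / sqrt(n_frames)
    style$heading_noise * stats::filter(w, rep(1 / 15, 15), sides = 2)
  } else rep(0, n_frames)
  drift[is.na(drift)] <- 0
  drift <- as.numeric(drift)

  side_sign <- c(L = -1, R = 1)    # lateral lane of each foot
  aff <- style$affected_side
  aff_sign <- side_sign[[aff]]

  # Per-frame, per-side phase bookkeeping.
  leg <- list()
  for (side in c("L", "R")) {
    off <- if (side == "L") 0 else 0.5
    phs <- phi - off
    k <- floor(phs)
    u_cycle <- phs - k
    in_stance <- u_cycle < d[[side]]
    zP <- if (side == "L") zP_L else zP_R   # indexed by k + 2 (k >= -1)
    zP_this <- zP[pmin(length(zP), pmax(1L, k + 2L))]
    zP_next <- zP[pmin(length(zP), pmax(1L, k + 3L))]
    u_sw <- pmin(1, pmax(0, (u_cycle - d[[side]]) / (1 - d[[side]])))
    # swing profile: forward velocity equals pelvis velocity at both
    # ends, so the ankle-relative-forward extrema land exactly on the
    # events; the sine-bump velocity shape keeps those extrema sharply
    # curved (quadratic), which noise-robust peak detection needs
    adv <- stride * (1 - d[[side]]) * u_sw
    extra <- (zP_next - zP_this - stride * (1 - d[[side]])) *
      (1 - cos(pi * u_sw)) / 2
    z <- ifelse(in_stance, zP_this, zP_this + adv + extra)
    lift <- style$foot_lift[[side]]
    y <- p$ankle_h + ifelse(in_stance, 0, lift * .bump(u_sw))
    x <- side_sign[[side]] * style$step_width / 2 + drift
    leg[[side]] <- list(ax = x, ay = y, az = z, k = k, u_cycle = u_cycle,
                        in_stance = in_stance, u_sw = u_sw)
  }

  # Pelvis: advances with the phase, vaults over the planted limb(s).
  # During double support the height blends between the two stance-leg
  # constraints with a smooth load-transfer weight.
  L_leg <- p$l_thigh + p$l_shank
  pelvis_z <- stride * phi
  pelvis_x <- style$sway_amp * sin(2 * pi * phi) + drift
  hip_y_off <- 0.05 * p$scale
  ss <- function(x) sin(pi / 2 * pmin(1, pmax(0, x)))^2
  num <- rep(0, n_frames)
  den <- rep(0, n_frames)
  for (side in c("L", "R")) {
    lg <- leg[[side]]
    Leff <- L_leg * style$ext_frac[[side]]
    h <- sqrt(pmax((0.6 * L_leg)^2, Leff^2 - (lg$az - pelvis_z)^2)) + lg$ay
    q <- lg$u_cycle / d[[side]]                  # stance progress in [0,1)
    r <- style$load_ramp[[side]]
    w <- ifelse(lg$in_stance, ss(q / r) * ss((1 - q) / r), 0)
    num <- num + w * h
    den <- den + w
  }
  fallback <- L_leg * 0.97 + p$ankle_h
  pelvis_y <- ifelse(den > 1e-9, num / pmax(den, 1e-9), fallback) + hip_y_off

  # Trunk lean angles.
  lat <- if (isTRUE(style$trunk_lat_pulse)) {
    aff_sign * style$trunk_lat_amp *
      .bump(leg[[aff]]$u_cycle / d[[aff]]) * leg[[aff]]$in_stance
  } else {
    style$trunk_lat_amp * sin(2 * pi * phi)
  }
  post <- if (style$trunk_post_amp > 0) {
    # posterior lean pulse centred on the affected heel strike
    ph_aff <- leg[[aff]]$u_cycle
    style$trunk_post_amp * exp(-(pmin(ph_aff, 1 - ph_aff))^2 / (2 * 0.08^2))
  } else rep(0, n_frames)

  # Pelvic drop (rotation of the hip axis about the forward axis).
  rho <- if (style$pelvic_drop_amp > 0) {
    -aff_sign * style$pelvic_drop_amp *
      .bump(leg[[aff]]$u_cycle / d[[aff]]) * leg[[aff]]$in_stance
  } else rep(0, n_frames)

  N <- n_joints(joints)
  pos <- array(0, dim = c(n_frames, N, 3))
  jidx <- function(role) joint_index(joints, role)
  set_j <- function(role, m) pos[, jidx(role), ] <<- m

  pelvis <- cbind(pelvis_x, pelvis_y, pelvis_z)
  set_j("PELVIS", pelvis)

  # Trunk chain: rigid trunk vector rotated by lateral/posterior lean.
  up <- c(0, 1, 0)
  trunk_dir <- t(vapply(seq_len(n_frames), function(i) {
    as.vector(.rot_z(lat[i]) %*% .rot_x(-post[i]) %*% up)
  }, numeric(3)))
  trunk_fracs <- c(SPINE = 0.60, HEAD = 1.00)
  extra_fracs <- c(SPINE_NAVEL = 0.30, NECK = 0.85)  # by joint name
  for (role in names(trunk_fracs)) {
    pos[, jidx(role), ] <- pelvis + trunk_dir * (trunk_fracs[role] * p$l_trunk)
  }
  for (nm in names(extra_fracs)) {
    ji <- match(nm, joints$names)
    if (!is.na(ji)) {
      pos[, ji, ] <- pelvis + trunk_dir * (extra_fracs[nm] * p$l_trunk)
    }
  }
  chest <- pelvis + trunk_dir * (0.60 * p$l_trunk)

  # Arms: sagittal swing anti-phase with the ipsilateral leg.
  for (side in c("L", "R")) {
    sgn <- side_sign[[side]]
    swing_deg <- 20 * sin(2 * pi * (phi - (if (side == "L") 0 else 0.5)) + pi)
    sh <- chest
    sh[, 1] <- sh[, 1] + sgn * p$w_shoulder
    set_j(paste0("SHOULDER_", side), sh)
    el <- sh
    wr <- sh
    for (i in seq_len(n_frames)) {
      dirA <- as.vector(.rot_x(swing_deg[i]) %*% c(0, -1, 0))
      dirF <- as.vector(.rot_x(swing_deg[i] + 25) %*% c(0, -1, 0))
      el[i, ] <- sh[i, ] + dirA * p$l_upper_arm
      wr[i, ] <- el[i, ] + dirF * p$l_forearm
    }
    set_j(paste0("ELBOW_", side), el)
    set_j(paste0("WRIST_", side), wr)
  }

  # Legs: hips from pelvis (with pelvic drop), knee by two-link IK.
  fwd <- c(0, 0, 1)
  for (side in c("L", "R")) {
    sgn <- side_sign[[side]]
    lg <- leg[[side]]
    hip <- pelvis
    for (i in seq_len(n_frames)) {
      off <- as.vector(.rot_z(rho[i]) %*% c(sgn * p$w_pelvis / 2,
                                            -hip_y_off, 0))
      hip[i, ] <- pelvis[i, ] + off
    }
    ankle <- cbind(lg$ax, lg$ay, lg$az)
    # stiff-legged circumduction: push the swing ankle laterally until
    # the hip-ankle distance keeps the knee near extension
    if (style$circumduct[[side]] > 0) {
      tgt <- 0.98 * L_leg
      for (i in which(!lg$in_stance)) {
        dy <- ankle[i, 2] - hip[i, 2]
        dz <- ankle[i, 3] - hip[i, 3]
        need2 <- tgt^2 - dy^2 - dz^2
        if (need2 > 0) {
          dx <- sgn * sqrt(need2) * .bump(lg$u_sw[i]) +
            (ankle[i, 1] - hip[i, 1]) * (1 - .bump(lg$u_sw[i]))
          ankle[i, 1] <- hip[i, 1] + dx
        }
      }
    }
    knee <- ankle
    for (i in seq_len(n_frames)) {
      v <- ankle[i, ] - hip[i, ]
      dist <- sqrt(sum(v^2))
      dmax <- 0.9999 * (p$l_thigh + p$l_shank)
      if (dist > dmax) {
        horiz2 <- v[1]^2 + v[3]^2
        if (lg$in_stance[i] && horiz2 < dmax^2) {
          # late-stance overstretch: heel rise (raise the ankle, keep
          # the planted forward position so event geometry is intact)
          ankle[i, 2] <- hip[i, 2] - sqrt(dmax^2 - horiz2)
        } else {
          ankle[i, ] <- hip[i, ] + v * dmax / dist
        }
        v <- ankle[i, ] - hip[i, ]
        dist <- sqrt(sum(v^2))
      }
      u <- v / dist
      a1 <- (p$l_thigh^2 - p$l_shank^2 + dist^2) / (2 * dist)
      hk <- sqrt(max(0, p$l_thigh^2 - a1^2))
      e <- fwd - sum(fwd * u) * u
      en <- sqrt(sum(e^2))
      e <- if (en > 1e-9) e / en else c(0, 0, 1)
      knee[i, ] <- hip[i, ] + a1 * u + hk * e
    }
    # foot (tiptoe) from ankle, pitched down; dropped during swing
    drop_deg <- ifelse(lg$in_stance, 15,
                       15 + (style$foot_drop[[side]] - 10) * .bump(lg$u_sw))
    foot <- ankle
    a <- drop_deg * pi / 180
    foot[, 2] <- ankle[, 2] - sin(a) * p$l_foot
    foot[, 3] <- ankle[, 3] + cos(a) * p$l_foot
    set_j(paste0("HIP_", side), hip)
    set_j(paste0("KNEE_", side), knee)
    set_j(paste0("ANKLE_", side), ankle)
    set_j(paste0("FOOT_", side), foot)
  }

  if (noise_sd > 0) {
    pos <- pos + array(noise_sd * rng$norm(length(pos)), dim = dim(pos))
  }
  sequence <- skeleton_sequence(joints, pos, fps)

  # Ground truth: event frame indices and commanded parameters.
  ev_frames <- function(ph_values) {
    tt <- inv_phi(ph_values) - t0
    idx <- round(tt * fps) + 1
    sort(unique(idx[idx >= 1 & idx <= n_frames]))
  }
  ks <- 0:k_max
  gt <- list(
    events = list(
      heel_strikes_L = ev_frames(ks),
      heel_strikes_R = ev_frames(ks + 0.5),
      toe_offs_L = ev_frames(ks + d[["L"]]),
      toe_offs_R = ev_frames(ks + 0.5 + d[["R"]])
    ),
    commanded = list(
      walking_speed = stride / tau,
      step_len_L = unname(step["L"]), step_len_R = unname(step["R"]),
      stance_time_L = unname(d["L"] * tau),
      stance_time_R = unname(d["R"] * tau),
      swing_time_L = unname((1 - d["L"]) * tau),
      swing_time_R = unname((1 - d["R"]) * tau),
      step_width = style$step_width,
      cycle_duration = tau
    ),
    style = style$name, affected_side = aff
  )
  if (dur < 2 * tau) {
    gt$warning <- paste0("sequence shorter than 2 gait cycles (",
                         round(dur, 2), " s < ", round(2 * tau, 2), " s)")
  }
  list(sequence = sequence, ground_truth = gt)
}

#' Simulation specification
#'
#' @param n_subjects subjects per dataset.
#' @param n_walks walks per subject per class.
#' @param classes gait class names.
#' @param frames_range inclusive range of per-walk frame counts.
#' @param fps frames per second.
#' @param noise_sd sensor noise standard deviation, meters.
#' @param seed master seed; every walk derives its own seed from it.
#' @param mirror_augment add a left/right mirrored copy of each walk?
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_subjects = 12, n_walks = 20,
                     classes = .gait_classes,
                     frames_range = c(80, 120), fps = 30,
                     noise_sd = 0.003, seed = 1, mirror_augment = TRUE) {
  stopifnot(n_subjects >= 1, n_walks >= 1, length(classes) >= 2,
            frames_range[1] >= 2, frames_range[2] >= frames_range[1])
  structure(list(n_subjects = n_subjects, n_walks = n_walks,
                 classes = classes, frames_range = frames_range, fps = fps,
                 noise_sd = noise_sd, seed = seed,
                 mirror_augment = mirror_augment),
            class = "sim_spec")
}

.derive_seed <- function(master, a, b = 0L, c = 0L) {
  as.integer((as.numeric(master) + 7919 * a + 104729 * b + 1299709 * c) %%
               2147483647)
}

#' Generate a labeled multi-class gait dataset
#'
#' Produces `n_subjects x length(classes) x n_walks` examples (plus
#' mirrored copies when `mirror_augment`), each with ground truth
#' attached. The affected side of each subject's pathological gaits is
#' drawn once per subject.
#'
#' @param spec a `sim_spec`.
#' @return a `gait_dataset`; each example carries a `ground_truth`
#'   field.
#' @export
generate_dataset <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  examples <- list()
  n <- 0L
  for (si in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%02d", si)
    prof <- subject_profile(sid, .derive_seed(spec$seed, si))
    side_rng <- .new_rng(.derive_seed(spec$seed, si, 999L))
    aff <- c("L", "R")[side_rng$int(1, 2)]
    for (ci in seq_along(spec$classes)) {
      style <- gait_style(spec$classes[ci], affected_side = aff)
      for (wi in seq_len(spec$n_walks)) {
        wseed <- .derive_seed(spec$seed, si, ci, wi)
        frng <- .new_rng(wseed)
        nf <- spec$frames_range[1] +
          frng$int(1, spec$frames_range[2] - spec$frames_range[1] + 1L) - 1L
        walk <- simulate_walk(style, prof, n_frames = nf, fps = spec$fps,
                              seed = wseed + 1L, noise_sd = spec$noise_sd)
        ex <- gait_example(walk$sequence, sid, ci, wi)
        ex$ground_truth <- walk$ground_truth
        n <- n + 1L
        examples[[n]] <- ex
        if (spec$mirror_augment) {
          n <- n + 1L
          examples[[n]] <- mirror_lr(ex)
        }
      }
    }
  }
  gait_dataset(examples, spec$classes,
               provenance = list(spec = unclass(spec)))
}

#' Generate a binary healthy-vs-disorder dataset
#'
#' Emulates a two-walks-per-subject clinical collection: healthy
#' subjects walk normally, patients walk with the vestibular-like
#' style. A configurable number of deliberately short sequences
#' (< `short_below` frames) is injected for exercising the
#' short-sequence filter.
#'
#' @param n_healthy healthy subject count.
#' @param n_patients patient subject count.
#' @param n_short number of examples drawn short (below `short_below`).
#' @param short_below frame threshold the short examples fall under.
#' @param n_walks walks per subject.
#' @param frames_range frame-count range for regular examples.
#' @param fps frames per second.
#' @param noise_sd sensor noise, meters.
#' @param seed master seed.
#' @return a `gait_dataset` with classes `c("healthy", "disorder")`.
#' @export
generate_vestibular_like <- function(n_healthy = 33, n_patients = 128,
                                     n_short = 10, short_below = 90,
                                     n_walks = 2, frames_range = c(90, 120),
                                     fps = 30, noise_sd = 0.003, seed = 1) {
  n_sub <- n_healthy + n_patients
  n_total <- n_sub * n_walks
  stopifnot(n_short <= n_total)
  pick_rng <- .new_rng(.derive_seed(seed, 424242L))
  short_ids <- sort(pick_rng$int(n_short, n_total))
  # sample with replacement can repeat; redraw until distinct
  while (length(unique(short_ids)) < n_short) {
    short_ids <- sort(unique(c(short_ids,
                               pick_rng$int(n_short, n_total))))[1:n_short]
  }
  examples <- vector("list", n_total)
  idx <- 0L
  for (si in seq_len(n_sub)) {
    healthy <- si <= n_healthy
    sid <- sprintf("%s%03d", if (healthy) "H" else "P", si)
    prof <- subject_profile(sid, .derive_seed(seed, si))
    side_rng <- .new_rng(.derive_seed(seed, si, 999L))
    aff <- c("L", "R")[side_rng$int(1, 2)]
    style <- gait_style(if (healthy) "normal" else "vestibular_like",
                        affected_side = aff)
    for (wi in seq_len(n_walks)) {
      idx <- idx + 1L
      wseed <- .derive_seed(seed, si, 1L, wi)
      frng <- .new_rng(wseed)
      nf <- if (idx %in% short_ids) {
        (short_below - 20L) + frng$int(1, 19L) - 1L
      } else {
        frames_range[1] +
          frng$int(1, frames_range[2] - frames_range[1] + 1L) - 1L
      }
      walk <- simulate_walk(style, prof, n_frames = nf, fps = fps,
                            seed = wseed + 1L, noise_sd = noise_sd)
      ex <- gait_example(walk$sequence, sid, if (healthy) 1L else 2L, wi)
      ex$ground_truth <- walk$ground_truth
      examples[[idx]] <- ex
    }
  }
  gait_dataset(examples, c("healthy", "disorder"),
               provenance = list(n_healthy = n_healthy,
                                 n_patients = n_patients,
                                 n_short = n_short, seed = seed))
}
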