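# hand-built sequence whose ankle-minus-pelvis forward signal is an
# exact sinusoid; peak locations are known analytically
sinusoid_seq <- function(T_ = 121, fps = 30, period_s = 1) {
  js <- default_joint_set()
  pos <- array(0, dim = c(T_, n_joints(js), 3))
  t <- (seq_len(T_) - 1) / fps
  for (j in seq_len(n_joints(js))) {
    pos[, j, 1] <- 0.01 * j
    pos[, j, 2] <- 1
    pos[, j, 3] <- t                       # everything advances at 1 m/s
  }
  rel <- 0.3 * sin(2 * pi * t / period_s)
  for (role in c("ANKLE_L", "ANKLE_R")) {
    idx <- joint_index(js, role)
    shift <- if (role == "ANKLE_R") -rel else rel
    pos[, idx, 3] <- t + shift
  }
  skeleton_sequence(js, pos, fps)
}

test_that("events sit at analytic extrema of a sinusoidal signal", {
  s <- sinusoid_seq()
  ev <- detect_gait_events(s)
  # left rel = 0.3 sin(2 pi t), maxima at t = 0.25, 1.25, ... (frames 8.5)
  expected <- c(0.25, 1.25, 2.25, 3.25) * 30 + 1
  expect_equal(length(ev$heel_strikes_L), 4)
  expect_true(all(abs(ev$heel_strikes_L - expected) <= 1))
  expected_to <- c(0.75, 1.75, 2.75, 3.75) * 30 + 1
  expect_true(all(abs(ev$toe_offs_L - expected_to) <= 1))
})

test_that("a static skeleton has insufficient gait cycles", {
  seq1 <- fixture_walk()$sequence
  static <- skeleton_sequence(seq1$joints,
                              seq1$positions[rep(3, 60), , , drop = FALSE],
                              30)
  expect_error(detect_gait_events(static), "insufficient gait cycles")
})

test_that("detected events match simulator ground truth within 2 frames", {
  total <- 0
  matched <- 0
  for (seed in 1:5) {
    walk <- simulate_walk(gait_style("normal"), fixture_subject(seed),
                          n_frames = 110, fps = 30, seed = seed,
                          noise_sd = 0.003)
    ev <- detect_gait_events(walk$sequence)
    gt <- walk$ground_truth$events
    for (nm in names(gt)) {
      # ground truth includes events at the sequence edges that a local
      # extremum detector cannot see; score the interior ones
      interior <- gt[[nm]][gt[[nm]] > 3 & gt[[nm]] < 108]
      total <- total + length(interior)
      for (f in interior) {
        if (any(abs(ev[[nm]] - f) <= 2)) matched <- matched + 1
      }
    }
  }
  expect_gte(matched / total, 0.9)
})

test_that("basic parameters reproduce hand values", {
  # symmetric sinusoid: zero asymmetry, speed exactly 1 m/s
  s <- sinusoid_seq()
  ev <- detect_gait_events(s)
  bp <- basic_parameters(s, ev)
  expect_equal(unname(bp["walking_speed"]), 1, tolerance = 1e-9)
  expect_lt(bp[["step_length_asymmetry"]], 0.05)

  # pelvis advancing 2 m over 2 s -> 1 m/s regardless of events
  s2 <- sinusoid_seq(T_ = 61, fps = 30)
  ev2 <- detect_gait_events(s2)
  expect_equal(unname(basic_parameters(s2, ev2)["walking_speed"]), 1,
               tolerance = 1e-9)
})

test_that("commanded asymmetric step lengths are recovered", {
  style <- gait_style("normal", step_len = c(L = 0.5, R = 0.4))
  prof <- fixture_subject(9)
  prof$step_scale <- 1
  walk <- simulate_walk(style, prof, n_frames = 120, fps = 30, seed = 2,
                        noise_sd = 0)
  ev <- detect_gait_events(walk$sequence)
  bp <- basic_parameters(walk$sequence, ev)
  expect_equal(unname(bp["avg_step_length"]), 0.45, tolerance = 0.05 * 9)
  expect_lt(abs(bp[["avg_step_length"]] - 0.45) / 0.45, 0.05)
  expect_lt(abs(bp[["step_length_asymmetry"]] - 2 * 0.1 / 0.9) / (2 * 0.1 / 0.9),
            0.25)
})

test_that("phase parameters are event-interval means in seconds", {
  ev <- structure(list(heel_strikes_L = c(1L, 31L), toe_offs_L = 19L,
                       heel_strikes_R = c(16L, 46L), toe_offs_R = 34L),
                  class = "gait_events")
  pp <- phase_parameters(ev, 30)
  expect_equal(unname(pp["stance_time_L"]), 18 / 30)
  expect_equal(unname(pp["swing_time_L"]), 12 / 30)
  expect_equal(unname(pp["stance_time_R"]), 18 / 30)
  expect_equal(unname(pp["swing_time_R"]), 12 / 30)

  bad <- ev
  bad$toe_offs_L <- integer(0)
  expect_error(phase_parameters(bad, 30), "non-alternating")
})

test_that("commanded stance/swing fractions are recovered within 5%", {
  style <- gait_style("normal", stance_frac = c(L = 0.6, R = 0.6))
  prof <- fixture_subject(3)
  walk <- simulate_walk(style, prof, n_frames = 120, fps = 30, seed = 4,
                        noise_sd = 0)
  ev <- detect_gait_events(walk$sequence)
  pp <- phase_parameters(ev, 30)
  cmd <- walk$ground_truth$commanded
  for (nm in c("stance_time_L", "stance_time_R",
               "swing_time_L", "swing_time_R")) {
    expect_lt(abs(pp[[nm]] - cmd[[nm]]) / cmd[[nm]], 0.05)
  }
})

test_that("angle-based parameters match projection trigonometry", {
  js <- default_joint_set()
  mk_trunk <- function(head_offset) {
    pos <- array(0, dim = c(3, n_joints(js), 3))
    for (j in seq_len(n_joints(js))) pos[, j, ] <- rep(c(j, j, j), each = 3)
    pel <- joint_index(js, "PELVIS")
    hd <- joint_index(js, "HEAD")
    pos[, pel, ] <- 0
    pos[, hd, ] <- rep(head_offset, each = 3)
    # keep hips/knees/ankles/feet non-degenerate
    skeleton_sequence(js, pos, 30)
  }
  vertical <- angle_based_parameters(mk_trunk(c(0, 1, 0)))
  expect_equal(unname(vertical["frontal_spine_mean"]), 0, tolerance = 1e-9)
  expect_equal(unname(vertical["lateral_spine_mean"]), 0, tolerance = 1e-9)

  tilt <- 10 * pi / 180
  lateral10 <- angle_based_parameters(mk_trunk(c(sin(tilt), cos(tilt), 0)))
  expect_equal(unname(lateral10["frontal_spine_mean"]), 10,
               tolerance = 1e-6)
  expect_equal(unname(lateral10["lateral_spine_mean"]), 0,
               tolerance = 1e-6)

  walk <- fixture_walk()$sequence
  ap <- angle_based_parameters(walk)
  for (sig in c("frontal_spine", "lateral_spine", "knee_L", "knee_R",
                "hip_L", "hip_R")) {
    expect_lte(ap[[paste0(sig, "_min")]], ap[[paste0(sig, "_mean")]])
    expect_lte(ap[[paste0(sig, "_mean")]], ap[[paste0(sig, "_max")]])
  }
})

test_that("constant angles collapse mean/min/max", {
  seq1 <- fixture_walk()$sequence
  static <- skeleton_sequence(seq1$joints,
                              seq1$positions[rep(8, 5), , , drop = FALSE],
                              30)
  ap <- angle_based_parameters(static)
  expect_equal(unname(ap["knee_L_min"]), unname(ap["knee_L_max"]),
               tolerance = 1e-9)
  expect_equal(unname(ap["knee_L_mean"]), unname(ap["knee_L_max"]),
               tolerance = 1e-9)
})

test_that("the assembled parameter vector is normalized and ordered", {
  v <- assemble_parameter_vector(
    c(avg_step_length = 0.5, step_length_asymmetry = 0.1,
      step_width = 0.12, walking_speed = 1),
    c(stance_time_L = 0.6, stance_time_R = 0.6,
      swing_time_L = 0.4, swing_time_R = 0.4),
    stats::setNames(c(rep(0, 17), 180), paste0("a", 1:18))
  )
  expect_length(v, 26)
  expect_equal(unname(v[26]), 1.8)        # 180 degrees stored as 1.8
  expect_equal(unname(v[1]), 0.5)         # non-angle entries pass through

  zero <- assemble_parameter_vector(numeric(4), numeric(4), numeric(18))
  expect_length(zero, 26)
  expect_true(all(zero == 0))

  expect_error(
    assemble_parameter_vector(c(a = NaN, b = 1, c = 1, d = 1),
                              numeric(4), numeric(18)),
    "a")
})

test_that("full pipeline vector has 26 labeled entries in range", {
  gp <- extract_gait_parameters(fixture_walk()$sequence)
  expect_length(gp, 26)
  expect_true(all(is.finite(gp)))
  expect_equal(names(gp)[1:8],
               c("avg_step_length", "step_length_asymmetry", "step_width",
                 "walking_speed", "stance_time_L", "stance_time_R",
                 "swing_time_L", "swing_time_R"))
  expect_true(all(gp[1:8] >= 0 & gp[1:8] <= 2))
})

test_that("mirroring swaps sides and keeps symmetric parameters", {
  walk <- simulate_walk(gait_style("antalgic", affected_side = "L"),
                        fixture_subject(11), 110, 30, seed = 6,
                        noise_sd = 0)
  ex <- gait_example(walk$sequence, "S1", 1L)
  g0 <- extract_gait_parameters(ex$sequence)
  g1 <- extract_gait_parameters(mirror_lr(ex)$sequence)
  for (nm in c("step_length_asymmetry", "step_width", "walking_speed",
               "avg_step_length")) {
    expect_equal(g0[[nm]], g1[[nm]], tolerance = 1e-6)
  }
  expect_equal(g0[["stance_time_L"]], g1[["stance_time_R"]],
               tolerance = 1e-6)
  expect_equal(g0[["swing_time_R"]], g1[["swing_time_L"]],
               tolerance = 1e-6)
  expect_equal(g0[["knee_L_mean"]], g1[["knee_R_mean"]], tolerance = 1e-6)
})
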