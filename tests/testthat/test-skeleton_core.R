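test_that("skeleton sequences round-trip through both file dialects", {
  seq <- fixture_linear_sequence(12)
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    save_skeleton_sequence(seq, path)
    back <- load_skeleton_sequence(path, seq$joints)
    expect_equal(n_frames(back), 12)
    expect_equal(back$positions, seq$positions, tolerance = 1e-9)
    expect_equal(back$fps, seq$fps)
  }
})

test_that("a simulated 120-frame walk round-trips losslessly", {
  walk <- simulate_walk(gait_style("normal"), fixture_subject(),
                        n_frames = 120, fps = 30, seed = 3, noise_sd = 0.003)
  path <- withr::local_tempfile(fileext = ".csv")
  save_skeleton_sequence(walk$sequence, path)
  back <- load_skeleton_sequence(path)
  expect_lt(max(abs(back$positions - walk$sequence$positions)), 1e-9)
})

test_that("malformed skeleton files are rejected with context", {
  seq <- fixture_linear_sequence(8)
  path <- withr::local_tempfile(fileext = ".csv")
  save_skeleton_sequence(seq, path)

  # corrupt one coordinate at frame 5 (0-based in the file)
  lines <- readLines(path)
  bad <- grep("^5,HEAD", lines)[1]
  lines[bad] <- sub("[-0-9.e]+$", "NaN", lines[bad])
  writeLines(lines, path)
  expect_error(load_skeleton_sequence(path), "frame 5")

  # drop a joint row entirely
  save_skeleton_sequence(seq, path)
  lines <- readLines(path)
  writeLines(lines[-grep("^3,KNEE_LEFT", lines)[1]], path)
  expect_error(load_skeleton_sequence(path), "KNEE_LEFT")

  expect_error(load_skeleton_sequence("no/such/file.csv"), "not found")
})

test_that("unknown joint names in a file are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,joint,x,y,z", "0,NOT_A_JOINT,0,0,0"), path)
  expect_error(load_skeleton_sequence(path), "NOT_A_JOINT")
})

test_that("calibration applies R p + t and composes with its inverse", {
  seq <- fixture_linear_sequence(10)
  expect_equal(apply_calibration(seq, rigid_transform())$positions,
               seq$positions)

  # 90 degrees about the vertical axis, checked against the hand product
  R90 <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3)
  tf <- rigid_transform(R90, c(0.1, -0.2, 0.3))
  out <- apply_calibration(seq, tf)
  p <- seq$positions[4, 7, ]
  expect_equal(out$positions[4, 7, ], as.numeric(R90 %*% p) + tf$translation,
               tolerance = 1e-12)

  back <- apply_calibration(out, invert_transform(tf))
  expect_lt(max(abs(back$positions - seq$positions)), 1e-9)
})

test_that("calibration is rigid: inter-joint distances are preserved", {
  walk <- fixture_walk()$sequence
  ang <- stats::runif(3, -pi, pi)
  Rz <- matrix(c(cos(ang[1]), sin(ang[1]), 0,
                 -sin(ang[1]), cos(ang[1]), 0, 0, 0, 1), 3, 3)
  tf <- rigid_transform(Rz, c(1, 2, 3))
  out <- apply_calibration(walk, tf)
  d0 <- dist(walk$positions[5, , ])
  d1 <- dist(out$positions[5, , ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("non-orthonormal rotations are rejected", {
  expect_error(rigid_transform(diag(3) * 1.01, c(0, 0, 0)), "orthonormal")
  flip <- diag(c(-1, 1, 1))   # determinant -1
  expect_error(rigid_transform(flip, c(0, 0, 0)), "determinant")
})

test_that("mirror_lr is an involution that swaps sides and keeps rigidity", {
  walk <- fixture_walk()
  ex <- gait_example(walk$sequence, "S1", 1L)
  m1 <- mirror_lr(ex)
  expect_true(m1$mirrored)
  expect_identical(m1$subject_id, "S1")
  m2 <- mirror_lr(m1)
  expect_false(m2$mirrored)
  expect_equal(m2$sequence$positions, ex$sequence$positions)

  la_out <- joint_track(m1$sequence, "ANKLE_L")
  ra_in <- joint_track(ex$sequence, "ANKLE_R")
  expect_equal(la_out[, 1], -ra_in[, 1])
  expect_equal(la_out[, 2:3], ra_in[, 2:3])

  # reflection is an isometry up to the left/right relabeling
  js <- ex$sequence$joints
  perm <- seq_len(n_joints(js))
  li <- match(js$lr_pairs[, 1], js$names)
  ri <- match(js$lr_pairs[, 2], js$names)
  perm[li] <- ri
  perm[ri] <- li
  d0 <- as.matrix(dist(ex$sequence$positions[10, , ]))
  d1 <- as.matrix(dist(m1$sequence$positions[10, , ]))
  expect_lt(max(abs(d0[perm, perm] - d1)), 1e-9)
})

test_that("windowing keeps the frames immediately before the tail", {
  seq <- fixture_linear_sequence(120)
  w <- window_sequence(seq, 100, 10)
  expect_equal(n_frames(w), 100)
  # frames 10..109 in 0-based indexing = rows 11..110
  expect_equal(w$positions, seq$positions[11:110, , , drop = FALSE])

  expect_equal(window_sequence(seq, 120, 0)$positions, seq$positions)

  seq90 <- fixture_linear_sequence(90)
  w2 <- window_sequence(seq90, 80, 10)
  expect_equal(w2$positions, seq90$positions[1:80, , , drop = FALSE])

  err <- expect_error(window_sequence(seq90, 100, 10), "110")
})

test_that("windowed length always equals the window", {
  for (case in list(c(95, 60, 10), c(61, 60, 1), c(200, 100, 10))) {
    seq <- fixture_linear_sequence(case[1])
    expect_equal(n_frames(window_sequence(seq, case[2], case[3])), case[2])
  }
})

test_that("short-sequence filtering keeps exactly the long-enough walks", {
  lens <- c(100, 85, 95)
  exs <- lapply(seq_along(lens), function(i) {
    gait_example(fixture_linear_sequence(lens[i]), "S1", 1L, i)
  })
  ds <- gait_dataset(exs, c("a", "b"))
  expect_message(out <- filter_short_sequences(ds, 90), "removed 1")
  expect_equal(length(out$examples), 2)
  expect_equal(vapply(out$examples, function(e) n_frames(e$sequence),
                      integer(1)), c(100L, 95L))

  expect_silent(all_keep <- filter_short_sequences(ds, 50))
  expect_equal(length(all_keep$examples), 3)
})

test_that("filter size matches a brute-force count on random fixtures", {
  withr::local_seed(42)
  for (rep in 1:5) {
    lens <- sample(60:120, 20, replace = TRUE)
    exs <- lapply(seq_along(lens), function(i) {
      gait_example(fixture_linear_sequence(lens[i]), "S1", 1L, i)
    })
    ds <- gait_dataset(exs, c("a", "b"))
    m <- sample(70:110, 1)
    out <- suppressMessages(filter_short_sequences(ds, m))
    expect_equal(length(out$examples), sum(lens >= m))
  }
})

test_that("dataset manifests round-trip", {
  ds <- fixture_tiny_dataset(n_subjects = 2, mirror = TRUE)
  dir <- withr::local_tempdir()
  man <- save_gait_dataset(ds, dir)
  back <- load_gait_dataset(man, class_names = ds$class_names)
  expect_equal(length(back$examples), length(ds$examples))
  expect_equal(dataset_labels(back), dataset_labels(ds))
  expect_equal(dataset_subjects(back), dataset_subjects(ds))
  expect_equal(vapply(back$examples, function(e) e$mirrored, logical(1)),
               vapply(ds$examples, function(e) e$mirrored, logical(1)))
  expect_lt(max(abs(back$examples[[3]]$sequence$positions -
                    ds$examples[[3]]$sequence$positions)), 1e-9)
})
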