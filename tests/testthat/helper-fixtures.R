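# Shared fixtures: everything is generated in code at test time.

fixture_subject <- function(seed = 5) subject_profile("S1", seed)

# one deterministic zero-noise normal walk, cached per session
fixture_walk <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_walk(gait_style("normal"), fixture_subject(),
                              n_frames = 110, fps = 30, seed = 7,
                              noise_sd = 0)
    }
    cache
  }
})

# hand-built skeleton sequence with every joint at a fixed offset of a
# moving pelvis; useful for I/O and windowing tests
fixture_linear_sequence <- function(T_ = 12, fps = 30) {
  js <- default_joint_set()
  N <- n_joints(js)
  pos <- array(0, dim = c(T_, N, 3))
  for (j in seq_len(N)) {
    pos[, j, 1] <- 0.01 * j
    pos[, j, 2] <- 1 + 0.02 * j
    pos[, j, 3] <- (seq_len(T_) - 1) * 0.03 + 0.001 * j
  }
  skeleton_sequence(js, pos, fps)
}

# tiny three-joint chain joint set (A - B - C), pelvis role at the end
fixture_chain_joints <- function() {
  joint_set(
    names = c("A", "B", "C"),
    roles = c(PELVIS = "A", HEAD = "C", HIP_L = "A", HIP_R = "A",
              KNEE_L = "B", KNEE_R = "B", ANKLE_L = "C", ANKLE_R = "C",
              FOOT_L = "C", FOOT_R = "C"),
    bones = rbind(c("A", "B"), c("B", "C")),
    lr_pairs = matrix(character(0), ncol = 2)
  )
}

# small labeled dataset for split/evaluation tests (no simulation cost)
fixture_tiny_dataset <- function(n_subjects = 4, n_walks = 2, T_ = 12,
                                 mirror = FALSE) {
  seqs <- list()
  k <- 0L
  for (s in seq_len(n_subjects)) {
    for (w in seq_len(n_walks)) {
      k <- k + 1L
      ex <- gait_example(fixture_linear_sequence(T_), sprintf("S%02d", s),
                        gait_label = 1L + (s + w) %% 2L, walk_index = w)
      seqs[[length(seqs) + 1L]] <- ex
      if (mirror) seqs[[length(seqs) + 1L]] <- mirror_lr(ex)
    }
  }
  gait_dataset(seqs, c("healthy", "disorder"))
}
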