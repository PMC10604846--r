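#' Standard synthetic benchmark
#'
#' The package's end-to-end evaluation at desk scale: a reduced
#' simulated dataset (6 subjects x 6 gait classes x 5 walks, mirrored
#' to 360 examples, ~3 s walks), network inputs windowed to 60 frames,
#' the reduced model configuration ([hybrid_config_small()]), 30
#' training epochs with Adam at learning rate 2e-3, and
#' leave-one-subject-out cross-validation. Four input configurations
#' are trained: each branch alone and all three together. The
#' benchmark schedule is short (30 epochs of 6 minibatches), so it
#' uses a higher learning rate than the package default together with
#' gradient-norm clipping.
#'
#' @param seed master seed for data generation and training.
#' @param epochs training epochs per fold.
#' @param lr Adam learning rate.
#' @param n_subjects,n_walks dataset scale overrides.
#' @param window network input length in frames.
#' @param verbose print progress messages?
#' @return list with `table` (accuracy per input configuration, %),
#'   `three_input_accuracy` (pooled LOSO, %), `single_accuracies`
#'   (named, %), and `confusion` for the three-input model.
#' @export
standard_benchmark <- function(seed = 1, epochs = 30, lr = 1e-2,
                               n_subjects = 6, n_walks = 5, window = 60,
                               verbose = FALSE) {
  spec <- sim_spec(n_subjects = n_subjects, n_walks = n_walks,
                   frames_range = c(90, 110), seed = seed,
                   mirror_augment = TRUE)
  ds <- generate_dataset(spec)
  views <- prepare_views(ds, window = window, tail_drop = 10)
  plan <- loso_split(ds)
  cfg <- hybrid_config_small(length(ds$class_names),
                             seed = .derive_seed(seed, 77L))
  opts <- train_options(epochs = epochs, lr = lr, clip_norm = 1,
                        seed = .derive_seed(seed, 78L))
  graph <- build_joint_graph(default_joint_set())
  combos <- list(c("params"), c("angles"), c("skeleton"),
                 c("params", "angles", "skeleton"))
  rows <- vector("list", length(combos))
  confusion <- NULL
  for (ci in seq_along(combos)) {
    cfg_i <- cfg
    cfg_i$branches <- combos[[ci]]
    if (verbose) {
      message("benchmark: training [", paste(combos[[ci]], collapse = "+"),
              "]")
    }
    res <- run_cross_validation(views, plan, cfg_i, opts, graph)
    rows[[ci]] <- data.frame(
      inputs = paste(combos[[ci]], collapse = "+"),
      n_inputs = length(combos[[ci]]),
      accuracy = 100 * res$accuracy,
      mean_fold_acc = 100 * mean(res$fold_acc),
      sd_fold_acc = 100 * stats::sd(res$fold_acc)
    )
    if (length(combos[[ci]]) == 3L) confusion <- res$confusion
  }
  tab <- do.call(rbind, rows)
  singles <- tab$accuracy[tab$n_inputs == 1]
  names(singles) <- tab$inputs[tab$n_inputs == 1]
  list(table = tab,
       three_input_accuracy = tab$accuracy[tab$n_inputs == 3],
       single_accuracies = singles,
       confusion = confusion)
}
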