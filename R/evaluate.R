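#' Subject-disjoint cross-validation and classification metrics
#'
#' Folds are always built at the subject level so that no walker
#' contributes examples to both sides of a split; mirrored copies
#' carry their source subject's id and therefore always travel with
#' it.
#'
#' @name evaluation
NULL

#' Leave-one-subject-out fold plan
#'
#' @param ds a `gait_dataset` with at least two subjects.
#' @return a `fold_plan`: list of folds, each with `train_subjects`
#'   and `test_subjects`; attributes `protocol` and `subjects`.
#' @export
loso_split <- function(ds) {
  subs <- unique(dataset_subjects(ds))
  if (length(subs) < 2L) stop("need at least 2 subjects for LOSO")
  folds <- lapply(subs, function(s) {
    list(train_subjects = setdiff(subs, s), test_subjects = s)
  })
  structure(folds, class = "fold_plan", protocol = "loso", subjects = subs)
}

#' K-fold subject-level plan
#'
#' Subjects are shuffled with the given seed and dealt into `k`
#' near-equal folds.
#'
#' @param ds a `gait_dataset`.
#' @param k number of folds (>= 2, <= number of subjects).
#' @param seed shuffle seed.
#' @return a `fold_plan`.
#' @export
kfold_split <- function(ds, k = 5, seed = 1) {
  if (k < 2L) stop("k must be >= 2")
  subs <- unique(dataset_subjects(ds))
  if (length(subs) < k) stop("fewer subjects than folds")
  old_seed <- .Random.seed_get()
  on.exit(.Random.seed_set(old_seed))
  set.seed(seed)
  shuffled <- sample(subs)
  assign_fold <- rep_len(seq_len(k), length(subs))
  folds <- lapply(seq_len(k), function(i) {
    test <- shuffled[assign_fold == i]
    list(train_subjects = setdiff(subs, test), test_subjects = test)
  })
  structure(folds, class = "fold_plan", protocol = "kfold",
            subjects = subs, seed = seed)
}

#' Confusion matrix
#'
#' @param y_true,y_pred integer class labels in 1..C.
#' @param C class count.
#' @return C x C integer matrix; entry (i, j) counts true class i
#'   predicted as class j.
#' @export
confusion_matrix <- function(y_true, y_pred, C) {
  stopifnot(length(y_true) == length(y_pred))
  if (any(y_true < 1 | y_true > C) || any(y_pred < 1 | y_pred > C)) {
    stop("label out of range 1..", C)
  }
  m <- matrix(0L, C, C)
  for (i in seq_along(y_true)) {
    m[y_true[i], y_pred[i]] <- m[y_true[i], y_pred[i]] + 1L
  }
  m
}

#' Binary classification metrics from confusion counts
#'
#' Percentages: accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), precision = TP/(TP+FP). A metric whose
#' denominator is zero is returned as `NA` (undefined), never as 0.
#'
#' @param TP,FP,TN,FN nonnegative counts. Alternatively pass a list
#'   with those fields as `TP`.
#' @return named numeric vector (percent): `accuracy`, `sensitivity`,
#'   `specificity`, `precision`.
#' @export
binary_metrics <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (is.list(TP)) {
    cc <- TP
    TP <- cc$TP; FP <- cc$FP; TN <- cc$TN; FN <- cc$FN
  }
  counts <- c(TP, FP, TN, FN)
  if (any(counts < 0)) stop("negative confusion count")
  total <- TP + FP + TN + FN
  safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(accuracy = safe(TP + TN, total),
    sensitivity = safe(TP, TP + FN),
    specificity = safe(TN, TN + FP),
    precision = safe(TP, TP + FP))
}

#' Round half-up to 2 decimals for display
#' @param x numeric.
#' @return numeric rounded half-up to 2 decimals.
#' @export
round_display <- function(x) floor(x * 100 + 0.5) / 100

.example_indices <- function(views, subjects) {
  which(views$subjects %in% subjects)
}

# inner validation subjects: ~10% of the training subjects (at least 1)
.val_subjects <- function(train_subjects, seed) {
  old_seed <- .Random.seed_get()
  on.exit(.Random.seed_set(old_seed))
  set.seed(seed)
  n_val <- max(1L, round(0.1 * length(train_subjects)))
  sample(train_subjects, n_val)
}

#' Run cross-validation for one model configuration
#'
#' Trains one model per fold (validation = 10% of the fold's training
#' subjects, for early stopping) and pools test predictions across
#' folds.
#'
#' @param views a `model_views` list.
#' @param plan a `fold_plan`.
#' @param config a `hybrid_config` (its `seed` is re-derived per fold).
#' @param opts a `train_options`.
#' @param graph optional `joint_graph` shared across folds.
#' @return list with pooled `y_true`, `y_pred`, `confusion`,
#'   `accuracy` (pooled, fraction), `fold_acc` (per-fold fractions).
#' @export
run_cross_validation <- function(views, plan, config,
                                 opts = train_options(), graph = NULL) {
  y_true <- integer(0)
  y_pred <- integer(0)
  fold_acc <- numeric(length(plan))
  for (fi in seq_along(plan)) {
    fold <- plan[[fi]]
    val_sub <- .val_subjects(fold$train_subjects, opts$seed + fi)
    tr_idx <- .example_indices(views, setdiff(fold$train_subjects, val_sub))
    va_idx <- .example_indices(views, val_sub)
    te_idx <- .example_indices(views, fold$test_subjects)
    cfg <- config
    cfg$seed <- .derive_seed(config$seed, fi)
    m <- hybrid_model(cfg, graph)
    fold_opts <- opts
    fold_opts$seed <- .derive_seed(opts$seed, fi, 7L)
    m <- train_hybrid(m, views, tr_idx, va_idx, fold_opts)
    pred <- predict_hybrid(m, views, te_idx)
    y_true <- c(y_true, views$labels[te_idx])
    y_pred <- c(y_pred, pred$class)
    fold_acc[fi] <- mean(pred$class == views$labels[te_idx])
  }
  cm <- confusion_matrix(y_true, y_pred, config$n_classes)
  list(y_true = y_true, y_pred = y_pred, confusion = cm,
       accuracy = sum(diag(cm)) / sum(cm), fold_acc = fold_acc)
}

.branch_combos <- list(
  c("params"), c("angles"), c("skeleton"),
  c("params", "angles"), c("params", "skeleton"),
  c("angles", "skeleton"),
  c("params", "angles", "skeleton")
)

#' Input-combination ablation
#'
#' Re-trains the model with every combination of the three input
#' branches (3 single, 3 pairs, 1 triple) under the same fold plan and
#' reports pooled accuracy (and binary metrics when `C == 2`, with
#' class 2 treated as the positive/disorder class).
#'
#' @param views a `model_views` list.
#' @param plan a `fold_plan`.
#' @param config a `hybrid_config` template.
#' @param opts a `train_options`.
#' @param graph optional shared `joint_graph`.
#' @param combos list of branch combinations (defaults to all 7).
#' @return data frame: one row per combination with `inputs`,
#'   `n_inputs`, `accuracy` (%), and for binary tasks `sensitivity`,
#'   `specificity`, `precision` (%), plus `mean_fold_acc` (%).
#' @export
run_ablation <- function(views, plan, config, opts = train_options(),
                         graph = NULL, combos = .branch_combos) {
  rows <- vector("list", length(combos))
  for (ci in seq_along(combos)) {
    cfg <- config
    cfg$branches <- combos[[ci]]
    res <- tryCatch(
      run_cross_validation(views, plan, cfg, opts, graph),
      error = function(e) {
        stop("ablation configuration [",
             paste(combos[[ci]], collapse = "+"), "] failed: ",
             conditionMessage(e))
      }
    )
    row <- data.frame(
      inputs = paste(combos[[ci]], collapse = "+"),
      n_inputs = length(combos[[ci]]),
      accuracy = 100 * res$accuracy,
      mean_fold_acc = 100 * mean(res$fold_acc)
    )
    if (config$n_classes == 2) {
      cm <- res$confusion    # positive class = 2 (disorder)
      bm <- binary_metrics(TP = cm[2, 2], FP = cm[1, 2],
                           TN = cm[1, 1], FN = cm[2, 1])
      row$sensitivity <- bm[["sensitivity"]]
      row$specificity <- bm[["specificity"]]
      row$precision <- bm[["precision"]]
    }
    rows[[ci]] <- row
  }
  do.call(rbind, rows)
}
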