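#' Training options
#'
#' @param batch_size minibatch size (50 by default).
#' @param epochs maximum training epochs (200 by default).
#' @param patience early-stopping patience in epochs (validation loss;
#'   best weights are restored).
#' @param lr Adam learning rate.
#' @param lr_decay cosine-decay the learning rate to ~0 over `epochs`
#'   (off by default).
#' @param clip_norm global gradient-norm clip (`Inf` disables). Keeps
#'   high learning rates stable on the recurrent and graph branches.
#' @param weight_decay optimizer-level decoupled weight decay (kept 0
#'   by default; the explicit L2 term in the loss handles
#'   regularization).
#' @param seed integer seed governing shuffling and dropout.
#' @param verbose print per-epoch progress?
#' @return a `train_options` list.
#' @export
train_options <- function(batch_size = 50, epochs = 200, patience = 20,
                         lr = 1e-3, lr_decay = FALSE, clip_norm = 5,
                         weight_decay = 0, seed = 1, verbose = FALSE) {
  stopifnot(batch_size >= 1, epochs >= 1, patience >= 1, lr > 0,
            weight_decay >= 0, clip_norm > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patience = as.integer(patience), lr = lr,
                 lr_decay = isTRUE(lr_decay), clip_norm = clip_norm,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 verbose = verbose),
            class = "train_options")
}

.clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

#' Precompute the three model input views of a dataset
#'
#' For every example: the windowed skeleton tensor (3, window, V),
#' expressed relative to the pelvis at every frame (the standard
#' root-centering of skeleton action recognition; global progression
#' is carried by the gait parameters instead); the windowed
#' joint-angle matrix; and the gait-parameter vector computed from the
#' full (unwindowed) sequence. Examples whose sequences are shorter
#' than `window + tail_drop` are rejected.
#'
#' @param ds a `gait_dataset`.
#' @param window network input length in frames.
#' @param tail_drop trailing frames to discard before windowing.
#' @param angle_config angle configuration for the LSTM view.
#' @return a `model_views` list: `skel` (3, window, V, n) array, `ang`
#'   (A, window, n) array, `par` (P, n) matrix, `labels`, `subjects`,
#'   `n`.
#' @export
prepare_views <- function(ds, window = 100, tail_drop = 10,
                          angle_config = default_angle_config()) {
  n <- length(ds$examples)
  stopifnot(n > 0)
  V <- n_joints(ds$examples[[1]]$sequence$joints)
  A <- n_angles(angle_config)
  skel <- array(0, dim = c(3, window, V, n))
  ang <- array(0, dim = c(A, window, n))
  par <- NULL
  for (i in seq_len(n)) {
    e <- ds$examples[[i]]
    w <- window_sequence(e$sequence, window, tail_drop)
    pos <- w$positions                       # (T, V, 3)
    pel <- pos[, joint_index(w$joints, "PELVIS"), ]  # (T, 3)
    pos <- pos - aperm(array(pel, dim = c(window, 3, dim(pos)[2])),
                       c(1, 3, 2))
    skel[, , , i] <- aperm(pos, c(3, 1, 2))
    ang[, , i] <- t(extract_angle_matrix(w, angle_config))
    gp <- extract_gait_parameters(e$sequence)
    if (is.null(par)) par <- matrix(0, length(gp), n)
    par[, i] <- gp
  }
  list(skel = skel, ang = ang, par = par,
       labels = dataset_labels(ds), subjects = dataset_subjects(ds),
       n = n)
}

.views_subset <- function(views, idx) {
  list(skel = views$skel[, , , idx, drop = FALSE],
       ang = views$ang[, , idx, drop = FALSE],
       par = views$par[, idx, drop = FALSE])
}

.l2_penalty <- function(m) {
  if (m$cfg$lambda <= 0) return(0)
  m$cfg$lambda / 2 *
    sum(vapply(model_weights(m), function(w) sum(w^2), numeric(1)))
}

# One Adam update in place; st holds first/second moments and step count.
.adam_step <- function(params, grads, st, lr, wd) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  st$t <- st$t + 1L
  corr1 <- 1 - b1^st$t
  corr2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(params[[nm]])) next
    if (wd > 0) g <- g + wd * params[[nm]]
    if (is.null(st$m[[nm]])) {
      st$m[[nm]] <- g * 0
      st$v[[nm]] <- g * 0
    }
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / corr1) / (sqrt(st$v[[nm]] / corr2) + eps)
  }
  list(params = params, st = st)
}

#' Train a hybrid model
#'
#' Minibatch Adam on cross-entropy + L2, with early stopping on the
#' validation loss (best-epoch weights restored). Deterministic for a
#' fixed `opts$seed`.
#'
#' @param m a `hybrid_model` (modified in place and returned).
#' @param views a `model_views` list from [prepare_views()].
#' @param train_idx,val_idx integer example indices for the training
#'   and validation splits.
#' @param opts a `train_options`.
#' @return the model, with `m$history` set to a per-epoch data frame
#'   (train/validation loss and accuracy).
#' @export
train_hybrid <- function(m, views, train_idx, val_idx,
                         opts = train_options()) {
  stopifnot(inherits(m, "hybrid_model"))
  if (length(train_idx) == 0L || length(val_idx) == 0L) {
    stop("empty train or validation split")
  }
  old_seed <- .Random.seed_get()
  on.exit(.Random.seed_set(old_seed))
  set.seed(opts$seed)

  adam <- list(t = 0L, m = list(), v = list())
  labels <- views$labels
  best <- list(acc = -Inf, loss = Inf, params = NULL, state = NULL,
               epoch = 0L)
  hist <- vector("list", opts$epochs)
  n_tr <- length(train_idx)

  for (epoch in seq_len(opts$epochs)) {
    lr_t <- if (opts$lr_decay) {
      opts$lr * 0.5 * (1 + cos(pi * (epoch - 1) / opts$epochs))
    } else {
      opts$lr
    }
    ord <- sample(train_idx)
    ep_loss <- 0
    ep_hits <- 0
    for (start in seq(1, n_tr, by = opts$batch_size)) {
      idx <- ord[start:min(start + opts$batch_size - 1L, n_tr)]
      bviews <- .views_subset(views, idx)
      fw <- .forward(m, bviews, train = TRUE)
      bl <- labels[idx]
      # objective: mean cross-entropy + lambda/2 ||W||^2 (penalty not
      # averaged over the batch, matching the analytic gradients)
      loss <- cross_entropy_loss(bl, fw$probs, 0) / length(idx) +
        .l2_penalty(m)
      grads <- .backward(m, bviews, fw$cache, bl)
      grads <- .clip_gradients(grads, opts$clip_norm)
      upd <- .adam_step(m$params, grads, adam, lr_t, opts$weight_decay)
      m$params <- upd$params
      adam <- upd$st
      ep_loss <- ep_loss + loss * length(idx)
      ep_hits <- ep_hits + sum(apply(fw$probs, 2, which.max) == bl)
    }
    val <- .evaluate_split(m, views, val_idx)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = ep_loss / n_tr,
      train_acc = ep_hits / n_tr,
      val_loss = val$loss, val_acc = val$acc
    )
    if (opts$verbose) {
      message(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f",
                      epoch, ep_loss / n_tr, ep_hits / n_tr,
                      val$loss, val$acc))
    }
    # model selection on validation accuracy (validation folds can be a
    # single subject, whose loss is noisy); loss breaks ties
    improved <- val$acc > best$acc + 1e-9 ||
      (abs(val$acc - best$acc) <= 1e-9 && val$loss < best$loss - 1e-9)
    if (improved) {
      best <- list(acc = val$acc, loss = val$loss, params = m$params,
                   state = m$state, epoch = epoch)
    } else if (epoch - best$epoch >= opts$patience) {
      break
    }
  }
  if (!is.null(best$params)) {
    m$params <- best$params
    m$state <- best$state
  }
  m$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  m
}

.evaluate_split <- function(m, views, idx, chunk = 200L) {
  loss <- 0
  hits <- 0
  for (start in seq(1, length(idx), by = chunk)) {
    sub <- idx[start:min(start + chunk - 1L, length(idx))]
    fw <- .forward(m, .views_subset(views, sub), train = FALSE)
    bl <- views$labels[sub]
    loss <- loss + cross_entropy_loss(bl, fw$probs, 0)
    hits <- hits + sum(apply(fw$probs, 2, which.max) == bl)
  }
  list(loss = loss / length(idx), acc = hits / length(idx))
}

#' Predict gait classes
#'
#' Inference mode: dropout off, batch normalization using running
#' statistics; deterministic.
#'
#' @param m a trained `hybrid_model`.
#' @param views a `model_views` list.
#' @param idx indices of the examples to classify (default all).
#' @return list with `class` (1-based indices) and `probs`
#'   (C x n matrix).
#' @export
predict_hybrid <- function(m, views, idx = seq_len(views$n)) {
  for (br in m$cfg$branches) {
    key <- c(skeleton = "skel", angles = "ang", params = "par")[[br]]
    if (is.null(views[[key]])) stop("missing input view for branch ", br)
  }
  probs <- NULL
  for (start in seq(1, length(idx), by = 200L)) {
    sub <- idx[start:min(start + 199L, length(idx))]
    fw <- .forward(m, .views_subset(views, sub), train = FALSE)
    probs <- cbind(probs, fw$probs)
  }
  list(class = apply(probs, 2, which.max), probs = probs)
}
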