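#' Hybrid three-branch gait classifier
#'
#' The model encodes three views of one walk: the raw skeleton
#' sequence through a stack of spatial-temporal graph-convolution
#' blocks, the joint-angle sequence through a multilayer LSTM, and the
#' gait-parameter vector through a single fully connected layer. The
#' branch features are concatenated, batch-normalized, passed through
#' dropout and a final affine layer, and turned into class
#' probabilities by softmax. Training minimizes cross-entropy plus an
#' L2 penalty on the weight matrices. All forward and reverse passes
#' are exact (hand-derived) so seeded training is bit-reproducible on
#' one device.
#'
#' @name hybrid_model
NULL

#' Model configuration
#'
#' Defaults follow the reference configuration: ten ST-GCN blocks with
#' channel plan 64x4, 128x3, 256x3 and kernel (9, 3) (temporal stride
#' 2 at the channel-doubling blocks), a four-layer LSTM with 128
#' hidden units feeding a 16-unit fully connected layer, a 16-unit
#' parameter encoder, dropout 0.5 before the classification layer.
#'
#' @param n_classes number of gait classes C (>= 2).
#' @param skeleton_channels output channels per ST-GCN block.
#' @param skeleton_strides temporal stride per block.
#' @param temporal_kernel temporal kernel size Gamma (odd).
#' @param skeleton_out skeleton feature size (f_S length).
#' @param residual use residual connections inside blocks.
#' @param lstm_layers,lstm_hidden LSTM depth and width.
#' @param angle_dim angle-sequence feature count (25 by default).
#' @param angle_out angle feature size (f_A length).
#' @param angle_scale multiplier applied to angle inputs (degrees are
#'   divided by 100 so inputs sit in roughly [0, 2]).
#' @param param_dim gait-parameter vector length.
#' @param param_out parameter feature size (f_P length).
#' @param dropout dropout ratio before the classification layer.
#' @param lambda L2 regularization weight.
#' @param branches active input branches, subset of
#'   `c("skeleton", "angles", "params")`.
#' @param seed integer seed for weight initialization.
#' @return a `hybrid_config` list.
#' @export
hybrid_config <- function(n_classes,
                          skeleton_channels = c(64, 64, 64, 64, 128, 128,
                                                128, 256, 256, 256),
                          skeleton_strides = c(1, 1, 1, 1, 2, 1, 1, 2, 1, 1),
                          temporal_kernel = 9,
                          skeleton_out = 64,
                          residual = TRUE,
                          lstm_layers = 4, lstm_hidden = 128,
                          angle_dim = 25, angle_out = 16,
                          angle_scale = 1 / 100,
                          param_dim = 26, param_out = 16,
                          dropout = 0.5, lambda = 1e-4,
                          branches = c("skeleton", "angles", "params"),
                          seed = 1) {
  if (n_classes < 2) stop("need at least 2 classes")
  if (length(branches) == 0L) {
    stop("configuration error: all branches deactivated")
  }
  branches <- match.arg(branches, c("skeleton", "angles", "params"),
                        several.ok = TRUE)
  stopifnot(length(skeleton_channels) == length(skeleton_strides),
            temporal_kernel %% 2 == 1, dropout >= 0, dropout < 1,
            lambda >= 0)
  structure(list(
    n_classes = as.integer(n_classes),
    skeleton_channels = skeleton_channels,
    skeleton_strides = skeleton_strides,
    temporal_kernel = as.integer(temporal_kernel),
    skeleton_out = as.integer(skeleton_out), residual = residual,
    lstm_layers = as.integer(lstm_layers),
    lstm_hidden = as.integer(lstm_hidden),
    angle_dim = as.integer(angle_dim), angle_out = as.integer(angle_out),
    angle_scale = angle_scale,
    param_dim = as.integer(param_dim), param_out = as.integer(param_out),
    dropout = dropout, lambda = lambda, branches = branches,
    seed = as.integer(seed)
  ), class = "hybrid_config")
}

#' Reduced configuration for desk-scale benchmarks
#'
#' A small channel plan (8, 16 with stride 2, 16) and a single 32-unit
#' LSTM layer: the same architecture family at a size that trains in
#' seconds per epoch on one CPU. Used by the package's synthetic
#' benchmark.
#'
#' @param n_classes number of classes.
#' @param ... overrides forwarded to [hybrid_config()].
#' @return a `hybrid_config`.
#' @export
hybrid_config_small <- function(n_classes, ...) {
  hybrid_config(n_classes,
                skeleton_channels = c(8, 16, 16),
                skeleton_strides = c(1, 2, 1),
                skeleton_out = 16,
                lstm_layers = 1, lstm_hidden = 32,
                ...)
}

.weight_param_pattern <- "^(gw|tw|rw|fsW|Wx|Wh|faW|fpW|headW)"

#' Instantiate a hybrid model
#'
#' @param config a `hybrid_config`.
#' @param graph a `joint_graph` (required when the skeleton branch is
#'   active).
#' @return a `hybrid_model` environment holding parameters, batch-norm
#'   state and the configuration.
#' @export
hybrid_model <- function(config, graph = NULL) {
  stopifnot(inherits(config, "hybrid_config"))
  if ("skeleton" %in% config$branches && is.null(graph)) {
    graph <- build_joint_graph(default_joint_set(),
                               gamma = config$temporal_kernel)
  }
  m <- new.env(parent = emptyenv())
  m$cfg <- config
  m$graph <- graph
  m$params <- list()
  m$state <- list()

  old_seed <- .Random.seed_get()
  on.exit(.Random.seed_set(old_seed))
  set.seed(config$seed)
  he <- function(dims, fan_in) {
    array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
  }
  p <- list()
  st <- list()

  if ("skeleton" %in% config$branches) {
    K <- graph$K
    cin <- 3
    p$bn0g <- rep(1, cin)
    p$bn0b <- numeric(cin)
    st$bn0 <- list(mean = numeric(cin), var = rep(1, cin))
    for (i in seq_along(config$skeleton_channels)) {
      cout <- config$skeleton_channels[i]
      G <- config$temporal_kernel
      p[[paste0("gw", i)]] <- he(c(cin, cout, K), cin * K)
      p[[paste0("tw", i)]] <- he(c(cout, cout, G), cout * G)
      p[[paste0("tb", i)]] <- numeric(cout)
      p[[paste0("bn1g", i)]] <- rep(1, cout)
      p[[paste0("bn1b", i)]] <- numeric(cout)
      p[[paste0("bn2g", i)]] <- rep(1, cout)
      p[[paste0("bn2b", i)]] <- numeric(cout)
      st[[paste0("bn1", i)]] <- list(mean = numeric(cout), var = rep(1, cout))
      st[[paste0("bn2", i)]] <- list(mean = numeric(cout), var = rep(1, cout))
      if (config$residual &&
          (cin != cout || config$skeleton_strides[i] != 1)) {
        p[[paste0("rw", i)]] <- he(c(cin, cout, 1), cin)
        p[[paste0("rb", i)]] <- numeric(cout)
      }
      cin <- cout
    }
    p$fsW <- he(c(config$skeleton_out, cin), cin)
    p$fsb <- numeric(config$skeleton_out)
  }

  if ("angles" %in% config$branches) {
    H <- config$lstm_hidden
    din <- config$angle_dim
    for (l in seq_len(config$lstm_layers)) {
      r <- 1 / sqrt(H)
      p[[paste0("Wx", l)]] <- matrix(stats::runif(4 * H * din, -r, r),
                                     4 * H, din)
      p[[paste0("Wh", l)]] <- matrix(stats::runif(4 * H * H, -r, r),
                                     4 * H, H)
      p[[paste0("lb", l)]] <- numeric(4 * H)
      din <- H
    }
    p$bnag <- rep(1, H)
    p$bnab <- numeric(H)
    st$bna <- list(mean = numeric(H), var = rep(1, H))
    p$faW <- he(c(config$angle_out, H), H)
    p$fab <- numeric(config$angle_out)
  }

  if ("params" %in% config$branches) {
    p$fpW <- he(c(config$param_out, config$param_dim), config$param_dim)
    p$fpb <- numeric(config$param_out)
  }

  fdim <- sum(c(skeleton = config$skeleton_out, angles = config$angle_out,
                params = config$param_out)[config$branches])
  p$bnhg <- rep(1, fdim)
  p$bnhb <- numeric(fdim)
  st$bnh <- list(mean = numeric(fdim), var = rep(1, fdim))
  p$headW <- he(c(config$n_classes, fdim), fdim)
  p$headb <- numeric(config$n_classes)

  m$params <- p
  m$state <- st
  m$fusion_dim <- fdim
  class(m) <- "hybrid_model"
  m
}

# --- batch norm over the first array dimension ------------------------------

.bn_eps <- 1e-5
.bn_momentum <- 0.1

.bn_forward <- function(x, g, b, state, train) {
  C <- length(g)
  n <- length(x) / C
  if (train) {
    res <- bn_train_forward(x, C, g, b, .bn_eps)
    state$mean <- (1 - .bn_momentum) * state$mean + .bn_momentum * res$mu
    state$var <- (1 - .bn_momentum) * state$var +
      .bn_momentum * res$var * n / max(1, n - 1)
    list(y = res$y,
         cache = list(xhat = res$xhat, istd = res$istd, g = g),
         state = state)
  } else {
    y <- bn_eval_forward(x, C, g, b, state$mean, state$var, .bn_eps)
    list(y = y, cache = NULL, state = state)
  }
}

.bn_backward <- function(dy, cache) {
  bn_backward_cpp(dy, cache$xhat, cache$istd, cache$g)
}

.relu <- function(x) relu_forward(x)

# --- skeleton branch --------------------------------------------------------

.skel_forward <- function(m, x, train) {
  cfg <- m$cfg
  A <- m$graph$A
  caches <- list()
  # data batch norm over the three coordinate channels
  bn0 <- .bn_forward(x, m$params$bn0g, m$params$bn0b, m$state$bn0, train)
  m$state$bn0 <- bn0$state
  bn0_cache <- bn0$cache
  x <- bn0$y
  for (i in seq_along(cfg$skeleton_channels)) {
    p <- m$params
    stride <- cfg$skeleton_strides[i]
    xin <- x
    g <- gconv_forward(x, A, p[[paste0("gw", i)]])
    bn1 <- .bn_forward(g, p[[paste0("bn1g", i)]], p[[paste0("bn1b", i)]],
                       m$state[[paste0("bn1", i)]], train)
    m$state[[paste0("bn1", i)]] <- bn1$state
    r1 <- .relu(bn1$y)
    tc <- tconv_forward(r1, p[[paste0("tw", i)]], p[[paste0("tb", i)]],
                        stride)
    bn2 <- .bn_forward(tc, p[[paste0("bn2g", i)]], p[[paste0("bn2b", i)]],
                       m$state[[paste0("bn2", i)]], train)
    m$state[[paste0("bn2", i)]] <- bn2$state
    out <- bn2$y
    res <- NULL
    if (cfg$residual) {
      if (!is.null(p[[paste0("rw", i)]])) {
        res <- tconv_forward(xin, p[[paste0("rw", i)]],
                             p[[paste0("rb", i)]], stride)
      } else {
        res <- xin
      }
      out <- out + res
    }
    y <- .relu(out)
    caches[[i]] <- list(xin = xin, g = g, bn1 = bn1$cache, r1 = r1,
                        bn2 = bn2$cache, pre = out, stride = stride)
    x <- y
  }
  caches$bn0 <- bn0_cache
  d <- dim(x)                                 # (C, T', V, B)
  # global average pool over frames and joints, per channel and example
  pooled <- vapply(seq_len(d[4]), function(b) {
    rowMeans(matrix(x[, , , b], nrow = d[1]))
  }, numeric(d[1]))
  pooled <- matrix(pooled, nrow = d[1])       # (C, B)
  z <- m$params$fsW %*% pooled + m$params$fsb
  fS <- .relu(z)
  list(fS = fS, caches = caches, pooled = pooled, z = z, outdim = d)
}

.skel_backward <- function(m, fwd, dfS) {
  cfg <- m$cfg
  A <- m$graph$A
  grads <- list()
  dz <- dfS * (fwd$z > 0)
  grads$fsW <- dz %*% t(fwd$pooled)
  grads$fsb <- rowSums(dz)
  dpooled <- t(m$params$fsW) %*% dz           # (C, B)
  d <- fwd$outdim
  ntv <- d[2] * d[3]
  dx <- array(0, dim = d)
  for (b in seq_len(d[4])) {
    dx[, , , b] <- array(rep(dpooled[, b] / ntv, ntv), dim = d[1:3])
  }
  for (i in rev(seq_along(cfg$skeleton_channels))) {
    cc <- fwd$caches[[i]]
    p <- m$params
    dout <- relu_backward(dx, cc$pre)
    dres <- NULL
    if (cfg$residual) {
      if (!is.null(p[[paste0("rw", i)]])) {
        rb <- tconv_backward(cc$xin, p[[paste0("rw", i)]], dout, cc$stride)
        grads[[paste0("rw", i)]] <- rb$dW
        grads[[paste0("rb", i)]] <- rb$db
        dres <- rb$dX
      } else {
        dres <- dout
      }
    }
    bn2 <- .bn_backward(dout, cc$bn2)
    grads[[paste0("bn2g", i)]] <- bn2$dg
    grads[[paste0("bn2b", i)]] <- bn2$db
    tb <- tconv_backward(cc$r1, p[[paste0("tw", i)]], bn2$dx, cc$stride)
    grads[[paste0("tw", i)]] <- tb$dW
    grads[[paste0("tb", i)]] <- tb$db
    dr1 <- relu_backward(tb$dX, cc$r1)
    bn1 <- .bn_backward(dr1, cc$bn1)
    grads[[paste0("bn1g", i)]] <- bn1$dg
    grads[[paste0("bn1b", i)]] <- bn1$db
    gb <- gconv_backward(cc$xin, A, p[[paste0("gw", i)]], bn1$dx)
    grads[[paste0("gw", i)]] <- gb$dW
    dx <- gb$dX
    if (!is.null(dres)) dx <- dx + dres
  }
  bn0 <- .bn_backward(dx, fwd$caches$bn0)
  grads$bn0g <- bn0$dg
  grads$bn0b <- bn0$db
  grads
}

# --- angle branch -----------------------------------------------------------

.angle_forward <- function(m, xa, train) {
  cfg <- m$cfg
  layers <- list()
  x <- xa                                      # (D, T, B)
  for (l in seq_len(cfg$lstm_layers)) {
    out <- lstm_forward(x, m$params[[paste0("Wx", l)]],
                        m$params[[paste0("Wh", l)]],
                        m$params[[paste0("lb", l)]])
    layers[[l]] <- c(out, list(x = x))
    x <- out$H
  }
  d <- dim(x)                                  # (H, T, B)
  hT <- matrix(x[, d[2], ], nrow = d[1])       # last hidden state
  bn <- .bn_forward(hT, m$params$bnag, m$params$bnab, m$state$bna, train)
  m$state$bna <- bn$state
  z <- m$params$faW %*% bn$y + m$params$fab
  fA <- .relu(z)
  list(fA = fA, layers = layers, hT_dim = d, bn = bn$cache, z = z)
}

.angle_backward <- function(m, fwd, dfA) {
  cfg <- m$cfg
  grads <- list()
  dz <- dfA * (fwd$z > 0)
  bn_in <- fwd$bn
  y_bn <- bn_in$xhat * bn_in$g + m$params$bnab
  grads$faW <- dz %*% t(matrix(y_bn, nrow = length(m$params$bnag)))
  grads$fab <- rowSums(dz)
  dbn_y <- t(m$params$faW) %*% dz
  bnb <- .bn_backward(dbn_y, bn_in)
  grads$bnag <- bnb$dg
  grads$bnab <- bnb$db
  d <- fwd$hT_dim
  dH <- array(0, dim = d)
  dH[, d[2], ] <- bnb$dx
  for (l in rev(seq_len(cfg$lstm_layers))) {
    lay <- fwd$layers[[l]]
    back <- lstm_backward(lay$x, m$params[[paste0("Wx", l)]],
                          m$params[[paste0("Wh", l)]],
                          lay$H, lay$C, lay$gates, dH)
    grads[[paste0("Wx", l)]] <- back$dWx
    grads[[paste0("Wh", l)]] <- back$dWh
    grads[[paste0("lb", l)]] <- back$db
    dH <- back$dX
  }
  grads
}

# --- full forward / backward ------------------------------------------------

.forward <- function(m, views, train = FALSE) {
  cfg <- m$cfg
  cache <- list()
  feats <- list()
  if ("skeleton" %in% cfg$branches) {
    cache$skel <- .skel_forward(m, views$skel, train)
    feats$skeleton <- cache$skel$fS
  }
  if ("angles" %in% cfg$branches) {
    cache$ang <- .angle_forward(m, views$ang * cfg$angle_scale, train)
    feats$angles <- cache$ang$fA
  }
  if ("params" %in% cfg$branches) {
    z <- m$params$fpW %*% views$par + m$params$fpb
    cache$par <- list(z = z, x = views$par)
    feats$params <- .relu(z)
  }
  f <- do.call(rbind, feats[cfg$branches])
  bn <- .bn_forward(f, m$params$bnhg, m$params$bnhb, m$state$bnh, train)
  m$state$bnh <- bn$state
  h <- bn$y
  mask <- NULL
  if (train && cfg$dropout > 0) {
    mask <- (matrix(stats::runif(length(h)), nrow = nrow(h)) >=
               cfg$dropout) / (1 - cfg$dropout)
    h <- h * mask
  }
  logits <- m$params$headW %*% h + m$params$headb
  mx <- apply(logits, 2, max)
  el <- exp(sweep(logits, 2, mx))
  probs <- sweep(el, 2, colSums(el), "/")
  cache$head <- list(f = f, bn = bn$cache, h = h, mask = mask,
                     probs = probs)
  list(probs = probs, cache = cache)
}

.backward <- function(m, views, cache, labels) {
  cfg <- m$cfg
  B <- length(labels)
  probs <- cache$head$probs
  dlogits <- probs
  dlogits[cbind(labels, seq_len(B))] <-
    dlogits[cbind(labels, seq_len(B))] - 1
  dlogits <- dlogits / B
  grads <- list()
  grads$headW <- dlogits %*% t(cache$head$h)
  grads$headb <- rowSums(dlogits)
  dh <- t(m$params$headW) %*% dlogits
  if (!is.null(cache$head$mask)) dh <- dh * cache$head$mask
  bnb <- .bn_backward(dh, cache$head$bn)
  grads$bnhg <- bnb$dg
  grads$bnhb <- bnb$db
  df <- bnb$dx
  offset <- 0L
  sizes <- c(skeleton = cfg$skeleton_out, angles = cfg$angle_out,
             params = cfg$param_out)
  for (br in cfg$branches) {
    rows <- (offset + 1):(offset + sizes[[br]])
    dbr <- df[rows, , drop = FALSE]
    if (br == "skeleton") {
      grads <- c(grads, .skel_backward(m, cache$skel, dbr))
    } else if (br == "angles") {
      grads <- c(grads, .angle_backward(m, cache$ang, dbr))
    } else {
      dz <- dbr * (cache$par$z > 0)
      grads$fpW <- dz %*% t(cache$par$x)
      grads$fpb <- rowSums(dz)
    }
    offset <- offset + sizes[[br]]
  }
  # L2 penalty on weight matrices
  if (cfg$lambda > 0) {
    for (nm in names(m$params)) {
      if (grepl(.weight_param_pattern, nm)) {
        g <- grads[[nm]]
        if (is.null(g)) g <- 0
        grads[[nm]] <- g + cfg$lambda * m$params[[nm]]
      }
    }
  }
  grads
}

#' Cross-entropy loss with L2 penalty
#'
#' `-sum(y * log(yhat)) + lambda/2 * ||W||^2`, with predicted
#' probabilities clamped at 1e-12 before the logarithm. `weights` may
#' be a list of arrays (e.g. a model's weight matrices) entering the
#' penalty term.
#'
#' @param y_true one-hot vector/matrix (classes x examples) or integer
#'   class labels.
#' @param y_hat predicted probability vector/matrix (classes x
#'   examples).
#' @param lambda L2 weight.
#' @param weights list of numeric arrays to penalize.
#' @return scalar loss (summed over examples).
#' @export
cross_entropy_loss <- function(y_true, y_hat, lambda = 0, weights = NULL) {
  y_hat <- as.matrix(y_hat)
  if (!is.matrix(y_true) && length(y_true) != nrow(y_hat) * ncol(y_hat)) {
    yt <- matrix(0, nrow(y_hat), length(y_true))
    yt[cbind(as.integer(y_true), seq_along(y_true))] <- 1
    y_true <- yt
  }
  y_true <- as.matrix(y_true)
  if (!all(dim(y_true) == dim(y_hat))) {
    stop("class-count mismatch between y_true and y_hat")
  }
  ce <- -sum(y_true * log(pmax(y_hat, 1e-12)))
  pen <- if (lambda > 0 && length(weights) > 0) {
    lambda / 2 * sum(vapply(weights, function(w) sum(w^2), numeric(1)))
  } else 0
  ce + pen
}

#' Weight matrices of a model (for the L2 term)
#' @param m a `hybrid_model`.
#' @return named list of the trainable weight arrays (biases and batch
#'   norm parameters excluded).
#' @export
model_weights <- function(m) {
  m$params[grepl(.weight_param_pattern, names(m$params))]
}

# --- encoder-level wrappers (single example, inference mode) ----------------

.single <- function(x) {
  d <- dim(x)
  dim(x) <- c(d, 1L)
  x
}

#' Encode one skeleton sequence to f_S
#' @param m a `hybrid_model` with an active skeleton branch.
#' @param x numeric array (3, T, V): channels x frames x joints.
#' @return numeric feature vector of length `skeleton_out`.
#' @export
stgcn_encode <- function(m, x) {
  if (!"skeleton" %in% m$cfg$branches) stop("skeleton branch inactive")
  t_min <- prod(ifelse(m$cfg$skeleton_strides > 1,
                       m$cfg$skeleton_strides, 1))
  if (dim(x)[2] < t_min) {
    stop("sequence too short for temporal strides: need T >= ", t_min)
  }
  as.numeric(.skel_forward(m, .single(x), train = FALSE)$fS)
}

#' Encode one angle sequence to f_A
#' @param m a `hybrid_model` with an active angle branch.
#' @param xa numeric matrix (T x A) of angles in degrees.
#' @return numeric feature vector of length `angle_out`.
#' @export
lstm_encode <- function(m, xa) {
  if (!"angles" %in% m$cfg$branches) stop("angle branch inactive")
  if (ncol(xa) != m$cfg$angle_dim) {
    stop("angle dimension mismatch: got ", ncol(xa), ", expected ",
         m$cfg$angle_dim)
  }
  x <- .single(t(xa))                          # (A, T, 1)
  as.numeric(.angle_forward(m, x * m$cfg$angle_scale, train = FALSE)$fA)
}

#' Encode one gait-parameter vector to f_P
#' @param m a `hybrid_model` with an active parameter branch.
#' @param xp numeric vector of length `param_dim`.
#' @return numeric feature vector of length `param_out`.
#' @export
ann_encode <- function(m, xp) {
  if (!"params" %in% m$cfg$branches) stop("parameter branch inactive")
  if (length(xp) != m$cfg$param_dim) {
    stop("parameter length mismatch: got ", length(xp), ", expected ",
         m$cfg$param_dim)
  }
  as.numeric(.relu(m$params$fpW %*% xp + m$params$fpb))
}

#' Fuse encoder outputs and classify
#'
#' Concatenates the active branch features, applies inference-mode
#' batch normalization and the final affine + softmax layer.
#'
#' @param m a `hybrid_model`.
#' @param fS,fA,fP branch feature vectors (only those for active
#'   branches are used).
#' @return class-probability vector (sums to 1).
#' @export
fuse_and_classify <- function(m, fS = NULL, fA = NULL, fP = NULL) {
  feats <- list(skeleton = fS, angles = fA, params = fP)
  f <- unlist(feats[m$cfg$branches], use.names = FALSE)
  if (length(f) != m$fusion_dim) {
    stop("fused feature length ", length(f), " != ", m$fusion_dim)
  }
  st <- m$state$bnh
  xhat <- (f - st$mean) / sqrt(st$var + .bn_eps)
  h <- xhat * m$params$bnhg + m$params$bnhb
  logits <- as.numeric(m$params$headW %*% h + m$params$headb)
  e <- exp(logits - max(logits))
  e / sum(e)
}
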