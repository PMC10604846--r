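# -- joint graph -------------------------------------------------------------

test_that("a 3-joint chain partitions into self/centripetal/centrifugal", {
  g <- build_joint_graph(fixture_chain_joints(), max_hop = 1)
  expect_equal(g$K, 3)
  A <- g$A
  # subset 1: equal root distance (here only the self loops)
  expect_equal(A[, , 1] > 0, diag(3) > 0, ignore_attr = TRUE)
  # subset 2 (centripetal): edges pointing toward the root A
  expect_equal(which(A[, , 2] > 0, arr.ind = TRUE),
               cbind(row = c(1L, 2L), col = c(2L, 3L)), ignore_attr = TRUE)
  # subset 3 (centrifugal): away from the root
  expect_equal(which(A[, , 3] > 0, arr.ind = TRUE),
               cbind(row = c(2L, 3L), col = c(1L, 2L)), ignore_attr = TRUE)
})

test_that("subset supports tile A + I and normalization sums to one", {
  js <- default_joint_set()
  g <- build_joint_graph(js)
  V <- n_joints(js)
  support <- (g$A[, , 1] + g$A[, , 2] + g$A[, , 3]) > 0
  adj <- matrix(FALSE, V, V)
  bi <- cbind(match(js$bones[, 1], js$names), match(js$bones[, 2], js$names))
  adj[bi] <- TRUE
  adj[bi[, 2:1]] <- TRUE
  diag(adj) <- TRUE
  expect_equal(support, adj)
  # incoming weight per joint sums to 1 across subsets
  expect_equal(colSums(g$A[, , 1] + g$A[, , 2] + g$A[, , 3]), rep(1, V),
               tolerance = 1e-6)
})

test_that("disconnected bone graphs are rejected with their components", {
  js <- fixture_chain_joints()
  js$bones <- js$bones[1, , drop = FALSE]      # drop B-C
  expect_error(build_joint_graph(js), "disconnected")
})

# -- graph convolution vs dense oracle ---------------------------------------

test_that("graph convolution equals the dense matrix product on small graphs", {
  withr::local_seed(11)
  for (rep in 1:5) {
    V <- sample(3:5, 1)
    Cin <- sample(2:4, 1)
    Cout <- sample(2:5, 1)
    T_ <- 4
    B <- 2
    K <- 3
    A <- array(stats::runif(V * V * K), dim = c(V, V, K))
    W <- array(stats::rnorm(Cin * Cout * K), dim = c(Cin, Cout, K))
    x <- array(stats::rnorm(Cin * T_ * V * B), dim = c(Cin, T_, V, B))
    got <- graph_conv_apply(x, A, W)
    want <- array(0, dim = c(Cout, T_, V, B))
    for (b in 1:B) {
      for (t in 1:T_) {
        X <- matrix(x[, t, , b], Cin, V)       # joints as columns
        acc <- matrix(0, Cout, V)
        for (k in 1:K) {
          acc <- acc + t(W[, , k]) %*% X %*% A[, , k]
        }
        want[, t, , b] <- acc
      }
    }
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("relabeling joints together with the graph leaves f_S unchanged", {
  withr::local_seed(3)
  js <- default_joint_set()
  graph <- build_joint_graph(js)
  cfg <- hybrid_config_small(4, branches = "skeleton", seed = 8)
  m <- hybrid_model(cfg, graph)
  T_ <- 20
  V <- n_joints(js)
  x <- array(stats::rnorm(3 * T_ * V), dim = c(3, T_, V))
  f0 <- stgcn_encode(m, x)

  perm <- sample(V)
  m2 <- hybrid_model(cfg, graph)               # same seed, same weights
  m2$graph <- graph
  m2$graph$A <- graph$A[perm, perm, , drop = FALSE]
  f1 <- stgcn_encode(m2, x[, , perm, drop = FALSE])
  expect_lt(max(abs(f0 - f1)), 1e-5)
})

# -- branch encoders ---------------------------------------------------------

test_that("the default skeleton encoder emits a 64-vector on (3,100,N)", {
  js <- default_joint_set()
  cfg <- hybrid_config(6, branches = "skeleton", seed = 2)
  m <- hybrid_model(cfg, build_joint_graph(js))
  x <- array(stats::rnorm(3 * 100 * n_joints(js)),
             dim = c(3, 100, n_joints(js)))
  fS <- stgcn_encode(m, x)
  expect_length(fS, 64)
  expect_true(all(fS >= 0))

  expect_error(stgcn_encode(m, x[, 1:2, , drop = FALSE]), "too short")
})

test_that("LSTM forward matches a straight-line per-gate oracle", {
  withr::local_seed(13)
  D <- 3
  H <- 4
  T_ <- 6
  Wx <- matrix(stats::rnorm(4 * H * D, sd = 0.5), 4 * H, D)
  Wh <- matrix(stats::rnorm(4 * H * H, sd = 0.5), 4 * H, H)
  b <- stats::rnorm(4 * H, sd = 0.2)
  x <- array(stats::rnorm(D * T_), dim = c(D, T_, 1))
  out <- gaitfuse:::lstm_forward(x, Wx, Wh, b)

  sig <- function(z) 1 / (1 + exp(-z))
  h <- numeric(H)
  cc <- numeric(H)
  for (t in seq_len(T_)) {
    z <- Wx %*% x[, t, 1] + Wh %*% h + b
    i <- sig(z[1:H])
    f <- sig(z[(H + 1):(2 * H)])
    g <- tanh(z[(2 * H + 1):(3 * H)])
    o <- sig(z[(3 * H + 1):(4 * H)])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    expect_lt(max(abs(out$H[, t, 1] - h)), 1e-9)
    expect_lt(max(abs(out$C[, t, 1] - cc)), 1e-9)
  }
})

test_that("zero weights give sigma(0) gates and f_A = ReLU(b_A)", {
  cfg <- hybrid_config(3, branches = "angles", lstm_layers = 2,
                       lstm_hidden = 5, angle_dim = 25, angle_out = 4,
                       seed = 1)
  m <- hybrid_model(cfg)
  for (nm in names(m$params)) {
    if (grepl("^(Wx|Wh|lb)", nm)) m$params[[nm]][] <- 0
  }
  bA <- c(-1, 0.5, 2, -0.2)
  m$params$faW[] <- 0
  m$params$fab <- bA
  # neutral batch norm
  m$params$bnag[] <- 1
  m$params$bnab[] <- 0
  m$state$bna <- list(mean = numeric(5), var = rep(1, 5))
  xa <- matrix(0, 10, 25)
  fA <- lstm_encode(m, xa)
  expect_equal(fA, pmax(bA, 0), tolerance = 1e-12)

  expect_length(lstm_encode(m, matrix(1, 33, 25)), 4)
  expect_error(lstm_encode(m, matrix(0, 10, 7)), "dimension mismatch")
})

test_that("the parameter encoder is a ReLU affine map", {
  cfg <- hybrid_config(3, branches = "params", param_dim = 2,
                       param_out = 2, seed = 1)
  m <- hybrid_model(cfg)
  m$params$fpW <- matrix(c(1, -2, 3, 0.5), 2, 2)
  m$params$fpb <- c(-1, 0.25)
  x <- c(0.3, -0.4)
  want <- pmax(as.numeric(m$params$fpW %*% x + m$params$fpb), 0)
  expect_equal(ann_encode(m, x), want, tolerance = 1e-12)

  m$params$fpW[] <- 0
  expect_equal(ann_encode(m, x), c(0, 0.25))

  withr::local_seed(2)
  for (i in 1:20) {
    m$params$fpW <- matrix(stats::rnorm(4), 2, 2)
    expect_true(all(ann_encode(m, stats::rnorm(2)) >= 0))
  }
  expect_error(ann_encode(m, c(1, 2, 3)), "length mismatch")
})

# -- fusion, classification, loss --------------------------------------------

test_that("fusion head produces normalized probabilities", {
  cfg <- hybrid_config(4, branches = c("params"), param_dim = 3,
                       param_out = 6, seed = 5)
  m <- hybrid_model(cfg)
  fP <- ann_encode(m, c(0.5, 1, 0.2))

  m0 <- hybrid_model(cfg)
  m0$params$headW[] <- 0
  m0$params$headb[] <- 0
  expect_equal(fuse_and_classify(m0, fP = fP), rep(0.25, 4))

  withr::local_seed(9)
  for (i in 1:10) {
    m$params$headW <- matrix(stats::rnorm(4 * 6), 4, 6)
    p <- fuse_and_classify(m, fP = fP)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
})

test_that("binary softmax matches the closed form", {
  cfg <- hybrid_config(2, branches = "params", param_dim = 2,
                       param_out = 2, seed = 3)
  m <- hybrid_model(cfg)
  m$params$bnhg[] <- 1
  m$params$bnhb[] <- 0
  m$state$bnh <- list(mean = c(0, 0), var = c(1, 1))
  m$params$headW <- diag(2)
  m$params$headb <- c(0.7, -0.3)
  fP <- c(0, 0)
  p <- fuse_and_classify(m, fP = fP)
  a <- 0.7 + 0   # bn of 0 input with unit stats is ~0 (up to eps)
  b <- -0.3
  expect_equal(p[1], exp(a) / (exp(a) + exp(b)), tolerance = 1e-3)
})

test_that("cross-entropy closed forms and L2 additivity hold", {
  expect_equal(cross_entropy_loss(c(0, 1, 0), c(0, 1, 0)), 0)
  for (C in c(2, 5, 9)) {
    y <- rep(0, C)
    y[2] <- 1
    expect_equal(cross_entropy_loss(y, rep(1 / C, C)), log(C),
                 tolerance = 1e-12)
  }
  withr::local_seed(4)
  W <- list(a = matrix(stats::rnorm(6), 2), b = stats::rnorm(3))
  y <- c(1, 0)
  p <- c(0.7, 0.3)
  base <- cross_entropy_loss(y, p)
  lam <- 0.37
  expect_equal(cross_entropy_loss(y, p, lam, W),
               base + lam / 2 * (sum(W$a^2) + sum(W$b^2)),
               tolerance = 1e-12)
  expect_gt(cross_entropy_loss(y, p, lam, W), base)
  expect_error(cross_entropy_loss(diag(3), matrix(0.5, 2, 2)), "mismatch")
})

# -- training and prediction -------------------------------------------------

test_that("all-branches-off is a configuration error", {
  expect_error(hybrid_config(3, branches = character(0)), "deactivated")
})

test_that("training reduces loss and is exactly reproducible", {
  withr::local_seed(99)
  ds <- fixture_tiny_dataset(n_subjects = 4, n_walks = 3, T_ = 30)
  # make the two classes linearly separable in the parameter view
  views <- list(
    skel = NULL, ang = NULL,
    par = matrix(stats::rnorm(26 * length(ds$examples), sd = 0.1), 26),
    labels = dataset_labels(ds),
    subjects = dataset_subjects(ds),
    n = length(ds$examples)
  )
  views$par[1, views$labels == 2] <- views$par[1, views$labels == 2] + 3

  cfg <- hybrid_config(2, branches = "params", seed = 12, dropout = 0.2)
  opts <- train_options(batch_size = 4, epochs = 25, seed = 7)
  run <- function() {
    m <- hybrid_model(cfg)
    train_hybrid(m, views, train_idx = 1:9, val_idx = 10:12, opts)
  }
  m1 <- run()
  expect_lt(mean(tail(m1$history$train_loss, 3)),
            mean(head(m1$history$train_loss, 3)))

  m2 <- run()
  expect_identical(m1$history, m2$history)     # bit-reproducible
  expect_identical(m1$params, m2$params)

  p1 <- predict_hybrid(m1, views)
  expect_equal(p1$class, apply(p1$probs, 2, which.max))
  p2 <- predict_hybrid(m1, views)
  expect_identical(p1, p2)

  expect_error(train_hybrid(hybrid_model(cfg), views, integer(0), 1:3,
                            opts), "empty")
  bad_views <- views
  bad_views$par <- NULL
  expect_error(predict_hybrid(m1, bad_views), "missing input view")
})

test_that("analytic gradients match numeric differentiation", {
  withr::local_seed(31)
  js <- default_joint_set()
  graph <- build_joint_graph(js)
  cfg <- hybrid_config(3, skeleton_channels = c(4, 5),
                       skeleton_strides = c(1, 2), temporal_kernel = 3,
                       skeleton_out = 4, lstm_layers = 1, lstm_hidden = 5,
                       angle_out = 3, param_out = 3, dropout = 0,
                       lambda = 0, seed = 6)
  m <- hybrid_model(cfg, graph)
  B <- 3
  T_ <- 8
  V <- n_joints(js)
  views <- list(skel = array(stats::rnorm(3 * T_ * V * B), c(3, T_, V, B)),
                ang = array(stats::rnorm(25 * T_ * B), c(25, T_, B)),
                par = matrix(stats::rnorm(26 * B), 26, B))
  labels <- c(1L, 2L, 3L)
  state0 <- m$state
  fw <- gaitfuse:::.forward(m, views, train = TRUE)
  grads <- gaitfuse:::.backward(m, views, fw$cache, labels)
  lossfn <- function() {
    m$state <- state0
    f <- gaitfuse:::.forward(m, views, train = TRUE)
    cross_entropy_loss(labels, f$probs) / B
  }
  eps <- 1e-6
  check <- c("gw1", "tw2", "Wx1", "Wh1", "fpW", "headW", "bnhg", "faW")
  for (nm in check) {
    p <- m$params[[nm]]
    idx <- sample(length(p), 3)
    for (i in idx) {
      m$params[[nm]][i] <- p[i] + eps
      lp <- lossfn()
      m$params[[nm]][i] <- p[i] - eps
      lm <- lossfn()
      m$params[[nm]][i] <- p[i]
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - grads[[nm]][i]) /
                  max(1e-4, abs(num) + abs(grads[[nm]][i])), 1e-3)
    }
  }
})

test_that("model checkpoints round-trip predictions", {
  withr::local_seed(5)
  cfg <- hybrid_config_small(3, branches = c("angles", "params"), seed = 4)
  m <- hybrid_model(cfg)
  B <- 4
  views <- list(skel = NULL,
                ang = array(stats::rnorm(25 * 15 * B), c(25, 15, B)),
                par = matrix(stats::rnorm(26 * B), 26, B),
                labels = rep(1L, B), subjects = rep("s", B), n = B)
  p0 <- predict_hybrid(m, views)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  p1 <- predict_hybrid(m2, views)
  expect_equal(p0$probs, p1$probs, tolerance = 1e-12)
})
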