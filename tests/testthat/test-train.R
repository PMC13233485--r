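test_that("the arctangent surrogate has its closed form, peak and symmetry", {
  expect_equal(surrogate_atan_grad(0, 2), 1.0) # peak alpha/2
  expect_equal(surrogate_atan_grad(1, 2), 2 / (2 * (1 + pi^2)))
  set.seed(2)
  x <- rnorm(50, sd = 2)
  expect_equal(surrogate_atan_grad(x, 1.7), surrogate_atan_grad(-x, 1.7))
  expect_true(all(surrogate_atan_grad(x, 2) <= 1))
  # numerically the derivative of the soft spike it smooths
  h <- 1e-6
  soft <- function(z) 0.5 + atan(pi / 2 * 2 * z) / pi
  expect_equal(surrogate_atan_grad(0.37, 2),
               (soft(0.37 + h) - soft(0.37 - h)) / (2 * h),
               tolerance = 1e-7)
})

test_that("STBP gradients match finite differences of the soft forward", {
  # with the smooth spike the surrogate is the exact derivative, so the
  # whole spatio-temporal chain rule can be checked against central
  # differences, reset path and all
  set.seed(42)
  net <- tiny_net(seed = 3)
  X <- matrix(runif(2 * 6), 2, 6)
  y <- c(1L, 2L)
  T <- 4
  loss_soft <- function(n) {
    fw <- forward_train(n, X, T, alpha = 2, soft = TRUE)
    cssnn:::.loss_and_grad(fw$rates, y, "ce")$value
  }
  fw <- forward_train(net, X, T, alpha = 2, soft = TRUE)
  lg <- cssnn:::.loss_and_grad(fw$rates, y, "ce")
  g <- stbp_gradients(net, fw, lg$grad)
  eps <- 1e-6
  for (l in 2:3) {
    W <- net$layers[[l]]$W
    fd <- W * 0
    for (i in seq_along(W)) {
      n1 <- net; n1$layers[[l]]$W[i] <- W[i] + eps
      n2 <- net; n2$layers[[l]]$W[i] <- W[i] - eps
      fd[i] <- (loss_soft(n1) - loss_soft(n2)) / (2 * eps)
    }
    expect_equal(g[[l]], fd, tolerance = 1e-5)
  }
  # encoder straight-through gradient equals the exact gradient w.r.t.
  # the binary matrix entries (perturbed continuously)
  B <- binary_matrix(net$layers[[1]]$mm)
  loss_soft_B <- function(Bp) {
    n1 <- net
    n1$layers[[1]] <- list(type = "grm", W = Bp,
                           params = net$layers[[1]]$params)
    loss_soft(n1)
  }
  fdB <- B * 0
  for (i in seq_along(B)) {
    B1 <- B; B1[i] <- B[i] + eps
    B2 <- B; B2[i] <- B[i] - eps
    fdB[i] <- (loss_soft_B(B1) - loss_soft_B(B2)) / (2 * eps)
  }
  expect_equal(g[[1]], fdB, tolerance = 1e-5)
})

test_that("gradient estimators: strict masking zeroes unselected entries", {
  set.seed(8)
  net <- tiny_net(seed = 8)
  X <- matrix(runif(3 * 6), 3, 6)
  fw <- forward_train(net, X, 3)
  lg <- cssnn:::.loss_and_grad(fw$rates, c(1L, 2L, 1L), "ce")
  g_ste <- stbp_gradients(net, fw, lg$grad, estimator = "ste")
  g_mask <- stbp_gradients(net, fw, lg$grad, estimator = "mask")
  B <- binary_matrix(net$layers[[1]]$mm)
  expect_true(all(g_mask[[1]][B == 0] == 0))
  expect_equal(g_mask[[1]][B == 1], g_ste[[1]][B == 1])
  # zero loss gradient -> zero parameter gradients everywhere
  g0 <- stbp_gradients(net, fw, lg$grad * 0)
  for (l in 1:3) expect_true(all(g0[[l]] == 0))
})

test_that("training trivia: zero epochs, constant lr, frozen GRM encoder", {
  ds <- grid_dataset()
  net <- build_network("64-cs8-fc6-fc4", sample = 4, seed = 5)
  f0 <- fit_cssnn(net, ds, train_config(epochs = 0, T = 3))
  expect_equal(f0$net$layers[[2]]$W, net$layers[[2]]$W)
  expect_equal(f0$net$layers[[1]]$mm$W, net$layers[[1]]$mm$W)
  f1 <- fit_cssnn(net, ds, train_config(epochs = 3, T = 3, lr_decay = 1))
  expect_true(all(f1$history$lr == f1$history$lr[1]))
  f2 <- fit_cssnn(net, ds, train_config(epochs = 2, T = 3, lr_decay = 0.5))
  expect_equal(f2$history$lr, c(0.001, 0.0005))
  # compressed-learning mode: the fixed GRM encoder never moves while the
  # SNN layers do
  g <- build_network("64-cs8-fc6-fc4", encoder = "grm", seed = 5)
  fg <- fit_cssnn(g, ds, train_config(epochs = 2, T = 3))
  expect_identical(fg$net$layers[[1]]$W, g$layers[[1]]$W)
  expect_false(identical(fg$net$layers[[2]]$W, g$layers[[2]]$W))
})

test_that("encoder weights stay in [-1, 1] after every update", {
  ds <- grid_dataset()
  net <- build_network("64-cs8-fc6-fc4", sample = 4, seed = 2)
  cfg <- train_config(epochs = 3, T = 4, lr = 0.05, lr_decay = 1) # large lr
  fit <- fit_cssnn(net, ds, cfg)
  expect_true(all(abs(fit$net$layers[[1]]$mm$W) <= 1))
  expect_true(all(rowSums(binary_matrix(fit$net$layers[[1]]$mm)) == 4))
})

test_that("separable two-class data trains to high accuracy", {
  spec <- synthetic_spec(n_features = 784, n_classes = 2,
                         samples_per_class = 30, k_active = 20,
                         overlap = 4, seed = 13)
  ds <- gen_sparse_frames(spec)
  net <- build_network("784-cs64-fc32-fc2", sample = 20, seed = 13)
  cfg <- train_config(epochs = 30, lr_decay = 0.9, T = 10, seed = 13)
  fit <- fit_cssnn(net, ds, cfg)
  expect_gt(fit$history$train_acc[nrow(fit$history)], 0.9)
  # loss trends down over the early epochs on separable data
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
})

test_that("a full run is reproducible from its seed", {
  ds <- grid_dataset()
  cfg <- train_config(epochs = 2, T = 4, seed = 77)
  f1 <- fit_cssnn(build_network("64-cs8-fc6-fc4", sample = 4, seed = 7),
                  ds, cfg)
  f2 <- fit_cssnn(build_network("64-cs8-fc6-fc4", sample = 4, seed = 7),
                  ds, cfg)
  expect_identical(f1$net$layers[[1]]$mm$W, f2$net$layers[[1]]$mm$W)
  expect_identical(f1$net$layers[[3]]$W, f2$net$layers[[3]]$W)
  expect_identical(f1$history, f2$history)
})

test_that("accuracy evaluation matches a counting oracle with per-class tallies", {
  ds <- grid_dataset()
  net <- tiny_net(seed = 1, arch = "64-cs8-fc6-fc4", sample = 4)
  acc <- evaluate_accuracy(net, ds, T = 4)
  preds <- attr(acc, "predictions")
  expect_equal(as.numeric(acc), sum(preds == ds$y) / length(ds$y))
  pc <- attr(acc, "per_class")
  N <- length(ds$y)
  for (r in seq_len(nrow(pc))) {
    k <- pc$class[r]
    expect_equal(pc$tp[r], sum(preds == k & ds$y == k))
    expect_equal(pc$tp[r] + pc$tn[r] + pc$fp[r] + pc$fn[r], N)
  }
  # hand case: 9 of 10 correct is 0.9
  expect_equal(mean(c(rep(TRUE, 9), FALSE)), 0.9)
  expect_error(evaluate_accuracy(net, list(x = ds$x[0, , drop = FALSE],
                                           y = integer(0)), T = 4),
               "empty")
})

test_that("forward_train is deterministic and honors degenerate budgets", {
  net <- tiny_net(seed = 5)
  X <- matrix(runif(2 * 6), 2, 6)
  f1 <- forward_train(net, X, 4)
  f2 <- forward_train(net, X, 4)
  expect_identical(f1$rates, f2$rates)
  # sample = n: the binary matrix is all ones, the projection is a plain
  # (unpruned) binary sum
  net2 <- build_network("5-cs2-fc3-fc2", sample = 5, seed = 2)
  B <- binary_matrix(net2$layers[[1]]$mm)
  expect_true(all(B == 1))
  x <- runif(5)
  expect_equal(cs_encode(B, x), rep(sum(x), 2))
})

test_that("a sweep tabulates the grid with a coherent Pareto front", {
  spec <- synthetic_spec(n_features = 64, n_classes = 3,
                         samples_per_class = 8, k_active = 6, overlap = 2,
                         seed = 31)
  ds <- gen_sparse_frames(spec)
  sp <- split_frames(ds, 1/4, seed = 31)
  cfg <- train_config(epochs = 2, T = 4, lr_decay = 0.8, seed = 31)
  tab <- sweep_cssnn(sp$train, sp$test, cr_values = 0.25,
                     sparsity_values = c(0.25, 0.0625), hidden = 6,
                     cfg = cfg)
  expect_equal(nrow(tab), 2)
  # encoder OPs shrink strictly with the sensing budget at fixed CR
  expect_true(tab$ops_encoder[1] > tab$ops_encoder[2])
  expect_true(any(tab$pareto))
  # a 1x1 grid equals a direct fit of the same configuration
  tab1 <- sweep_cssnn(sp$train, sp$test, 0.25, 0.25, hidden = 6, cfg = cfg)
  expect_equal(tab1$accuracy, tab$accuracy[1])
  expect_error(sweep_cssnn(sp$train, sp$test, numeric(0), 0.25), "empty")
})
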