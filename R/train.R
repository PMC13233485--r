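#' Training configuration for CSSNN co-optimization
#'
#' Defaults follow the reference training protocol: AdamW, initial learning
#' rate 0.001 decayed by a factor `lr_decay` per epoch, 64 epochs, batch
#' size 18, arctangent surrogate with `alpha = 2`, and 100 simulation
#' timesteps (frame data). Scale `epochs`, `T` and `lr_decay` down for
#' quick experiments.
#'
#' @param lr initial learning rate.
#' @param lr_decay multiplicative per-epoch learning-rate factor in (0, 1].
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size.
#' @param T simulation timesteps per forward pass.
#' @param alpha arctangent surrogate sharpness.
#' @param loss `"ce"` (cross-entropy on time-averaged output firing rates,
#'   the default) or `"mse"` (mean squared error of rates against one-hot
#'   targets).
#' @param estimator gradient estimator through the binarization: `"ste"`
#'   (straight-through onto the full real weight matrix, the default) or
#'   `"mask"` (gradients restricted to currently selected entries).
#' @param weight_decay AdamW decoupled weight decay.
#' @param beta1,beta2,eps Adam moment constants.
#' @param seed RNG seed controlling shuffling (and hence the whole run).
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, lr_decay = 0.1, epochs = 64,
                         batch_size = 18, T = 100, alpha = 2.0,
                         loss = c("ce", "mse"),
                         estimator = c("ste", "mask"),
                         weight_decay = 0.01,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         seed = 1L) {
  loss <- match.arg(loss)
  estimator <- match.arg(estimator)
  stopifnot(lr > 0, lr_decay > 0, lr_decay <= 1, epochs >= 0, T >= 1,
            alpha > 0, batch_size >= 1)
  structure(list(lr = lr, lr_decay = lr_decay, epochs = epochs,
                 batch_size = batch_size, T = T, alpha = alpha,
                 loss = loss, estimator = estimator,
                 weight_decay = weight_decay, beta1 = beta1,
                 beta2 = beta2, eps = eps, seed = seed),
            class = "train_config")
}

#' Arctangent surrogate gradient
#'
#' Smooth stand-in for the derivative of the Heaviside spike function,
#' evaluated at the membrane-potential offset from threshold. It is the
#' exact derivative of the soft spike `1/2 + atan(pi/2 * alpha * x)/pi`,
#' symmetric in `x`, and peaks at `alpha/2` at `x = 0`.
#'
#' @param x membrane-potential offset `u - v_th` (vectorized).
#' @param alpha sharpness parameter (> 0).
#' @return Gradient values `alpha / (2 * (1 + ((pi/2) * alpha * x)^2))`.
#' @export
surrogate_atan_grad <- function(x, alpha = 2.0) {
  stopifnot(alpha > 0)
  alpha / (2 * (1 + ((pi / 2) * alpha * x)^2))
}

#' Batched training-mode forward pass
#'
#' Runs the layered spiking forward on a minibatch, re-deriving the binary
#' measurement matrix from the current real encoder weights first (so the
#' sampling pattern always tracks the weights being optimized). Caches the
#' per-timestep membrane potentials and spikes needed by
#' [stbp_gradients()].
#'
#' @param net a `cssnn_network`.
#' @param X minibatch, `batch x n_in` (static frames) or an array
#'   `(batch, T, n_in)` of per-timestep frames.
#' @param T timesteps.
#' @param alpha surrogate sharpness (recorded for the backward pass).
#' @param soft if `TRUE` the hard spike is replaced by the smooth ATan
#'   antiderivative — used only by gradient-checking oracles, never for
#'   reported results.
#' @return Object of class `cssnn_forward`: spike/potential caches plus
#'   `rates`, the `batch x n_out` time-averaged output firing rates.
#' @export
forward_train <- function(net, X, T, alpha = 2.0, soft = FALSE) {
  fw <- .batched_forward(net, X, T, soft = soft, alpha = alpha)
  L <- length(net$layers)
  out <- fw$S[[L]]
  rates <- apply(out, c(1, 2), mean)
  fw$rates <- matrix(rates, dim(out)[1], dim(out)[2])
  fw$alpha <- alpha
  fw$X <- X
  class(fw) <- "cssnn_forward"
  fw
}

# loss value and gradient w.r.t. the output rates
.loss_and_grad <- function(rates, y, loss) {
  batch <- nrow(rates)
  K <- ncol(rates)
  Y <- matrix(0, batch, K)
  Y[cbind(seq_len(batch), y)] <- 1
  if (loss == "ce") {
    z <- rates - apply(rates, 1, max)
    ez <- exp(z)
    p <- ez / rowSums(ez)
    value <- -mean(log(p[cbind(seq_len(batch), y)] + 1e-12))
    grad <- (p - Y) / batch
  } else {
    value <- mean((rates - Y)^2)
    grad <- 2 * (rates - Y) / (batch * K)
  }
  list(value = value, grad = grad)
}

.slice <- function(a, t) matrix(a[, , t], dim(a)[1], dim(a)[2])

#' Spatio-temporal backpropagation gradients
#'
#' Backpropagates a loss gradient on the time-averaged output rates
#' through the unrolled spiking dynamics. The spike nonlinearity's
#' derivative is replaced by [surrogate_atan_grad()]; the hard-reset path
#' stays in the graph (`dv/du = (1 - s) + (v_reset - u) * sg`). Temporal
#' credit flows through every LIF layer's membrane recursion; the encoder
#' projection is a time-constant input current, so no temporal path
#' reaches the measurement matrix — its gradient is purely spatial,
#' carried through the binary matrix onto the real weights by the
#' straight-through estimator (or restricted to selected entries under
#' `estimator = "mask"`).
#'
#' @param net a `cssnn_network`.
#' @param fw a `cssnn_forward` from [forward_train()].
#' @param d_rates gradient of the loss w.r.t. `fw$rates`
#'   (`batch x n_out`).
#' @param estimator `"ste"` or `"mask"` (see [train_config()]).
#' @return List of per-layer weight gradients (`NULL` for the fixed GRM
#'   encoder), shaped like each layer's weight matrix.
#' @export
stbp_gradients <- function(net, fw, d_rates,
                           estimator = c("ste", "mask")) {
  estimator <- match.arg(estimator)
  L <- length(net$layers)
  T <- fw$T
  batch <- fw$batch
  sizes <- vapply(net$layers, .layer_size, integer(1))
  dV <- lapply(sizes, function(s) matrix(0, batch, s))
  grads <- vector("list", L)
  for (l in seq_len(L)) {
    if (net$layers[[l]]$type == "fc")
      grads[[l]] <- matrix(0, sizes[l], sizes[l - 1])
  }
  enc <- net$layers[[1]]
  dW1 <- if (enc$type == "cs") matrix(0, enc$mm$m, enc$mm$n) else NULL
  dI1 <- matrix(0, batch, sizes[1])
  d_out <- d_rates / T
  for (t in rev(seq_len(T))) {
    ds <- vector("list", L)
    ds[[L]] <- d_out
    for (l in rev(seq_len(L))) {
      p <- net$layers[[l]]$params
      u <- .slice(fw$U[[l]], t)
      s <- .slice(fw$S[[l]], t)
      sg <- surrogate_atan_grad(u - p$v_th, fw$alpha)
      dsl <- if (is.null(ds[[l]])) 0 else ds[[l]]
      du <- dsl * sg + dV[[l]] * ((1 - s) + (p$v_reset - u) * sg)
      dV[[l]] <- du * p$decay
      if (l > 1) {
        s_prev <- .slice(fw$S[[l - 1]], t)
        grads[[l]] <- grads[[l]] + t(du) %*% s_prev
        add <- du %*% net$layers[[l]]$W
        ds[[l - 1]] <- if (is.null(ds[[l - 1]])) add else ds[[l - 1]] + add
      } else if (!is.null(dW1) && fw$per_step) {
        Xt <- matrix(fw$X[, t, ], batch)
        dW1 <- dW1 + t(du) %*% Xt
      } else {
        dI1 <- dI1 + du
      }
    }
  }
  if (!is.null(dW1)) {
    if (!fw$per_step) dW1 <- t(dI1) %*% fw$X
    if (estimator == "mask")
      dW1 <- dW1 * binarize_rows(enc$mm$W, enc$mm$sample)
    grads[[1]] <- dW1
  }
  grads
}

# one AdamW step on a weight matrix; returns list(W, m, v)
.adamw_step <- function(W, g, st, lr, cfg, t) {
  st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
  st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g^2
  mhat <- st$m / (1 - cfg$beta1^t)
  vhat <- st$v / (1 - cfg$beta2^t)
  st$W <- W - lr * (mhat / (sqrt(vhat) + cfg$eps) + cfg$weight_decay * W)
  st
}

#' Train a CSSNN (or compressed-learning baseline) with STBP
#'
#' Co-optimizes the encoder measurement matrix and the SNN classifier (or,
#' for a `"grm"`-encoder network, the SNN layers only — the
#' compressed-learning baseline) with AdamW. The binary matrix is
#' re-derived every forward pass; encoder weights are clipped to \[-1, 1\]
#' after every optimizer step; the learning rate is decayed by
#' `cfg$lr_decay` after each epoch. The run is fully determined by
#' `cfg$seed` and the initial network.
#'
#' @param net a `cssnn_network` (see [build_network()]).
#' @param dataset list with `x` (`N x n_in` matrix, or `(N, T, n_in)`
#'   array for event data) and `y` (integer labels in `1..n_classes`).
#' @param cfg a [train_config()].
#' @param verbose print a per-epoch summary line.
#' @return Object of class `cssnn_fit`: `net` (trained), `history`
#'   (per-epoch data frame with loss, training accuracy, learning rate and
#'   per-layer firing rates) and `cfg`.
#' @export
fit_cssnn <- function(net, dataset, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "cssnn_network"), inherits(cfg, "train_config"))
  per_step <- length(dim(dataset$x)) == 3
  N <- if (per_step) dim(dataset$x)[1] else nrow(dataset$x)
  if (N == 0) stop("empty dataset")
  if (length(dataset$y) != N) stop("labels do not match the sample count")
  L <- length(net$layers)
  opt <- vector("list", L)
  for (l in seq_len(L)) {
    tpl <- switch(net$layers[[l]]$type,
                  cs = net$layers[[l]]$mm$W,
                  fc = net$layers[[l]]$W,
                  grm = NULL)
    if (!is.null(tpl))
      opt[[l]] <- list(W = tpl, m = tpl * 0, v = tpl * 0)
  }
  history <- NULL
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(cfg$seed)
  lr <- cfg$lr
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(N)
    starts <- seq(1, N, by = cfg$batch_size)
    ep_loss <- 0; ep_correct <- 0
    fr_sum <- numeric(L); fr_n <- 0
    for (s0 in starts) {
      idx <- perm[s0:min(s0 + cfg$batch_size - 1, N)]
      Xb <- if (per_step) dataset$x[idx, , , drop = FALSE]
            else dataset$x[idx, , drop = FALSE]
      yb <- dataset$y[idx]
      fw <- forward_train(net, Xb, cfg$T, alpha = cfg$alpha)
      lg <- .loss_and_grad(fw$rates, yb, cfg$loss)
      if (!is.finite(lg$value))
        stop("non-finite loss at epoch ", epoch,
             " (learning rate ", lr, "); lower the learning rate")
      grads <- stbp_gradients(net, fw, lg$grad, estimator = cfg$estimator)
      step <- step + 1L
      for (l in seq_len(L)) {
        if (is.null(opt[[l]])) next
        opt[[l]] <- .adamw_step(opt[[l]]$W, grads[[l]], opt[[l]],
                                lr, cfg, step)
        if (net$layers[[l]]$type == "cs") {
          opt[[l]]$W <- clip_weights(opt[[l]]$W)
          net$layers[[l]]$mm$W <- opt[[l]]$W
        } else {
          net$layers[[l]]$W <- opt[[l]]$W
        }
      }
      ep_loss <- ep_loss + lg$value * length(idx)
      pred <- max.col(fw$rates, ties.method = "first")
      ep_correct <- ep_correct + sum(pred == yb)
      fr_sum <- fr_sum + vapply(fw$S, mean, numeric(1)) * length(idx)
      fr_n <- fr_n + length(idx)
    }
    row <- data.frame(epoch = epoch, lr = lr, loss = ep_loss / N,
                      train_acc = ep_correct / N)
    for (l in seq_len(L)) row[[paste0("fr_layer", l)]] <- fr_sum[l] / fr_n
    history <- rbind(history, row)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f acc %.3f lr %.2g",
                      epoch, row$loss, row$train_acc, lr))
    lr <- lr * cfg$lr_decay
  }
  structure(list(net = net, history = history, cfg = cfg),
            class = "cssnn_fit")
}

#' @export
print.cssnn_fit <- function(x, ...) {
  h <- x$history
  if (is.null(h)) {
    cat("Untrained CSSNN fit (0 epochs)\n")
  } else {
    cat(sprintf("CSSNN fit: %d epochs, final loss %.4f, train acc %.3f\n",
                nrow(h), h$loss[nrow(h)], h$train_acc[nrow(h)]))
  }
  invisible(x)
}

#' Classification accuracy of a spiking network on a labeled dataset
#'
#' Predicts by output-spike voting over `T` timesteps and reports the
#' proportion of correctly classified samples. Per-class one-vs-all
#' true-positive/true-negative tallies are attached as the `"per_class"`
#' attribute.
#'
#' @param net a `cssnn_network` (or a `cssnn_fit`, whose network is used).
#' @param dataset list with `x` and `y` as in [fit_cssnn()].
#' @param T simulation timesteps.
#' @param batch_size evaluation minibatch size.
#' @return Accuracy in \[0, 1\], with attributes `per_class` (data frame
#'   of class, tp, tn, fp, fn) and `predictions`.
#' @export
evaluate_accuracy <- function(net, dataset, T, batch_size = 64) {
  if (inherits(net, "cssnn_fit")) net <- net$net
  per_step <- length(dim(dataset$x)) == 3
  N <- if (per_step) dim(dataset$x)[1] else nrow(dataset$x)
  if (N == 0) stop("empty dataset")
  preds <- integer(N)
  for (s0 in seq(1, N, by = batch_size)) {
    idx <- s0:min(s0 + batch_size - 1, N)
    Xb <- if (per_step) dataset$x[idx, , , drop = FALSE]
          else dataset$x[idx, , drop = FALSE]
    fw <- forward_train(net, Xb, T)
    preds[idx] <- max.col(fw$rates, ties.method = "first")
  }
  y <- dataset$y
  acc <- mean(preds == y)
  classes <- sort(unique(y))
  pc <- do.call(rbind, lapply(classes, function(k) {
    data.frame(class = k,
               tp = sum(preds == k & y == k),
               tn = sum(preds != k & y != k),
               fp = sum(preds == k & y != k),
               fn = sum(preds != k & y == k))
  }))
  attr(acc, "per_class") <- pc
  attr(acc, "predictions") <- preds
  acc
}

#' Mean per-layer firing rates of a network over a dataset
#'
#' @param net a `cssnn_network` or `cssnn_fit`.
#' @param dataset list with `x` (and optionally `y`, ignored).
#' @param T simulation timesteps.
#' @param batch_size evaluation minibatch size.
#' @return Numeric vector, one mean firing rate per layer.
#' @export
layer_firing_rates <- function(net, dataset, T, batch_size = 64) {
  if (inherits(net, "cssnn_fit")) net <- net$net
  per_step <- length(dim(dataset$x)) == 3
  N <- if (per_step) dim(dataset$x)[1] else nrow(dataset$x)
  L <- length(net$layers)
  acc <- numeric(L); wt <- 0
  for (s0 in seq(1, N, by = batch_size)) {
    idx <- s0:min(s0 + batch_size - 1, N)
    Xb <- if (per_step) dataset$x[idx, , , drop = FALSE]
          else dataset$x[idx, , drop = FALSE]
    fw <- forward_train(net, Xb, T)
    acc <- acc + vapply(fw$S, mean, numeric(1)) * length(idx)
    wt <- wt + length(idx)
  }
  acc / wt
}

#' Grid sweep over compression rate and measurement sparsity
#'
#' Trains one model per (CR, sparsity) cell on the training set, evaluates
#' on the test set, and tabulates accuracy, empirical operation counts
#' (encoder operations plus firing-rate-weighted SNN operations) and model
#' size. The Pareto-efficient subset under (maximize accuracy, minimize
#' OPs, minimize size) is flagged.
#'
#' @param train,test datasets as in [fit_cssnn()].
#' @param cr_values compression rates m/n to sweep.
#' @param sparsity_values measurement-matrix sparsities Sample/n to sweep.
#' @param hidden hidden-layer width of the SNN classifier.
#' @param cfg a [train_config()].
#' @param params shared [lif_params()].
#' @param weight_bits bit width used for the model-size column.
#' @param verbose print one line per cell.
#' @return Data frame with one row per grid cell (`pareto` flags the
#'   efficient subset).
#' @export
sweep_cssnn <- function(train, test, cr_values, sparsity_values,
                        hidden = 64, cfg = train_config(),
                        params = lif_params(), weight_bits = 8,
                        verbose = FALSE) {
  if (length(cr_values) == 0 || length(sparsity_values) == 0)
    stop("empty sweep grid")
  n_in <- ncol(train$x)
  K <- length(unique(train$y))
  rows <- NULL
  for (crv in cr_values) {
    for (sp in sparsity_values) {
      m <- max(1L, as.integer(round(crv * n_in)))
      sample <- max(1L, as.integer(round(sp * n_in)))
      arch <- sprintf("%d-cs%d-fc%d-fc%d", n_in, m, hidden, K)
      net <- build_network(arch, sample = sample, params = params,
                           seed = cfg$seed)
      fit <- fit_cssnn(net, train, cfg)
      acc <- as.numeric(evaluate_accuracy(fit$net, test, cfg$T))
      rates <- layer_firing_rates(fit$net, test, cfg$T)
      ops <- network_ops(fit$net, rates)
      size_mb <- model_size_cs(n_in, m / n_in, sample) +
        model_size(list(c(m, hidden), c(hidden, K)), weight_bits)
      row <- data.frame(cr = m / n_in, sample = sample,
                        sparsity = sample / n_in, accuracy = acc,
                        ops_total = ops$total, ops_encoder = ops$encoder,
                        ops_snn = ops$snn, model_size_mb = size_mb,
                        fr_encoder = rates[1])
      rows <- rbind(rows, row)
      if (verbose)
        message(sprintf("cr=%.3f sample=%d: acc %.3f ops %g",
                        crv, sample, acc, ops$total))
    }
  }
  rows$pareto <- .pareto_front(rows$accuracy, rows$ops_total,
                               rows$model_size_mb)
  rows
}

# TRUE where no other row is at least as good on all of (acc max, ops min,
# size min) and strictly better on one
.pareto_front <- function(acc, ops, size) {
  n <- length(acc)
  vapply(seq_len(n), function(i) {
    !any(acc >= acc[i] & ops <= ops[i] & size <= size[i] &
           (acc > acc[i] | ops < ops[i] | size < size[i]))
  }, logical(1))
}
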