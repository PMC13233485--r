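#' Build a spiking network from an architecture string
#'
#' Architecture strings follow the `"784-cs256-fc64-fc10"` convention: the
#' first token is the flattened input length, a `cs` token is the
#' compressed-sensing encoder layer (its size is the number of measurements
#' m), and `fc` tokens are fully connected LIF layers. All layers are LIF
#' neurons sharing `params`.
#'
#' With `encoder = "cs"` the first layer holds a learnable
#' [measurement_matrix()] whose binary form is re-derived from the real
#' weights at every forward pass. With `encoder = "grm"` the first layer is
#' a fixed (non-trainable) Gaussian random matrix scaled by `1/sqrt(m)` —
#' the classical compressed-learning baseline; only the SNN layers train.
#'
#' @param arch architecture string, e.g. `"784-cs64-fc32-fc10"`.
#' @param sample per-row sensing budget of the binary measurement matrix
#'   (required when the architecture has a `cs` layer and
#'   `encoder = "cs"`).
#' @param params shared [lif_params()].
#' @param encoder `"cs"` (learnable binary sampling) or `"grm"` (fixed
#'   Gaussian baseline).
#' @param seed RNG seed for weight initialization.
#' @return Object of class `cssnn_network`.
#' @export
build_network <- function(arch, sample = NULL, params = lif_params(),
                          encoder = c("cs", "grm"), seed = 1L) {
  encoder <- match.arg(encoder)
  toks <- strsplit(arch, "-", fixed = TRUE)[[1]]
  if (length(toks) < 2) stop("architecture needs an input size and at least one layer")
  n_in <- suppressWarnings(as.integer(gsub("[^0-9]", "", toks[1])))
  if (is.na(n_in) || n_in < 1) stop("bad input-size token: ", toks[1])
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  layers <- list()
  prev <- n_in
  for (tok in toks[-1]) {
    kind <- gsub("[0-9]", "", tok)
    size <- as.integer(gsub("[^0-9]", "", tok))
    if (is.na(size) || size < 1) stop("bad layer token: ", tok)
    if (kind == "cs") {
      if (length(layers) > 0) stop("the cs encoder must be the first layer")
      if (encoder == "cs") {
        if (is.null(sample)) stop("`sample` is required for a cs encoder")
        mm <- measurement_matrix(size, prev, sample)
        layers[[length(layers) + 1]] <-
          list(type = "cs", mm = mm, params = params)
      } else {
        W <- matrix(stats::rnorm(size * prev), size, prev) / sqrt(size)
        layers[[length(layers) + 1]] <-
          list(type = "grm", W = W, params = params)
      }
    } else if (kind == "fc") {
      k <- sqrt(6 / (prev + size))
      W <- matrix(stats::runif(size * prev, -k, k), size, prev)
      layers[[length(layers) + 1]] <-
        list(type = "fc", W = W, params = params)
    } else {
      stop("unknown layer kind: ", kind)
    }
    prev <- size
  }
  if (length(layers) == 0) stop("empty network")
  structure(list(arch = arch, n_in = n_in, layers = layers,
                 encoder = encoder),
            class = "cssnn_network")
}

#' @export
print.cssnn_network <- function(x, ...) {
  sizes <- vapply(x$layers, function(l) .layer_size(l), integer(1))
  cat(sprintf("CSSNN network %s (%s encoder): %d input -> %s\n",
              x$arch, x$encoder, x$n_in,
              paste(sizes, collapse = " -> ")))
  if (x$layers[[1]]$type == "cs")
    cat(sprintf("  encoder Sample=%d (sparsity %.4g)\n",
                x$layers[[1]]$mm$sample,
                matrix_sparsity(x$layers[[1]]$mm)))
  invisible(x)
}

.layer_size <- function(layer) {
  switch(layer$type,
         cs = layer$mm$m,
         grm = nrow(layer$W),
         fc = nrow(layer$W))
}

#' Number of output classes of a network
#' @param net a `cssnn_network`.
#' @return Size of the last layer.
#' @export
n_classes <- function(net) .layer_size(net$layers[[length(net$layers)]])

# encoder input current for a batch: X is batch x n_in
.encoder_current <- function(layer, X) {
  if (layer$type == "cs") {
    B <- binarize_rows(layer$mm$W, layer$mm$sample)
    X %*% t(B)
  } else {
    X %*% t(layer$W)
  }
}

# Batched layered forward with state caching (shared by simulation,
# evaluation and the training backward pass).
# X: batch x n_in (static input, re-applied every timestep) or an array
# (batch, T, n_in) of per-timestep frames (event data).
# Returns S and U: lists over layers of arrays (batch, size, T), plus the
# per-batch encoder current (for static input).
.batched_forward <- function(net, X, T, soft = FALSE, alpha = 2.0) {
  stopifnot(T >= 1)
  per_step <- length(dim(X)) == 3
  batch <- if (per_step) dim(X)[1] else nrow(X)
  L <- length(net$layers)
  sizes <- vapply(net$layers, .layer_size, integer(1))
  V <- lapply(sizes, function(s) matrix(0, batch, s))
  S <- lapply(sizes, function(s) array(0, c(batch, s, T)))
  U <- lapply(sizes, function(s) array(0, c(batch, s, T)))
  I1 <- if (!per_step) .encoder_current(net$layers[[1]], X) else NULL
  for (t in seq_len(T)) {
    s_prev <- NULL
    for (l in seq_len(L)) {
      layer <- net$layers[[l]]
      p <- layer$params
      I <- if (l == 1) {
        if (per_step)
          .encoder_current(layer, matrix(X[, t, ], nrow = batch))
        else I1
      } else {
        s_prev %*% t(layer$W)
      }
      u <- V[[l]] * p$decay + I
      s <- if (soft) .soft_spike(u - p$v_th, alpha)
           else (u >= p$v_th) + 0
      V[[l]] <- u * (1 - s) + p$v_reset * s
      U[[l]][, , t] <- u
      S[[l]][, , t] <- s
      s_prev <- s
    }
  }
  list(S = S, U = U, I1 = I1, batch = batch, T = T, per_step = per_step)
}

# antiderivative of the ATan surrogate: a smooth spike used only by the
# gradient-checking oracle path
.soft_spike <- function(x, alpha) {
  0.5 + atan(pi / 2 * alpha * x) / pi
}

#' Run the layered spiking forward simulation
#'
#' Applies the encoder current to the first LIF layer and propagates
#' spikes layer by layer within each timestep (zero inter-layer latency);
#' membrane potentials persist across timesteps. A static input vector is
#' re-applied at every timestep; a `T x n` matrix supplies one frame per
#' timestep (event-style input).
#'
#' @param net a `cssnn_network`.
#' @param input numeric vector of length `n_in`, or a `T x n_in` matrix of
#'   per-timestep frames.
#' @param T number of simulation timesteps (>= 1).
#' @return List of binary spike rasters, one `T x size` matrix per layer;
#'   the last element is the output raster fed to [classify_by_votes()].
#' @export
network_forward <- function(net, input, T) {
  stopifnot(inherits(net, "cssnn_network"))
  if (T < 1) stop("T must be at least 1")
  if (is.matrix(input)) {
    if (nrow(input) != T || ncol(input) != net$n_in)
      stop("per-step input must be a T x n_in matrix")
    X <- array(0, c(1, T, net$n_in))
    X[1, , ] <- input
  } else {
    if (length(input) != net$n_in)
      stop("input length ", length(input), " does not match n_in ", net$n_in)
    X <- matrix(input, 1, net$n_in)
  }
  fw <- .batched_forward(net, X, T)
  lapply(fw$S, function(a) {
    r <- matrix(a[1, , ], dim(a)[2], T)
    t(r)
  })
}
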