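#' Operation count of a stack of fully connected / CS layers
#'
#' Each multiply-accumulate counts as two operations, so a dense layer
#' with `n_in` inputs and `n_out` outputs contributes `2 * n_in * n_out`.
#' A binary compressed-sensing encoder layer performs additions only —
#' one per stored one of the sampling matrix — contributing
#' `m * sample` operations.
#'
#' @param layers list of layer descriptors: either `c(n_in, n_out)` for a
#'   dense layer, or `list(type = "cs", m = , sample = )` for the binary
#'   encoder.
#' @return Total operation count.
#' @examples
#' ops_fc(list(c(64, 10)))                             # 1280
#' ops_fc(list(list(type = "cs", m = 256, sample = 6))) # 1536
#' @export
ops_fc <- function(layers) {
  total <- 0
  for (layer in layers) {
    if (is.list(layer) && identical(layer$type, "cs")) {
      stopifnot(layer$m > 0, layer$sample > 0)
      total <- total + layer$m * layer$sample
    } else {
      stopifnot(length(layer) == 2, all(layer > 0))
      total <- total + 2 * layer[1] * layer[2]
    }
  }
  total
}

#' Model size of dense layers in megabytes
#'
#' Parameter bits divided by `8 * 1024^2`: each layer holds
#' `n_in * n_out` weights plus `bias` bias terms at `bits` each.
#'
#' @param layers list of `c(n_in, n_out)` pairs.
#' @param bits fixed-point width per parameter (> 0).
#' @param bias bias parameters per layer: `"out"` (one per output neuron,
#'   the default) or `"none"`.
#' @return Size in MB.
#' @export
model_size <- function(layers, bits, bias = c("out", "none")) {
  bias <- match.arg(bias)
  if (bits <= 0) stop("bits must be positive")
  params <- sum(vapply(layers, function(l) {
    l[1] * l[2] + if (bias == "out") l[2] else 0
  }, numeric(1)))
  params * bits / (8 * 1024^2)
}

#' Model size of the compressed-sensing encoder in megabytes
#'
#' The binarized measurement matrix stores only the indices of its ones:
#' `L_in * CR * sample` entries at `ceil(log2(L_in))` bits each. Input
#' lengths 784, 2312 and 32768 therefore take 10-, 12- and 15-bit indices
#' respectively (2312 needs 12 bits by the ceiling; see
#' [index_bit_width()]).
#'
#' @param L_in flattened input length.
#' @param CR compression rate m/n, in (0, 1).
#' @param sample ones per measurement row.
#' @return Size in MB.
#' @export
model_size_cs <- function(L_in, CR, sample) {
  if (!(CR > 0 && CR < 1)) stop("CR must lie in (0, 1)")
  m <- L_in * CR
  if (abs(m - round(m)) > 1e-9) {
    warning("L_in * CR = ", m, " is not an integer; rounding to ",
            round(m), " measurements")
    m <- round(m)
  }
  bits <- index_bit_width(L_in)
  (m * sample) * bits / (8 * 1024^2)
}

#' Index bit width for a given input length
#' @param L_in flattened input length.
#' @return `ceil(log2(L_in))`, the bits needed to address one input
#'   element.
#' @export
index_bit_width <- function(L_in) {
  stopifnot(L_in >= 2)
  as.integer(ceiling(log2(L_in)))
}

#' Dense versus index-matching encoder resource comparison
#'
#' Tabulates the three hardware costs of the encoder under the
#' conventional dense binary matrix-multiplication scheme against the
#' index-matching scheme: storage (`m*n*1` bits dense vs
#' `m*sample*bits` indexed), weight reads (`m*n` vs `m*sample`) and
#' cycles (`m*n` vs `m*sample + n` — one cycle per arriving pixel plus one
#' per table entry). Ratios are dense/indexed, rounded to two decimals.
#'
#' @param m,n encoder dimensions.
#' @param sample ones per row.
#' @param bits storage bits per index-table entry.
#' @return Data frame with rows `storage_bits`, `weight_reads`, `cycles`
#'   and columns `dense`, `indexed`, `ratio`.
#' @examples
#' compare_encoder_methods(256, 784, 6, 14)
#' @export
compare_encoder_methods <- function(m, n, sample, bits) {
  stopifnot(m > 0, n > 0, sample > 0, bits > 0)
  dense <- c(storage_bits = m * n * 1, weight_reads = m * n, cycles = m * n)
  indexed <- c(storage_bits = m * sample * bits,
               weight_reads = m * sample,
               cycles = m * sample + n)
  data.frame(quantity = names(dense),
             dense = unname(dense),
             indexed = unname(indexed),
             ratio = round(unname(dense / indexed), 2),
             row.names = NULL)
}

#' Empirical operation count of a spiking network
#'
#' Encoder term: `m * sample` additions for a binary cs encoder, or
#' `2 * m * n` for a dense real (GRM) encoder. Each subsequent layer's
#' term is its dense count weighted by the measured firing rate of its
#' pre-synaptic layer — the spike-driven cost, since weights are
#' accumulated only when pre-neurons fire.
#'
#' @param net a `cssnn_network` (or `cssnn_fit`).
#' @param rates measured per-layer firing rates (from
#'   [layer_firing_rates()]); `rates[l]` is the rate of layer `l`.
#' @return List with `encoder`, `snn` and `total` operation counts.
#' @export
network_ops <- function(net, rates) {
  if (inherits(net, "cssnn_fit")) net <- net$net
  enc <- net$layers[[1]]
  encoder_ops <- if (enc$type == "cs") enc$mm$m * enc$mm$sample
                 else 2 * nrow(enc$W) * ncol(enc$W)
  snn_ops <- 0
  for (l in seq_along(net$layers)[-1]) {
    W <- net$layers[[l]]$W
    snn_ops <- snn_ops + 2 * nrow(W) * ncol(W) * rates[l - 1]
  }
  list(encoder = encoder_ops, snn = snn_ops, total = encoder_ops + snn_ops)
}

#' Empirical OPs reduction of a sparse-binary CSSNN versus a GRM baseline
#'
#' Measures the firing rates of both models over a dataset, computes each
#' model's empirical operation count with [network_ops()] (encoder
#' operations plus firing-rate-weighted SNN operations) and returns the
#' percentage reduction `100 * (1 - sparse / grm)`.
#'
#' @param model_sparse trained CSSNN (`cssnn_network` or `cssnn_fit`)
#'   with a binary cs encoder.
#' @param model_grm trained baseline with a dense GRM encoder and the
#'   same SNN topology.
#' @param dataset list with `x` (and `y`, unused here).
#' @param T simulation timesteps.
#' @return List with `reduction_pct`, `ops_sparse`, `ops_grm` and both
#'   rate vectors.
#' @export
ops_reduction_vs_grm <- function(model_sparse, model_grm, dataset, T) {
  if (inherits(model_sparse, "cssnn_fit")) model_sparse <- model_sparse$net
  if (inherits(model_grm, "cssnn_fit")) model_grm <- model_grm$net
  N <- if (length(dim(dataset$x)) == 3) dim(dataset$x)[1]
       else nrow(dataset$x)
  if (N == 0) stop("empty dataset")
  sizes_s <- vapply(model_sparse$layers[-1], function(l) nrow(l$W),
                    integer(1))
  sizes_g <- vapply(model_grm$layers[-1], function(l) nrow(l$W),
                    integer(1))
  if (!identical(sizes_s, sizes_g))
    stop("the two models must share the SNN topology")
  r_s <- layer_firing_rates(model_sparse, dataset, T)
  r_g <- layer_firing_rates(model_grm, dataset, T)
  ops_s <- network_ops(model_sparse, r_s)
  ops_g <- network_ops(model_grm, r_g)
  list(reduction_pct = 100 * (1 - ops_s$total / ops_g$total),
       ops_sparse = ops_s, ops_grm = ops_g,
       rates_sparse = r_s, rates_grm = r_g)
}
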