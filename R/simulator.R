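#' Behavioral simulation of the spike-driven processor inference
#'
#' Walks the processor finite-state machine on a quantized network: each
#' timestep, the CS encoder re-streams the input pixels through the
#' index-matching table (`CS_IN`), then every layer's neurons are swept in
#' address order (`V_CALCU`) — leak, integrate, compare; a firing neuron is
#' reset and its outgoing synaptic weight column is accumulated into the
#' post-neurons (`W_ACC`, the spike-driven step), a silent neuron just
#' leaks — and finally the output spikes are tallied as votes (`EXPORT`).
#' All arithmetic is the fixed-point arithmetic of
#' [quantized_forward()], so the predicted class and every spike agree
#' with that reference path bit for bit; the value the simulator adds is
#' its exact cycle / read / write accounting.
#'
#' Counter model: the encoder phase costs `m * Sample + n` cycles per
#' timestep (one per arriving pixel plus one per table entry); `V_CALCU`
#' costs one cycle per neuron and `W_ACC` one cycle, one weight read and
#' one post-neuron read-modify-write per accumulated synapse.
#'
#' @param qnet a `quantized_network` with a `cs` encoder (the
#'   index-matching scheme needs the binary sampling matrix; float models
#'   are rejected — quantize first).
#' @param input numeric vector in \[0, 1\] (static frame) or `T x n_in`
#'   matrix of per-timestep frames.
#' @param T number of timesteps.
#' @return List with `class` (predicted, 1-based), `votes` (output spike
#'   counts), `counters` (cycles, matrix_reads, weight_reads,
#'   neuron_reads, neuron_writes), `weight_reads_by_layer`, and `rasters`
#'   (per-layer `T x size` spike matrices).
#' @export
simulate_inference <- function(qnet, input, T) {
  if (!inherits(qnet, "quantized_network"))
    stop("the simulator is fixed-point only: quantize the model first ",
         "(see quantize_network)")
  if (qnet$layers[[1]]$type != "cs")
    stop("index-matching simulation needs a binary cs encoder layer")
  stopifnot(T >= 1)
  per_step <- is.matrix(input)
  enc <- qnet$layers[[1]]
  table <- build_index_table(enc$B)
  mpb <- qnet$spec$mp_bits
  L <- length(qnet$layers)
  sizes <- vapply(qnet$layers, function(l)
    if (l$type == "cs") nrow(l$B) else nrow(l$Wq), integer(1))
  v <- lapply(sizes, numeric)       # MP codes per layer
  vth_code <- vapply(qnet$layers, function(l)
    round_half_away(l$params$v_th / l$mp_scale), numeric(1))
  vreset_code <- vapply(qnet$layers, function(l)
    round_half_away(l$params$v_reset / l$mp_scale), numeric(1))
  counters <- list(cycles = 0, matrix_reads = 0, weight_reads = 0,
                   neuron_reads = 0, neuron_writes = 0)
  wreads_layer <- numeric(L)        # W_ACC reads feeding layer l (l >= 2)
  rasters <- lapply(sizes, function(s) matrix(0L, T, s))
  votes <- numeric(sizes[L])
  for (t in seq_len(T)) {
    # CS_IN: stream the 8-bit pixel codes through the index table
    x <- if (per_step) input[t, ] else input
    xq <- round_half_away(x * qnet$pixel_levels)
    st <- stream_cs_encode(table, xq)
    for (nm in names(st$counters))
      counters[[nm]] <- counters[[nm]] + st$counters[[nm]]
    meas <- st$measurements
    # synaptic accumulators for the layer below each sweep
    acc_next <- lapply(seq_len(L), function(l)
      if (l < L) numeric(sizes[l + 1]) else NULL)
    for (l in seq_len(L)) {
      layer <- qnet$layers[[l]]
      spikes <- integer(sizes[l])
      for (i in seq_len(sizes[l])) {       # V_CALCU, ascending address
        counters$cycles <- counters$cycles + 1
        counters$neuron_reads <- counters$neuron_reads + 1
        I_code <- if (l == 1)
          round_half_away((meas[i] / qnet$pixel_levels) / layer$mp_scale)
        else
          round_half_away(acc_next[[l - 1]][i] *
                            qnet$layers[[l]]$w_scale / layer$mp_scale)
        vv <- .sat(round_half_away(v[[l]][i] * layer$params$decay) + I_code,
                   mpb)
        if (vv >= vth_code[l]) {
          spikes[i] <- 1L
          v[[l]][i] <- vreset_code[l]
          if (l < L) {                     # W_ACC: spike-driven fan-out
            npost <- sizes[l + 1]
            acc_next[[l]] <- acc_next[[l]] + qnet$layers[[l + 1]]$Wq[, i]
            counters$cycles <- counters$cycles + npost
            counters$weight_reads <- counters$weight_reads + npost
            counters$neuron_reads <- counters$neuron_reads + npost
            counters$neuron_writes <- counters$neuron_writes + npost
            wreads_layer[l + 1] <- wreads_layer[l + 1] + npost
          }
        } else {
          v[[l]][i] <- vv
        }
        counters$neuron_writes <- counters$neuron_writes + 1
      }
      rasters[[l]][t, ] <- spikes
    }
    votes <- votes + rasters[[L]][t, ]     # EXPORT
    counters$cycles <- counters$cycles + 1
  }
  list(class = which.max(votes), votes = votes, counters = counters,
       weight_reads_by_layer = wreads_layer, rasters = rasters)
}

#' Analytic read/write counts of the processor memories
#'
#' Closed-form counters for one pass: the encoder costs `m * Sample`
#' measurement-matrix reads and `m * Sample` neuron reads/writes; a
#' spike-driven SNN layer with `n_pre` inputs and `n_post` outputs costs
#' `n_post * n_pre * firing_rate` weight reads and
#' `n_post * n_pre * firing_rate + n_pre` neuron reads/writes, where the
#' firing rate is the whole-inference average spike probability of the
#' pre-synaptic layer.
#'
#' @param m,n encoder dimensions (measurements x input length).
#' @param sample ones per measurement row.
#' @param firing_rate pre-layer firing rate(s) in \[0, 1\]: one value per
#'   SNN layer (recycled if scalar).
#' @param layers list of `c(n_pre, n_post)` pairs, one per SNN layer.
#' @return Data frame with one row per component (`encoder`, then each
#'   SNN layer): `matrix_reads`, `weight_reads`, `neuron_rw`.
#' @export
predicted_rw_counts <- function(m, n, sample, firing_rate = 0,
                                layers = list()) {
  stopifnot(m > 0, n > 0, sample >= 0, all(firing_rate >= 0),
            all(firing_rate <= 1))
  out <- data.frame(component = "encoder",
                    matrix_reads = m * sample,
                    weight_reads = 0,
                    neuron_rw = m * sample)
  if (length(layers) > 0) {
    fr <- rep_len(firing_rate, length(layers))
    for (i in seq_along(layers)) {
      pre <- layers[[i]][1]; post <- layers[[i]][2]
      out <- rbind(out, data.frame(
        component = paste0("snn", i),
        matrix_reads = 0,
        weight_reads = post * pre * fr[i],
        neuron_rw = post * pre * fr[i] + pre))
    }
  }
  out
}
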