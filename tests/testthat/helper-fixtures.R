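# shared in-code fixtures: tiny networks, small datasets, random binary
# matrices — everything is generated at test time under explicit seeds

tiny_net <- function(seed = 1, arch = "6-cs3-fc4-fc2", sample = 2) {
  net <- build_network(arch, sample = sample, seed = seed)
  # give the SNN layers some spread so spikes actually happen
  set.seed(seed + 1000)
  for (l in seq_along(net$layers)[-1]) {
    W <- net$layers[[l]]$W
    net$layers[[l]]$W <- matrix(stats::rnorm(length(W), sd = 0.8), nrow(W))
  }
  net
}

random_binary_matrix <- function(m, n, sample, seed) {
  set.seed(seed)
  B <- matrix(0L, m, n)
  for (i in seq_len(m)) B[i, sample.int(n, sample)] <- 1L
  B
}

# small sparse-frame dataset on the 8-bit pixel grid (so the float and
# fixed-point paths see identical inputs)
grid_dataset <- function(n_classes = 4, samples_per_class = 6, seed = 3,
                         n_features = 64, k_active = 6) {
  spec <- synthetic_spec(n_features = n_features, n_classes = n_classes,
                         samples_per_class = samples_per_class,
                         k_active = k_active, overlap = 2, seed = seed)
  ds <- gen_sparse_frames(spec)
  ds$x <- round(ds$x * 255) / 255
  ds
}

# independent LIF recursion oracle: scalar neuron, constant current
lif_spike_times_oracle <- function(current, T, decay, v_th = 1,
                                   v_reset = 0) {
  v <- 0; spikes <- integer(T)
  for (t in seq_len(T)) {
    v <- v * decay + current
    if (v >= v_th) { spikes[t] <- 1L; v <- v_reset }
  }
  spikes
}
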