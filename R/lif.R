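#' Leaky integrate-and-fire neuron parameters
#'
#' Constructs the constant set governing discrete-time LIF dynamics:
#' membrane potentials leak multiplicatively each step, integrate weighted
#' synaptic input, and fire a spike with hard reset on crossing the
#' threshold.
#'
#' @param v_th firing threshold of the membrane potential (dimensionless).
#' @param v_reset potential a neuron is reset to immediately after a spike.
#' @param tau membrane leak time constant (same units as `dt`).
#' @param dt simulation step length.
#' @param leak leak form: `"exp"` uses the exact exponential factor
#'   `exp(-dt/tau)`; `"linear"` uses the `1 - dt/tau` approximation common
#'   in SNN training frameworks. Both leave a per-step decay factor in
#'   (0, 1).
#' @return An object of class `lif_params`: a list with fields `v_th`,
#'   `v_reset`, `tau`, `dt`, `leak` and the derived `decay` factor.
#' @examples
#' p <- lif_params()
#' p$decay # exp(-1/2) = 0.6065...
#' @export
lif_params <- function(v_th = 1.0, v_reset = 0.0, tau = 2.0, dt = 1.0,
                       leak = c("exp", "linear")) {
  leak <- match.arg(leak)
  stopifnot(is.numeric(v_th), is.numeric(v_reset), is.numeric(tau),
            is.numeric(dt))
  if (!(v_th > v_reset)) stop("`v_th` must exceed `v_reset`")
  if (!(tau > 0) || !(dt > 0)) stop("`tau` and `dt` must be positive")
  decay <- switch(leak, exp = exp(-dt / tau), linear = 1 - dt / tau)
  if (!(decay > 0 && decay < 1))
    stop("derived decay factor must lie in (0, 1); increase tau")
  structure(list(v_th = v_th, v_reset = v_reset, tau = tau, dt = dt,
                 leak = leak, decay = decay),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf("LIF parameters: v_th=%g v_reset=%g tau=%g dt=%g (%s leak, decay=%.5f)\n",
              x$v_th, x$v_reset, x$tau, x$dt, x$leak, x$decay))
  invisible(x)
}

#' Create an initial layer state
#'
#' @param n number of neurons in the layer.
#' @param v_init initial membrane potential: a scalar (recycled) or a
#'   vector of length `n`.
#' @return Object of class `layer_state` with fields `v` (membrane
#'   potentials) and `spikes` (binary vector of last-step outputs).
#' @export
layer_state <- function(n, v_init = 0) {
  if (!(length(v_init) %in% c(1L, n)))
    stop("v_init must be a scalar or length-", n, " vector")
  structure(list(v = rep_len(v_init, n), spikes = rep(0L, n)),
            class = "layer_state")
}

#' Advance one LIF layer by a single timestep
#'
#' Applies the leak, integrates the input current, emits spikes where the
#' updated potential reaches `v_th`, and hard-resets spiking neurons to
#' `v_reset`.
#'
#' @param state a `layer_state` (see [layer_state()]).
#' @param input_current numeric vector of synaptic input, same length as
#'   `state$v`.
#' @param params a `lif_params` object.
#' @return List with `spikes` (binary integer vector) and `state` (the
#'   updated `layer_state`).
#' @examples
#' st <- layer_state(1)
#' lif_step(st, 0.5, lif_params())$spikes # 0: v' = 0.5 < 1
#' @export
lif_step <- function(state, input_current, params) {
  stopifnot(inherits(state, "layer_state"), inherits(params, "lif_params"))
  if (length(input_current) != length(state$v))
    stop("input_current length (", length(input_current),
         ") does not match layer size (", length(state$v), ")")
  v_new <- state$v * params$decay + input_current
  spikes <- as.integer(v_new >= params$v_th)
  v_new[spikes == 1L] <- params$v_reset
  state$v <- v_new
  state$spikes <- spikes
  list(spikes = spikes, state = state)
}

#' Propagate spikes through a weighted LIF layer
#'
#' Equivalent to [lif_step()] with `input_current = weights %*% pre_spikes`.
#' The accumulation can be computed densely or in spike-driven form
#' (iterating only over firing pre-neurons); both give identical results
#' and the choice is an implementation mode, mirroring event-driven
#' hardware where synaptic weights are accumulated only when pre-neurons
#' fire.
#'
#' @param weights numeric matrix shaped (n_post x n_pre).
#' @param pre_spikes binary vector of pre-synaptic spikes, length n_pre.
#' @param state `layer_state` of the post layer (length n_post).
#' @param params `lif_params`.
#' @param mode `"dense"` (matrix-vector product) or `"event"`
#'   (spike-driven accumulation over firing pre-neurons only).
#' @return As [lif_step()].
#' @export
layer_forward <- function(weights, pre_spikes, state, params,
                          mode = c("dense", "event")) {
  mode <- match.arg(mode)
  if (ncol(weights) != length(pre_spikes))
    stop("weights have ", ncol(weights), " columns but ",
         length(pre_spikes), " pre-synaptic spikes were given")
  if (nrow(weights) != length(state$v))
    stop("weights have ", nrow(weights), " rows but the post layer has ",
         length(state$v), " neurons")
  if (mode == "dense") {
    input_current <- as.numeric(weights %*% pre_spikes)
  } else {
    input_current <- numeric(nrow(weights))
    for (j in which(pre_spikes != 0)) {
      input_current <- input_current + weights[, j]
    }
  }
  lif_step(state, input_current, params)
}

#' Firing rate of a spike raster
#'
#' @param raster binary spike matrix shaped (timesteps x neurons), or a
#'   list of such matrices (rates are computed over all entries pooled).
#' @return Mean spike probability per neuron per timestep, in \[0, 1\].
#' @export
firing_rate <- function(raster) {
  if (is.list(raster)) raster <- unlist(raster)
  if (length(raster) == 0) stop("empty raster")
  mean(raster)
}

#' Classify by output-spike voting
#'
#' Aggregates per-neuron spike counts over all timesteps and returns the
#' index of the most active output neuron. Ties are broken toward the
#' lowest class index, so an all-zero raster yields class 1.
#'
#' @param raster binary spike matrix (timesteps x output neurons).
#' @return Integer class index (1-based).
#' @export
classify_by_votes <- function(raster) {
  raster <- as.matrix(raster)
  if (length(raster) == 0) stop("empty raster")
  counts <- colSums(raster)
  which.max(counts)
}
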