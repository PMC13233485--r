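#' Save a network checkpoint as JSON
#'
#' Stores the architecture, encoder kind, per-layer weights (full double
#' precision), sensing budget and LIF constants in a single documented
#' JSON container, portable across platforms.
#'
#' @param net a `cssnn_network` or `cssnn_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path) {
  if (inherits(net, "cssnn_fit")) net <- net$net
  stopifnot(inherits(net, "cssnn_network"))
  layers <- lapply(net$layers, function(layer) {
    p <- layer$params
    base <- list(type = layer$type,
                 lif = list(v_th = p$v_th, v_reset = p$v_reset,
                            tau = p$tau, dt = p$dt, leak = p$leak))
    if (layer$type == "cs") {
      c(base, list(m = layer$mm$m, n = layer$mm$n,
                   sample = layer$mm$sample,
                   W = as.numeric(layer$mm$W)))
    } else {
      c(base, list(n_out = nrow(layer$W), n_in = ncol(layer$W),
                   W = as.numeric(layer$W)))
    }
  })
  obj <- list(format = "cssnn-checkpoint-1", arch = net$arch,
              n_in = net$n_in, encoder = net$encoder, layers = layers)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint path.
#' @return A `cssnn_network`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cssnn-checkpoint-1"))
    stop("not a cssnn checkpoint: ", path)
  layers <- lapply(seq_len(nrow(obj$layers)), function(i) {
    rec <- obj$layers[i, ]
    p <- lif_params(v_th = rec$lif$v_th, v_reset = rec$lif$v_reset,
                    tau = rec$lif$tau, dt = rec$lif$dt,
                    leak = rec$lif$leak)
    if (rec$type == "cs") {
      W <- matrix(rec$W[[1]], rec$m, rec$n)
      list(type = "cs",
           mm = measurement_matrix(rec$m, rec$n, rec$sample, W = W),
           params = p)
    } else {
      list(type = rec$type, W = matrix(rec$W[[1]], rec$n_out, rec$n_in),
           params = p)
    }
  })
  structure(list(arch = obj$arch, n_in = obj$n_in, layers = layers,
                 encoder = obj$encoder),
            class = "cssnn_network")
}

#' Save a quantized network as JSON
#'
#' Stores integer weight codes with their per-tensor scales, the frozen
#' binary sampling matrix, per-layer membrane-potential scales and the
#' quantization spec — the container a deployment toolchain would consume.
#'
#' @param qnet a `quantized_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_quantized_checkpoint <- function(qnet, path) {
  stopifnot(inherits(qnet, "quantized_network"))
  layers <- lapply(qnet$layers, function(layer) {
    p <- layer$params
    base <- list(type = layer$type, mp_scale = layer$mp_scale,
                 lif = list(v_th = p$v_th, v_reset = p$v_reset,
                            tau = p$tau, dt = p$dt, leak = p$leak))
    if (layer$type == "cs") {
      c(base, list(m = nrow(layer$B), n = ncol(layer$B),
                   sample = layer$sample, B = as.integer(layer$B)))
    } else {
      c(base, list(n_out = nrow(layer$Wq), n_in = ncol(layer$Wq),
                   w_scale = layer$w_scale, Wq = as.integer(layer$Wq)))
    }
  })
  obj <- list(format = "cssnn-qcheckpoint-1", arch = qnet$arch,
              n_in = qnet$n_in, encoder = qnet$encoder,
              pixel_levels = qnet$pixel_levels,
              spec = unclass(qnet$spec), layers = layers)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a quantized checkpoint written by [save_quantized_checkpoint()]
#' @param path checkpoint path.
#' @return A `quantized_network`.
#' @export
load_quantized_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cssnn-qcheckpoint-1"))
    stop("not a cssnn quantized checkpoint: ", path)
  layers <- lapply(seq_len(nrow(obj$layers)), function(i) {
    rec <- obj$layers[i, ]
    p <- lif_params(v_th = rec$lif$v_th, v_reset = rec$lif$v_reset,
                    tau = rec$lif$tau, dt = rec$lif$dt,
                    leak = rec$lif$leak)
    if (rec$type == "cs") {
      list(type = "cs", B = matrix(rec$B[[1]], rec$m, rec$n),
           sample = rec$sample, params = p, mp_scale = rec$mp_scale)
    } else {
      list(type = rec$type, Wq = matrix(rec$Wq[[1]], rec$n_out, rec$n_in),
           w_scale = rec$w_scale, params = p, mp_scale = rec$mp_scale)
    }
  })
  structure(list(arch = obj$arch, n_in = obj$n_in, encoder = obj$encoder,
                 layers = layers,
                 spec = quant_spec(obj$spec$weight_bits, obj$spec$mp_bits,
                                   obj$spec$float_bits),
                 pixel_levels = obj$pixel_levels),
            class = "quantized_network")
}
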