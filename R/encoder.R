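#' Binarize a measurement matrix row-wise by top-`sample` selection
#'
#' Each row of the binary output has exactly `sample` ones, placed at the
#' positions of that row's `sample` largest real weights. One row is one
#' measurement (one encoder neuron), so `sample` is the fixed per-measurement
#' sensing budget. Ties are broken toward the lowest column index, making
#' the selection deterministic across platforms.
#'
#' @param W real matrix (m x n) of learnable weights.
#' @param sample number of ones per row, `1 <= sample <= ncol(W)`.
#' @return Binary \{0,1\} matrix of the same shape as `W`.
#' @examples
#' binarize_rows(rbind(c(0.3, -0.2, 0.9, 0.1)), 2) # 1 0 1 0
#' @export
binarize_rows <- function(W, sample) {
  W <- as.matrix(W)
  n <- ncol(W)
  if (!(is.numeric(sample) && length(sample) == 1 && sample >= 1 &&
        sample == as.integer(sample)))
    stop("`sample` must be a positive integer")
  if (sample > n)
    stop("`sample` (", sample, ") exceeds the row length (", n, ")")
  B <- matrix(0L, nrow(W), n)
  for (i in seq_len(nrow(W))) {
    # stable two-key ordering: value descending, column index ascending
    keep <- order(-W[i, ], seq_len(n))[seq_len(sample)]
    B[i, keep] <- 1L
  }
  B
}

#' Learnable compressed-sensing measurement matrix
#'
#' Wraps the real weight matrix `W` (clipped to \[-1, 1\]) together with its
#' per-row sensing budget. The binary sampling operator is derived from `W`
#' on demand by [binarize_rows()]; during training it is re-derived on every
#' forward pass so the selection tracks the weights.
#'
#' @param m number of measurements (rows).
#' @param n input signal length (columns).
#' @param sample ones per row of the derived binary matrix.
#' @param W optional initial real weights (m x n); defaults to
#'   U(-1, 1) draws.
#' @param seed optional RNG seed for the default initialization.
#' @return Object of class `measurement_matrix` with fields `W`, `m`, `n`,
#'   `sample`. Compression rate `m/n` and matrix sparsity `sample/n` are
#'   available via [cr()] and [matrix_sparsity()].
#' @export
measurement_matrix <- function(m, n, sample, W = NULL, seed = NULL) {
  stopifnot(m >= 1, n >= 1)
  if (!(m < n)) stop("a compressing matrix needs m < n")
  if (sample > n) stop("`sample` cannot exceed the input length n")
  if (is.null(W)) {
    if (!is.null(seed)) {
      old <- .save_seed(); on.exit(.restore_seed(old))
      set.seed(seed)
    }
    W <- matrix(stats::runif(m * n, -1, 1), m, n)
  }
  W <- clip_weights(as.matrix(W))
  if (nrow(W) != m || ncol(W) != n) stop("W must be an m x n matrix")
  structure(list(W = W, m = m, n = n, sample = as.integer(sample)),
            class = "measurement_matrix")
}

#' @export
print.measurement_matrix <- function(x, ...) {
  cat(sprintf(
    "Measurement matrix: %d x %d, Sample=%d (CR=%.4g, sparsity=%.4g)\n",
    x$m, x$n, x$sample, cr(x), matrix_sparsity(x)))
  invisible(x)
}

#' Compression rate m/n of a measurement matrix
#' @param mm a `measurement_matrix`.
#' @return `m/n`.
#' @export
cr <- function(mm) mm$m / mm$n

#' Matrix sparsity Sample/n of a measurement matrix
#' @param mm a `measurement_matrix`.
#' @return `sample/n`.
#' @export
matrix_sparsity <- function(mm) mm$sample / mm$n

#' Derived binary sampling operator of a measurement matrix
#' @param mm a `measurement_matrix`.
#' @return Binary m x n matrix with exactly `sample` ones per row.
#' @export
binary_matrix <- function(mm) binarize_rows(mm$W, mm$sample)

#' Compress a signal through a binary sampling operator
#'
#' Computes the measurement vector `B %*% x`. With a \{0,1\} operator and
#' non-negative pixel input the accumulation is non-negative and needs no
#' sign handling, which is what makes the scheme hardware-friendly.
#'
#' @param B binary m x n matrix (e.g. from [binary_matrix()]).
#' @param x non-negative numeric vector of length n.
#' @return Numeric measurement vector of length m.
#' @export
cs_encode <- function(B, x) {
  B <- as.matrix(B)
  if (length(x) != ncol(B))
    stop("signal length ", length(x), " does not match matrix width ",
         ncol(B))
  if (any(x < 0)) stop("pixel input must be non-negative")
  as.numeric(B %*% x)
}

#' Clip weights elementwise to \[-1, 1\]
#'
#' Applied to the encoder weights after every optimizer step to stabilize
#' training; idempotent and order-preserving up to saturation.
#'
#' @param W numeric vector, matrix or array.
#' @return `W` with every entry clamped into \[-1, 1\].
#' @export
clip_weights <- function(W) {
  W[W > 1] <- 1
  W[W < -1] <- -1
  W
}

#' Fixed Gaussian random measurement matrix (compressed-learning baseline)
#'
#' The classical non-learnable compressed-sensing operator: i.i.d. standard
#' normal entries, reproducible from a seed. Used as the fixed-encoder
#' baseline the learned binary matrix is compared against.
#'
#' @param m,n matrix dimensions.
#' @param seed RNG seed.
#' @return m x n numeric matrix of N(0, 1) draws.
#' @export
gaussian_baseline <- function(m, n, seed) {
  stopifnot(m >= 1, n >= 1)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  matrix(stats::rnorm(m * n), m, n)
}

#' Write a measurement matrix to a text file with a JSON sidecar
#'
#' The real weights go to a whitespace-delimited text matrix; `m`, `n`,
#' `sample` and the derived compression rate go to `<path>.json`.
#'
#' @param mm a `measurement_matrix`.
#' @param path output file for the weight matrix.
#' @return `path`, invisibly.
#' @export
write_measurement_matrix <- function(mm, path) {
  stopifnot(inherits(mm, "measurement_matrix"))
  utils::write.table(mm$W, path, row.names = FALSE, col.names = FALSE)
  meta <- list(m = mm$m, n = mm$n, sample = mm$sample, cr = cr(mm),
               sparsity = matrix_sparsity(mm))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a measurement matrix written by [write_measurement_matrix()]
#' @param path file holding the weight matrix (sidecar `<path>.json`).
#' @return A `measurement_matrix`.
#' @export
read_measurement_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  W <- as.matrix(utils::read.table(path))
  dimnames(W) <- NULL
  measurement_matrix(meta$m, meta$n, meta$sample, W = W)
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's
# RNG stream
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
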