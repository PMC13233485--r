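#' Specification of a synthetic sparse-signal dataset
#'
#' Describes the class-structured sparse signals the generators emulate:
#' each class owns a fixed random support of `k_active` pixels (a sparse
#' linear combination of point "basis functions" — the signal family
#' compressed sensing presumes), with `overlap` support pixels shared by
#' all classes. Dense frames carry amplitudes on the support plus clipped
#' Gaussian noise; event frames fire Bernoulli spikes on the support over
#' `T` timesteps on two anti-correlated polarity channels.
#'
#' @param n_features flattened signal length (for event data,
#'   `2 * height * width`).
#' @param n_classes number of classes.
#' @param samples_per_class samples generated per class.
#' @param k_active informative pixels per class support.
#' @param amplitude length-2 range of uniform support amplitudes.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (frames are clipped back into \[0, 1\]).
#' @param overlap support pixels shared by every class; the remaining
#'   `k_active - overlap` pixels are class-exclusive.
#' @param T timesteps (event mode).
#' @param event_rate per-timestep Bernoulli spike probability on the
#'   support (event mode), in \[0, 1\].
#' @param height,width spatial frame shape (event mode;
#'   `2 * height * width` must equal `n_features`).
#' @param seed RNG seed; the generators are pure functions of
#'   (spec, seed).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_features = 784, n_classes = 10,
                           samples_per_class = 60, k_active = 20,
                           amplitude = c(0.5, 1), noise_sd = 0.02,
                           overlap = 4, T = 10, event_rate = 0.3,
                           height = NULL, width = NULL, seed = 1L) {
  stopifnot(k_active <= n_features, noise_sd >= 0,
            event_rate >= 0, event_rate <= 1,
            overlap >= 0, overlap <= k_active,
            length(amplitude) == 2, amplitude[1] <= amplitude[2])
  excl <- (k_active - overlap) * n_classes + overlap
  if (excl > n_features)
    stop("infeasible config: ", n_classes, " classes with ",
         k_active - overlap, " exclusive pixels each plus ", overlap,
         " shared need ", excl, " > ", n_features, " features")
  structure(list(n_features = n_features, n_classes = n_classes,
                 samples_per_class = samples_per_class,
                 k_active = k_active, amplitude = amplitude,
                 noise_sd = noise_sd, overlap = overlap, T = T,
                 event_rate = event_rate, height = height, width = width,
                 seed = seed),
            class = "synthetic_spec")
}

# draw the per-class supports: `overlap` shared pixels plus disjoint
# class-exclusive pixels (classes remain distinguishable by support)
.class_supports <- function(spec) {
  pool <- sample.int(spec$n_features)
  shared <- pool[seq_len(spec$overlap)]
  rest <- pool[setdiff(seq_along(pool), seq_len(spec$overlap))]
  k_excl <- spec$k_active - spec$overlap
  lapply(seq_len(spec$n_classes), function(k) {
    own <- rest[seq_len(k_excl) + (k - 1) * k_excl]
    sort(c(shared, own))
  })
}

#' Generate dense sparse-support frames
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return List of class `synthetic_frames`: `x` (`N x n_features` matrix
#'   in \[0, 1\]), `y` (labels `1..n_classes`), `supports` (per-class
#'   pixel index sets) and `spec`.
#' @export
gen_sparse_frames <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  supports <- .class_supports(spec)
  N <- spec$n_classes * spec$samples_per_class
  x <- matrix(0, N, spec$n_features)
  y <- integer(N)
  i <- 0L
  for (k in seq_len(spec$n_classes)) {
    for (s in seq_len(spec$samples_per_class)) {
      i <- i + 1L
      v <- numeric(spec$n_features)
      v[supports[[k]]] <- stats::runif(spec$k_active, spec$amplitude[1],
                                       spec$amplitude[2])
      if (spec$noise_sd > 0)
        v <- v + stats::rnorm(spec$n_features, 0, spec$noise_sd)
      x[i, ] <- pmin(pmax(v, 0), 1)
      y[i] <- k
    }
  }
  structure(list(x = x, y = y, supports = supports, spec = spec),
            class = "synthetic_frames")
}

#' Generate binary event frames (spiking-sensor emulation)
#'
#' Each class has a spatial support on the `height x width` grid; per
#' timestep, support pixels fire on the ON channel with probability
#' `event_rate`, and the OFF channel fires (with the same probability)
#' only where the ON channel stayed silent, making the two polarities
#' anti-correlated. Frames are flattened in (channel, row, column)
#' row-major order with channel varying slowest — the order the index
#' table assumes.
#'
#' @param spec a [synthetic_spec()] with `height`/`width` set and
#'   `2 * height * width == n_features`.
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return List of class `synthetic_events`: `x` (binary array
#'   `(N, T, n_features)`), `y`, `supports` (per-class pixel indices on
#'   the `height x width` grid), `spec`.
#' @export
gen_event_frames <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$height; w <- spec$width
  if (is.null(h) || is.null(w) || 2 * h * w != spec$n_features)
    stop("event mode needs height/width with 2 * height * width == n_features")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  hw <- h * w
  pool <- sample.int(hw)
  shared <- pool[seq_len(spec$overlap)]
  rest <- pool[setdiff(seq_along(pool), seq_len(spec$overlap))]
  k_excl <- spec$k_active - spec$overlap
  if (k_excl * spec$n_classes + spec$overlap > hw)
    stop("infeasible config: supports do not fit on the spatial grid")
  supports <- lapply(seq_len(spec$n_classes), function(k)
    sort(c(shared, rest[seq_len(k_excl) + (k - 1) * k_excl])))
  N <- spec$n_classes * spec$samples_per_class
  x <- array(0L, c(N, spec$T, spec$n_features))
  y <- integer(N)
  i <- 0L
  for (k in seq_len(spec$n_classes)) {
    # (channel, row, col) row-major, channel slowest: ON at idx,
    # OFF at hw + idx (1-based layout of 0-based ch*h*w + r*w + c)
    on_idx <- supports[[k]]
    off_idx <- hw + supports[[k]]
    for (s in seq_len(spec$samples_per_class)) {
      i <- i + 1L
      for (t in seq_len(spec$T)) {
        on <- stats::rbinom(spec$k_active, 1, spec$event_rate)
        off <- (1L - on) * stats::rbinom(spec$k_active, 1, spec$event_rate)
        x[i, t, on_idx] <- on
        x[i, t, off_idx] <- off
      }
      y[i] <- k
    }
  }
  structure(list(x = x, y = y, supports = supports, spec = spec),
            class = "synthetic_events")
}

#' Stratified disjoint train/test split
#'
#' @param dataset a `synthetic_frames` or `synthetic_events` (or any list
#'   with `x` and `y`).
#' @param test_frac fraction of each class held out for testing.
#' @param seed RNG seed for the within-class shuffle.
#' @return List with `train` and `test`, each holding `x` and `y`; the
#'   two index sets partition the dataset.
#' @export
split_frames <- function(dataset, test_frac = 1/3, seed = 1L) {
  y <- dataset$y
  per_step <- length(dim(dataset$x)) == 3
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  test_idx <- unlist(lapply(unique(y), function(k) {
    idx <- which(y == k)
    sample(idx, max(1, round(length(idx) * test_frac)))
  }))
  take <- function(idx) {
    list(x = if (per_step) dataset$x[idx, , , drop = FALSE]
             else dataset$x[idx, , drop = FALSE],
         y = y[idx])
  }
  list(train = take(setdiff(seq_along(y), test_idx)),
       test = take(test_idx))
}

#' Read an IDX (MNIST-distribution format) file
#'
#' Parses the big-endian IDX container: magic `0x00000801` holds a label
#' vector, `0x00000803` an image stack. Images are returned as raw 8-bit
#' values flattened row-major to length `rows * cols`; divide by 255
#' before encoding (normalization is the encoder's job, the reader is
#' format-faithful).
#'
#' @param path file path.
#' @return For an image file, a list with `images` (`N x (rows*cols)`
#'   integer matrix), `rows`, `cols`; for a label file, a list with
#'   `labels` (integer vector).
#' @export
read_idx <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (length(magic) == 0 || is.na(magic)) stop("empty IDX file")
  if (!(magic %in% c(0x00000801L, 0x00000803L)))
    stop(sprintf("bad IDX magic 0x%08x", magic))
  if (magic == 0x00000801L) {
    n <- readBin(con, "integer", 1, size = 4, endian = "big")
    labels <- readBin(con, "integer", n, size = 1, signed = FALSE)
    if (length(labels) != n)
      stop("truncated IDX file: header promises ", n, " labels, got ",
           length(labels))
    list(labels = as.integer(labels))
  } else {
    dims <- readBin(con, "integer", 3, size = 4, endian = "big")
    n <- dims[1]; rows <- dims[2]; cols <- dims[3]
    px <- readBin(con, "integer", n * rows * cols, size = 1,
                  signed = FALSE)
    if (length(px) != n * rows * cols)
      stop("truncated IDX file: header promises ", n * rows * cols,
           " pixels, got ", length(px))
    # row-major flattening: one image row after another
    images <- matrix(as.integer(px), n, rows * cols, byrow = TRUE)
    list(images = images, rows = rows, cols = cols)
  }
}
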