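#' Build the relative-index table of a binary measurement matrix
#'
#' The sparse hardware representation of the \{0,1\} sampling operator:
#' the coordinates of the ones, sorted along the pixel axis (ties ordered
#' by ascending neuron address), with each pixel index stored as the gap
#' (`diff_pixel`) to the previously sampled pixel. Entries sharing a pixel
#' appear consecutively with `diff_pixel = 0`, so one arriving pixel can
#' be saved into several measurement neurons back to back. The streamed
#' encoder walks this table while pixels arrive serially.
#'
#' @param B binary m x n matrix.
#' @param bits_per_entry storage width per entry; defaults to
#'   `ceil(log2(n))` gap bits plus `ceil(log2(m))` address bits.
#' @return Object of class `index_table`: a data frame with columns
#'   `idx_matrix` (0-based running entry index), `idx_pixel` (0-based
#'   pixel index), `diff_pixel`, `addr_neuron` (0-based measurement row),
#'   with attributes `m`, `n`, `sample`, `bits_per_entry`.
#' @examples
#' B <- matrix(0L, 2, 4); B[1, 2] <- B[2, 2] <- B[1, 4] <- B[2, 4] <- 1L
#' build_index_table(B)$diff_pixel # 1 0 2 0
#' @export
build_index_table <- function(B, bits_per_entry = NULL) {
  B <- as.matrix(B)
  if (!all(B %in% c(0, 1))) stop("B must be a binary {0,1} matrix")
  m <- nrow(B); n <- ncol(B)
  ones <- which(B == 1, arr.ind = TRUE)
  # sort along the pixel axis n, ties by ascending neuron address
  ord <- order(ones[, "col"], ones[, "row"])
  ones <- ones[ord, , drop = FALSE]
  pix <- ones[, "col"] - 1L
  diffs <- diff(c(0L, pix))
  tab <- data.frame(idx_matrix = seq_len(nrow(ones)) - 1L,
                    idx_pixel = pix,
                    diff_pixel = as.integer(diffs),
                    addr_neuron = ones[, "row"] - 1L,
                    row.names = NULL)
  if (is.null(bits_per_entry))
    bits_per_entry <- ceiling(log2(max(n, 2))) + ceiling(log2(max(m, 2)))
  attr(tab, "m") <- m
  attr(tab, "n") <- n
  attr(tab, "sample") <- if (m > 0) as.integer(rowSums(B)[1]) else 0L
  attr(tab, "bits_per_entry") <- as.integer(bits_per_entry)
  class(tab) <- c("index_table", "data.frame")
  tab
}

#' Reconstruct the dense binary matrix from an index table
#' @param table an `index_table`.
#' @return Binary m x n matrix equal to the one the table was built from.
#' @export
reconstruct_matrix <- function(table) {
  m <- attr(table, "m"); n <- attr(table, "n")
  B <- matrix(0L, m, n)
  if (nrow(table) > 0) {
    pix <- cumsum(table$diff_pixel)        # gaps rebuild the pixel index
    B[cbind(table$addr_neuron + 1L, pix + 1L)] <- 1L
  }
  B
}

#' Write an index table as CSV with a JSON-style header line
#'
#' The first line carries `m`, `n`, `sample` and `bits_per_entry` as a
#' comment; the body has one `(diff_pixel, addr_neuron)` row per entry,
#' matching the measurement-matrix memory layout of the processor.
#'
#' @param table an `index_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_index_table <- function(table, path) {
  hdr <- sprintf("# m=%d n=%d sample=%d bits_per_entry=%d",
                 attr(table, "m"), attr(table, "n"),
                 attr(table, "sample"), attr(table, "bits_per_entry"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  writeLines("diff_pixel,addr_neuron", con)
  if (nrow(table) > 0)
    writeLines(paste(table$diff_pixel, table$addr_neuron, sep = ","), con)
  invisible(path)
}

#' Read an index table written by [write_index_table()]
#' @param path file path.
#' @return An `index_table`.
#' @export
read_index_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  get1 <- function(key)
    as.integer(sub(sprintf(".*%s=(\\d+).*", key), "\\1", hdr))
  m <- get1("m"); n <- get1("n"); sample <- get1("sample")
  bits <- get1("bits_per_entry")
  body <- utils::read.csv(text = lines[-1])
  B <- matrix(0L, m, n)
  if (nrow(body) > 0) {
    pix <- cumsum(body$diff_pixel)
    B[cbind(body$addr_neuron + 1L, pix + 1L)] <- 1L
  }
  build_index_table(B, bits_per_entry = bits)
}

#' Streamed compressed-sensing encoding (index-matching FSM)
#'
#' Behavioral emulation of the encoder finite-state machine: pixels arrive
#' serially (one `INPUT_LOAD` cycle each); whenever the running pixel-gap
#' counter matches the current table entry's `diff_pixel`, the pixel value
#' is accumulated into the addressed measurement neuron (one `INPUT_SAVE`
#' cycle and one matrix read per saved entry), repeating immediately for
#' further entries with gap 0 on the same pixel. The result equals the
#' dense product `B %*% pixel_stream` exactly — integer pixel codes give
#' bit-exact agreement. The measurements are complete once the last table
#' entry has been consumed (i.e. once the last sampled pixel has arrived);
#' remaining pixels still take their load cycles, so the encoder phase
#' costs `m * Sample + n` cycles in total.
#'
#' @param table an `index_table`.
#' @param pixel_stream numeric vector of length `n` in arrival order.
#' @return List with `measurements` (length m), `counters` (a
#'   `processor_counters` list: cycles, matrix_reads, neuron_reads,
#'   neuron_writes) and `last_pixel` (0-based index of the last sampled
#'   pixel, or `NA` for an empty table).
#' @export
stream_cs_encode <- function(table, pixel_stream) {
  stopifnot(inherits(table, "index_table"))
  m <- attr(table, "m"); n <- attr(table, "n")
  if (length(pixel_stream) != n)
    stop("pixel stream length ", length(pixel_stream),
         " does not match n = ", n)
  acc <- numeric(m)
  counters <- list(cycles = 0, matrix_reads = 0, weight_reads = 0,
                   neuron_reads = 0, neuron_writes = 0)
  entry <- 1L                      # CS_INIT: point at the first table entry
  last_saved <- 0L                 # pixel index of the last save (0 start)
  n_entries <- nrow(table)
  for (px0 in seq_len(n) - 1L) {   # INPUT_LOAD: one cycle per pixel
    counters$cycles <- counters$cycles + 1
    gap <- px0 - last_saved        # diff-counter value at this pixel
    while (entry <= n_entries && table$diff_pixel[entry] == gap) {
      # INPUT_SAVE: matched entry; repeated saves handle gap-0 entries
      counters$cycles <- counters$cycles + 1
      counters$matrix_reads <- counters$matrix_reads + 1
      counters$neuron_reads <- counters$neuron_reads + 1
      counters$neuron_writes <- counters$neuron_writes + 1
      a <- table$addr_neuron[entry] + 1L
      acc[a] <- acc[a] + pixel_stream[px0 + 1L]
      entry <- entry + 1L
      last_saved <- px0
      gap <- 0L
    }
  }
  if (entry <= n_entries)
    stop("pixel stream ended before the last sampled pixel arrived")
  list(measurements = acc, counters = counters,
       last_pixel = if (n_entries > 0) table$idx_pixel[n_entries] else NA)
}
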