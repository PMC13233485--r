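test_that("the index table encodes sorted coordinates with pixel gaps", {
  # ones at (row, col) = (1,2),(2,2),(1,4),(2,4): column-major walk gives
  # gaps 1,0,2,0 with neuron addresses 0,1,0,1
  B <- matrix(0L, 2, 4)
  B[1, 2] <- B[2, 2] <- B[1, 4] <- B[2, 4] <- 1L
  tab <- build_index_table(B)
  expect_equal(tab$diff_pixel, c(1L, 0L, 2L, 0L))
  expect_equal(tab$addr_neuron, c(0L, 1L, 0L, 1L))
  expect_equal(tab$idx_matrix, 0:3)
  # minimal case: single one at the first pixel has gap 0 from the start
  B1 <- matrix(0L, 1, 3); B1[1, 1] <- 1L
  t1 <- build_index_table(B1)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$diff_pixel, 0L)
  expect_error(build_index_table(matrix(2, 1, 2)), "binary")
})

test_that("index tables reconstruct their matrix exactly", {
  for (seed in 1:10) {
    B <- random_binary_matrix(5, 12, 3, seed)
    tab <- build_index_table(B)
    expect_equal(nrow(tab), 5 * 3)
    # sorted along the pixel axis, ties by neuron address
    expect_true(all(diff(tab$idx_pixel) >= 0))
    expect_identical(reconstruct_matrix(tab), B)
    # gaps rebuild every pixel index
    expect_equal(cumsum(tab$diff_pixel), tab$idx_pixel)
  }
})

test_that("streamed encoding walks the FSM to the dense product", {
  B <- matrix(0L, 2, 4)
  B[1, 2] <- B[2, 2] <- B[1, 4] <- B[2, 4] <- 1L
  tab <- build_index_table(B)
  res <- stream_cs_encode(tab, c(5, 7, 1, 9))
  expect_equal(res$measurements, c(16, 16)) # 7 + 9 on both rows
  expect_equal(res$counters$matrix_reads, 4)
  expect_equal(res$counters$cycles, 2 * 2 + 4) # m*Sample + n
  expect_equal(res$last_pixel, 3L)
  # degenerate all-zero matrix: nothing sampled, no matrix reads
  tab0 <- build_index_table(matrix(0L, 3, 5))
  res0 <- stream_cs_encode(tab0, 1:5)
  expect_equal(res0$measurements, c(0, 0, 0))
  expect_equal(res0$counters$matrix_reads, 0)
  expect_error(stream_cs_encode(tab, c(5, 7)), "length")
})

test_that("streamed encoding equals B %*% x bit-exactly on integer pixels", {
  for (seed in 1:30) {
    set.seed(seed + 500)
    m <- sample(2:6, 1); n <- sample(8:20, 1)
    s <- sample(1:4, 1)
    B <- random_binary_matrix(m, n, s, seed)
    x <- sample(0:255, n, replace = TRUE)
    tab <- build_index_table(B)
    res <- stream_cs_encode(tab, x)
    expect_identical(res$measurements, as.numeric(B %*% x))
    expect_equal(res$counters$matrix_reads, m * s)
    expect_equal(res$counters$cycles, m * s + n)
  }
})

test_that("the processor simulator reproduces the fixed-point reference", {
  for (seed in 1:8) {
    set.seed(seed)
    net <- tiny_net(seed = seed, arch = "8-cs3-fc5-fc3", sample = 2)
    qn <- quantize_network(net, quant_spec())
    x <- round(runif(8) * 255) / 255
    T <- 5
    ref <- quantized_forward(qn, x, T)
    sim <- simulate_inference(qn, x, T)
    for (l in seq_along(ref))
      expect_identical(sim$rasters[[l]], ref[[l]])
    expect_identical(sim$class, classify_by_votes(ref[[length(ref)]]))
    # spike-driven weight reads: firing pre-neurons times post fan-out
    expect_equal(sim$weight_reads_by_layer[2], sum(ref[[1]]) * 5)
    expect_equal(sim$weight_reads_by_layer[3], sum(ref[[2]]) * 3)
    expect_equal(sim$counters$matrix_reads, 3 * 2 * T)
  }
})

test_that("the simulator rejects float models and silent inputs idle", {
  net <- tiny_net(seed = 3)
  expect_error(simulate_inference(net, runif(6), 3), "fixed-point")
  qn <- quantize_network(net)
  res <- simulate_inference(qn, rep(0, 6), 4)
  expect_identical(res$class, 1L) # tie rule on zero votes
  expect_equal(res$counters$weight_reads, 0)
  expect_true(all(vapply(res$rasters, sum, numeric(1)) == 0))
  # analytic floor: only the encoder phase and neuron sweeps remain
  expect_equal(res$counters$matrix_reads, 4 * 3 * 2)
})

test_that("counters grow with activity", {
  net <- tiny_net(seed = 12, arch = "8-cs3-fc5-fc3", sample = 2)
  qn <- quantize_network(net)
  quiet <- simulate_inference(qn, rep(0, 8), 4)$counters
  set.seed(1)
  busy <- simulate_inference(qn, round(runif(8, 0.5, 1) * 255) / 255,
                             4)$counters
  expect_gte(busy$weight_reads, quiet$weight_reads)
  expect_gte(busy$neuron_writes, quiet$neuron_writes)
  expect_gte(busy$cycles, quiet$cycles)
})

test_that("analytic read/write counts follow the closed forms", {
  pr <- predicted_rw_counts(256, 784, 6)
  expect_equal(pr$matrix_reads[1], 1536)
  expect_equal(pr$neuron_rw[1], 1536)
  # silent network floors at the per-layer sweep term
  pr0 <- predicted_rw_counts(4, 16, 2, firing_rate = 0,
                             layers = list(c(4, 8), c(8, 3)))
  expect_equal(pr0$weight_reads[-1], c(0, 0))
  expect_equal(pr0$neuron_rw[-1], c(4, 8))
  # random parameters match direct formula evaluation
  set.seed(33)
  for (rep in 1:10) {
    m <- sample(2:50, 1); n <- sample(51:200, 1)
    s <- sample(1:10, 1); fr <- runif(1)
    pre <- sample(2:40, 1); post <- sample(2:40, 1)
    pr <- predicted_rw_counts(m, n, s, fr, layers = list(c(pre, post)))
    expect_equal(pr$matrix_reads[1], m * s)
    expect_equal(pr$weight_reads[2], post * pre * fr)
    expect_equal(pr$neuron_rw[2], post * pre * fr + pre)
  }
  # counters are monotone in the firing rate
  f1 <- predicted_rw_counts(4, 16, 2, 0.2, list(c(4, 8)))
  f2 <- predicted_rw_counts(4, 16, 2, 0.6, list(c(4, 8)))
  expect_gt(f2$weight_reads[2], f1$weight_reads[2])
})

test_that("index tables round-trip through their CSV container", {
  B <- random_binary_matrix(4, 10, 2, seed = 44)
  tab <- build_index_table(B)
  path <- tempfile(fileext = ".csv")
  write_index_table(tab, path)
  tab2 <- read_index_table(path)
  expect_identical(reconstruct_matrix(tab2), B)
  expect_equal(attr(tab2, "bits_per_entry"), attr(tab, "bits_per_entry"))
})
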