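test_that("sparse-frame generation is a pure function of spec and seed", {
  spec <- synthetic_spec(n_features = 100, n_classes = 3,
                         samples_per_class = 5, k_active = 8, overlap = 2,
                         seed = 6)
  d1 <- gen_sparse_frames(spec)
  d2 <- gen_sparse_frames(spec)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$supports, d2$supports)
  expect_false(identical(d1$x, gen_sparse_frames(spec, seed = 7)$x))
  expect_true(all(d1$x >= 0 & d1$x <= 1))
  expect_equal(dim(d1$x), c(15, 100))
})

test_that("noise-free fixed-amplitude classes are identical and separable", {
  spec <- synthetic_spec(n_features = 60, n_classes = 3,
                         samples_per_class = 4, k_active = 6, overlap = 0,
                         amplitude = c(0.8, 0.8), noise_sd = 0, seed = 2)
  ds <- gen_sparse_frames(spec)
  for (k in 1:3) {
    rows <- ds$x[ds$y == k, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(col) length(unique(col)) == 1)))
  }
  # a nearest-centroid oracle classifies noiseless data perfectly
  centroids <- t(sapply(1:3, function(k) colMeans(ds$x[ds$y == k, ])))
  pred <- apply(ds$x, 1, function(r)
    which.min(colSums((t(centroids) - r)^2)))
  expect_equal(mean(pred == ds$y), 1.0)
})

test_that("infeasible support configurations are rejected", {
  expect_error(synthetic_spec(n_features = 20, n_classes = 5,
                              k_active = 6, overlap = 0),
               "infeasible")
  # the same budget fits once supports may share pixels
  expect_s3_class(synthetic_spec(n_features = 26, n_classes = 5,
                                 k_active = 6, overlap = 1),
                  "synthetic_spec")
})

test_that("event frames honor the rate, polarity and flattening contracts", {
  spec <- synthetic_spec(n_features = 2 * 8 * 8, n_classes = 2,
                         samples_per_class = 3, k_active = 10, overlap = 2,
                         T = 6, event_rate = 1, height = 8, width = 8,
                         seed = 9)
  ev <- gen_event_frames(spec)
  expect_true(all(ev$x %in% c(0L, 1L)))
  # rate 1: ON support fires every step, frames identical across time
  for (i in seq_len(dim(ev$x)[1]))
    for (t in 2:6)
      expect_identical(ev$x[i, t, ], ev$x[i, 1, ])
  # rate 0: silence
  spec0 <- synthetic_spec(n_features = 2 * 8 * 8, n_classes = 2,
                          samples_per_class = 3, k_active = 10,
                          overlap = 2, T = 6, event_rate = 0, height = 8,
                          width = 8, seed = 9)
  expect_true(all(gen_event_frames(spec0)$x == 0))
  # ON and OFF are anti-correlated: never both active at a pixel-timestep
  specm <- synthetic_spec(n_features = 2 * 8 * 8, n_classes = 2,
                          samples_per_class = 5, k_active = 10,
                          overlap = 2, T = 10, event_rate = 0.4,
                          height = 8, width = 8, seed = 4)
  evm <- gen_event_frames(specm)
  hw <- 8 * 8
  on <- evm$x[, , 1:hw]
  off <- evm$x[, , hw + 1:hw]
  expect_true(all(on * off == 0))
  # support firing rate within a 3-sigma binomial bound of event_rate
  n_sup_obs <- 0; n_fired <- 0
  for (i in seq_len(dim(evm$x)[1])) {
    sup <- evm$supports[[evm$y[i]]]
    n_sup_obs <- n_sup_obs + length(sup) * 10
    n_fired <- n_fired + sum(on[i, , sup])
  }
  phat <- n_fired / n_sup_obs
  expect_lt(abs(phat - 0.4), 3 * sqrt(0.4 * 0.6 / n_sup_obs))
  expect_error(gen_event_frames(synthetic_spec(n_features = 100,
                                               height = 8, width = 8,
                                               k_active = 10)),
               "height/width")
})

test_that("train/test splits are stratified and disjoint", {
  spec <- synthetic_spec(n_features = 60, n_classes = 3,
                         samples_per_class = 9, k_active = 6, overlap = 2,
                         seed = 3)
  ds <- gen_sparse_frames(spec)
  sp <- split_frames(ds, 1/3, seed = 3)
  expect_equal(nrow(sp$train$x) + nrow(sp$test$x), 27)
  expect_equal(as.numeric(table(sp$test$y)), rep(3, 3))
  # no sample appears on both sides
  key <- function(x) apply(x, 1, function(r) paste(r, collapse = ","))
  expect_length(intersect(key(sp$train$x), key(sp$test$x)), 0)
})

test_that("the IDX reader recovers images, labels and fails loudly", {
  img_path <- tempfile()
  con <- file(img_path, "wb")
  writeBin(0x00000803L, con, size = 4, endian = "big")
  writeBin(c(2L, 2L, 3L), con, size = 4, endian = "big")
  writeBin(as.raw(c(10, 20, 30, 40, 50, 60, 200, 210, 220, 230, 240, 255)),
           con)
  close(con)
  r <- read_idx(img_path)
  expect_equal(r$rows, 2); expect_equal(r$cols, 3)
  # row-major flattening, 8-bit values untouched
  expect_equal(r$images[1, ], c(10, 20, 30, 40, 50, 60))
  expect_equal(r$images[2, ], c(200, 210, 220, 230, 240, 255))

  lab_path <- tempfile()
  con <- file(lab_path, "wb")
  writeBin(0x00000801L, con, size = 4, endian = "big")
  writeBin(2L, con, size = 4, endian = "big")
  writeBin(as.raw(c(7, 9)), con)
  close(con)
  expect_equal(read_idx(lab_path)$labels, c(7L, 9L))

  # header promises more pixels than the file holds
  bad_path <- tempfile()
  con <- file(bad_path, "wb")
  writeBin(0x00000803L, con, size = 4, endian = "big")
  writeBin(c(5L, 2L, 3L), con, size = 4, endian = "big")
  writeBin(as.raw(1:6), con)
  close(con)
  expect_error(read_idx(bad_path), "truncated")

  empty_path <- tempfile()
  file.create(empty_path)
  expect_error(read_idx(empty_path), "empty|IDX")
  expect_error(read_idx(tempfile()), "no such file")
  wrong_path <- tempfile()
  writeBin(as.raw(c(1, 2, 3, 4)), wrong_path)
  expect_error(read_idx(wrong_path), "magic")
})
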