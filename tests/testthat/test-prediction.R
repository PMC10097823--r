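# Structural contracts of the decoder pipeline; the learning behaviour
# itself is exercised in the acceptance suite.

test_that("model spec enforces the 32,000 / 100 / 500 contract", {
  sp <- model_spec(3)
  expect_equal(sp$conv_filters * 500L, 32000L)
  expect_equal(utils::tail(sp$fc_encoder_sizes, 1), 100L)
  expect_equal(utils::tail(sp$fc_decoder_sizes, 1), 500L)
  expect_error(model_spec(3, conv_filters = 32), "32,000")
  expect_error(model_spec(3, fc_encoder_sizes = c(2000, 500, 200, 50)),
               "bottleneck")
  expect_error(model_spec(3, fc_decoder_sizes = c(200, 400)), "500")
  expect_error(model_spec(4), "n_cells")
})

test_that("model building is deterministic and layer shapes chain", {
  sp <- model_spec(2, seed = 77)
  m1 <- build_model(sp)
  m2 <- build_model(sp)
  expect_identical(m1$weights$Wc, m2$weights$Wc)
  expect_identical(m1$weights$fc[[1]]$W, m2$weights$fc[[1]]$W)
  expect_equal(dim(m1$weights$Wc), c(9 * 2, 64))
  dims <- vapply(m1$weights$fc, function(l) dim(l$W), integer(2))
  expect_equal(dims[1, ], c(32000, 2000, 500, 200, 100, 200, 500))
  expect_equal(dims[2, ], c(2000, 500, 200, 100, 200, 500, 500))
  # forward pass emits a 500-bin waveform per segment
  x <- array(rnorm(4 * 2 * 500, 0, 0.01), dim = c(4, 2, 500))
  out <- predict(m1, x)
  expect_equal(dim(out), c(4, 500))
})

test_that("folds partition the recording into contiguous disjoint blocks", {
  cfg <- generator_config(n_vm_cells = 1, duration_s = 300,
                          spike_rate_per_cycle = 0, seed = 55)
  g <- generate_dataset(cfg)
  folds <- make_folds(g$dataset, "LFP", "Vm1")
  expect_length(folds$blocks, 10)
  lens <- vapply(folds$blocks, function(b) b["end"] - b["start"] + 1,
                 numeric(1))
  expect_true(all(lens == 15000))  # 30 s at 500 Hz
  ends <- vapply(folds$blocks, `[`, numeric(1), "end")
  starts <- vapply(folds$blocks, `[`, numeric(1), "start")
  expect_equal(starts[-1], ends[-10] + 1)  # contiguous, disjoint
  expect_equal(starts[1], 1)
  expect_equal(ends[10], length(folds$lfp))  # union covers the recording
  short <- generate_dataset(generator_config(n_vm_cells = 1,
                                             duration_s = 100, seed = 56))
  expect_error(make_folds(short$dataset, "LFP", "Vm1"), "too short")
  expect_error(make_folds(g$dataset, "LFP", "nope"), "unknown")
})

test_that("segment extraction strides correctly and respects boundaries", {
  cfg <- generator_config(n_vm_cells = 1, duration_s = 300,
                          spike_rate_per_cycle = 0, seed = 55)
  g <- generate_dataset(cfg)
  folds <- make_folds(g$dataset, "LFP", "Vm1")
  te <- extract_segments(folds, 1, "test")        # 30-s block, 100-ms stride
  expect_equal(dim(te$x)[1], 291)                  # floor((30-1)/0.1) + 1
  expect_equal(dim(te$x)[2:3], c(1, 500))
  tr <- extract_segments(folds, 1, "train", stride_s = 1)
  expect_equal(dim(tr$x)[1], 9 * 30)               # 9 blocks, 1-s stride
  # test segments never cross into training blocks
  blk <- folds$blocks[[1]]
  expect_true(all(te$t0_s * 500 + 1 >= blk["start"]))
  expect_true(all(te$t0_s * 500 + 500 <= blk["end"]))
  # capping subsamples reproducibly
  cap <- extract_segments(folds, 1, "train", stride_s = 0.1,
                          max_segments = 100, seed = 3)
  cap2 <- extract_segments(folds, 1, "train", stride_s = 0.1,
                           max_segments = 100, seed = 3)
  expect_equal(dim(cap$x)[1], 100)
  expect_identical(cap$t0_s, cap2$t0_s)
})

test_that("the within-cell shuffle preserves per-channel multisets", {
  set.seed(12)
  segs <- list(x = array(rnorm(20 * 3 * 500), dim = c(20, 3, 500)),
               y = matrix(rnorm(20 * 500), 20, 500), t0_s = 1:20,
               fold_id = 1)
  sh <- shuffle_training(segs, seed = 4)
  expect_identical(sh$y, segs$y)                   # targets untouched
  for (c in 1:3) {
    before <- sort(rowSums(segs$x[, c, ]))
    after <- sort(rowSums(sh$x[, c, ]))
    expect_equal(after, before, tolerance = 1e-12)
  }
  # channels permuted independently: alignment destroyed somewhere
  expect_false(identical(sh$x, segs$x))
  one <- list(x = array(rnorm(1 * 2 * 500), dim = c(1, 2, 500)),
              y = matrix(rnorm(500), 1, 500), t0_s = 0, fold_id = 1)
  expect_identical(shuffle_training(one, seed = 1)$x, one$x)
})

test_that("rmse matches closed forms", {
  expect_equal(rmse(1:10, 1:10), 0)
  expect_equal(rmse(1:10 + 0.3, 1:10), 0.3)
  t <- seq(0, 1 - 1 / 500, by = 1 / 500)
  A <- 2.5
  expect_equal(rmse(rep(0, 500), A * sin(2 * pi * 5 * t)), A / sqrt(2),
               tolerance = 1e-3)
  expect_error(rmse(1:3, 1:4), "length mismatch")
})

test_that("band generalization rejects bands at or above Nyquist", {
  cfg <- generator_config(n_vm_cells = 1, duration_s = 300,
                          spike_rate_per_cycle = 0, seed = 55)
  g <- generate_dataset(cfg)
  expect_error(band_generalization(g$dataset, "LFP", "Vm1",
                                   bands = list(bad = c(200, 300))),
               "Nyquist")
})

test_that("blocks shorter than one window yield no segments", {
  folds <- structure(list(lfp = rnorm(1200), vms = list(rnorm(1200)),
                          fs = 500,
                          blocks = lapply(0:3, function(i)
                            c(start = i * 300 + 1, end = (i + 1) * 300)),
                          lfp_label = "L", cell_labels = "V",
                          band = c(3, 10)),
                     class = "decoder_folds")
  te <- extract_segments(folds, 1, "test")
  expect_equal(dim(te$x)[1], 0)
})
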