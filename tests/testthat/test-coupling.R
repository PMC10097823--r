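test_that("power correlation follows Pearson with the t-test for r", {
  a <- c(1, 2, 3, 5, 8, 4, 2, 6)
  same <- power_correlation(a, a)
  expect_equal(same$r, 1)
  aff <- power_correlation(a, 2 * a + 1)
  expect_equal(aff$r, 1)
  expect_equal(aff$slope, 2)
  expect_equal(aff$intercept, 1)
  set.seed(5)
  x <- rnorm(100); y <- rnorm(100) + 0.5 * x
  pc <- power_correlation(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(pc$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ref$p.value, tolerance = 1e-9)
  expect_error(power_correlation(1:2, 1:2), "3 finite")
  expect_error(power_correlation(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("Dice coefficient matches the 2-ms brute force and its conventions", {
  A <- intervals(0, 2); B <- intervals(1, 3)
  expect_equal(dice_coefficient(A, B), 0.5)
  expect_equal(dice_coefficient(A, B), dice_brute(A, B, 4), tolerance = 1e-9)
  expect_equal(dice_coefficient(A, A), 1)
  expect_equal(dice_coefficient(A, intervals(3, 4)), 0)
  expect_equal(dice_coefficient(intervals(), intervals()), 0)  # empty-empty
  # symmetry and subdivision invariance
  C <- intervals(c(0, 1), c(1, 2))    # same set as A, split in two
  expect_equal(dice_coefficient(C, B), dice_coefficient(B, C))
  expect_equal(dice_coefficient(C, B), dice_coefficient(A, B),
               tolerance = 1e-12)
  set.seed(6)
  for (i in 1:5) {
    s1 <- sort(runif(4, 0, 80)); s2 <- sort(runif(4, 0, 80))
    P1 <- intervals(s1[c(1, 3)], s1[c(2, 4)])
    P2 <- intervals(s2[c(1, 3)], s2[c(2, 4)])
    expect_equal(dice_coefficient(P1, P2), dice_brute(P1, P2, 100, 0.0005),
                 tolerance = 2e-2)
  }
})

test_that("surrogates preserve the duration multiset and match the analytic mean", {
  per <- intervals(c(10, 40), c(12, 43))  # durations 2 and 3 in 100 s
  surr <- surrogate_periods(per, 100, n = 200, seed = 9)
  expect_length(surr, 200)
  for (s in surr[1:20]) {
    expect_equal(sort(interval_lengths(s)), c(2, 3), tolerance = 1e-9)
    expect_true(all(s$start_s >= 0 & s$end_s <= 100 + 1e-9))
    expect_true(all(diff(s$start_s) > 0))
    expect_true(all(s$start_s[-1] >= s$end_s[-nrow(s)] - 1e-9))  # no overlap
  }
  expect_error(surrogate_periods(intervals(0, 100), 100), "freedom")
  expect_error(surrogate_periods(intervals(), 100), "no periods")
})

test_that("cross-correlogram recovers constructed lags with the lead convention", {
  b_eq <- sine_trace(6, dur_s = 30, label = "b")
  expect_equal(crosscorr_lag(b_eq, b_eq)$lag_ms, 0)
  fs <- 500
  for (lag_ms in c(-20, -10, 10, 20)) {
    cfg <- generator_config(n_vm_cells = 0, duration_s = 60,
                            lfp_lag_ms = c(0, lag_ms), noise_sd = 0.2,
                            seed = 31 + lag_ms)
    g <- generate_dataset(cfg)
    a <- bandpass_trace(g$dataset$traces$LFP1)
    b <- bandpass_trace(g$dataset$traces$LFP2)
    expect_equal(crosscorr_lag(a, b)$lag_ms, lag_ms, tolerance = 2)
  }
  # 90-degree offset of a 6-Hz pair: quarter period = 41.7 ms
  s1 <- sine_trace(6, dur_s = 30)
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  s2 <- theta_trace(sin(2 * pi * 6 * t - pi / 2), fs, label = "b")
  expect_equal(abs(crosscorr_lag(s1, s2)$lag_ms), 41.7, tolerance = 2.1)
  expect_error(crosscorr_lag(theta_trace(rep(1, 100), fs),
                             theta_trace(rnorm(100), fs)), "constant")
})

test_that("co-theta periods intersect members and respect the 1-s floor", {
  pa <- structure(data.frame(start_s = 0, end_s = 5, peak_freq_hz = 6,
                             mean_power = 1),
                  class = c("theta_periods", "data.frame"))
  pb <- structure(data.frame(start_s = 4, end_s = 9, peak_freq_hz = 6,
                             mean_power = 1),
                  class = c("theta_periods", "data.frame"))
  cps <- co_theta_periods(list(A = pa, B = pb))
  expect_equal(nrow(cps), 1)        # [4,5): exactly 1 s, kept
  expect_equal(cps$start_s, 4)
  expect_equal(cps$end_s, 5)
  ident <- co_theta_periods(list(A = pa, B = pa))
  expect_equal(ident$start_s, pa$start_s)
  expect_equal(ident$end_s, pa$end_s)
  none <- co_theta_periods(list(A = pa, B = pb[0, ]))
  expect_equal(nrow(none), 0)
  short <- structure(data.frame(start_s = 4.2, end_s = 9,
                                peak_freq_hz = 6, mean_power = 1),
                     class = c("theta_periods", "data.frame"))
  expect_equal(nrow(co_theta_periods(list(A = pa, B = short))), 0)
})

test_that("frequency similarity (1/CV^2) matches hand computations", {
  expect_equal(frequency_similarity(c(4, 5, 6)), 25)
  expect_equal(frequency_similarity(c(6, 6, 6)), Inf)
  expect_equal(frequency_similarity(c(6, 6, 6.6)), 320.3333,
               tolerance = 1e-4)
  expect_error(frequency_similarity(c(4, 5)), "three positive")
  expect_error(frequency_similarity(c(-1, 5, 6)), "three positive")
})

test_that("frequency difference shrinks with power in a constructed relation", {
  pw <- seq(0.5, 5, length.out = 30)
  cps <- data.frame(start_s = seq_len(30), end_s = seq_len(30) + 1,
                    freq_A = 6 + 1 / pw, freq_B = 6,
                    pow_A = pw, pow_B = pw)
  reg <- freq_difference_vs_power(cps, "A", "B")
  expect_lt(reg$r, -0.8)
  expect_lt(reg$p, 1e-6)
  cps2 <- cps; cps2$freq_A <- 6.5
  expect_equal(freq_difference_vs_power(cps2, "A", "B")$slope, 0)
})

test_that("phase differences over co-periods recover constructed offsets", {
  fs <- 500
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  for (off in c(-90, -74, 0, 30, 90)) {
    pa <- instantaneous_phase(theta_trace(cos(2 * pi * 6 * t), fs))
    pb <- instantaneous_phase(
      theta_trace(cos(2 * pi * 6 * t - off * pi / 180), fs))
    cps <- data.frame(start_s = seq(2, 110, by = 5),
                      end_s = seq(2, 110, by = 5) + 2)
    cps$freq_A <- 6; cps$freq_B <- 6
    out <- phase_difference_stats(pa, pb, fs, cps, "A", "B")
    expect_equal(out$n, 22)
    # a lags b by -off: phase_a - phase_b = +off (a at later phase)
    d <- thetalink:::wrap_deg(out$mean_angle_deg - off)
    expect_lt(abs(d), 5)
    expect_lt(out$p, 0.01)
  }
  # frequency gate excludes dissimilar periods
  cps_far <- data.frame(start_s = 2, end_s = 4, freq_A = 6, freq_B = 7)
  empty <- phase_difference_stats(rep(0, length(t)), rep(0, length(t)),
                                  fs, cps_far, "A", "B")
  expect_equal(empty$n, 0)
})

test_that("LFP power tracks the number of theta-emitting cells", {
  ps <- structure(list(values = c(0, 1, 0, 2, 0, 3, 0, 3, 1, 2),
                       bin_s = 1, times_s = 0:9),
                  class = "power_series")
  mk <- function(iv) structure(cbind(iv, peak_freq_hz = 6, mean_power = 1),
                               class = c("theta_periods", "data.frame"))
  vm <- list(
    c1 = mk(intervals(c(1, 3, 5, 7, 8, 9), c(2, 4, 6, 8, 9, 10))),
    c2 = mk(intervals(c(3, 5, 7, 9), c(4, 6, 8, 10))),
    c3 = mk(intervals(c(5, 7), c(6, 8))))
  out <- lfp_power_vs_cell_count(ps, vm)
  expect_equal(unname(out$group_means), c(0, 1, 2, 3))
  expect_gt(out$test$statistic, 2)
  expect_lt(out$test$p, 0.01)
  solo <- list(c1 = mk(intervals(0, 10)))
  expect_error(lfp_power_vs_cell_count(ps, solo), "two non-empty")
})

test_that("similarity analyses recover constructed sign patterns", {
  set.seed(8)
  n <- 100
  f <- matrix(6 + rnorm(3 * n, 0, 0.4), ncol = 3)
  inv <- apply(f, 1, frequency_similarity)
  cps <- data.frame(start_s = seq_len(n), end_s = seq_len(n) + 1,
                    freq_Vm1 = f[, 1], freq_Vm2 = f[, 2], freq_Vm3 = f[, 3],
                    pow_Vm1 = 1, pow_Vm2 = 1, pow_Vm3 = 1)
  # LFP power rises with similarity; LFP frequency sits at the cell mean
  cps$pow_LFP <- log(inv) + rnorm(n, 0, 0.3)
  cps$freq_LFP <- rowMeans(f) + rnorm(n, 0, 2 / sqrt(inv))
  out <- similarity_analyses(cps)
  expect_gt(out$power_vs_similarity$r, 0.3)
  expect_lt(out$power_vs_similarity$p, 0.05)
  expect_lt(out$freq_gap_vs_similarity$r, -0.1)
  expect_equal(out$n_inf, 0)
  cps$freq_Vm1 <- cps$freq_Vm2 <- cps$freq_Vm3 <- 6
  expect_error(similarity_analyses(cps), "finite frequency similarity")
})

test_that("firing-rate relations standardize within cells and pool", {
  mk_cell <- function(powers, rates, seed) {
    per <- structure(data.frame(start_s = seq_along(powers) * 10,
                                end_s = seq_along(powers) * 10 + 2,
                                peak_freq_hz = 5 + 0.3 * seq_along(powers),
                                mean_power = powers),
                     class = c("theta_periods", "data.frame"))
    set.seed(seed)
    times <- unlist(lapply(seq_along(powers), function(i)
      sort(runif(rates[i], per$start_s[i], per$end_s[i]))))
    list(periods = per, spikes = spike_train(sort(times)))
  }
  cells <- lapply(1:6, function(k)
    mk_cell(powers = c(1, 2, 3, 4, 5) * k,
            rates = c(2, 4, 8, 12, 16), seed = k))
  out <- firing_rate_relations(cells)
  expect_gt(out$rate_vs_power$slope, 0.5)
  expect_lt(out$rate_vs_power$p, 0.001)
  # constant rate: zero slope by the zero-variance convention
  const <- lapply(1:4, function(k)
    mk_cell(powers = c(1, 2, 3), rates = c(5, 5, 5), seed = 10 + k))
  expect_equal(firing_rate_relations(const)$rate_vs_power$slope, 0,
               tolerance = 0.2)
  single <- list(mk_cell(powers = 2, rates = 5, seed = 99))
  expect_error(firing_rate_relations(single), "no cell")
})

test_that("linear-sum control degenerates correctly on identical inputs", {
  g <- coupled_fixture()
  v1 <- bandpass_trace(g$dataset$traces$Vm1)
  lfp_as_v1 <- theta_trace(v1$samples, 500, kind = "LFP", label = "L")
  out <- linear_sum_control(lfp_as_v1, list(v1, v1, v1))
  # all Vms identical: every k gives the same correlations, all 1
  expect_true(all(abs(out[["1"]] - 1) < 1e-9))
  expect_equal(length(out[["2"]]), length(out[["1"]]))  # 3 subsets each
  expect_true(all(abs(out[["3"]] - 1) < 1e-9))
})
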