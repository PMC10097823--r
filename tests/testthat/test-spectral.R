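test_that("Morlet spectrogram puts the ridge at a tone's frequency", {
  tr <- sine_trace(6, dur_s = 20)
  spec <- morlet_spectrogram(tr)
  ic <- thetalink:::interior_cols(spec)
  ridge <- spec$freqs_hz[apply(spec$power[, ic], 2, which.max)]
  expect_true(all(abs(ridge - 6) <= 0.25))
  # amplitude-normalized: ridge power ~ tone amplitude
  expect_equal(median(spec$power[spec$freqs_hz == 6, ic]), 1,
               tolerance = 0.05)
  expect_error(morlet_spectrogram(tr, freqs_hz = c(10, 300)), "fs/2")
})

test_that("zero input gives zero power; two tones give two ridges", {
  z <- theta_trace(rep(0, 5000), 500, label = "z")
  expect_equal(max(morlet_spectrogram(z)$power), 0)
  t <- seq(0, 20 - 1 / 500, by = 1 / 500)
  tr <- theta_trace(sin(2 * pi * 4 * t) + sin(2 * pi * 40 * t), 500)
  spec <- morlet_spectrogram(tr)
  ic <- thetalink:::interior_cols(spec)
  p4 <- mean(spec$power[spec$freqs_hz == 4, ic])
  p40 <- mean(spec$power[spec$freqs_hz == 40, ic])
  expect_gt(p4, 0.8); expect_gt(p40, 0.8)
  band <- thetalink:::band_rows(spec, c(3, 10))
  p_theta <- mean(spec$power[band, ic])
  p7 <- mean(spec$power[spec$freqs_hz == 7, ic])
  expect_gt(p4, 5 * p7)   # theta-band mean is dominated by the 4-Hz ridge
})

test_that("threshold rule, run deletion and gap merging follow the contract", {
  baseline <- rep(c(0.5, 1.5), 350)  # mean 1, SD 0.5, 7 s at 100 Hz
  spec <- fake_spectrogram(baseline, theta_power = 10, theta_span = c(2, 5))
  per <- detect_theta_periods(spec)
  expect_equal(nrow(per), 1)
  expect_equal(per$start_s, 2, tolerance = 0.02)
  expect_equal(per$end_s, 5, tolerance = 0.02)
  expect_equal(per$mean_power, 10)

  # constant spectrogram: nothing exceeds mean + 2 SD
  const <- fake_spectrogram(rep(1, 700), theta_power = 1,
                            theta_span = c(0, 0.01))
  expect_equal(nrow(detect_theta_periods(const)), 0)

  # theta runs [0,2] and [2.5,5] with a 0.5-s gap merge into [0,5]
  spec2 <- fake_spectrogram(rep(c(0.5, 1.5), 350), 10, c(0, 2))
  cols <- which(spec2$times_s >= 2.5 & spec2$times_s < 5)
  rows <- which(spec2$freqs_hz >= 3 & spec2$freqs_hz <= 10)
  spec2$power[rows, cols] <- 10
  per2 <- detect_theta_periods(spec2)
  expect_equal(nrow(per2), 1)
  expect_equal(per2$start_s, 0, tolerance = 0.02)
  expect_equal(per2$end_s, 5, tolerance = 0.02)

  # sub-1-s theta runs are deleted
  spec3 <- fake_spectrogram(rep(c(0.5, 1.5), 350), 10, c(2, 2.6))
  expect_equal(nrow(detect_theta_periods(spec3)), 0)

  # recording shorter than min_dur gives an empty list
  tiny <- fake_spectrogram(rep(1, 50), 10, c(0, 0.2))
  expect_equal(nrow(detect_theta_periods(tiny)), 0)
})

test_that("detected periods are disjoint, long enough, and amplitude-invariant", {
  g <- coupled_fixture()
  spec <- morlet_spectrogram(g$dataset$traces$LFP)
  per <- detect_theta_periods(spec)
  expect_gt(nrow(per), 2)
  expect_true(all(per$end_s - per$start_s >= 1 - 1e-9))
  if (nrow(per) > 1)
    expect_true(all(per$start_s[-1] >= per$end_s[-nrow(per)]))
  expect_true(all(per$peak_freq_hz >= 3 & per$peak_freq_hz <= 10))
  scaled <- g$dataset$traces$LFP
  scaled$samples <- scaled$samples * 13.7
  per_s <- detect_theta_periods(morlet_spectrogram(scaled))
  expect_equal(per_s$start_s, per$start_s)
  expect_equal(per_s$end_s, per$end_s)
})

test_that("peak frequency takes the band argmax with low-frequency ties", {
  tr <- sine_trace(6, dur_s = 20)
  spec <- morlet_spectrogram(tr)
  f <- peak_frequency(spec, data.frame(start_s = 5, end_s = 15))
  expect_equal(f, 6, tolerance = 0.25)
  t <- seq(0, 20 - 1 / 500, by = 1 / 500)
  two <- theta_trace(2 * sin(2 * pi * 4 * t) + sin(2 * pi * 8 * t), 500)
  expect_equal(peak_frequency(morlet_spectrogram(two),
                              data.frame(start_s = 5, end_s = 15)), 4,
               tolerance = 0.25)
  # exact ties return the lower frequency (which.max contract)
  spec_tie <- fake_spectrogram(rep(1, 700), 5, c(0, 7))
  expect_equal(peak_frequency(spec_tie, data.frame(start_s = 1, end_s = 6)), 3)
  expect_error(peak_frequency(spec, data.frame(start_s = 50, end_s = 51)),
               "overlap")
})

test_that("Z-scored band power has population mean 0 / SD 1", {
  spec <- fake_spectrogram(rep(1, 1000), 1, c(0, 0.01), fs = 100)
  rows <- which(spec$freqs_hz >= 3 & spec$freqs_hz <= 10)
  # inject band-max powers 1, 2, 3 into three 1-s bins
  spec$power[rows, 1:100] <- 1
  spec$power[rows, 101:200] <- 2
  spec$power[rows, 201:300] <- 3
  spec$times_s <- spec$times_s[1:300]
  spec$power <- spec$power[, 1:300]
  ps <- zscore_band_power(spec, bin_s = 1)
  expect_equal(ps$values, c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  g <- coupled_fixture()
  sp <- morlet_spectrogram(g$dataset$traces$LFP)
  z <- zscore_band_power(sp, bin_s = 1)
  expect_lt(abs(mean(z$values)), 1e-9)
  expect_equal(stats::sd(z$values) * sqrt((length(z$values) - 1) /
                                            length(z$values)), 1,
               tolerance = 1e-9)
  const <- fake_spectrogram(rep(1, 700), 1, c(0, 7))
  expect_warning(zc <- zscore_band_power(const), "zero variance")
  expect_true(all(zc$values == 0))
})

test_that("bandpass keeps in-band tones and rejects out-of-band tones", {
  tone6 <- sine_trace(6, dur_s = 20)
  f6 <- bandpass_trace(tone6, 3, 10)
  mid <- 2000:8000
  expect_equal(max(abs(f6$samples[mid])), 1, tolerance = 0.05)
  # zero-phase: peaks aligned with the input
  expect_gt(stats::cor(f6$samples[mid], tone6$samples[mid]), 0.999)
  tone40 <- sine_trace(40, dur_s = 20)
  f40 <- bandpass_trace(tone40, 3, 10)
  expect_lt(max(abs(f40$samples[mid])), 0.1)  # > 20 dB attenuation
  z <- bandpass_trace(theta_trace(rep(0, 5000), 500), 3, 10)
  expect_equal(max(abs(z$samples)), 0)
  expect_error(bandpass_trace(tone6, 10, 3), "invalid band")
  expect_error(bandpass_trace(tone6, 3, 400), "invalid band")
})

test_that("instantaneous phase follows the peak = 0 convention and advances linearly", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  ph <- instantaneous_phase(theta_trace(cos(2 * pi * 5 * t), fs))
  mid <- 1000:4000
  # cos peaks at t = k/5: phase 0 there
  peaks <- which(abs((t * 5) %% 1) < 1e-9)
  peaks <- peaks[peaks > 1000 & peaks < 4000]
  expect_true(all(abs(ph[peaks]) < 1))
  # ascending zero-crossing at -90, trough at +/-180
  troughs <- peaks + 50
  expect_true(all(abs(abs(ph[troughs]) - 180) < 1))
  asc <- peaks - 25
  expect_true(all(abs(ph[asc] + 90) < 1))
  # phase advances 360 * f / fs per sample
  dph <- diff(ph[mid]) %% 360
  expect_true(all(abs(dph - 360 * 5 / fs) < 1))
})

test_that("spike detection thresholds with refractory separation", {
  flat <- theta_trace(rep(-60, 5000), 500, kind = "Vm")
  expect_length(detect_spikes(flat)$times_s, 0)
  vm <- rep(-60, 5000)
  for (i in c(1000, 2000, 3000)) vm[i:(i + 1)] <- 20
  three <- detect_spikes(theta_trace(vm, 500, kind = "Vm"))
  expect_length(three$times_s, 3)
  expect_equal(three$times_s, c(1000, 2000, 3000) / 500, tolerance = 0.004)
  # two crossings 1 ms apart at 2000 Hz collapse to one spike
  vm2 <- rep(-60, 2000)
  vm2[500] <- 10; vm2[502] <- 10  # 1 ms apart at 2 kHz
  one <- detect_spikes(theta_trace(vm2, 2000, kind = "Vm"))
  expect_length(one$times_s, 1)
})

test_that("spike phase assignment keeps only in-period spikes", {
  fs <- 500
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  ph <- instantaneous_phase(theta_trace(cos(2 * pi * 5 * t), fs))
  per <- structure(data.frame(start_s = 2, end_s = 4, peak_freq_hz = 5,
                              mean_power = 1),
                   class = c("theta_periods", "data.frame"))
  sp <- spike_train(c(1.0, 2.4, 3.0, 5.0))  # peaks of the 5-Hz cosine
  out <- spike_theta_phases(sp, ph, fs, per)
  expect_equal(out$times_s, c(2.4, 3.0))
  expect_true(all(abs(out$phases_deg) < 2))
  none <- spike_theta_phases(sp, ph, fs, per[0, ])
  expect_length(none$times_s, 0)
})

test_that("despiking restores wavelet theta detection on spiking cells", {
  cfg <- generator_config(n_vm_cells = 1, duration_s = 120, coupling_c = 1,
                          noise_sd = 0.2, spike_rate_per_cycle = 0.4,
                          seed = 61)
  g <- generate_dataset(cfg)
  vm <- g$dataset$traces$Vm1
  raw_per <- detect_theta_periods(morlet_spectrogram(vm))
  de <- despike_trace(vm)
  de_per <- detect_theta_periods(morlet_spectrogram(de))
  # spike transients are gone; subthreshold signal untouched elsewhere
  expect_lt(max(de$samples), -20)
  d <- dice_coefficient(de_per, g$ground_truth$theta_epochs)
  expect_gt(d, 0.8)
  expect_gte(d, dice_coefficient(raw_per, g$ground_truth$theta_epochs))
  # a spike-free trace passes through unchanged
  flat <- theta_trace(rep(-60, 1000), 500, kind = "Vm")
  expect_identical(despike_trace(flat)$samples, flat$samples)
})
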