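# Shared fixtures, all built in code.

sine_trace <- function(freq_hz, dur_s = 10, fs = 500, amp = 1,
                       phase_rad = 0, label = "s", kind = "LFP") {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  theta_trace(amp * sin(2 * pi * freq_hz * t + phase_rad), fs,
              kind = kind, label = label)
}

# Hand-built spectrogram object for threshold-rule tests: every frequency
# carries the baseline pattern; theta rows get `theta_power` inside
# `theta_span`. edge_s = 0 so the whole recording is interior.
fake_spectrogram <- function(baseline, theta_power, theta_span,
                             freqs = 1:100, fs = 100) {
  n <- length(baseline)
  power <- matrix(rep(baseline, each = length(freqs)), nrow = length(freqs))
  times <- (seq_len(n) - 1) / fs
  rows <- which(freqs >= 3 & freqs <= 10)
  cols <- which(times >= theta_span[1] & times < theta_span[2])
  power[rows, cols] <- theta_power
  structure(list(power = power, freqs_hz = freqs, times_s = times,
                 fs = fs, edge_s = 0),
            class = "theta_spectrogram")
}

# Brute-force Dice on a 2-ms grid (independent oracle).
dice_brute <- function(pa, pb, duration_s, dt = 0.002) {
  grid <- seq(0, duration_s - dt, by = dt) + dt / 2
  ina <- rep(FALSE, length(grid)); inb <- ina
  for (i in seq_len(nrow(pa)))
    ina <- ina | (grid >= pa$start_s[i] & grid < pa$end_s[i])
  for (i in seq_len(nrow(pb)))
    inb <- inb | (grid >= pb$start_s[i] & grid < pb$end_s[i])
  if (!sum(ina) && !sum(inb)) return(0)
  2 * sum(ina & inb) / (sum(ina) + sum(inb))
}

# Brute-force Jonckheere J by full pair enumeration.
jonckheere_brute <- function(groups) {
  J <- 0
  k <- length(groups)
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    for (x in groups[[i]]) for (y in groups[[j]])
      J <- J + (y > x) + 0.5 * (y == x)
  J
}

# One moderately coupled two-cell dataset reused across test files.
coupled_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_vm_cells = 2, duration_s = 120,
                              coupling_c = 0.8, noise_sd = 0.3, seed = 101)
      cache <<- generate_dataset(cfg)
    }
    cache
  }
})
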