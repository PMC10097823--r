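# Synthetic LFP/Vm/spike generator with known ground truth.
#
# The generator emulates the statistical structure the analyses assume:
# alternating theta/non-theta epochs, a shared theta oscillator with
# frequency drift inside 3-10 Hz, per-cell coupling to that oscillator,
# mediolateral LFP lags, per-cell phase offsets, pink-noise LFP background,
# and spikes locked to theta_Vm peaks.

#' Configuration for the synthetic generator
#'
#' Defaults describe the regime of the recordings the pipeline targets:
#' anesthetized-type (type 2) theta alternating with non-theta at roughly a
#' one-third duty cycle, theta drifting inside 3-10 Hz, weak-to-moderate
#' coupling of single cells to the shared rhythm, and sparse spiking locked
#' to theta_Vm peaks.
#'
#' @param n_vm_cells number of patched cells (0-3).
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz (analysis rate 500).
#' @param theta_freq_range frequency band the shared oscillator drifts in.
#' @param theta_epoch_mean_s,inter_epoch_mean_s mean theta epoch and
#'   inter-epoch durations in seconds (exponential-plus-1 s renewal).
#' @param coupling_c per-cell fraction of theta_Vm drawn from the shared
#'   oscillator, in \[0,1\]; recycled to `n_vm_cells`.
#' @param lfp_lag_ms per-LFP-channel mediolateral lag in ms; the number of
#'   LFP channels equals `length(lfp_lag_ms)`.
#' @param vm_phase_offset_deg per-cell phase offset of the shared component.
#' @param freq_drift_sd random-walk scale of the oscillator frequency in
#'   Hz per sqrt(s).
#' @param noise_sd background noise SD relative to the theta amplitude
#'   (pink noise on LFP channels, white noise on Vm).
#' @param theta_amp_vm_mv theta_Vm amplitude in mV.
#' @param baseline_vm_mv resting Vm in mV.
#' @param spike_rate_per_cycle Bernoulli probability of a spike per
#'   theta_Vm cycle.
#' @param spike_phase_jitter_deg SD of the spike phase around the cycle
#'   peak, degrees.
#' @param lfp_mode `"shared"`: LFP channels carry the shared oscillator
#'   (plus noise); `"cell_mean"`: the single LFP is the mean of the cells'
#'   theta components plus noise (used for multi-cell
#'   interference/similarity experiments).
#' @param seed integer RNG seed; a fixed seed reproduces the dataset
#'   exactly.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_vm_cells = 3, duration_s = 300, fs = 500,
                             theta_freq_range = c(3, 10),
                             theta_epoch_mean_s = 5,
                             inter_epoch_mean_s = 10,
                             coupling_c = 0.5,
                             lfp_lag_ms = 0,
                             vm_phase_offset_deg = 0,
                             freq_drift_sd = 0.2,
                             noise_sd = 0.3,
                             theta_amp_vm_mv = 2,
                             baseline_vm_mv = -60,
                             spike_rate_per_cycle = 0.1,
                             spike_phase_jitter_deg = 30,
                             lfp_mode = c("shared", "cell_mean"),
                             seed = 1L) {
  lfp_mode <- match.arg(lfp_mode)
  if (n_vm_cells < 0 || n_vm_cells > 3)
    stop("'n_vm_cells' must be between 0 and 3")
  if (any(coupling_c < 0 | coupling_c > 1))
    stop("'coupling_c' must lie in [0, 1]")
  if (theta_freq_range[1] <= 0 || theta_freq_range[2] >= fs / 2 ||
      diff(theta_freq_range) <= 0)
    stop("'theta_freq_range' must be an increasing band inside (0, fs/2)")
  if (theta_epoch_mean_s < 1 || inter_epoch_mean_s < 1)
    stop("epoch means must be >= 1 s (epochs have a 1-s minimum)")
  if (n_vm_cells > 0) {
    coupling_c <- rep_len(coupling_c, n_vm_cells)
    vm_phase_offset_deg <- rep_len(vm_phase_offset_deg, n_vm_cells)
  }
  structure(list(
    n_vm_cells = as.integer(n_vm_cells), duration_s = duration_s, fs = fs,
    theta_freq_range = theta_freq_range,
    theta_epoch_mean_s = theta_epoch_mean_s,
    inter_epoch_mean_s = inter_epoch_mean_s,
    coupling_c = coupling_c, lfp_lag_ms = lfp_lag_ms,
    vm_phase_offset_deg = vm_phase_offset_deg,
    freq_drift_sd = freq_drift_sd, noise_sd = noise_sd,
    theta_amp_vm_mv = theta_amp_vm_mv, baseline_vm_mv = baseline_vm_mv,
    spike_rate_per_cycle = spike_rate_per_cycle,
    spike_phase_jitter_deg = spike_phase_jitter_deg,
    lfp_mode = lfp_mode, seed = as.integer(seed)),
    class = "generator_config")
}

# Alternating-renewal epochs: durations are 1 s + exponential with the
# requested mean. Returns an `intervals` data.frame of theta epochs.
draw_epochs <- function(duration_s, theta_mean, inter_mean) {
  t <- 0; st <- numeric(0); en <- numeric(0)
  # start in a non-theta stretch (random fraction of one inter-epoch)
  t <- stats::runif(1, 0, inter_mean)
  while (t < duration_s) {
    d <- 1 + if (theta_mean > 1) stats::rexp(1, 1 / (theta_mean - 1)) else 0
    if (t + 1 > duration_s) break
    st <- c(st, t); en <- c(en, min(t + d, duration_s))
    t <- t + d + 1 +
      if (inter_mean > 1) stats::rexp(1, 1 / (inter_mean - 1)) else 0
  }
  if (!length(st)) intervals() else intervals(st, en)
}

# Reflected random-walk frequency series inside [lo, hi].
draw_freq_walk <- function(n, dt, range, drift_sd) {
  lo <- range[1]; hi <- range[2]; span <- hi - lo
  f0 <- stats::runif(1, lo, hi)
  g <- f0 + cumsum(c(0, stats::rnorm(n - 1, 0, drift_sd * sqrt(dt))))
  m <- (g - lo) %% (2 * span)
  lo + ifelse(m > span, 2 * span - m, m)
}

# Raised-cosine-gated epoch indicator (100-ms ramps avoid onset clicks).
epoch_gate <- function(epochs, n, fs, ramp_s = 0.1) {
  g <- numeric(n)
  if (!nrow(epochs)) return(g)
  for (i in seq_len(nrow(epochs))) {
    i0 <- max(1L, floor(epochs$start_s[i] * fs) + 1L)
    i1 <- min(n, ceiling(epochs$end_s[i] * fs))
    g[i0:i1] <- 1
  }
  nr <- max(1L, as.integer(round(ramp_s * fs)))
  kern <- 0.5 - 0.5 * cos(2 * pi * seq_len(nr) / (nr + 1))
  kern <- kern / sum(kern)
  g <- stats::filter(c(rep(g[1], nr), g, rep(g[n], nr)), kern, sides = 2)
  as.numeric(g[(nr + 1):(nr + n)])
}

# 1/f-amplitude (pink) noise with the requested SD.
pink_noise <- function(n, sd_target) {
  if (sd_target == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- c(1, seq_len(n - 1))           # avoid division by zero at DC
  f <- pmin(k, n - k + 1)             # symmetric frequency index
  Wp <- W / sqrt(f)
  Wp[1] <- 0
  x <- Re(stats::fft(Wp, inverse = TRUE) / n)
  x * sd_target / stats::sd(x)
}

# Shift a series by a (possibly fractional) number of samples; positive
# lag_s delays the series (y(t) = x(t - lag)).
shift_series <- function(x, lag_s, fs) {
  n <- length(x)
  lag <- lag_s * fs
  idx <- seq_len(n) - lag
  stats::approx(seq_len(n), x, xout = idx, rule = 2)$y
}

#' Generate a synthetic LFP/Vm/spike dataset with ground truth
#'
#' Construction: (i) alternating-renewal theta/non-theta epochs; (ii)
#' within theta epochs a shared oscillator `s(t) = sin(Phi(t))` whose
#' frequency performs a reflected random walk inside the theta band; (iii)
#' LFP channels are lagged copies of the shared oscillator plus pink noise
#' (or, with `lfp_mode = "cell_mean"`, the mean of the cells' theta
#' components plus pink noise); (iv) each cell's theta_Vm mixes the shared
#' oscillator (weight `coupling_c`) with a private oscillator having its
#' own epochs and frequency walk (weight `1 - coupling_c`), on a -60 mV
#' baseline with white noise; (v) spikes are drawn per theta_Vm cycle
#' (Bernoulli) at the cycle peak plus Gaussian phase jitter and rendered as
#' 2-ms 80-mV triangular transients.
#'
#' @param config a [generator_config()].
#' @return list with `dataset` (a `theta_dataset`) and `ground_truth`
#'   (class `synthetic_ground_truth`: shared `theta_epochs`, `inst_freq`,
#'   per-cell private epochs and frequency walks, configured lags, offsets
#'   and couplings).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  fs <- config$fs; n <- as.integer(round(config$duration_s * fs))
  dt <- 1 / fs
  epochs <- draw_epochs(config$duration_s, config$theta_epoch_mean_s,
                        config$inter_epoch_mean_s)
  f_sh <- draw_freq_walk(n, dt, config$theta_freq_range, config$freq_drift_sd)
  phi <- 2 * pi * cumsum(f_sh) * dt
  gate <- epoch_gate(epochs, n, fs)
  s_shared <- gate * sin(phi)

  ncell <- config$n_vm_cells
  cells <- vector("list", ncell)
  vm_traces <- list()
  spikes <- list()
  theta_comp <- matrix(0, nrow = n, ncol = max(ncell, 1))
  for (i in seq_len(ncell)) {
    pe <- draw_epochs(config$duration_s, config$theta_epoch_mean_s,
                      config$inter_epoch_mean_s)
    f_pr <- draw_freq_walk(n, dt, config$theta_freq_range,
                           config$freq_drift_sd)
    phi_pr <- 2 * pi * cumsum(f_pr) * dt
    g_pr <- epoch_gate(pe, n, fs)
    ci <- config$coupling_c[i]
    off <- config$vm_phase_offset_deg[i] * pi / 180
    y <- config$theta_amp_vm_mv *
      (ci * gate * sin(phi + off) + (1 - ci) * g_pr * sin(phi_pr))
    theta_comp[, i] <- y
    vm <- config$baseline_vm_mv + y +
      stats::rnorm(n, 0, config$noise_sd * config$theta_amp_vm_mv)
    lb <- paste0("Vm", i)
    sp <- draw_spikes(y, f_sh, f_pr, ci, fs, config)
    vm <- add_spike_waveforms(vm, sp, fs)
    vm_traces[[lb]] <- theta_trace(vm, fs, kind = "Vm", label = lb,
                             coords = c(-2.0, 2.0 + 0.1 * i, 1.2))
    spikes[[lb]] <- spike_train(sp)
    cells[[i]] <- list(private_epochs = pe, private_freq = f_pr,
                       coupling = ci,
                       phase_offset_deg = config$vm_phase_offset_deg[i])
  }

  lfp_traces <- list()
  if (config$lfp_mode == "shared") {
    for (k in seq_along(config$lfp_lag_ms)) {
      lag_s <- config$lfp_lag_ms[k] / 1000
      x <- shift_series(s_shared, lag_s, fs) +
        pink_noise(n, config$noise_sd)
      lb <- if (length(config$lfp_lag_ms) == 1) "LFP" else paste0("LFP", k)
      # ML coordinate increases with the configured lag: medial leads
      lfp_traces[[lb]] <- theta_trace(x, fs, kind = "LFP", label = lb,
                                coords = c(-2.0, 1.8 + 0.2 * k, 1.1))
    }
  } else {
    if (ncell == 0) stop("'cell_mean' LFP mode needs at least one cell")
    x <- rowMeans(theta_comp[, seq_len(ncell), drop = FALSE]) /
      config$theta_amp_vm_mv + pink_noise(n, config$noise_sd)
    lfp_traces[["LFP"]] <- theta_trace(x, fs, kind = "LFP", label = "LFP",
                                 coords = c(-2.0, 2.0, 1.1))
  }

  ds <- theta_dataset(c(lfp_traces, vm_traces),
                      spikes = if (length(spikes)) spikes else NULL,
                      meta = list(generator_seed = config$seed))
  gt <- structure(list(
    theta_epochs = epochs, inst_freq = f_sh,
    cells = cells, lfp_lag_ms = config$lfp_lag_ms,
    vm_phase_offset_deg = config$vm_phase_offset_deg,
    coupling_c = config$coupling_c, config = config),
    class = "synthetic_ground_truth")
  list(dataset = ds, ground_truth = gt)
}

# Spikes: Bernoulli per theta_Vm cycle at the cycle peak + phase jitter.
draw_spikes <- function(theta_vm, f_shared, f_private, ci, fs, config) {
  if (config$spike_rate_per_cycle <= 0) return(numeric(0))
  n <- length(theta_vm)
  amp <- config$theta_amp_vm_mv
  d <- diff(theta_vm)
  pk <- which(d[-1] <= 0 & d[-length(d)] > 0) + 1L
  pk <- pk[theta_vm[pk] > 0.3 * amp]     # peaks of a substantial cycle
  if (!length(pk)) return(numeric(0))
  fire <- stats::runif(length(pk)) < config$spike_rate_per_cycle
  pk <- pk[fire]
  if (!length(pk)) return(numeric(0))
  f_loc <- if (ci >= 0.5) f_shared[pk] else f_private[pk]
  jit <- stats::rnorm(length(pk), 0, config$spike_phase_jitter_deg)
  t_sp <- (pk - 1) / fs + jit / 360 / f_loc
  sort(t_sp[t_sp > 0 & t_sp < n / fs])
}

# Render 2-ms, 80-mV triangular spike transients into the Vm trace.
add_spike_waveforms <- function(vm, spike_times, fs, amp_mv = 80,
                                width_s = 0.002) {
  if (!length(spike_times)) return(vm)
  half <- max(1L, as.integer(round(width_s * fs / 2)))
  shape <- amp_mv * (1 - abs(seq(-half, half)) / (half + 1))
  n <- length(vm)
  for (t in spike_times) {
    i <- as.integer(round(t * fs)) + 1L
    lo <- max(1L, i - half); hi <- min(n, i + half)
    vm[lo:hi] <- vm[lo:hi] + shape[(lo - (i - half) + 1L):(hi - (i - half) + 1L)]
  }
  vm
}

#' Summarize generator ground truth epochs
#'
#' @param gt a `synthetic_ground_truth`.
#' @return data.frame with one row per shared theta epoch: `start_s`,
#'   `end_s`, `duration_s`, `mean_freq_hz` (mean oscillator frequency over
#'   the epoch).
#' @export
summarize_ground_truth <- function(gt) {
  stopifnot(inherits(gt, "synthetic_ground_truth"))
  ep <- gt$theta_epochs
  if (!nrow(ep))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), mean_freq_hz = numeric(0)))
  fs <- gt$config$fs
  mean_f <- vapply(seq_len(nrow(ep)), function(i) {
    i0 <- floor(ep$start_s[i] * fs) + 1
    i1 <- min(length(gt$inst_freq), ceiling(ep$end_s[i] * fs))
    mean(gt$inst_freq[i0:i1])
  }, numeric(1))
  data.frame(start_s = ep$start_s, end_s = ep$end_s,
             duration_s = ep$end_s - ep$start_s, mean_freq_hz = mean_f)
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat(sprintf("<synthetic_ground_truth> %d theta epochs, %d cell(s), seed %d\n",
              nrow(x$theta_epochs), length(x$cells), x$config$seed))
  invisible(x)
}
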