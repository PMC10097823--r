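# Wavelet spectrograms, theta-period detection, band filtering, phase and
# spike extraction.

#' Default wavelet frequency grid
#'
#' 1-100 Hz: 0.25-Hz steps up to 20 Hz (dense where theta lives), 1-Hz
#' steps above.
#' @return increasing numeric vector of frequencies in Hz.
#' @export
theta_freq_grid <- function() c(seq(1, 20, by = 0.25), seq(21, 100, by = 1))

#' Complex-Morlet wavelet spectrogram
#'
#' Computes the magnitude of complex Morlet coefficients (centre parameter
#' `omega0 = 6`) at each frequency of the grid, via FFT convolution with the
#' analytic wavelet. Coefficients are amplitude-normalized: a pure sinusoid
#' of amplitude A yields ridge power A at its frequency. Columns within one
#' wavelet support (3 temporal SDs at the lowest frequency) of either end
#' are edge-flagged and excluded from baseline statistics downstream.
#'
#' @param tr a `theta_trace`; analyses assume the 500-Hz rate (downsample
#'   first via [downsample_trace()]).
#' @param freqs_hz frequency grid, default [theta_freq_grid()]; must lie in
#'   (0, fs/2).
#' @param omega0 Morlet centre frequency parameter (default 6).
#' @return object of class `theta_spectrogram`: `power` (n_freqs x n_times
#'   magnitude matrix), `freqs_hz`, `times_s`, `fs`, `edge_s` (edge margin
#'   in seconds).
#' @export
morlet_spectrogram <- function(tr, freqs_hz = theta_freq_grid(), omega0 = 6) {
  stopifnot(inherits(tr, "theta_trace"))
  fs <- tr$fs
  if (any(freqs_hz <= 0) || any(freqs_hz >= fs / 2))
    stop("frequency grid must lie strictly inside (0, fs/2)")
  freqs_hz <- sort(freqs_hz)
  x <- tr$samples
  n <- length(x)
  nfft <- stats::nextn(2L * n, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  w <- 2 * pi * fs * c(seq(0, floor(nfft / 2)),
                       seq(floor(nfft / 2) + 1, nfft - 1) - nfft) / nfft
  pos <- w > 0
  power <- matrix(0, nrow = length(freqs_hz), ncol = n)
  for (i in seq_along(freqs_hz)) {
    a <- omega0 / (2 * pi * freqs_hz[i])          # scale in seconds
    H <- numeric(nfft)
    H[pos] <- 2 * exp(-0.5 * (a * w[pos] - omega0)^2)
    W <- stats::fft(X * H, inverse = TRUE) / nfft
    power[i, ] <- Mod(W[seq_len(n)])
  }
  edge_s <- 3 * omega0 / (2 * pi * min(freqs_hz))
  structure(list(power = power, freqs_hz = freqs_hz,
                 times_s = (seq_len(n) - 1) / fs, fs = fs,
                 edge_s = edge_s),
            class = "theta_spectrogram")
}

#' @export
print.theta_spectrogram <- function(x, ...) {
  cat(sprintf("<theta_spectrogram> %d freqs (%g-%g Hz) x %d times (%.1f s)\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_s), length(x$times_s) / x$fs))
  invisible(x)
}

band_rows <- function(spec, band) {
  which(spec$freqs_hz >= band[1] & spec$freqs_hz <= band[2])
}

# Columns unaffected by wavelet edge effects.
interior_cols <- function(spec) {
  t <- spec$times_s
  which(t >= spec$edge_s & t <= t[length(t)] - spec$edge_s)
}

#' Detect theta periods from a wavelet spectrogram
#'
#' A sample belongs to the theta state when the mean wavelet magnitude over
#' 3-10 Hz exceeds `mean + k_sd * SD` of the baseline statistic, where the
#' baseline is the time series of mean magnitude across the whole 1-100 Hz
#' grid, summarized over the (edge-trimmed) recording. The threshold is
#' self-normalized: rescaling the whole trace leaves the detected periods
#' unchanged. Morphological cleanup deletes theta runs shorter than
#' `min_dur_s` first and then fills shorter-than-`min_dur_s` gaps (this
#' order is idempotent).
#'
#' @param spec a `theta_spectrogram` covering 1-100 Hz.
#' @param k_sd SD multiplier (default 2, the calibrated value; see
#'   [threshold_scan()]).
#' @param min_dur_s minimum duration of both theta runs and gaps (default 1).
#' @param band theta band in Hz (default `c(3, 10)`).
#' @return data.frame of class `theta_periods` with columns `start_s`,
#'   `end_s`, `peak_freq_hz`, `mean_power`; zero rows when nothing exceeds
#'   threshold or the recording is shorter than `min_dur_s`.
#' @export
detect_theta_periods <- function(spec, k_sd = 2, min_dur_s = 1,
                                 band = c(3, 10)) {
  stopifnot(inherits(spec, "theta_spectrogram"))
  empty <- structure(data.frame(start_s = numeric(0), end_s = numeric(0),
                                peak_freq_hz = numeric(0),
                                mean_power = numeric(0)),
                     class = c("theta_periods", "data.frame"))
  n <- length(spec$times_s)
  if (n / spec$fs < min_dur_s) return(empty)
  theta_series <- colMeans(spec$power[band_rows(spec, band), , drop = FALSE])
  base_series <- colMeans(spec$power)
  ic <- interior_cols(spec)
  if (!length(ic)) ic <- seq_len(n)
  thr <- mean(base_series[ic]) + k_sd * stats::sd(base_series[ic])
  mask <- theta_series > thr
  min_len <- as.integer(round(min_dur_s * spec$fs))
  mask <- prune_runs(mask, min_len, value = TRUE)    # delete short theta runs
  mask <- prune_runs(mask, min_len, value = FALSE)   # fill short gaps
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(empty)
  out <- lapply(keep, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    iv_start <- spec$times_s[i0]
    iv_end <- spec$times_s[i1] + 1 / spec$fs
    data.frame(start_s = iv_start, end_s = iv_end,
               peak_freq_hz = peak_freq_cols(spec, i0:i1, band),
               mean_power = mean(theta_series[i0:i1]))
  })
  out <- do.call(rbind, out)
  class(out) <- c("theta_periods", "data.frame")
  out
}

# Flip runs of `value` shorter than min_len to the opposite state. Runs
# touching the recording edges are treated like interior runs for theta
# deletions but edge gaps are never filled (they are not between theta runs).
prune_runs <- function(mask, min_len, value) {
  r <- rle(mask)
  k <- length(r$lengths)
  for (j in seq_len(k)) {
    if (r$values[j] == value && r$lengths[j] < min_len) {
      if (!value && (j == 1L || j == k)) next  # don't fill edge gaps
      r$values[j] <- !value
    }
  }
  inverse.rle(r)
}

peak_freq_cols <- function(spec, cols, band) {
  rows <- band_rows(spec, band)
  prof <- rowMeans(spec$power[rows, cols, drop = FALSE])
  spec$freqs_hz[rows[which.max(prof)]]  # which.max ties -> lowest frequency
}

#' Peak frequency of a spectrogram over an interval
#'
#' The frequency at which the time-averaged wavelet power over the interval
#' is maximal, restricted to `band`. Ties return the lowest frequency.
#'
#' @param spec a `theta_spectrogram`.
#' @param interval one-row data.frame (or list) with `start_s`, `end_s`.
#' @param band frequency band, default `c(3, 10)` Hz.
#' @return frequency in Hz.
#' @export
peak_frequency <- function(spec, interval, band = c(3, 10)) {
  i0 <- floor(interval$start_s[1] * spec$fs) + 1
  i1 <- ceiling(interval$end_s[1] * spec$fs)
  i1 <- min(i1, length(spec$times_s))
  if (i1 < i0) stop("interval does not overlap the spectrogram")
  peak_freq_cols(spec, i0:i1, band)
}

#' Binned, Z-scored band power series
#'
#' Averages the wavelet power of each frequency across `bin_s` bins, takes
#' the maximum across the band per bin, and Z-scores the resulting series
#' across all bins of the recording (population SD).
#'
#' @param spec a `theta_spectrogram`.
#' @param band band in Hz, default `c(3, 10)`.
#' @param bin_s bin width in seconds (1 for segment analyses, 0.1 for the
#'   100-ms power tracking).
#' @param zscore if `FALSE`, return the raw per-bin band-max powers.
#' @return object of class `power_series`: `values`, `bin_s`, `times_s`
#'   (bin start times).
#' @export
zscore_band_power <- function(spec, band = c(3, 10), bin_s = 1,
                              zscore = TRUE) {
  nbin_len <- as.integer(round(bin_s * spec$fs))
  nb <- floor(length(spec$times_s) / nbin_len)
  if (nb < 2) stop("need at least 2 bins")
  rows <- band_rows(spec, band)
  vals <- vapply(seq_len(nb), function(b) {
    cols <- ((b - 1L) * nbin_len + 1L):(b * nbin_len)
    max(rowMeans(spec$power[rows, cols, drop = FALSE]))
  }, numeric(1))
  if (zscore) {
    s <- stats::sd(vals) * sqrt((nb - 1) / nb)  # population SD
    if (s == 0) {
      warning("zero variance in band power; returning all-zero series")
      vals <- rep(0, nb)
    } else vals <- (vals - mean(vals)) / s
  }
  structure(list(values = vals, bin_s = bin_s,
                 times_s = (seq_len(nb) - 1) * bin_s),
            class = "power_series")
}

#' Zero-phase Butterworth bandpass
#'
#' Order-3 Butterworth applied forward-backward (`filtfilt`), so the output
#' is phase-neutral -- mandatory because phase differences are analysed.
#'
#' @param tr a `theta_trace`.
#' @param lo_hz,hi_hz band edges, `0 < lo < hi < fs/2`.
#' @return filtered `theta_trace` with attribute `band`.
#' @export
bandpass_trace <- function(tr, lo_hz = 3, hi_hz = 10) {
  stopifnot(inherits(tr, "theta_trace"))
  if (!(lo_hz > 0 && hi_hz > lo_hz && hi_hz < tr$fs / 2))
    stop("invalid band: need 0 < lo < hi < fs/2")
  bf <- signal::butter(3, c(lo_hz, hi_hz) / (tr$fs / 2), type = "pass")
  out <- tr
  out$samples <- signal::filtfilt(bf, tr$samples)
  attr(out, "band") <- c(lo_hz, hi_hz)
  out
}

#' Instantaneous phase of a band-filtered trace
#'
#' Analytic-signal (Hilbert) phase in degrees with the waveform convention
#' 0 deg = local peak, -90 deg = ascending zero-crossing, +/-180 deg =
#' trough; range \[-180, 180).
#'
#' @param tr a theta-band-filtered `theta_trace` (see [bandpass_trace()]).
#' @return numeric vector of phases in degrees, one per sample.
#' @export
instantaneous_phase <- function(tr) {
  x <- if (inherits(tr, "theta_trace")) tr$samples else as.numeric(tr)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  wrap_deg(Arg(z) * 180 / pi)
}

#' Detect spikes by threshold crossing
#'
#' Upward crossings of `thresh_mv` with a 2-ms refractory separation; the
#' spike time is the crossing time. The -20 mV default mirrors the unit
#' inclusion criterion for action potential amplitude.
#'
#' @param vm a Vm `theta_trace`.
#' @param thresh_mv detection threshold in mV (default -20).
#' @param refractory_s minimum separation in seconds (default 0.002).
#' @return a `spike_train` (phases unassigned).
#' @export
detect_spikes <- function(vm, thresh_mv = -20, refractory_s = 0.002) {
  x <- vm$samples
  up <- which(x[-1] >= thresh_mv & x[-length(x)] < thresh_mv)
  if (!length(up)) return(spike_train(numeric(0)))
  times <- up / vm$fs  # first sample at/above threshold
  keep <- c(TRUE, diff(times) >= refractory_s)
  # enforce refractory sequentially (diff-based pruning can chain)
  out <- numeric(0); last <- -Inf
  for (t in times) {
    if (t - last >= refractory_s) { out <- c(out, t); last <- t }
  }
  spike_train(out)
}

#' Remove action-potential transients from a Vm trace
#'
#' Detects spikes by threshold crossing and replaces a short window around
#' each spike with a linear interpolation of the flanking subthreshold
#' values. Off by default in the analysis chain (the theta bandpass
#' attenuates 2-ms transients), but spike energy is broadband and large, so
#' wavelet-based theta-period detection on spiking cells needs it: the
#' 1-100 Hz baseline statistic is otherwise inflated by spike power.
#'
#' @param vm a Vm `theta_trace`.
#' @param thresh_mv spike detection threshold in mV (default -20).
#' @param window_ms half-width of the replaced window in ms (default 4).
#' @return the despiked `theta_trace`.
#' @export
despike_trace <- function(vm, thresh_mv = -20, window_ms = 4) {
  sp <- detect_spikes(vm, thresh_mv = thresh_mv)
  if (!length(sp$times_s)) return(vm)
  x <- vm$samples
  n <- length(x)
  half <- max(1L, as.integer(round(window_ms / 1000 * vm$fs)))
  for (t in sp$times_s) {
    i <- as.integer(round(t * vm$fs)) + 1L
    lo <- max(2L, i - half); hi <- min(n - 1L, i + half)
    x[lo:hi] <- seq(x[lo - 1L], x[hi + 1L], length.out = hi - lo + 1L)
  }
  out <- vm
  out$samples <- x
  out
}

#' Assign theta phases to spikes inside theta periods
#'
#' Spikes falling outside all supplied theta periods are dropped; the rest
#' get the instantaneous phase of the (theta-filtered) reference trace at
#' the spike time.
#'
#' @param spikes a `spike_train`.
#' @param phase numeric phase series in degrees (from
#'   [instantaneous_phase()]).
#' @param fs sampling rate of `phase` in Hz.
#' @param periods `theta_periods` data.frame.
#' @return a `spike_train` with `phases_deg` set; only in-period spikes.
#' @export
spike_theta_phases <- function(spikes, phase, fs, periods) {
  if (!nrow(periods) || !length(spikes$times_s))
    return(spike_train(numeric(0), numeric(0)))
  t <- spikes$times_s
  inside <- vapply(t, function(ti)
    any(ti >= periods$start_s & ti < periods$end_s), logical(1))
  t <- t[inside]
  if (!length(t)) return(spike_train(numeric(0), numeric(0)))
  idx <- pmin(pmax(round(t * fs) + 1, 1), length(phase))
  spike_train(t, phase[idx])
}
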