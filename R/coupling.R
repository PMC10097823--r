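# Pairwise and triple-wise theta-coupling statistics: power correlations
# over time, Dice overlap with surrogate calibration, cross-correlogram
# lags, co-theta frequency/phase relations, cell-count and
# frequency-similarity analyses, and firing-rate relations.

# Ordinary regression summary used throughout: slope/intercept by OLS,
# Pearson r, t = r * sqrt((n-2) / (1-r^2)), two-sided p.
reg_result <- function(x, y, method = "regression") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop(method, ": need at least 3 finite observations")
  if (stats::sd(x) == 0) stop(method, ": predictor has zero variance")
  if (stats::sd(y) == 0) {
    return(structure(list(slope = 0, intercept = mean(y), r = 0,
                          t_stat = 0, p = 1, n = n, method = method),
                     class = "theta_regression"))
  }
  r <- stats::cor(x, y)
  slope <- r * stats::sd(y) / stats::sd(x)
  intercept <- mean(y) - slope * mean(x)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  structure(list(slope = slope, intercept = intercept, r = r,
                 t_stat = tt, p = clamp_p(p), n = n, method = method),
            class = "theta_regression")
}

#' @export
print.theta_regression <- function(x, ...) {
  cat(sprintf("%s: R = %.3g, slope = %.3g, t(%d) = %.3g, p = %.3g\n",
              x$method, x$r, x$slope, x$n - 2, x$t_stat, x$p))
  invisible(x)
}

#' Correlation between two binned power series
#'
#' Pearson correlation of per-bin theta powers with the t-test for
#' correlation coefficients (the segment-wise power-coupling statistic).
#'
#' @param a,b `power_series` objects (or numeric vectors) with identical
#'   binning and length.
#' @return `theta_regression` with `slope`, `intercept`, `r`, `t_stat`,
#'   `p`, `n`.
#' @export
power_correlation <- function(a, b) {
  va <- if (inherits(a, "power_series")) a$values else as.numeric(a)
  vb <- if (inherits(b, "power_series")) b$values else as.numeric(b)
  if (length(va) != length(vb))
    stop("power series must have equal length and binning")
  if (inherits(a, "power_series") && inherits(b, "power_series") &&
      !isTRUE(all.equal(a$bin_s, b$bin_s)))
    stop("power series must have equal binning")
  reg_result(va, vb, method = "power correlation")
}

#' Dice similarity coefficient of two interval sets
#'
#' `2 |A intersect B| / (|A| + |B|)` on interval measure (identical to the
#' 2-ms binarized count in the limit). Two empty sets give 0 by convention
#' (not 1), so silent channels never report perfect overlap.
#'
#' @param pa,pb interval sets: `intervals`/`theta_periods` data.frames with
#'   `start_s`, `end_s`.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(pa, pb) {
  la <- interval_measure(pa); lb <- interval_measure(pb)
  if (la + lb == 0) return(0)
  ai <- intervals(pa$start_s, pa$end_s)
  bi <- intervals(pb$start_s, pb$end_s)
  2 * interval_measure(interval_intersect(ai, bi)) / (la + lb)
}

#' Duration-preserving surrogate period sets
#'
#' Shuffles the timings of the individual periods without changing any
#' period's duration: each surrogate places the same multiset of durations
#' uniformly at random without overlap inside `[0, duration_s)` (durations
#' permuted, inter-period gaps drawn as scaled sorted uniforms, which
#' samples the uniform non-overlapping arrangement exactly).
#'
#' @param periods interval set to shuffle.
#' @param duration_s recording duration; total period length must be
#'   strictly less than it.
#' @param n number of surrogates (the calibration analyses use 10,000).
#' @param seed RNG seed.
#' @return list of `n` interval data.frames.
#' @export
surrogate_periods <- function(periods, duration_s, n = 10000, seed = 1) {
  d <- interval_lengths(periods)
  m <- length(d)
  free <- duration_s - sum(d)
  if (m == 0) stop("no periods to shuffle")
  if (free <= 0)
    stop("periods fill the whole recording; no placement freedom")
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    dp <- if (m > 1) sample(d) else d
    gaps <- diff(c(0, sort(stats::runif(m)), 1)) * free
    starts <- cumsum(gaps[seq_len(m)]) + cumsum(c(0, dp[-m]))
    intervals(starts, starts + dp)
  })
}

#' Expected surrogate Dice under independent random placement
#'
#' For two independently, uniformly placed interval sets the expected
#' intersection is the product of occupancies times the duration, giving
#' `E(Dice) ~ 2 oA oB T / (|A| + |B|)`.
#'
#' @param pa,pb interval sets.
#' @param duration_s recording duration.
#' @return expected Dice coefficient.
#' @export
expected_surrogate_dice <- function(pa, pb, duration_s) {
  la <- interval_measure(pa); lb <- interval_measure(pb)
  if (la + lb == 0) return(0)
  2 * (la / duration_s) * (lb / duration_s) * duration_s / (la + lb)
}

#' Scan detection thresholds against surrogate overlap
#'
#' For each candidate SD multiplier `k`, detects theta periods on every
#' channel, computes the pairwise Dice coefficients between simultaneous
#' channels, builds a surrogate Dice distribution by shuffling each
#' channel's periods, and compares original vs. surrogate distributions
#' with a two-sample KS test. The best threshold maximizes the KS D value
#' (the calibration that selects the 2-SD rule).
#'
#' @param specs list of >= 2 simultaneous `theta_spectrogram`s.
#' @param k_values candidate SD multipliers (default 1:4).
#' @param n_surr surrogates per channel pair (default 10,000).
#' @param seed RNG seed.
#' @param min_dur_s minimum period/gap duration passed to the detector.
#' @return list with `table` (data.frame `k`, `ks_d`, `p`, `valid`) and
#'   `best_k` (argmax D among valid thresholds).
#' @export
threshold_scan <- function(specs, k_values = 1:4, n_surr = 10000, seed = 1,
                           min_dur_s = 1) {
  if (length(specs) < 2) stop("need at least two simultaneous spectrograms")
  duration_s <- length(specs[[1]]$times_s) / specs[[1]]$fs
  rows <- lapply(k_values, function(k) {
    pers <- lapply(specs, detect_theta_periods, k_sd = k,
                   min_dur_s = min_dur_s)
    if (any(vapply(pers, nrow, integer(1)) == 0))
      return(data.frame(k = k, ks_d = NA_real_, p = NA_real_, valid = FALSE))
    pairs <- utils::combn(length(specs), 2)
    orig <- apply(pairs, 2, function(ij)
      dice_coefficient(pers[[ij[1]]], pers[[ij[2]]]))
    surr <- unlist(lapply(seq_len(ncol(pairs)), function(pi) {
      i <- pairs[1, pi]; j <- pairs[2, pi]
      sa <- surrogate_periods(pers[[i]], duration_s, n = n_surr,
                              seed = seed + 7919L * pi)
      sb <- surrogate_periods(pers[[j]], duration_s, n = n_surr,
                              seed = seed + 7919L * pi + 104729L)
      vapply(seq_len(n_surr), function(s)
        dice_coefficient(sa[[s]], sb[[s]]), numeric(1))
    }))
    kt <- ks_two_sample(orig, surr)
    data.frame(k = k, ks_d = kt$statistic, p = kt$p, valid = TRUE)
  })
  tab <- do.call(rbind, rows)
  best_k <- if (any(tab$valid)) tab$k[which.max(tab$ks_d)] else NA_real_
  list(table = tab, best_k = best_k)
}

#' Cross-correlogram lag between two filtered traces
#'
#' Normalized cross-correlation within `+/- max_lag_ms`; the reported lag
#' maximizes the correlation. Positive lag means the first argument leads.
#' To reproduce the mediolateral sign convention, pass the more-medial
#' channel first.
#'
#' @param a,b theta-band-filtered `theta_trace`s at equal rates.
#' @param max_lag_ms maximum lag searched (default 200).
#' @return list with `lag_ms`, `lags_ms`, `correlogram` (r at each lag).
#' @export
crosscorr_lag <- function(a, b, max_lag_ms = 200) {
  stopifnot(inherits(a, "theta_trace"), inherits(b, "theta_trace"),
            a$fs == b$fs)
  xa <- a$samples - mean(a$samples)
  xb <- b$samples - mean(b$samples)
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0)
    stop("constant input has no defined cross-correlation")
  max_lag <- as.integer(round(max_lag_ms * a$fs / 1000))
  n <- min(length(xa), length(xb))
  xa <- xa[seq_len(n)]; xb <- xb[seq_len(n)]
  cc <- stats::ccf(xb, xa, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)
  r <- as.numeric(cc$acf)       # r[k] ~ cor(b[t + k], a[t]); k>0: a leads
  lags <- as.numeric(cc$lag) / a$fs * 1000
  list(lag_ms = lags[which.max(r)], lags_ms = lags, correlogram = r)
}

#' Co-theta periods across channels
#'
#' Maximal intervals during which all required channels are simultaneously
#' in the theta state; intersections shorter than `min_dur_s` are dropped.
#' When spectrograms are supplied, each member's peak frequency and mean
#' theta power are recomputed on the intersection interval.
#'
#' @param periods_by_channel named list of `theta_periods` per channel.
#' @param required channel labels that must all be in theta (default: all).
#' @param specs optional named list of `theta_spectrogram`s for (a superset
#'   of) the required channels.
#' @param min_dur_s minimum co-period duration (default 1 s).
#' @param band theta band for the recomputed members (default `c(3, 10)`).
#' @return data.frame of class `co_theta_periods`: `start_s`, `end_s`, and
#'   per member `freq_<label>`, `pow_<label>` columns (NA without `specs`).
#' @export
co_theta_periods <- function(periods_by_channel,
                             required = names(periods_by_channel),
                             specs = NULL, min_dur_s = 1, band = c(3, 10)) {
  stopifnot(all(required %in% names(periods_by_channel)))
  cur <- NULL
  for (lb in required) {
    p <- periods_by_channel[[lb]]
    iv <- if (nrow(p)) intervals(p$start_s, p$end_s) else intervals()
    cur <- if (is.null(cur)) iv else interval_intersect(cur, iv)
    if (!nrow(cur)) break
  }
  if (is.null(cur)) cur <- intervals()
  keep <- interval_lengths(cur) >= min_dur_s - 1e-9
  cur <- cur[keep, , drop = FALSE]
  out <- data.frame(start_s = cur$start_s, end_s = cur$end_s)
  for (lb in required) {
    if (!is.null(specs) && lb %in% names(specs)) {
      sp <- specs[[lb]]
      fr <- numeric(nrow(out)); pw <- numeric(nrow(out))
      for (i in seq_len(nrow(out))) {
        iv <- out[i, ]
        fr[i] <- peak_frequency(sp, iv, band)
        pw[i] <- mean_band_power(sp, iv, band)
      }
      out[[paste0("freq_", lb)]] <- fr
      out[[paste0("pow_", lb)]] <- pw
    } else {
      out[[paste0("freq_", lb)]] <- rep(NA_real_, nrow(out))
      out[[paste0("pow_", lb)]] <- rep(NA_real_, nrow(out))
    }
  }
  attr(out, "members") <- required
  class(out) <- c("co_theta_periods", "data.frame")
  out
}

# Mean band power of a spectrogram over an interval.
mean_band_power <- function(spec, interval, band = c(3, 10)) {
  i0 <- floor(interval$start_s[1] * spec$fs) + 1
  i1 <- min(length(spec$times_s), ceiling(interval$end_s[1] * spec$fs))
  rows <- band_rows(spec, band)
  mean(spec$power[rows, i0:i1])
}

#' Frequency difference vs. geometric-mean power across co-theta periods
#'
#' Regresses `|f1 - f2|` on `sqrt(P1 * P2)` across co-theta periods (the
#' frequencies of two channels converge when both oscillate strongly).
#'
#' @param cps `co_theta_periods` with members `ch1`, `ch2` filled in.
#' @param ch1,ch2 member labels.
#' @return `theta_regression`.
#' @export
freq_difference_vs_power <- function(cps, ch1, ch2) {
  f1 <- cps[[paste0("freq_", ch1)]]; f2 <- cps[[paste0("freq_", ch2)]]
  p1 <- cps[[paste0("pow_", ch1)]];  p2 <- cps[[paste0("pow_", ch2)]]
  reg_result(sqrt(p1 * p2), abs(f1 - f2),
             method = "freq difference vs geometric-mean power")
}

#' Circular statistics of the theta phase difference across co-periods
#'
#' Restricts to co-theta periods in which the two channels oscillate at
#' similar frequencies (`|f1 - f2| < max_df_hz`), computes the circular
#' mean of the per-sample phase difference `phase_a - phase_b` within each
#' qualifying period, and summarizes the period-wise means with a Rayleigh
#' test.
#'
#' @param phase_a,phase_b per-sample phase series in degrees (from
#'   [instantaneous_phase()] of the theta-filtered traces).
#' @param fs sampling rate of the phase series.
#' @param cps `co_theta_periods` with member frequencies for `ch1`, `ch2`.
#' @param ch1,ch2 member labels ordering the difference (a minus b).
#' @param max_df_hz frequency-similarity gate (default 0.01 Hz).
#' @return list of class `circular_summary`: `mean_angle_deg`,
#'   `resultant_r`, `rayleigh_z`, `p`, `n`, `period_means_deg`; `n = 0`
#'   when no period qualifies.
#' @export
phase_difference_stats <- function(phase_a, phase_b, fs, cps, ch1, ch2,
                                   max_df_hz = 0.01) {
  df <- abs(cps[[paste0("freq_", ch1)]] - cps[[paste0("freq_", ch2)]])
  sel <- which(is.finite(df) & df < max_df_hz)
  if (!length(sel))
    return(structure(list(mean_angle_deg = NA_real_, resultant_r = NA_real_,
                          rayleigh_z = NA_real_, p = NA_real_, n = 0L,
                          period_means_deg = numeric(0)),
                     class = "circular_summary"))
  means <- vapply(sel, function(i) {
    i0 <- floor(cps$start_s[i] * fs) + 1
    i1 <- min(length(phase_a), ceiling(cps$end_s[i] * fs))
    circular_mean(wrap_deg(phase_a[i0:i1] - phase_b[i0:i1]))
  }, numeric(1))
  means <- means[is.finite(means)]
  n <- length(means)
  if (n >= 2) {
    rt <- rayleigh_test(means)
    out <- list(mean_angle_deg = rt$mean_deg, resultant_r = rt$r,
                rayleigh_z = rt$statistic, p = rt$p, n = n,
                period_means_deg = means)
  } else {
    out <- list(mean_angle_deg = if (n) means else NA_real_,
                resultant_r = if (n) 1 else NA_real_,
                rayleigh_z = NA_real_, p = NA_real_, n = n,
                period_means_deg = means)
  }
  structure(out, class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("circular summary: mean %.1f deg, R = %.3g, Rayleigh Z = %.3g, p = %.3g (n = %d periods)\n",
              x$mean_angle_deg, x$resultant_r, x$rayleigh_z, x$p, x$n))
  invisible(x)
}

#' LFP theta power as a function of the number of theta-emitting cells
#'
#' Bins the LFP theta power series, counts in each bin how many cells are
#' inside one of their theta periods, groups the LFP power by that count,
#' and tests the ordered trend with the Jonckheere-Terpstra statistic.
#'
#' @param lfp_power `power_series` of LFP theta power.
#' @param vm_periods named list (one entry per cell) of `theta_periods`.
#' @return list with `group_means` (named by cell count), `groups`, and
#'   `test` (`theta_test` from [jonckheere_trend()]).
#' @export
lfp_power_vs_cell_count <- function(lfp_power, vm_periods) {
  centers <- lfp_power$times_s + lfp_power$bin_s / 2
  counts <- rowSums(vapply(vm_periods, function(p) {
    if (!nrow(p)) return(rep(FALSE, length(centers)))
    vapply(centers, function(tc)
      any(tc >= p$start_s & tc < p$end_s), logical(1))
  }, logical(length(centers))))
  groups <- lapply(0:length(vm_periods), function(k)
    lfp_power$values[counts == k])
  names(groups) <- as.character(0:length(vm_periods))
  nonempty <- vapply(groups, length, integer(1)) > 0
  if (sum(nonempty) < 2)
    stop("need at least two non-empty cell-count groups")
  groups <- groups[nonempty]
  list(group_means = vapply(groups, mean, numeric(1)),
       groups = groups,
       test = jonckheere_trend(groups))
}

#' Similarity of three theta frequencies (1 / CV^2)
#'
#' `(mean / SD)^2` with the sample SD (n - 1). Identical frequencies give
#' `Inf`, a sentinel that downstream regressions exclude (and count).
#'
#' @param freqs three positive frequencies in Hz.
#' @return similarity score, possibly `Inf`.
#' @export
frequency_similarity <- function(freqs) {
  if (length(freqs) != 3 || any(!is.finite(freqs)) || any(freqs <= 0))
    stop("need three positive finite frequencies")
  s <- stats::sd(freqs)
  if (s == 0) return(Inf)
  (mean(freqs) / s)^2
}

#' Frequency-similarity analyses over LFP + three-cell co-theta periods
#'
#' (i) regresses LFP theta power on the 1/CV^2 similarity of the three
#' theta_Vm frequencies; (ii) regresses the absolute difference between
#' the LFP theta frequency and the geometric mean of the three theta_Vm
#' frequencies on the same similarity. Infinite similarities (identical
#' frequencies) are excluded and counted.
#'
#' @param cps `co_theta_periods` over the LFP and three cells, with member
#'   frequencies/powers filled in.
#' @param lfp_label label of the LFP member.
#' @param cell_labels labels of the three cell members.
#' @return list with `power_vs_similarity`, `freq_gap_vs_similarity`
#'   (both `theta_regression`) and `n_inf` (excluded sentinels).
#' @export
similarity_analyses <- function(cps, lfp_label = "LFP",
                                cell_labels = c("Vm1", "Vm2", "Vm3")) {
  stopifnot(length(cell_labels) == 3)
  fmat <- sapply(cell_labels, function(lb) cps[[paste0("freq_", lb)]])
  if (!is.matrix(fmat)) fmat <- matrix(fmat, ncol = 3)
  invcv <- apply(fmat, 1, frequency_similarity)
  lfp_pow <- cps[[paste0("pow_", lfp_label)]]
  lfp_freq <- cps[[paste0("freq_", lfp_label)]]
  gap <- abs(lfp_freq - apply(fmat, 1, function(f) exp(mean(log(f)))))
  fin <- is.finite(invcv)
  n_inf <- sum(!fin)
  if (sum(fin) < 3)
    stop("fewer than 3 co-theta periods with finite frequency similarity")
  list(power_vs_similarity =
         reg_result(invcv[fin], lfp_pow[fin],
                    method = "LFP theta power vs 1/CV^2"),
       freq_gap_vs_similarity =
         reg_result(invcv[fin], gap[fin],
                    method = "|f_LFP - geomean(f_Vm)| vs 1/CV^2"),
       n_inf = n_inf)
}

#' Firing rate vs. theta power and frequency across cells
#'
#' Within each cell, the per-period mean firing rate (log10(rate + 0.01),
#' then Z-standardized across the cell's theta periods) and the
#' Z-standardized theta power and frequency are computed; the standardized
#' values are pooled across cells and regressed (a standardize-then-pool
#' approximation of a mixed model with per-cell intercepts).
#'
#' @param cells list with one entry per cell: `list(periods =
#'   theta_periods, spikes = spike_train)`; only cells with at least one
#'   spike and two or more theta periods contribute.
#' @return list with `rate_vs_power` and `rate_vs_freq`
#'   (`theta_regression`s over the pooled standardized values).
#' @export
firing_rate_relations <- function(cells) {
  pooled <- list(rate = numeric(0), pow = numeric(0), frq = numeric(0))
  used <- 0L
  for (cl in cells) {
    p <- cl$periods
    if (is.null(p) || nrow(p) < 2) next
    if (is.null(cl$spikes) || !length(cl$spikes$times_s)) next
    rates <- vapply(seq_len(nrow(p)), function(i)
      sum(cl$spikes$times_s >= p$start_s[i] &
            cl$spikes$times_s < p$end_s[i]) / (p$end_s[i] - p$start_s[i]),
      numeric(1))
    lr <- log10(rates + 0.01)
    zs <- function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
    pooled$rate <- c(pooled$rate, zs(lr))
    pooled$pow <- c(pooled$pow, zs(p$mean_power))
    pooled$frq <- c(pooled$frq, zs(p$peak_freq_hz))
    used <- used + 1L
  }
  if (!used) stop("no cell with spikes and >= 2 theta periods")
  if (stats::sd(pooled$pow) == 0 || length(pooled$rate) < 3)
    stop("within-cell centering left no usable variance")
  list(rate_vs_power = reg_result(pooled$pow, pooled$rate,
                                  method = "firing rate vs theta power"),
       rate_vs_freq = reg_result(pooled$frq, pooled$rate,
                                 method = "firing rate vs theta frequency"))
}

#' Linear-sum control: segment-wise correlation of LFP with k-cell means
#'
#' For each 1-s segment, the Pearson correlation between the theta-filtered
#' LFP and the mean of every k-subset of theta-filtered Vm traces, for k =
#' 1..n cells. The per-k correlation distributions test whether averaging
#' more cells makes the mean trace more LFP-like (the linear-summation
#' hypothesis).
#'
#' @param lfp_theta theta-filtered LFP `theta_trace`.
#' @param vm_thetas list of theta-filtered Vm `theta_trace`s.
#' @param window_s segment length (default 1 s).
#' @return named list (`"1"`, `"2"`, ...) of correlation vectors pooled
#'   over segments and subsets.
#' @export
linear_sum_control <- function(lfp_theta, vm_thetas, window_s = 1) {
  fs <- lfp_theta$fs
  segs_l <- segment_series(lfp_theta$samples, fs, window_s)
  segs_v <- lapply(vm_thetas, function(tr)
    segment_series(tr$samples, fs, window_s)$segments)
  nseg <- length(segs_l$segments)
  ncell <- length(vm_thetas)
  out <- stats::setNames(vector("list", ncell), as.character(seq_len(ncell)))
  for (k in seq_len(ncell)) {
    subsets <- utils::combn(ncell, k)
    rs <- numeric(0)
    for (ci in seq_len(ncol(subsets))) {
      idx <- subsets[, ci]
      for (s in seq_len(nseg)) {
        m <- Reduce(`+`, lapply(idx, function(i) segs_v[[i]][[s]])) / k
        y <- segs_l$segments[[s]]
        if (stats::sd(m) > 0 && stats::sd(y) > 0)
          rs <- c(rs, stats::cor(y, m))
      }
    }
    out[[k]] <- rs
  }
  out
}
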