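# Self-contained statistical tests driving the headline analyses: Rayleigh
# (spike-phase locking), two-sample Kuiper (circular distribution
# comparison), Jonckheere-Terpstra (ordered trend across cell-count
# groups), two-sample Kolmogorov-Smirnov (real-vs-shuffled RMSE
# distributions), and circular descriptives. Implemented here rather than
# delegated because brute-force oracles for each are part of the package's
# validation surface.
#
# p-values are clamped to [1e-323, 1] so extreme underflow prints as the
# smallest representable magnitude rather than 0.

P_MIN <- 1e-323

clamp_p <- function(p) min(max(p, P_MIN), 1)

new_test_result <- function(statistic, p, n, method, ...) {
  structure(c(list(statistic = statistic, p = p, n = n, method = method),
              list(...)),
            class = "theta_test")
}

#' @export
print.theta_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g (n = %s)\n",
              x$method, x$statistic, x$p, paste(x$n, collapse = ", ")))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular mean of angles in degrees
#'
#' `atan2` of the mean sine and cosine, in \[-180, 180). When the mean
#' resultant length is (numerically) zero the mean direction is undefined
#' and `NA` is returned.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @return mean direction in degrees, or `NA_real_` if undefined.
#' @export
circular_mean <- function(angles_deg) {
  stopifnot(length(angles_deg) >= 1)
  a <- deg2rad(angles_deg)
  s <- mean(sin(a)); c <- mean(cos(a))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  wrap_deg(rad2deg(atan2(s, c)))
}

#' Mean resultant length of angles in degrees
#' @param angles_deg numeric vector of angles in degrees.
#' @return resultant length R in \[0, 1\].
#' @export
circular_r <- function(angles_deg) {
  a <- deg2rad(angles_deg)
  sqrt(mean(sin(a))^2 + mean(cos(a))^2)
}

#' Rayleigh test of circular uniformity
#'
#' Z = n R^2 with R the mean resultant length; p by the standard series
#' approximation (Zar). Also reports the circular mean direction.
#'
#' @param angles_deg angles in degrees, n >= 2.
#' @return `theta_test` with `statistic` (Z), `p`, `n`, `r`
#'   (resultant length), `mean_deg`.
#' @export
rayleigh_test <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 2) stop("Rayleigh test needs n >= 2")
  R <- circular_r(angles_deg)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  new_test_result(Z, clamp_p(p), n, "Rayleigh test",
                  r = R, mean_deg = circular_mean(angles_deg))
}

#' Two-sample Kuiper test for circular data
#'
#' Rotation-invariant analogue of the two-sample KS test: V = D+ + D- of
#' the circular ECDF difference. The asymptotic p-value uses the Kuiper
#' series with the Stephens small-sample modification of the argument.
#'
#' @param a_deg,b_deg angle samples in degrees, each n >= 5.
#' @return `theta_test` with `statistic` (V), `p`, `n = c(n1, n2)`.
#' @export
kuiper_two_sample <- function(a_deg, b_deg) {
  n1 <- length(a_deg); n2 <- length(b_deg)
  if (n1 < 5 || n2 < 5) stop("Kuiper test needs n >= 5 per sample")
  a <- sort(deg2rad(wrap_deg(a_deg))); b <- sort(deg2rad(wrap_deg(b_deg)))
  all_v <- sort(unique(c(a, b)))
  Fa <- vapply(all_v, function(v) mean(a <= v), numeric(1))
  Fb <- vapply(all_v, function(v) mean(b <= v), numeric(1))
  d <- Fa - Fb
  V <- max(d) - min(d)             # D+ + D-, invariant to rotation
  ne <- n1 * n2 / (n1 + n2)
  lam <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * V
  # the asymptotic series is valid for lam away from 0; below that the
  # survival probability is 1 to double precision
  p <- if (lam < 0.4) 1 else {
    j <- 1:100
    2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))
  }
  new_test_result(V, clamp_p(p), c(n1, n2), "two-sample Kuiper test")
}

#' Jonckheere-Terpstra trend test
#'
#' J is the sum over ordered group pairs (i < j) of Mann-Whitney counts
#' (ties count 1/2). Normal approximation with tie correction gives Z and a
#' one-sided p for an increasing trend.
#'
#' @param groups list of numeric vectors in hypothesized increasing order;
#'   at least two non-empty groups.
#' @return `theta_test` with `statistic` (Z), `p`, `n` (per-group sizes),
#'   `J`.
#' @export
jonckheere_trend <- function(groups) {
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  k <- length(groups)
  if (k < 2) stop("need at least two non-empty groups")
  J <- 0
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    gi <- groups[[i]]; gj <- groups[[j]]
    for (x in gi) J <- J + sum(gj > x) + 0.5 * sum(gj == x)
  }
  ni <- vapply(groups, length, integer(1))
  N <- sum(ni)
  EJ <- (N^2 - sum(ni^2)) / 4
  pooled <- unlist(groups)
  tie_tab <- table(pooled)
  t1 <- sum(tie_tab * (tie_tab - 1) * (2 * tie_tab + 5))
  u1 <- sum(ni * (ni - 1) * (2 * ni + 5))
  t2 <- sum(tie_tab * (tie_tab - 1) * (tie_tab - 2))
  u2 <- sum(ni * (ni - 1) * (ni - 2))
  t3 <- sum(tie_tab * (tie_tab - 1))
  u3 <- sum(ni * (ni - 1))
  varJ <- (N * (N - 1) * (2 * N + 5) - u1 - t1) / 72 +
    u2 * t2 / (36 * N * (N - 1) * (N - 2)) +
    u3 * t3 / (8 * N * (N - 1))
  if (varJ <= 0) {  # all observations tied
    return(new_test_result(0, 0.5, ni, "Jonckheere trend test", J = J))
  }
  Z <- (J - EJ) / sqrt(varJ)
  p <- stats::pnorm(Z, lower.tail = FALSE)
  new_test_result(Z, clamp_p(p), ni, "Jonckheere trend test", J = J)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the absolute ECDF difference; the p-value uses the
#' asymptotic Kolmogorov distribution with the Stephens effective-n
#' modification.
#'
#' @param a,b numeric samples, both non-empty.
#' @return `theta_test` with `statistic` (D), `p`, `n = c(n1, n2)`.
#' @export
ks_two_sample <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (!n1 || !n2) stop("both samples must be non-empty")
  all_v <- sort(unique(c(a, b)))
  Fa <- vapply(all_v, function(v) mean(a <= v), numeric(1))
  Fb <- vapply(all_v, function(v) mean(b <= v), numeric(1))
  D <- max(abs(Fa - Fb))
  ne <- n1 * n2 / (n1 + n2)
  lam <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  p <- if (lam < 0.3) 1 else {
    j <- 1:100
    2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lam^2))
  }
  new_test_result(D, clamp_p(p), c(n1, n2),
                  "two-sample Kolmogorov-Smirnov test")
}
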