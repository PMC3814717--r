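# Comparison metrics: shifted correlation coefficient, Welch power spectra
# and cross-correlograms.

#' Shifted correlation coefficient between two rate trajectories
#'
#' Pearson correlation between two equally sampled series, maximized over
#' integer-bin shifts within `±max_shift_ms`. Series are mean-subtracted on
#' the overlapping support. A small shift allowance makes the score
#' insensitive to inconsequential timing offsets between a spiking
#' population and a rate model.
#'
#' @param a,b numeric series on a common grid.
#' @param dt_ms sample step (ms).
#' @param max_shift_ms shift window (ms); default 5.
#' @returns tibble with `coefficient`, `shift_ms` (positive shift: `b`
#'   delayed relative to `a`), `n_overlap`.
#' @export
shifted_correlation <- function(a, b, dt_ms = 1, max_shift_ms = 5) {
  n <- length(a)
  if (length(b) != n) abort("series must share one sampling grid")
  if (sd(a) == 0 || sd(b) == 0)
    abort("undefined correlation: an input series has zero variance")
  smax <- round(max_shift_ms / dt_ms)
  if (n - smax < 0.9 * n)
    warn("shift window exceeds 10% of the series; overlap below 90%")
  best <- c(cor = -Inf, shift = 0L, n = 0L)
  for (s in -smax:smax) {
    if (s >= 0) { ai <- seq_len(n - s); bi <- ai + s }
    else { bi <- seq_len(n + s); ai <- bi - s }
    r <- suppressWarnings(cor(a[ai], b[bi]))
    if (is.finite(r) && r > best["cor"])
      best <- c(cor = r, shift = s, n = length(ai))
  }
  tibble(coefficient = unname(best["cor"]),
         shift_ms = unname(best["shift"]) * dt_ms,
         n_overlap = as.integer(best["n"]))
}

#' Welch power spectrum
#'
#' Welch-averaged periodogram of a uniformly sampled series: the series is
#' split into overlapping segments, each mean-subtracted and windowed, and
#' the one-sided periodograms are averaged. Normalization is such that the
#' integral of the power density over frequency equals the series variance
#' (Parseval; exact for a rectangular window and a single segment).
#'
#' @param x numeric series.
#' @param dt_ms sample step (ms).
#' @param segment segment length in samples; default: the largest power of
#'   two not exceeding half the series (at least 64).
#' @param overlap fractional segment overlap.
#' @param window `"hann"` or `"rect"`.
#' @returns tibble with `freq_hz` (excluding DC) and `power`
#'   (variance per Hz).
#' @export
power_spectrum <- function(x, dt_ms, segment = NULL, overlap = 0.5,
                           window = c("hann", "rect")) {
  window <- match.arg(window)
  n <- length(x)
  if (!is.null(segment) && segment > n)
    abort("series too short for the requested segment length")
  segment <- segment %||% max(64L, 2^floor(log2(max(n / 2, 64))))
  segment <- min(segment, n)
  step <- max(1L, floor(segment * (1 - overlap)))
  starts <- seq(1L, n - segment + 1L, by = step)
  if (length(starts) < 1) abort("series too short for the requested segmenting")
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(segment) / (segment + 1))
  } else rep(1, segment)
  fs_hz <- 1000 / dt_ms
  u <- sum(w^2) # window power normalization
  acc <- 0
  for (s0 in starts) {
    seg <- x[s0:(s0 + segment - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / (u * fs_hz)
    acc <- acc + p
  }
  p <- acc / length(starts)
  half <- floor(segment / 2)
  freq <- (seq_len(half)) * fs_hz / segment
  pw <- 2 * p[2:(half + 1)]
  if (segment %% 2 == 0) pw[half] <- pw[half] / 2 # Nyquist not doubled
  tibble(freq_hz = freq, power = pw)
}

#' Dominant frequency of a series
#'
#' Argmax of the Welch spectrum over positive frequencies (DC excluded),
#' refined by quadratic interpolation of log-power around the peak.
#'
#' @inheritParams power_spectrum
#' @returns the dominant frequency (Hz).
#' @export
dominant_frequency <- function(x, dt_ms, segment = NULL, overlap = 0.5) {
  ps <- power_spectrum(x, dt_ms, segment, overlap)
  k <- which.max(ps$power)
  if (k > 1 && k < nrow(ps)) {
    lp <- log(ps$power[(k - 1):(k + 1)] + .Machine$double.xmin)
    denom <- lp[1] - 2 * lp[2] + lp[3]
    delta <- if (abs(denom) > 0) 0.5 * (lp[1] - lp[3]) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    df <- ps$freq_hz[2] - ps$freq_hz[1]
    ps$freq_hz[k] + delta * df
  } else {
    ps$freq_hz[k]
  }
}

#' Normalized cross-correlogram of two series
#'
#' Cross-correlation (Pearson-normalized, mean-subtracted) over lags within
#' `±max_lag_ms`. Positive lags mean that features of `b` follow features
#' of `a`.
#'
#' @inheritParams shifted_correlation
#' @param max_lag_ms lag window (ms).
#' @returns tibble with `lag_ms`, `correlation`; attribute `peak_lag_ms`.
#' @export
cross_correlogram <- function(a, b, dt_ms = 1, max_lag_ms = 25) {
  n <- length(a)
  if (length(b) != n) abort("series must share one sampling grid")
  if (sd(a) == 0 || sd(b) == 0)
    abort("undefined correlation: an input series has zero variance")
  lmax <- round(max_lag_ms / dt_ms)
  cc <- stats::ccf(a, b, lag.max = lmax, plot = FALSE, demean = TRUE)
  # ccf(a, b) at positive lag correlates a_{t+k} with b_t, i.e. b leads;
  # flip so positive lag means b follows a
  lag_ms <- -as.numeric(cc$lag) * dt_ms
  ord <- order(lag_ms)
  out <- tibble(lag_ms = lag_ms[ord], correlation = as.numeric(cc$acf)[ord])
  # rescale from ccf's n-normalization to Pearson at lag 0
  scl <- cor(a, b) / out$correlation[out$lag_ms == 0]
  if (is.finite(scl)) out$correlation <- out$correlation * scl
  attr(out, "peak_lag_ms") <- out$lag_ms[which.max(out$correlation)]
  out
}
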