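#' The five canonical EEG frequency bands
#'
#' @return A tibble with columns `band`, `low`, `high` (Hz): delta 0.5-3,
#'   theta 4-7, alpha 8-13, beta 13-30, gamma 31-50.
#' @export
#' @examples
#' band_defaults()
band_defaults <- function() {
  tibble(band = c("delta", "theta", "alpha", "beta", "gamma"),
         low = c(0.5, 4, 8, 13, 31),
         high = c(3, 7, 13, 30, 50))
}

resolve_band <- function(band) {
  if (is.character(band)) {
    bk <- band_defaults()
    i <- match(tolower(band), bk$band)
    if (is.na(i)) abort(sprintf("Unknown band `%s`; expected one of %s.",
                                band, paste(bk$band, collapse = ", ")))
    return(c(low = bk$low[i], high = bk$high[i]))
  }
  if (is.numeric(band) && length(band) == 2 && band[1] > 0 && band[2] > band[1]) {
    return(c(low = band[1], high = band[2]))
  }
  abort("`band` must be a band name or c(low, high) in Hz.")
}

# Chebyshev type-I bandpass design in zero-pole-gain form, returned as
# second-order sections. Transfer-function polynomials of order 2n are
# numerically unusable at EEG band edges (delta at 1 kHz needs poles at
# radius ~0.999), so the design stays in root form throughout: analog
# lowpass prototype (closed-form poles), lowpass-to-bandpass transform,
# bilinear transform with edge prewarping, conjugate-pair grouping.
cheby1_sos <- function(order, ripple_db, low, high, fs) {
  n <- as.integer(order)
  if (low <= 0 || high <= low) abort("Band edges must satisfy 0 < low < high.")
  if (high >= fs / 2) abort(sprintf("Band high edge %.3g Hz is at or above Nyquist (%.3g Hz).",
                                    high, fs / 2))
  eps <- sqrt(10^(ripple_db / 10) - 1)
  mu <- asinh(1 / eps) / n
  k <- seq_len(n)
  theta <- pi * (2 * k - 1) / (2 * n)
  p_lp <- complex(real = -sinh(mu) * sin(theta), imaginary = cosh(mu) * cos(theta))
  k_lp <- Re(prod(-p_lp))
  if (n %% 2 == 0) k_lp <- k_lp / sqrt(1 + eps^2)

  # prewarped analog band edges
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1

  # lowpass -> bandpass doubles the order: each prototype pole splits
  p_s <- p_lp * bw / 2
  rt <- sqrt(p_s^2 - w0^2)
  p_bp <- c(p_s + rt, p_s - rt)
  k_bp <- k_lp * bw^n

  # bilinear transform; n zeros at z = 1 (from s = 0), n at z = -1
  fs2 <- 2 * fs
  p_z <- (fs2 + p_bp) / (fs2 - p_bp)
  k_z <- k_bp * Re(fs2^n / prod(fs2 - p_bp))

  # group poles into conjugate pairs (upper half-plane sorted by modulus)
  up <- p_z[Im(p_z) >= 0]
  up <- up[order(Mod(up))]
  n_sec <- length(up)
  g <- abs(k_z)^(1 / n_sec)
  sos <- matrix(0, n_sec, 6)
  for (i in seq_len(n_sec)) {
    p <- up[i]
    # numerator (z - 1)(z + 1) = z^2 - 1 per section
    b <- g * c(1, 0, -1)
    if (i == 1 && k_z < 0) b <- -b
    sos[i, ] <- c(b, 1, -2 * Re(p), Mod(p)^2)
  }
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

# Complex frequency response of an SOS cascade at frequencies f (Hz).
sos_response <- function(sos, f, fs) {
  z1 <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos))) {
    h <- h * (sos[i, 1] + sos[i, 2] * z1 + sos[i, 3] * z1^2) /
      (sos[i, 4] + sos[i, 5] * z1 + sos[i, 6] * z1^2)
  }
  h
}

# Analytic magnitude of the designed Chebyshev-I bandpass at f (Hz): the
# lowpass prototype magnitude 1/sqrt(1 + eps^2 Tn(W)^2) evaluated at the
# prewarped bandpass frequency mapping W = (w^2 - w0^2) / (w bw). By
# construction of the bilinear transform this equals the digital response.
cheby1_analytic_gain <- function(f, low, high, fs, order = 10, ripple_db = 0.5) {
  eps <- sqrt(10^(ripple_db / 10) - 1)
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  w <- 2 * fs * tan(pi * f / fs)
  W <- (w^2 - w0^2) / (w * bw)
  Tn <- ifelse(abs(W) <= 1, cos(order * acos(pmax(-1, pmin(1, W)))),
               cosh(order * acosh(pmax(1, abs(W)))))
  1 / sqrt(1 + eps^2 * Tn^2)
}

# Single-series zero-phase SOS filtering: odd-reflection padding, forward
# pass through the cascade, time reversal, second pass, reversal.
sosfiltfilt_vec <- function(sos, x, padlen) {
  n <- length(x)
  padlen <- min(n - 1L, padlen)
  xp <- c(2 * x[1] - x[(padlen + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - padlen)])
  run <- function(v) {
    for (i in seq_len(nrow(sos))) {
      v <- stats::filter(v, filter = -sos[i, 5:6], method = "recursive",
                         init = c(0, 0))
      v <- sos[i, 1] * v + sos[i, 2] * c(0, v[-length(v)]) +
        sos[i, 3] * c(0, 0, v[-((length(v) - 1):length(v))])
    }
    v
  }
  y <- rev(run(rev(run(xp))))
  as.numeric(y[(padlen + 1L):(padlen + n)])
}

#' Zero-phase Chebyshev type-I bandpass filter
#'
#' Applies an order-10 Chebyshev type-I bandpass (0.5 dB passband ripple by
#' default) forward and backward (zero phase). The filter is designed and
#' applied in second-order sections.
#'
#' @param x Numeric vector, or samples x channels matrix/data frame.
#' @param band Band name (`"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"gamma"`) or `c(low, high)` in Hz.
#' @param fs Sampling rate in Hz; must exceed twice the band's high edge.
#' @param order Prototype filter order (default 10; the bandpass has twice
#'   as many poles).
#' @param ripple_db Passband ripple in dB (default 0.5).
#' @return Filtered data with the shape of the input.
#' @export
#' @examples
#' fs <- 128
#' t <- (0:511) / fs
#' x <- sin(2 * pi * 10 * t) + sin(2 * pi * 45 * t)
#' y <- chebyshev_bandpass(x, "alpha", fs)
chebyshev_bandpass <- function(x, band, fs, order = 10, ripple_db = 0.5) {
  edges <- resolve_band(band)
  sos <- cheby1_sos(order, ripple_db, edges["low"], edges["high"], fs)
  padlen <- ceiling(3 * fs / edges["low"])
  if (is.matrix(x) || is.data.frame(x)) {
    m <- as_series_matrix(x, "x")
    out <- apply(m, 2, function(col) sosfiltfilt_vec(sos, col, padlen))
    colnames(out) <- colnames(m)
    return(out)
  }
  sosfiltfilt_vec(sos, as.numeric(x), padlen)
}

# The SOS design for a named band; exported for response checks.
#' Second-order-section coefficients of a band filter
#'
#' @inheritParams chebyshev_bandpass
#' @return A matrix with columns `b0 b1 b2 a0 a1 a2`, one row per biquad.
#' @export
band_filter_sos <- function(band, fs, order = 10, ripple_db = 0.5) {
  edges <- resolve_band(band)
  cheby1_sos(order, ripple_db, edges["low"], edges["high"], fs)
}

#' Magnitude response of a band filter in dB
#'
#' @inheritParams chebyshev_bandpass
#' @param f Frequencies (Hz) at which to evaluate the single-pass response.
#' @export
band_filter_gain_db <- function(f, band, fs, order = 10, ripple_db = 0.5) {
  sos <- band_filter_sos(band, fs, order, ripple_db)
  20 * log10(Mod(sos_response(sos, f, fs)))
}
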