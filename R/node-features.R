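#' Frequency band scheme
#'
#' Named, non-overlapping, ascending frequency bands used for node features.
#' The defaults — Delta 2-4, Theta 4-8, Alpha 8-15, Beta 15-30, Low Gamma
#' 30-40 Hz — combine physiological convention with the slightly widened
#' alpha band used for this decoding task.
#'
#' @param bands Named list of `c(low, high)` Hz pairs.
#' @return A `band_scheme` object (the validated list).
#' @export
band_scheme <- function(bands = list(delta = c(2, 4), theta = c(4, 8),
                                     alpha = c(8, 15), beta = c(15, 30),
                                     low_gamma = c(30, 40))) {
  if (is.null(names(bands)) || any(names(bands) == ""))
    stop("all bands must be named")
  edges <- vapply(bands, function(b) {
    if (length(b) != 2L || !is.numeric(b) || b[1L] >= b[2L])
      stop("each band must be a numeric c(low, high) pair with low < high")
    b
  }, numeric(2))
  lows <- edges[1L, ]
  highs <- edges[2L, ]
  if (any(diff(lows) <= 0) || any(lows[-1L] < highs[-length(bands)]))
    stop("bands must be ascending and non-overlapping")
  structure(bands, class = "band_scheme")
}

# cache DPSS tapers per (N, NW, K); the tapers come from the eigenvectors of
# the symmetric tridiagonal Slepian matrix
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, as the top eigenvectors of the symmetric tridiagonal matrix
#' whose diagonal is `((n - 1 - 2 t) / 2)^2 cos(2 pi W)` and off-diagonal
#' `t (n - t) / 2` (W = nw / n). Tapers are normalized to unit energy and
#' sign-fixed so each has a nonnegative mean (or nonnegative first
#' derivative-like moment for the odd tapers).
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 2).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return An n-by-k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 2, k = 2 * nw - 1) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (k >= n) stop("need k < n tapers")
  w <- nw / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- t[-1L] * (n - t[-1L]) / 2
  mat <- matrix(0, n, n)
  mat[cbind(1:n, 1:n)] <- diag_main
  mat[cbind(1:(n - 1), 2:n)] <- diag_off
  mat[cbind(2:n, 1:(n - 1))] <- diag_off
  eig <- eigen(mat, symmetric = TRUE)
  tapers <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tapers[, j] <- tapers[, j] / sqrt(sum(tapers[, j]^2))
    s <- sum(tapers[, j])
    if (abs(s) < 1e-10) s <- sum(tapers[, j] * t)  # odd tapers have zero mean
    if (s < 0) tapers[, j] <- -tapers[, j]
  }
  .dpss_cache[[key]] <- tapers
  tapers
}

#' Multitaper power spectral density of one channel segment
#'
#' Averages direct spectral estimates over orthogonal DPSS tapers (default
#' NW = 2, 3 tapers), trading frequency resolution for variance reduction.
#' At the package's 0.5 s / 500 Hz segments the half-bandwidth is
#' NW / T = 4 Hz, which is coarse for the delta band — a known resolution
#' limit of short segments.
#'
#' @param channel_segment Numeric vector, at least 64 samples.
#' @param rate Sampling rate in Hz.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers.
#' @return A list with `frequencies` (Hz, 0 to Nyquist) and `psd`
#'   (one-sided, units^2/Hz, same length).
#' @export
multitaper_psd <- function(channel_segment, rate, nw = 2, k = 2 * nw - 1) {
  x <- as.numeric(channel_segment)
  n <- length(x)
  if (n < 64L) stop("segment too short for a PSD estimate (need >= 64 samples)")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be a positive sampling rate in Hz")
  tapers <- dpss_tapers(n, nw, k)
  nfreq <- n %/% 2L + 1L
  psd <- numeric(nfreq)
  for (j in seq_len(k)) {
    spec <- abs(stats::fft(x * tapers[, j]))^2 / rate
    psd <- psd + spec[seq_len(nfreq)]
  }
  psd <- psd / k
  # one-sided: double everything except DC and (for even n) Nyquist
  inner <- 2:(nfreq - 1L)
  psd[inner] <- 2 * psd[inner]
  if (n %% 2L == 1L) psd[nfreq] <- 2 * psd[nfreq]
  list(frequencies = (seq_len(nfreq) - 1L) * rate / n, psd = psd)
}

# rectangle-rule integral of psd over [low, high) on its frequency grid
band_integral <- function(frequencies, psd, low, high) {
  df <- frequencies[2L] - frequencies[1L]
  sel <- frequencies >= low & frequencies < high
  sum(psd[sel]) * df
}

#' Band-power fractions of a PSD
#'
#' For each band of `scheme`, the fraction of total power it holds:
#' `integral of psd over the band / integral over total_band`. Bands are
#' half-open `[low, high)` intervals on the PSD's frequency grid so shared
#' edges are never counted twice. The total power (denominator integral) is
#' returned alongside the fractions.
#'
#' @param frequencies,psd A PSD as returned by [multitaper_psd()].
#' @param scheme A [band_scheme()].
#' @param total_band `c(low, high)` Hz defining "total power" — typically
#'   the modality's filter band (2-40 Hz EEG, 2-100 Hz EMG).
#' @return A list with `fractions` (named numeric, one per band, each in
#'   [0, 1]) and `total_power`.
#' @export
band_fractions <- function(frequencies, psd, scheme = band_scheme(),
                           total_band = c(2, 40)) {
  if (any(psd < 0)) stop("psd must be nonnegative")
  total <- band_integral(frequencies, psd, total_band[1L], total_band[2L])
  if (total <= 0)
    stop("degenerate channel: zero total power in the total band")
  fractions <- vapply(scheme, function(b)
    band_integral(frequencies, psd, b[1L], b[2L]) / total, numeric(1))
  list(fractions = fractions, total_power = total)
}

#' Node feature vector of one channel segment
#'
#' Assembles the length-7 node feature used by the channel graphs: the five
#' band-power fractions, the total power, and the electrode index as a raw
#' location code, in that fixed order.
#'
#' @param channel_segment Numeric vector of samples.
#' @param electrode_index Integer in 0..39 (0-31 EEG in montage order, 32-39
#'   EMG in FDS, FCU, FCR, ECU, ECRL, BBS, TBL, LD order).
#' @param rate Sampling rate in Hz.
#' @param scheme A [band_scheme()].
#' @param total_band `c(low, high)` Hz for the total-power denominator.
#' @return Named numeric vector of length 7:
#'   `(delta, theta, alpha, beta, low_gamma, total_power, electrode)`.
#' @export
node_feature <- function(channel_segment, electrode_index, rate,
                         scheme = band_scheme(), total_band = c(2, 40)) {
  if (length(electrode_index) != 1L || is.na(electrode_index) ||
      electrode_index < 0 || electrode_index > 39)
    stop("electrode_index must be a single integer in 0..39")
  est <- multitaper_psd(channel_segment, rate)
  bf <- band_fractions(est$frequencies, est$psd, scheme, total_band)
  out <- c(bf$fractions, total_power = bf$total_power,
           electrode = as.numeric(electrode_index))
  names(out) <- c(names(scheme), "total_power", "electrode")
  out
}
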