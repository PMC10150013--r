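#' Ordinal-pattern configuration
#'
#' Settings for Bandt-Pompe symbolization of a time series: the embedding
#' dimension `n` (sub-vector length) and the time lag `tau` between the
#' samples of one embedding vector. A series of length `N` yields
#' `N - (n - 1) * tau` ordinal patterns, which must be at least 2 for a
#' nondegenerate pattern distribution.
#'
#' @param n Embedding dimension, integer >= 2. Default 5, the setting used
#'   for channel connectivity throughout the package.
#' @param tau Time lag, integer >= 1. Default 1.
#' @param degenerate One of `"error"` (default) or `"zero"`: what [spmi()]
#'   does when the joint permutation entropy is 0 (both series effectively
#'   monotone), where the SPMI ratio is undefined. `"zero"` maps such pairs
#'   to SPMI 0 for pipeline robustness.
#' @return An object of class `ordinal_config`.
#' @export
#' @examples
#' cfg <- ordinal_config(n = 3, tau = 1)
#' ordinal_patterns(c(1, 3, 2, 5, 4), cfg)
ordinal_config <- function(n = 5L, tau = 1L, degenerate = c("error", "zero")) {
  n <- as.integer(n)
  tau <- as.integer(tau)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("embedding dimension `n` must be a single integer >= 2")
  if (length(tau) != 1L || is.na(tau) || tau < 1L)
    stop("time lag `tau` must be a single integer >= 1")
  structure(
    list(n = n, tau = tau, degenerate = match.arg(degenerate)),
    class = "ordinal_config"
  )
}

# number of ordinal patterns a series of length len yields under cfg
n_patterns <- function(len, cfg) len - (cfg$n - 1L) * cfg$tau

check_series <- function(series, cfg) {
  if (!is.numeric(series)) stop("series must be numeric")
  if (anyNA(series) || any(!is.finite(series))) stop("series contains non-finite values")
  m <- n_patterns(length(series), cfg)
  if (m < 1L)
    stop(sprintf("series too short: length %d yields %d ordinal patterns (need >= 1 for patterns, >= 2 for entropy)",
                 length(series), m))
  m
}

#' Ordinal patterns of a time series
#'
#' Symbolizes a series into the sequence of ordinal patterns of its delay
#' embedding vectors: the i-th vector is
#' `(x[i], x[i + tau], ..., x[i + (n-1) tau])` and its pattern is the rank
#' ordering of those values. Ties are broken by order of occurrence (the
#' earlier sample gets the lower rank), the standard ordinal-pattern
#' convention. Each pattern is encoded as an integer in `0 .. n! - 1` via the
#' Lehmer code of the rank permutation, so equal integers mean equal
#' patterns.
#'
#' @param series Numeric vector, length at least `(n - 1) * tau + 1`.
#' @param cfg An [ordinal_config()].
#' @return Integer vector of `length(series) - (n - 1) * tau` pattern codes
#'   in `0 .. n! - 1`.
#' @export
ordinal_patterns <- function(series, cfg = ordinal_config()) {
  check_series(series, cfg)
  ordinal_codes(series, cfg$n, cfg$tau)
}

# Vectorized Lehmer-code symbolization. Ranks use the ties.method = "first"
# convention; the Lehmer digit of position j is the number of later positions
# with a strictly smaller rank, giving a dense code in 0 .. n!-1.
ordinal_codes <- function(series, n, tau) {
  m <- length(series) - (n - 1L) * tau
  emb <- matrix(0, nrow = m, ncol = n)
  for (j in seq_len(n)) emb[, j] <- series[seq_len(m) + (j - 1L) * tau]
  rk <- matrix(1L, nrow = m, ncol = n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (k == j) next
      if (k < j) rk[, j] <- rk[, j] + (emb[, k] <= emb[, j])
      else       rk[, j] <- rk[, j] + (emb[, k] <  emb[, j])
    }
  }
  code <- integer(m)
  if (n > 1L) {
    fact <- cumprod(c(1, seq_len(n - 1L)))  # 0!, 1!, ..., (n-1)!
    for (j in seq_len(n - 1L)) {
      lehmer <- integer(m)
      for (k in (j + 1L):n) lehmer <- lehmer + (rk[, k] < rk[, j])
      code <- code + lehmer * fact[n - j + 1L] / 1L
    }
  }
  as.integer(code)
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0L]
  p <- p / sum(p)
  -sum(p * log(p))
}

# entropy of an integer code vector, counting by sorting (codes may be sparse
# in a huge range, e.g. joint codes over n!^2 cells)
entropy_of_codes <- function(codes) {
  s <- sort.int(codes, method = "radix")
  m <- length(s)
  ends <- c(which(s[-1L] != s[-m]), m)
  entropy_from_counts(diff(c(0L, ends)))
}

#' Permutation entropy
#'
#' Shannon entropy (natural log) of the empirical distribution of ordinal
#' patterns of a series. Bounded by `log(n!)`; 0 for a strictly monotone
#' series (a single pattern).
#'
#' @inheritParams ordinal_patterns
#' @return Nonnegative scalar, in nats.
#' @export
permutation_entropy <- function(series, cfg = ordinal_config()) {
  m <- check_series(series, cfg)
  if (m < 2L)
    stop("series too short for an entropy estimate: need >= 2 ordinal patterns")
  entropy_of_codes(ordinal_codes(series, cfg$n, cfg$tau))
}

#' Joint permutation entropy of two series
#'
#' Entropy of the joint distribution of simultaneous ordinal patterns: the
#' pattern pair at index i couples x's and y's patterns at the same i.
#' Satisfies `max(PE_x, PE_y) <= PE_xy <= PE_x + PE_y`.
#'
#' @param x,y Numeric vectors of equal length.
#' @inheritParams ordinal_patterns
#' @return Nonnegative scalar, in nats.
#' @export
joint_permutation_entropy <- function(x, y, cfg = ordinal_config()) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  m <- check_series(x, cfg)
  check_series(y, cfg)
  if (m < 2L)
    stop("series too short for an entropy estimate: need >= 2 ordinal patterns")
  cx <- ordinal_codes(x, cfg$n, cfg$tau)
  cy <- ordinal_codes(y, cfg$n, cfg$tau)
  nf <- factorial(cfg$n)
  entropy_of_codes(cx * nf + cy)
}

#' Standardized permutation mutual information (SPMI)
#'
#' Normalized mutual information between the ordinal-pattern distributions of
#' two series: `(PE_x + PE_y - PE_xy) / PE_xy`. Symmetric, in `[0, 1]` for
#' nondegenerate signals (1 when the patterns of one series determine the
#' other's, 0 when the joint distribution factorizes), and invariant to the
#' logarithm base since the ratio cancels it.
#'
#' When both series are effectively monotone the joint entropy is 0 and the
#' ratio is undefined; `cfg$degenerate` selects between raising an error
#' (default) and returning 0.
#'
#' @inheritParams joint_permutation_entropy
#' @return Scalar in `[0, 1]`.
#' @export
spmi <- function(x, y, cfg = ordinal_config()) {
  pe_x <- permutation_entropy(x, cfg)
  pe_y <- permutation_entropy(y, cfg)
  pe_xy <- joint_permutation_entropy(x, y, cfg)
  spmi_from_entropies(pe_x, pe_y, pe_xy, cfg$degenerate)
}

spmi_from_entropies <- function(pe_x, pe_y, pe_xy, degenerate = "error") {
  if (pe_xy <= 0) {
    if (degenerate == "zero") return(0)
    stop("degenerate signal pair: joint permutation entropy is 0, SPMI undefined ",
         "(set degenerate = \"zero\" in ordinal_config to map this to 0)")
  }
  (pe_x + pe_y - pe_xy) / pe_xy
}

#' SPMI connectivity matrix of a multichannel segment
#'
#' Computes SPMI for every unordered channel pair of a segment and returns
#' the symmetric connectivity matrix with unit diagonal. All pairs — within
#' EEG, within EMG, and across the two modalities (where SPMI reads as a
#' corticomuscular coupling measure) — are treated identically.
#'
#' @param segment A numeric channels-by-samples matrix, or a
#'   `segment_window` (its `data` matrix is used).
#' @param cfg An [ordinal_config()].
#' @param channel_names Optional character vector of row names; defaults to
#'   the matrix's rownames or `ch1..chN`.
#' @return A `connectivity_matrix`: the N-by-N `values` matrix (dimnames =
#'   channel names) with attribute `channel_names`.
#' @export
spmi_matrix <- function(segment, cfg = ordinal_config(), channel_names = NULL) {
  data <- if (inherits(segment, "segment_window")) segment$data else segment
  if (!is.matrix(data) || nrow(data) < 2L)
    stop("segment must be a channels-by-samples matrix with >= 2 channels")
  nch <- nrow(data)
  if (is.null(channel_names)) channel_names <- rownames(data)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  m <- check_series(data[1L, ], cfg)
  if (m < 2L) stop("segment too short for SPMI")

  nf <- factorial(cfg$n)
  codes <- matrix(0L, nrow = nch, ncol = m)
  pe <- numeric(nch)
  for (i in seq_len(nch)) {
    codes[i, ] <- ordinal_codes(data[i, ], cfg$n, cfg$tau)
    pe[i] <- entropy_of_codes(codes[i, ])
  }
  # joint entropy by direct tabulation over the n!^2 joint cells when that
  # table is small; otherwise by sorting the sparse joint codes
  nbins <- nf * nf
  joint_entropy <- if (nbins <= 2^20) {
    function(cj) entropy_from_counts(tabulate(cj + 1L, nbins))
  } else {
    entropy_of_codes
  }
  values <- diag(1, nch)
  for (i in seq_len(nch - 1L)) {
    ci <- codes[i, ] * nf
    for (j in (i + 1L):nch) {
      pe_xy <- joint_entropy(ci + codes[j, ])
      values[i, j] <- values[j, i] <-
        spmi_from_entropies(pe[i], pe[j], pe_xy, cfg$degenerate)
    }
  }
  dimnames(values) <- list(channel_names, channel_names)
  structure(values, channel_names = channel_names, class = c("connectivity_matrix", "matrix", "array"))
}

#' Threshold a connectivity matrix into an edge list
#'
#' Retains the `k = floor(q * P)` strongest of the `P = N (N - 1) / 2`
#' unordered channel pairs as undirected edges (no self-loops). With the
#' default `q = 0.25` and 40 channels this keeps 195 of 780 pairs. Ties in
#' SPMI value are broken lexicographically by (row, column) channel index so
#' the edge set is deterministic.
#'
#' @param matrix A square symmetric numeric matrix (e.g. from
#'   [spmi_matrix()]).
#' @param q Fraction of pairs to retain, in (0, 1].
#' @return A data frame with integer columns `src`, `dst` (1-based channel
#'   indices, `src < dst`) and numeric `weight`, ordered by decreasing
#'   weight.
#' @export
threshold_edges <- function(matrix, q = 0.25) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q > 1)
    stop("q must be a single value in (0, 1]")
  n <- nrow(matrix)
  if (is.null(n) || n != ncol(matrix)) stop("matrix must be square")
  idx <- which(upper.tri(matrix), arr.ind = TRUE)
  w <- matrix[idx]
  k <- floor(q * nrow(idx))
  if (k < 1L) stop("q too small: no edges retained")
  ord <- order(-w, idx[, 1L], idx[, 2L])
  keep <- ord[seq_len(k)]
  data.frame(src = as.integer(idx[keep, 1L]),
             dst = as.integer(idx[keep, 2L]),
             weight = w[keep])
}

#' Export a connectivity matrix or edge list as TSV
#'
#' @param x A `connectivity_matrix` or an edge-list data frame from
#'   [threshold_edges()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_connectivity_tsv <- function(x, path) {
  if (inherits(x, "connectivity_matrix")) {
    tab <- as.data.frame(unclass(x))
    utils::write.table(cbind(channel = attr(x, "channel_names"), tab), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
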