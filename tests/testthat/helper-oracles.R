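# Independent brute-force oracles and small fixture builders.

# Brute-force permutation entropy: materialize every embedding window,
# stamp its pattern as the string of ties.method = "first" ranks, count the
# n! possible strings, and take Shannon entropy of the counts. Shares no
# code with the package's Lehmer-code path.
brute_patterns <- function(series, n, tau) {
  m <- length(series) - (n - 1) * tau
  vapply(seq_len(m), function(i) {
    v <- series[i + (0:(n - 1)) * tau]
    paste(rank(v, ties.method = "first"), collapse = "-")
  }, character(1))
}

brute_entropy <- function(tabcounts) {
  p <- tabcounts[tabcounts > 0] / sum(tabcounts)
  -sum(p * log(p))
}

brute_pe <- function(series, n, tau) {
  brute_entropy(table(brute_patterns(series, n, tau)))
}

brute_joint_pe <- function(x, y, n, tau) {
  px <- brute_patterns(x, n, tau)
  py <- brute_patterns(y, n, tau)
  brute_entropy(table(paste(px, py, sep = "|")))
}

brute_spmi <- function(x, y, n, tau) {
  pe_xy <- brute_joint_pe(x, y, n, tau)
  (brute_pe(x, n, tau) + brute_pe(y, n, tau) - pe_xy) / pe_xy
}

# small labeled graph with controllable class-dependent features
make_test_graph <- function(class, n_nodes = 10L, d = 7L, seed = 1L) {
  set.seed(seed)
  nf <- matrix(rnorm(n_nodes * d, mean = class / 4), n_nodes, d)
  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- sample(nrow(pairs), n_nodes)
  ed <- data.frame(src = as.integer(pairs[keep, 1]),
                   dst = as.integer(pairs[keep, 2]), weight = 1)
  structure(
    list(node_features = nf, edges = ed, subaction_class = as.integer(class),
         movement = if (class < 6) "push" else "pull",
         position = as.integer(class %% 6),
         subject_id = "t", group = "healthy", trial_id = "t1"),
    class = "channel_graph")
}

# permute a graph's nodes, relabeling features and edges consistently
permute_graph <- function(graph, perm) {
  g <- graph
  g$node_features <- graph$node_features[order(perm), , drop = FALSE]
  new_pos <- perm  # new index of old node i
  src <- new_pos[graph$edges$src]
  dst <- new_pos[graph$edges$dst]
  g$edges <- data.frame(src = pmin(src, dst), dst = pmax(src, dst),
                        weight = graph$edges$weight)
  g
}

# FFT magnitude of x at frequency f (Hz); amplitude of a pure sinusoid
fft_amplitude <- function(x, rate, f) {
  n <- length(x)
  k <- round(f * n / rate) + 1
  2 * Mod(stats::fft(x))[k] / n
}
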