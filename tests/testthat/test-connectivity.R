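test_that("ordinal patterns follow the rank-with-earlier-index-first rule", {
  cfg <- ordinal_config(2, 1)
  expect_identical(ordinal_patterns(c(1, 3, 2), cfg), c(0L, 1L))  # up, down
  # tie resolved as "up": the earlier equal sample ranks lower
  expect_identical(ordinal_patterns(c(2, 2, 1), cfg), c(0L, 1L))
  # strictly increasing: one repeated pattern
  expect_identical(ordinal_patterns(1:10, ordinal_config(3, 1)), rep(0L, 8))
  expect_error(ordinal_patterns(c(1, 2), ordinal_config(5, 1)), "too short")
})

test_that("pattern codes are a bijection onto 0..n!-1 for exhaustive permutations", {
  set.seed(2)
  for (n in 2:4) {
    perms <- unique(t(replicate(2000, sample(n))))
    codes <- apply(perms, 1, function(v)
      ordinal_patterns(v, ordinal_config(n, 1))[1])
    expect_length(unique(codes), factorial(n))
    expect_true(all(codes >= 0 & codes < factorial(n)))
  }
})

test_that("permutation entropy matches hand counts and bounds", {
  cfg <- ordinal_config(2, 1)
  expect_equal(permutation_entropy(c(1, 3, 2, 5, 4, 6), cfg),
               -(0.6 * log(0.6) + 0.4 * log(0.4)))
  expect_equal(permutation_entropy(sort(rnorm(50)), cfg), 0)
  cfg5 <- ordinal_config(5, 1)
  set.seed(3)
  for (i in 1:5)
    expect_lte(permutation_entropy(rnorm(300), cfg5), log(factorial(5)))
})

test_that("entropies agree with the brute-force pattern-enumeration oracle", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(2:4, 1)
    tau <- sample(1:2, 1)
    len <- sample(12:40, 1)
    x <- rnorm(len)
    y <- rnorm(len)
    cfg <- ordinal_config(n, tau)
    expect_equal(permutation_entropy(x, cfg), brute_pe(x, n, tau),
                 tolerance = 1e-12)
    expect_equal(joint_permutation_entropy(x, y, cfg),
                 brute_joint_pe(x, y, n, tau), tolerance = 1e-12)
    expect_equal(spmi(x, y, cfg), brute_spmi(x, y, n, tau), tolerance = 1e-12)
  }
})

test_that("joint permutation entropy brackets and factorizes correctly", {
  cfg <- ordinal_config(2, 1)
  x <- c(1, 3, 2, 5, 4, 6)
  expect_equal(joint_permutation_entropy(x, x, cfg), permutation_entropy(x, cfg))
  # y's pattern is the deterministic flip of x's: joint equals marginal
  y <- c(6, 4, 5, 2, 3, 1)
  expect_equal(joint_permutation_entropy(x, y, cfg), 0.6730117, tolerance = 1e-6)
  # constructed factorizing joint: 4 equiprobable pattern pairs -> log 4
  xf <- c(1, 3, 2, 4, 3)  # up down up down
  yf <- c(1, 2, 3, 1, 0)  # up up down down
  expect_equal(joint_permutation_entropy(xf, yf, cfg), log(4))
  expect_equal(joint_permutation_entropy(xf, yf, cfg),
               permutation_entropy(xf, cfg) + permutation_entropy(yf, cfg))
  expect_error(joint_permutation_entropy(1:5, 1:6, cfg), "equal length")
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(60); b <- rnorm(60)
    pe_ab <- joint_permutation_entropy(a, b, cfg)
    expect_gte(pe_ab + 1e-12, max(permutation_entropy(a, cfg),
                                  permutation_entropy(b, cfg)))
    expect_lte(pe_ab - 1e-12, permutation_entropy(a, cfg) +
                 permutation_entropy(b, cfg))
  }
})

test_that("SPMI is symmetric, self-unit, base-invariant, near zero for long independent noise", {
  cfg <- ordinal_config(2, 1)
  x <- c(1, 3, 2, 5, 4, 6)
  expect_equal(spmi(x, x, cfg), 1)
  expect_equal(spmi(x, c(6, 4, 5, 2, 3, 1), cfg), 1)
  set.seed(9)
  cfg5 <- ordinal_config(5, 1)
  vals <- replicate(20, spmi(rnorm(20000), rnorm(20000), cfg5))
  expect_true(all(vals < 0.05))
  expect_true(all(vals > -1e-12))
  # symmetry on random pairs
  for (i in 1:10) {
    a <- rnorm(200); b <- rnorm(200)
    expect_identical(spmi(a, b, cfg5), spmi(b, a, cfg5))
  }
  # degenerate pair: both monotone
  expect_error(spmi(1:50, 2 * (1:50), cfg), "degenerate")
  expect_equal(spmi(1:50, 2 * (1:50), ordinal_config(2, 1, degenerate = "zero")), 0)
})

test_that("spmi_matrix mirrors pairs, sets unit diagonal, matches direct calls", {
  set.seed(21)
  seg <- matrix(rnorm(8 * 250), 8)
  cfg <- ordinal_config(5, 1)
  cm <- spmi_matrix(seg, cfg)
  expect_identical(dim(cm), c(8L, 8L))
  expect_identical(unclass(cm)[upper.tri(cm)], t(unclass(cm))[upper.tri(cm)])
  expect_equal(unname(diag(cm)), rep(1, 8))
  pairs <- cbind(sample(8, 10, TRUE), sample(8, 10, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    expect_equal(cm[i, j], spmi(seg[i, ], seg[j, ], cfg))
  }
})

test_that("threshold_edges keeps exactly floor(q*P) strongest pairs with deterministic ties", {
  set.seed(5)
  seg <- matrix(rnorm(40 * 250), 40)
  cm <- spmi_matrix(seg, ordinal_config(5, 1))
  e <- threshold_edges(cm, 0.25)
  expect_identical(nrow(e), 195L)
  expect_true(all(e$src < e$dst))
  expect_identical(nrow(threshold_edges(cm[1:5, 1:5], 1.0)), 10L)
  # brute-force check on a hand-built 4x4 matrix
  m4 <- diag(1, 4)
  vals <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  m4[upper.tri(m4)] <- vals  # fills column-major: (1,2),(1,3),(2,3),(1,4),(2,4),(3,4)
  m4 <- m4 + t(m4) - diag(diag(m4))
  e4 <- threshold_edges(m4, 0.5)
  expect_identical(nrow(e4), 3L)
  expect_equal(sort(e4$weight, decreasing = TRUE), c(0.9, 0.8, 0.7))
  expect_error(threshold_edges(m4, 0), "q must be")
  expect_error(threshold_edges(m4, 1.2), "q must be")
  # all-tied values: lexicographic (src, dst) order wins
  mt <- matrix(0.5, 4, 4); diag(mt) <- 1
  et <- threshold_edges(mt, 0.5)
  expect_identical(et$src, c(1L, 1L, 1L))
  expect_identical(et$dst, c(2L, 3L, 4L))
})
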