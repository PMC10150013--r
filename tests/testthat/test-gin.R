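test_that("the GIN update matches hand sums and is permutation-equivariant", {
  path3 <- data.frame(src = c(1L, 2L), dst = c(2L, 3L))
  out <- gin_layer(matrix(c(1, 2, 3)), path3, epsilon = 0)
  expect_equal(drop(out), c(3, 6, 5))  # self + neighbors along the path
  # epsilon scales the self term
  out_eps <- gin_layer(matrix(c(1, 2, 3)), path3, epsilon = 0.5)
  expect_equal(drop(out_eps), c(1.5 + 2, 3 + 1 + 3, 4.5 + 2))
  # no edges: features unchanged under identity MLP
  expect_equal(gin_layer(matrix(c(1, 2, 3)), path3[0, ]), matrix(c(1, 2, 3)))
  # equivariance: permuting node labels permutes the output
  set.seed(14)
  x <- matrix(rnorm(5 * 3), 5)
  ed <- data.frame(src = c(1L, 1L, 2L, 4L), dst = c(2L, 5L, 3L, 5L))
  perm <- sample(5)
  xp <- x[order(perm), , drop = FALSE]
  edp <- data.frame(src = pmin(perm[ed$src], perm[ed$dst]),
                    dst = pmax(perm[ed$src], perm[ed$dst]))
  expect_equal(gin_layer(x, ed)[order(perm), , drop = FALSE],
               gin_layer(xp, edp))
  expect_error(gin_layer(x, data.frame(src = 1L, dst = 9L)), "outside")
})

test_that("the readout sum-pools, maps per depth and concatenates", {
  expect_equal(readout(list(rbind(c(1, 0), c(0, 2)))), c(1, 2))
  # linear map applied after pooling, concat across depths
  maps <- list(list(W = diag(2), b = c(0, 0)),
               list(W = matrix(c(0, 1, 1, 0), 2), b = c(10, 10)))
  embs <- list(rbind(c(1, 0), c(0, 2)), rbind(c(3, 1), c(1, 1)))
  expect_equal(readout(embs, maps), c(1, 2, 10 + 2, 10 + 4))
  expect_length(readout(embs, maps), 4L)
  # permutation invariance of pooling
  expect_equal(readout(list(rbind(c(0, 2), c(1, 0)))), c(1, 2))
  expect_error(readout(list()), "k = 0..K")
  expect_error(readout(embs, maps[1]), "per iteration")
})

test_that("the joint loss combines sub-action and marginalized movement terms", {
  # uniform logits: log 12 + weight * log 2
  expect_equal(joint_loss(matrix(0, 3, 12), c(0L, 5L, 11L)), log(12) + log(2))
  expect_equal(joint_loss(matrix(0, 1, 12), 3L, weight = 0.5),
               log(12) + 0.5 * log(2))
  # confident correct prediction: near-zero loss
  sharp <- rep(-50, 12); sharp[4] <- 50
  expect_lt(joint_loss(matrix(sharp, 1), 3L), 1e-6)
  # right movement, wrong position: movement term ~0, sub-action term large
  wrongpos <- rep(-50, 12); wrongpos[5] <- 50  # class 4 predicted, truth 3
  l_all <- joint_loss(matrix(wrongpos, 1), 3L, weight = 1)
  l_sub <- joint_loss(matrix(wrongpos, 1), 3L, weight = 0)
  expect_gt(l_sub, 10)               # sub-action term positive
  expect_lt(l_all - l_sub, 1e-6)     # movement term near zero
  # marginalized movement probabilities sum to 1
  set.seed(3)
  p <- corticograph:::softmax_rows(matrix(rnorm(24), 2))
  expect_equal(rowSums(corticograph:::block_marginals(p, 6L)), c(1, 1))
  expect_error(joint_loss(matrix(0, 1, 12), 12L), "out of range")
})

test_that("the analytic gradient matches finite differences", {
  set.seed(42)
  graphs <- lapply(c(0L, 3L, 7L, 11L), function(cl)
    make_test_graph(cl, n_nodes = 5L, d = 4L, seed = cl + 1L))
  cfg <- gin_config(K = 2, hidden = 5, seed = 1)
  params <- corticograph:::init_gin(cfg, d_in = 4L, n_classes = 12L)
  stats <- list(mean = rep(0, 4), sd = rep(1, 4))
  batch <- corticograph:::batch_graphs(graphs, stats)
  lossfun <- function(p) {
    cache <- corticograph:::gin_forward(p, batch, train = TRUE)
    joint_loss(cache$logits, batch$class, 1, 6L)
  }
  cache <- corticograph:::gin_forward(params, batch, train = TRUE)
  grads <- corticograph:::gin_backward(params, batch, cache, 1, 6L)
  paths <- corticograph:::trainable_paths(params)
  for (pth in paths) {
    g <- corticograph:::get_param(grads, pth)
    v <- corticograph:::get_param(params, pth)
    for (i in sample(length(v), min(3, length(v)))) {
      h <- 1e-5
      vp <- v; vp[i] <- vp[i] + h
      vm <- v; vm[i] <- vm[i] - h
      fd <- (lossfun(corticograph:::set_param(params, pth, vp)) -
               lossfun(corticograph:::set_param(params, pth, vm))) / (2 * h)
      expect_equal(g[i], fd, tolerance = 1e-5,
                   label = paste("grad", paste(pth, collapse = "/")))
    }
  }
})

test_that("forward passes are deterministic, permutation-invariant, softmax-normalized", {
  set.seed(50)
  graphs <- lapply(0:11, function(cl) make_test_graph(cl, seed = cl + 10L))
  model <- train_gin(graphs, gin_config(K = 2, hidden = 16, epochs = 5,
                                        batch_size = 8, seed = 2))
  l1 <- predict_logits(model, graphs[1:3])
  expect_true(all(is.finite(l1)))
  expect_identical(l1, predict_logits(model, graphs[1:3]))  # eval-mode stability
  probs <- corticograph:::softmax_rows(l1)
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
  # two isomorphic graphs give identical logits
  g <- graphs[[5]]
  set.seed(8)
  gp <- permute_graph(g, sample(nrow(g$node_features)))
  expect_equal(predict_logits(model, list(g)), predict_logits(model, list(gp)))
  # wrong feature width is refused
  bad <- g; bad$node_features <- bad$node_features[, 1:5]
  expect_error(predict_logits(model, list(bad)), "width mismatch")
})

test_that("training is seeded-reproducible, loss decreases, capacity overfits 2x12 graphs", {
  graphs <- lapply(rep(0:11, 2), function(cl)
    make_test_graph(as.integer(cl), n_nodes = 12L, seed = cl + 30L))
  cfg <- gin_config(K = 2, hidden = 32, epochs = 120, batch_size = 24, seed = 9)
  m1 <- train_gin(graphs, cfg)
  expect_lt(m1$history$loss[50], m1$history$loss[1])
  acc <- mean(predict_classes(m1, graphs) ==
                vapply(graphs, `[[`, integer(1), "subaction_class"))
  expect_gte(acc, 0.99)
  m2 <- train_gin(graphs, cfg)
  expect_identical(m1$params, m2$params)
  expect_error(train_gin(list(), cfg), "empty")
})

test_that("model checkpoints round-trip through JSON", {
  graphs <- lapply(0:11, function(cl) make_test_graph(cl, seed = cl + 60L))
  model <- train_gin(graphs, gin_config(K = 2, hidden = 8, epochs = 3,
                                        batch_size = 12, seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  save_gin(model, path)
  back <- load_gin(path)
  expect_equal(predict_logits(back, graphs[1:4]),
               predict_logits(model, graphs[1:4]), tolerance = 1e-12)
  expect_identical(back$config$K, model$config$K)
})

test_that("sequence prediction decodes six position-ordered labels", {
  graphs <- lapply(0:11, function(cl) make_test_graph(cl, seed = cl + 80L))
  model <- train_gin(graphs, gin_config(K = 2, hidden = 8, epochs = 3,
                                        batch_size = 12, seed = 4))
  trial <- lapply(0:5, function(p) {
    g <- make_test_graph(p, seed = 100L + p)
    g$trial_id <- "trialX"
    g$position <- p
    g
  })
  M <- predict_sequence(model, trial)
  expect_s3_class(M, "prediction_sequence")
  expect_identical(nrow(M), 6L)
  expect_true(all(M$movement %in% c("push", "pull")))
  expect_true(all(M$position %in% 0:5))
  expect_identical(M, predict_sequence(model, trial))
  expect_error(predict_sequence(model, trial[1:4]), "6 position-ordered")
})
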