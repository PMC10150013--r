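#' GIN training configuration
#'
#' Hyperparameters of the Graph Isomorphism Network classifier. Defaults
#' follow the package's standard decoding setup: 7 input channels (the node
#' feature length), 64 hidden channels, a 2-layer MLP with batch
#' normalization per GIN iteration, Adam with learning rate 0.005, 300
#' epochs, batch size 128, and a learnable epsilon per layer initialized at
#' 0. `K` is the number of GIN iterations (message-passing depth).
#'
#' @param K GIN iterations, >= 1 (default 3).
#' @param hidden MLP width (default 64).
#' @param epochs Training epochs (default 300).
#' @param batch_size Graphs per batch (default 128).
#' @param learning_rate Adam step size (default 0.005).
#' @param movement_loss_weight Weight of the whole-movement cross-entropy
#'   term added to the sub-action cross-entropy (default 1).
#' @param n_positions Segments per movement (default 6; the class count is
#'   `2 * n_positions`).
#' @param seed Integer seed for initialization and batch shuffling.
#' @return A `gin_config` object.
#' @export
gin_config <- function(K = 3L, hidden = 64L, epochs = 300L, batch_size = 128L,
                       learning_rate = 0.005, movement_loss_weight = 1,
                       n_positions = 6L, seed = 1L) {
  K <- as.integer(K)
  hidden <- as.integer(hidden)
  if (K < 1L) stop("K must be >= 1")
  if (hidden < 1L) stop("hidden must be >= 1")
  structure(
    list(K = K, hidden = hidden, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), learning_rate = learning_rate,
         movement_loss_weight = movement_loss_weight,
         n_positions = as.integer(n_positions), seed = as.integer(seed)),
    class = "gin_config"
  )
}

# ---- spec-level primitive operations (also used by tests) -----------------

# neighbor-sum aggregation over an undirected edge list (src < dst rows);
# both directions contribute, isolated nodes aggregate to zero
neighbor_sum <- function(x, edges, n_nodes = nrow(x)) {
  agg <- matrix(0, n_nodes, ncol(x))
  if (nrow(edges) > 0L) {
    src <- c(edges$src, edges$dst)
    dst <- c(edges$dst, edges$src)
    sums <- rowsum(x[src, , drop = FALSE], dst)
    agg[as.integer(rownames(sums)), ] <- sums
  }
  agg
}

#' One GIN update
#'
#' The injective message-passing step: each node's new representation is
#' `mlp((1 + epsilon) * x_i + sum over neighbors j of x_j)`. Undirected
#' edges aggregate in both directions; an isolated node keeps
#' `mlp((1 + epsilon) * x_i)`. Permutation-equivariant: relabeling nodes
#' permutes the output rows identically.
#'
#' @param node_features Nodes-by-features numeric matrix.
#' @param edges Data frame with integer `src`, `dst` columns (1-based).
#' @param epsilon Scalar self-weight offset.
#' @param mlp Function applied row-wise to the combined matrix (default
#'   identity).
#' @return Updated node-feature matrix.
#' @export
gin_layer <- function(node_features, edges, epsilon = 0, mlp = identity) {
  if (nrow(edges) > 0L &&
      (max(edges$src, edges$dst) > nrow(node_features) || min(edges$src, edges$dst) < 1L))
    stop("edges reference nodes outside the feature matrix")
  combined <- (1 + epsilon) * node_features + neighbor_sum(node_features, edges)
  mlp(combined)
}

#' Multi-depth sum readout
#'
#' Maps per-iteration node embeddings of one graph to the graph embedding:
#' sum-pool the nodes at each depth k = 0..K, apply that depth's linear
#' map, and concatenate across depths. Sum pooling makes the result exactly
#' invariant to node permutations.
#'
#' @param embeddings List of nodes-by-d_k matrices, one per iteration
#'   (k = 0 first).
#' @param maps Optional list of `list(W, b)` linear maps per iteration
#'   (default identity maps).
#' @return Numeric graph-embedding vector (concatenated across depths).
#' @export
readout <- function(embeddings, maps = NULL) {
  if (length(embeddings) == 0L) stop("need embeddings for iterations k = 0..K")
  if (!is.null(maps) && length(maps) != length(embeddings))
    stop("one linear map per iteration required (missing iteration?)")
  parts <- lapply(seq_along(embeddings), function(k) {
    pooled <- colSums(embeddings[[k]])
    if (is.null(maps)) pooled
    else drop(pooled %*% maps[[k]]$W + maps[[k]]$b)
  })
  unlist(parts, use.names = FALSE)
}

#' Joint sub-action + movement cross-entropy
#'
#' The training loss: cross-entropy over the 12 sub-action classes plus
#' `weight` times the cross-entropy over the 2 movements, where the
#' movement probability is the marginal of the 12-way softmax over each
#' movement's block of classes. Uniform logits give
#' `log(12) + weight * log(2)`.
#'
#' @param logits Batch-by-classes matrix (or a single logit vector).
#' @param class Integer vector of true sub-action codes (0-based).
#' @param weight Movement-loss weight (default 1).
#' @param n_positions Segments per movement (default 6).
#' @return Scalar mean loss.
#' @export
joint_loss <- function(logits, class, weight = 1, n_positions = 6L) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  class <- as.integer(class)
  if (any(class < 0L | class >= ncol(logits))) stop("class code out of range")
  p <- softmax_rows(logits)
  b <- seq_len(nrow(logits))
  ce_sub <- -log(p[cbind(b, class + 1L)])
  block <- class %/% n_positions
  p_move <- block_marginals(p, n_positions)
  ce_move <- -log(p_move[cbind(b, block + 1L)])
  mean(ce_sub) + weight * mean(ce_move)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# sum the 12-way probabilities within each movement block -> B x 2
block_marginals <- function(p, n_positions) {
  n_move <- ncol(p) %/% n_positions
  out <- matrix(0, nrow(p), n_move)
  for (m in seq_len(n_move))
    out[, m] <- rowSums(p[, (m - 1L) * n_positions + seq_len(n_positions), drop = FALSE])
  out
}

# ---- parameter initialization --------------------------------------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_gin <- function(config, d_in = 7L, n_classes = 12L) {
  hid <- config$hidden
  layers <- lapply(seq_len(config$K), function(k) {
    din_k <- if (k == 1L) d_in else hid
    list(W1 = glorot(din_k, hid), b1 = numeric(hid),
         gamma = rep(1, hid), beta = numeric(hid),
         run_mean = numeric(hid), run_var = rep(1, hid),
         W2 = glorot(hid, hid), b2 = numeric(hid),
         eps = 0)
  })
  ro <- lapply(seq_len(config$K + 1L), function(kk) {
    din_k <- if (kk == 1L) d_in else hid
    list(W = glorot(din_k, hid), b = numeric(hid))
  })
  out <- list(W = glorot((config$K + 1L) * hid, n_classes), b = numeric(n_classes))
  list(layers = layers, readout = ro, out = out)
}

# ---- batching -------------------------------------------------------------

standardize_stats <- function(graphs) {
  x <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[sd < 1e-8] <- 1
  list(mean = mu, sd = sd)
}

# stack graphs into one node matrix with offset edges and a graph index
batch_graphs <- function(graphs, stats) {
  sizes <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  x <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  x <- sweep(sweep(x, 2L, stats$mean), 2L, stats$sd, "/")
  src <- unlist(lapply(seq_along(graphs), function(i) graphs[[i]]$edges$src + offsets[i]))
  dst <- unlist(lapply(seq_along(graphs), function(i) graphs[[i]]$edges$dst + offsets[i]))
  list(x = x, edges = data.frame(src = as.integer(src), dst = as.integer(dst)),
       graph_id = rep(seq_along(graphs), sizes),
       n_graphs = length(graphs),
       class = vapply(graphs, `[[`, integer(1), "subaction_class"))
}

pool_sum <- function(h, graph_id, n_graphs) {
  sums <- rowsum(h, graph_id)
  out <- matrix(0, n_graphs, ncol(h))
  out[as.integer(rownames(sums)), ] <- sums
  out
}

# ---- forward / backward ---------------------------------------------------

bn_eps <- 1e-5
bn_momentum <- 0.1

gin_forward <- function(params, batch, train = FALSE) {
  K <- length(params$layers)
  h <- batch$x
  emb <- vector("list", K + 1L)
  emb[[1L]] <- h
  cache <- list(layers = vector("list", K))
  for (k in seq_len(K)) {
    ly <- params$layers[[k]]
    agg <- neighbor_sum(h, batch$edges, nrow(h))
    a <- (1 + ly$eps) * h + agg
    z <- a %*% ly$W1 + rep(ly$b1, each = nrow(a))
    if (train) {
      mu <- colMeans(z)
      va <- colMeans(z^2) - mu^2  # biased, used for normalization
    } else {
      mu <- ly$run_mean
      va <- ly$run_var
    }
    invstd <- 1 / sqrt(va + bn_eps)
    xhat <- sweep(sweep(z, 2L, mu), 2L, invstd, "*")
    g <- sweep(sweep(xhat, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
    r <- pmax(g, 0)
    hn <- r %*% ly$W2 + rep(ly$b2, each = nrow(r))
    cache$layers[[k]] <- list(h_in = h, a = a, z = z, mu = mu, invstd = invstd,
                              xhat = xhat, g = g, r = r)
    emb[[k + 1L]] <- hn
    h <- hn
  }
  pooled <- lapply(seq_len(K + 1L), function(kk)
    pool_sum(emb[[kk]], batch$graph_id, batch$n_graphs))
  s_parts <- lapply(seq_len(K + 1L), function(kk) {
    ro <- params$readout[[kk]]
    pooled[[kk]] %*% ro$W + rep(ro$b, each = batch$n_graphs)
  })
  s <- do.call(cbind, s_parts)
  logits <- s %*% params$out$W + rep(params$out$b, each = batch$n_graphs)
  cache$emb <- emb
  cache$pooled <- pooled
  cache$s <- s
  cache$logits <- logits
  cache
}

# gradient of the joint loss w.r.t. logits (mean reduction over the batch)
joint_loss_grad <- function(logits, class, weight, n_positions) {
  p <- softmax_rows(logits)
  bsz <- nrow(p)
  b <- seq_len(bsz)
  d <- p
  d[cbind(b, class + 1L)] <- d[cbind(b, class + 1L)] - 1
  block <- class %/% n_positions
  p_move <- block_marginals(p, n_positions)
  dm <- p
  in_block <- (col(p) - 1L) %/% n_positions == block[row(p)]
  dm[in_block] <- dm[in_block] - (p / p_move[cbind(b, block + 1L)])[in_block]
  (d + weight * dm) / bsz
}

gin_backward <- function(params, batch, cache, weight, n_positions) {
  K <- length(params$layers)
  ng <- batch$n_graphs
  grads <- list(layers = vector("list", K),
                readout = vector("list", K + 1L), out = NULL)
  dlogits <- joint_loss_grad(cache$logits, batch$class, weight, n_positions)
  grads$out <- list(W = crossprod(cache$s, dlogits), b = colSums(dlogits))
  ds <- dlogits %*% t(params$out$W)
  hid <- ncol(params$readout[[1L]]$W)
  d_emb <- vector("list", K + 1L)
  for (kk in seq_len(K + 1L)) {
    cols <- (kk - 1L) * hid + seq_len(hid)
    ds_k <- ds[, cols, drop = FALSE]
    ro <- params$readout[[kk]]
    grads$readout[[kk]] <- list(W = crossprod(cache$pooled[[kk]], ds_k),
                                b = colSums(ds_k))
    dp <- ds_k %*% t(ro$W)                       # n_graphs x d_k
    d_emb[[kk]] <- dp[batch$graph_id, , drop = FALSE]  # broadcast to nodes
  }
  dh_next <- d_emb[[K + 1L]]
  for (k in rev(seq_len(K))) {
    ly <- params$layers[[k]]
    cc <- cache$layers[[k]]
    m <- nrow(cc$z)
    dhn <- dh_next
    dr <- dhn %*% t(ly$W2)
    gW2 <- crossprod(cc$r, dhn)
    gb2 <- colSums(dhn)
    dg <- dr * (cc$g > 0)
    ggamma <- colSums(dg * cc$xhat)
    gbeta <- colSums(dg)
    dxhat <- sweep(dg, 2L, ly$gamma, "*")
    dz <- sweep(
      m * dxhat -
        rep(colSums(dxhat), each = m) -
        cc$xhat * rep(colSums(dxhat * cc$xhat), each = m),
      2L, cc$invstd / m, "*")
    da <- dz %*% t(ly$W1)
    gW1 <- crossprod(cc$a, dz)
    gb1 <- colSums(dz)
    geps <- sum(da * cc$h_in)
    dh <- (1 + ly$eps) * da + neighbor_sum(da, batch$edges, nrow(da))
    grads$layers[[k]] <- list(W1 = gW1, b1 = gb1, gamma = ggamma, beta = gbeta,
                              W2 = gW2, b2 = gb2, eps = geps)
    dh_next <- dh + d_emb[[k]]
  }
  grads
}

update_bn_running <- function(params, cache) {
  for (k in seq_along(params$layers)) {
    cc <- cache$layers[[k]]
    m <- nrow(cc$z)
    unbiased <- 1 / (cc$invstd^2) - bn_eps
    if (m > 1L) unbiased <- unbiased * m / (m - 1L)
    params$layers[[k]]$run_mean <-
      (1 - bn_momentum) * params$layers[[k]]$run_mean + bn_momentum * cc$mu
    params$layers[[k]]$run_var <-
      (1 - bn_momentum) * params$layers[[k]]$run_var + bn_momentum * unbiased
  }
  params
}

# ---- Adam over the nested parameter list ----------------------------------

trainable_paths <- function(params) {
  paths <- list()
  for (k in seq_along(params$layers))
    for (nm in c("W1", "b1", "gamma", "beta", "W2", "b2", "eps"))
      paths[[length(paths) + 1L]] <- c("layers", k, nm)
  for (kk in seq_along(params$readout))
    for (nm in c("W", "b"))
      paths[[length(paths) + 1L]] <- c("readout", kk, nm)
  paths[[length(paths) + 1L]] <- c("out", 1L, "W")
  paths[[length(paths) + 1L]] <- c("out", 1L, "b")
  paths
}

get_param <- function(params, path) {
  if (path[1L] == "out") params$out[[path[3L]]]
  else params[[path[1L]]][[as.integer(path[2L])]][[path[3L]]]
}

set_param <- function(params, path, value) {
  if (path[1L] == "out") params$out[[path[3L]]] <- value
  else params[[path[1L]]][[as.integer(path[2L])]][[path[3L]]] <- value
  params
}

adam_init <- function(params, paths) {
  lapply(paths, function(p) {
    v <- get_param(params, p)
    list(m = v * 0, v = v * 0)
  })
}

adam_step <- function(params, grads, state, paths, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    g <- get_param(grads, p)
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    state[[i]] <- st
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params <- set_param(params, p,
                        get_param(params, p) - lr * mhat / (sqrt(vhat) + eps))
  }
  list(params = params, state = state)
}

# ---- training and prediction ----------------------------------------------

#' Train the GIN classifier
#'
#' Trains on a list of channel graphs with the joint sub-action + movement
#' cross-entropy, Adam, and shuffled mini-batches. Node features are
#' z-scored per feature using training-set statistics (stored in the model
#' and reapplied at prediction time) so the raw electrode index cannot
#' dominate the scale. Seeded runs are bit-reproducible on one device.
#'
#' @param graphs List of `channel_graph` objects (training set).
#' @param config A [gin_config()].
#' @param verbose Print the loss every 25 epochs.
#' @return A `gin_model`: parameters, config, feature-standardization
#'   constants, and the per-epoch loss `history`.
#' @export
train_gin <- function(graphs, config = gin_config(), verbose = FALSE) {
  if (length(graphs) == 0L) stop("empty training set")
  n_classes <- 2L * config$n_positions
  stats <- standardize_stats(graphs)
  history <- numeric(config$epochs)
  with_seed(config$seed, {
    params <- init_gin(config, d_in = ncol(graphs[[1L]]$node_features),
                       n_classes = n_classes)
    paths <- trainable_paths(params)
    state <- adam_init(params, paths)
    t <- 0L
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(length(graphs))
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        batch <- batch_graphs(graphs[bi], stats)
        cache <- gin_forward(params, batch, train = TRUE)
        loss <- joint_loss(cache$logits, batch$class,
                           config$movement_loss_weight, config$n_positions)
        grads <- gin_backward(params, batch, cache,
                              config$movement_loss_weight, config$n_positions)
        params <- update_bn_running(params, cache)
        t <- t + 1L
        upd <- adam_step(params, grads, state, paths, config$learning_rate, t)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + loss * length(bi)
      }
      history[epoch] <- ep_loss / length(graphs)
      if (verbose && epoch %% 25L == 0L)
        message(sprintf("epoch %d loss %.4f", epoch, history[epoch]))
    }
    structure(
      list(params = params, config = config, standardize = stats,
           n_classes = n_classes,
           history = data.frame(epoch = seq_len(config$epochs), loss = history)),
      class = "gin_model"
    )
  })
}

#' @export
print.gin_model <- function(x, ...) {
  cat(sprintf("<gin_model> K=%d hidden=%d | %d classes | trained %d epochs (final loss %.4f)\n",
              x$config$K, x$config$hidden, x$n_classes,
              nrow(x$history), utils::tail(x$history$loss, 1L)))
  invisible(x)
}

#' Class logits for a list of graphs
#'
#' Evaluation-mode forward pass (batch-norm running statistics, no
#' dropout-style stochasticity anywhere): deterministic, and exactly
#' invariant to node permutations of isomorphic graphs.
#'
#' @param model A trained `gin_model`.
#' @param graphs List of `channel_graph` objects.
#' @return Graphs-by-classes logit matrix.
#' @export
predict_logits <- function(model, graphs) {
  d_expect <- nrow(model$params$layers[[1L]]$W1)
  bad <- vapply(graphs, function(g) ncol(g$node_features) != d_expect, logical(1))
  if (any(bad))
    stop("node-feature width mismatch: model expects ", d_expect, " features")
  batch <- batch_graphs(graphs, model$standardize)
  cache <- gin_forward(model$params, batch, train = FALSE)
  logits <- cache$logits
  colnames(logits) <- paste0("class", seq_len(ncol(logits)) - 1L)
  logits
}

#' @rdname predict_logits
#' @return `predict_classes`: integer vector of predicted class codes
#'   (0-based argmax of the logits).
#' @export
predict_classes <- function(model, graphs) {
  as.integer(max.col(predict_logits(model, graphs), ties.method = "first") - 1L)
}

#' Predict the sub-action sequence of one trial
#'
#' Runs the model on a trial's position-ordered segment graphs and decodes
#' the argmax class of each into its `(movement, position)` sub-action
#' label.
#'
#' @param model A trained `gin_model`.
#' @param trial_graphs The trial's graphs, ordered by position (length
#'   `n_positions`).
#' @return A `prediction_sequence`: data frame with columns `movement` and
#'   `position`, one row per segment, with the true labels in attributes
#'   `true_movement` / `trial_id`.
#' @export
predict_sequence <- function(model, trial_graphs) {
  n_pos <- model$config$n_positions
  if (length(trial_graphs) != n_pos)
    stop(sprintf("expected %d position-ordered graphs, got %d",
                 n_pos, length(trial_graphs)))
  codes <- predict_classes(model, trial_graphs)
  decoded <- lapply(codes, decode_label, n_positions = n_pos)
  structure(
    data.frame(movement = vapply(decoded, `[[`, character(1), "movement"),
               position = vapply(decoded, `[[`, integer(1), "position")),
    true_movement = trial_graphs[[1L]]$movement,
    trial_id = trial_graphs[[1L]]$trial_id,
    subject_id = trial_graphs[[1L]]$subject_id,
    group = trial_graphs[[1L]]$group,
    class = c("prediction_sequence", "data.frame")
  )
}

#' Save / load a model checkpoint (JSON)
#'
#' Single-file checkpoint holding the weights, the configuration, and the
#' feature-standardization constants, written with full double precision.
#'
#' @param model A `gin_model`.
#' @param path Checkpoint file.
#' @return `save_gin` returns `path` invisibly; `load_gin` the model.
#' @export
save_gin <- function(model, path) {
  jsonlite::write_json(
    list(params = model$params, config = unclass(model$config),
         standardize = model$standardize, n_classes = model$n_classes,
         history = model$history),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_gin
#' @export
load_gin <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- do.call(gin_config, raw$config)
  model <- list(params = raw$params, config = cfg,
                standardize = raw$standardize, n_classes = raw$n_classes,
                history = as.data.frame(raw$history))
  class(model) <- "gin_model"
  model
}
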