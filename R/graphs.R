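#' Encode / decode sub-action labels
#'
#' The 12-class sub-action space is the product of 2 movements and 6
#' segment positions. Codes 0-5 are push positions 0-5 and codes 6-11 are
#' pull positions 0-5 (the push block first — an arbitrary but fixed
#' ordering). `decode_label(encode_label(m, p))` is the identity.
#'
#' @param movement `"push"` or `"pull"`.
#' @param position Integer in `0 .. n_positions - 1`.
#' @param n_positions Segments per movement (default 6).
#' @return `encode_label`: integer class code in `0 .. 2 * n_positions - 1`.
#'   `decode_label`: list with `movement` and `position`.
#' @export
encode_label <- function(movement, position, n_positions = 6L) {
  movement <- match.arg(movement, movement_levels)
  position <- as.integer(position)
  if (is.na(position) || position < 0L || position >= n_positions)
    stop(sprintf("position must be in 0..%d", n_positions - 1L))
  (match(movement, movement_levels) - 1L) * n_positions + position
}

#' @rdname encode_label
#' @param code Integer class code.
#' @export
decode_label <- function(code, n_positions = 6L) {
  code <- as.integer(code)
  if (is.na(code) || code < 0L || code >= 2L * n_positions)
    stop(sprintf("class code must be in 0..%d", 2L * n_positions - 1L))
  list(movement = movement_levels[code %/% n_positions + 1L],
       position = code %% n_positions)
}

#' @rdname encode_label
#' @export
n_subaction_classes <- function(n_positions = 6L) 2L * n_positions

#' Build a channel graph from a segment window
#'
#' The graph-construction step of the pipeline: one node per channel with
#' the length-7 band-power feature vector ([node_feature()]; the EEG
#' channels use the EEG total band, the EMG channels the EMG total band),
#' and undirected edges from thresholding the segment's SPMI matrix
#' ([spmi_matrix()] then [threshold_edges()]). EEG and EMG nodes share one
#' feature schema and one edge semantics — the heterogeneity of the data is
#' representational only, and the GNN treats the result as a general graph.
#'
#' @param segment A [segment_window()].
#' @param ordinal_cfg An [ordinal_config()].
#' @param scheme A [band_scheme()].
#' @param q Edge retention fraction (default 0.25: 195 of 780 pairs for 40
#'   channels).
#' @param n_eeg Number of leading EEG rows (default 32).
#' @param eeg_total_band,emg_total_band Total-power bands per modality.
#' @return A `channel_graph`: list with `node_features` (N x 7 matrix),
#'   `edges` (data frame src/dst/weight, src < dst), `subaction_class`,
#'   `movement`, `position`, `subject_id`, `group`, `trial_id`.
#' @export
build_graph <- function(segment, ordinal_cfg = ordinal_config(),
                        scheme = band_scheme(), q = 0.25, n_eeg = 32L,
                        eeg_total_band = c(2, 40), emg_total_band = c(2, 100)) {
  data <- segment$data
  nch <- nrow(data)
  feats <- matrix(0, nch, 7L)
  colnames(feats) <- c(names(scheme), "total_power", "electrode")
  rownames(feats) <- rownames(data)
  for (ch in seq_len(nch)) {
    total_band <- if (ch <= n_eeg) eeg_total_band else emg_total_band
    feats[ch, ] <- node_feature(data[ch, ], ch - 1L, segment$rate, scheme,
                                total_band)
  }
  cm <- spmi_matrix(data, ordinal_cfg)
  edges <- threshold_edges(cm, q)
  structure(
    list(node_features = feats, edges = edges,
         subaction_class = encode_label(segment$movement, segment$position,
                                        segment$n_positions),
         movement = segment$movement, position = segment$position,
         subject_id = segment$subject_id, group = segment$group,
         trial_id = segment$trial_id),
    class = "channel_graph"
  )
}

#' @export
print.channel_graph <- function(x, ...) {
  cat(sprintf("<channel_graph> %s position %d (class %d) | %d nodes, %d edges | subject %s\n",
              x$movement, x$position, x$subaction_class,
              nrow(x$node_features), nrow(x$edges), x$subject_id))
  invisible(x)
}

#' Build graphs for a list of segments
#'
#' @param segments List of [segment_window()] objects.
#' @param ... Passed to [build_graph()].
#' @param progress Print a dot every 25 graphs (default FALSE).
#' @return List of `channel_graph` objects.
#' @export
build_graphs <- function(segments, ..., progress = FALSE) {
  out <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    out[[i]] <- build_graph(segments[[i]], ...)
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  out
}

#' Write / read a graph dataset (plain-text container)
#'
#' One directory per dataset: `graphs.tsv` (one row per graph: labels and
#' metadata), `features.tsv` (node-feature rows for all graphs, keyed by
#' graph index and node index) and `edges.tsv` (keyed by graph index).
#' Values are printed with 17 significant digits, so the round trip is
#' lossless.
#'
#' @param graphs List of `channel_graph` objects.
#' @param path Dataset directory.
#' @return `write_graphs` returns `path` invisibly; `read_graphs` the list
#'   of graphs.
#' @export
write_graphs <- function(graphs, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    data.frame(graph = i, subaction_class = g$subaction_class,
               movement = g$movement, position = g$position,
               subject_id = g$subject_id, group = g$group,
               trial_id = g$trial_id, n_nodes = nrow(g$node_features))
  }))
  utils::write.table(meta, file.path(path, "graphs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  feat_lines <- unlist(lapply(seq_along(graphs), function(i) {
    f <- graphs[[i]]$node_features
    vapply(seq_len(nrow(f)), function(v)
      paste(c(i, v, sprintf("%.17g", f[v, ])), collapse = "\t"), character(1))
  }))
  writeLines(c(paste(c("graph", "node", colnames(graphs[[1L]]$node_features)),
                     collapse = "\t"), feat_lines),
             file.path(path, "features.tsv"))
  edge_lines <- unlist(lapply(seq_along(graphs), function(i) {
    e <- graphs[[i]]$edges
    sprintf("%d\t%d\t%d\t%.17g", i, e$src, e$dst, e$weight)
  }))
  writeLines(c("graph\tsrc\tdst\tweight", edge_lines),
             file.path(path, "edges.tsv"))
  invisible(path)
}

#' @rdname write_graphs
#' @export
read_graphs <- function(path) {
  meta <- utils::read.table(file.path(path, "graphs.tsv"), sep = "\t",
                            header = TRUE, colClasses = "character")
  feats <- utils::read.table(file.path(path, "features.tsv"), sep = "\t",
                             header = TRUE)
  edges <- utils::read.table(file.path(path, "edges.tsv"), sep = "\t",
                             header = TRUE)
  lapply(seq_len(nrow(meta)), function(i) {
    f <- feats[feats$graph == i, , drop = FALSE]
    f <- f[order(f$node), , drop = FALSE]
    fm <- as.matrix(f[, -(1:2), drop = FALSE])
    rownames(fm) <- NULL
    e <- edges[edges$graph == i, c("src", "dst", "weight"), drop = FALSE]
    rownames(e) <- NULL
    structure(
      list(node_features = fm, edges = e,
           subaction_class = as.integer(meta$subaction_class[i]),
           movement = meta$movement[i],
           position = as.integer(meta$position[i]),
           subject_id = meta$subject_id[i], group = meta$group[i],
           trial_id = meta$trial_id[i]),
      class = "channel_graph")
  })
}

#' Dump one graph as JSON (debug aid)
#'
#' @param graph A `channel_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(
    list(subaction_class = graph$subaction_class, movement = graph$movement,
         position = graph$position, subject_id = graph$subject_id,
         group = graph$group, trial_id = graph$trial_id,
         node_features = graph$node_features,
         edges = graph$edges),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
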