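#' Pipeline configuration
#'
#' One configuration object for the full decoding pipeline, with defaults
#' equal to the package's standard settings: SPMI with embedding dimension
#' 5 and lag 1, top-25% edge retention, six 0.5 s segments, a 4:1
#' trial-level split, and GIN training with 64 hidden channels, learning
#' rate 0.005, 300 epochs, batch size 128. Unknown keys in any section are
#' rejected at load time.
#'
#' @param run_dir Directory for stage artifacts.
#' @param seed Master seed; stages derive their seeds from it.
#' @param simulate,preprocess,graph,split,train Per-stage named lists
#'   overriding individual defaults (see the vignette for every knob).
#' @return A validated `pipeline_config` object.
#' @export
pipeline_config <- function(run_dir = "corticograph_run", seed = 1L,
                            simulate = list(), preprocess = list(),
                            graph = list(), split = list(), train = list()) {
  defaults <- list(
    simulate = list(n_per_class = 15L, subjects = c("s01", "s02"),
                    groups = c("healthy", "healthy"), patient_subjects = character(0)),
    preprocess = list(eeg_band = c(2, 40), emg_band = c(2, 100),
                      n_segments = 6L, skip_ica = TRUE),
    graph = list(n = 5L, tau = 1L, q = 0.25),
    split = list(ratio = c(4, 1)),
    train = list(K = 3L, hidden = 64L, epochs = 300L, batch_size = 128L,
                 learning_rate = 0.005, movement_loss_weight = 1)
  )
  merge_section <- function(name, user) {
    base <- defaults[[name]]
    unknown <- setdiff(names(user), names(base))
    if (length(unknown))
      stop(sprintf("unknown key(s) in config section '%s': %s",
                   name, paste(unknown, collapse = ", ")))
    base[names(user)] <- user
    base
  }
  cfg <- list(run_dir = run_dir, seed = as.integer(seed),
              simulate = merge_section("simulate", simulate),
              preprocess = merge_section("preprocess", preprocess),
              graph = merge_section("graph", graph),
              split = merge_section("split", split),
              train = merge_section("train", train))
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys are `run_dir`, `seed` and the
#' per-stage sections of [pipeline_config()]; unknown keys anywhere are
#' rejected.
#'
#' @param path YAML file.
#' @param overrides Named list applied on top (e.g. from CLI flags).
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  known <- c("run_dir", "seed", "simulate", "preprocess", "graph", "split", "train")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

stage_manifest <- function(config, stage, inputs, outputs) {
  jsonlite::write_json(
    list(stage = stage, seed = config$seed, config_hash = config_hash(config),
         inputs = inputs, outputs = outputs,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(config$run_dir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE)
}

require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop(sprintf("missing artifact %s: run the `%s` stage first", path, producer),
         call. = FALSE)
  path
}

# segments container: manifest + one matrix file per segment
write_segments <- function(segments, path, split_table = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    f <- sprintf("seg%05d.tsv", i)
    write_matrix_tsv(s$data, file.path(path, f))
    data.frame(file = f, trial_id = s$trial_id, subject_id = s$subject_id,
               group = s$group, movement = s$movement, position = s$position,
               rate = s$rate, n_positions = s$n_positions)
  })
  utils::write.table(do.call(rbind, rows), file.path(path, "segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(split_table))
    utils::write.table(split_table, file.path(path, "split.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_segments <- function(path) {
  man <- utils::read.table(file.path(path, "segments.tsv"), sep = "\t",
                           header = TRUE, colClasses = "character")
  lapply(seq_len(nrow(man)), function(i) {
    segment_window(read_matrix_tsv(file.path(path, man$file[i])),
                   man$movement[i], as.integer(man$position[i]),
                   man$subject_id[i], man$group[i], man$trial_id[i],
                   as.numeric(man$rate[i]), as.integer(man$n_positions[i]))
  })
}

#' Run a pipeline stage
#'
#' Orchestrates the pipeline end to end. Stages and their artifacts (all
#' under `config$run_dir`):
#' \describe{
#'   \item{simulate}{synthetic dataset -> `dataset/`}
#'   \item{preprocess}{resample, filter, segment, trial-level split ->
#'     `segments/` (+ `split.tsv`)}
#'   \item{graphs}{channel graphs -> `graphs_train/`, `graphs_test/`}
#'   \item{train}{GIN training -> `model.json`, `training_log.csv`}
#'   \item{evaluate}{test-set movement / sub-action / position accuracy ->
#'     `evaluation.json`}
#'   \item{assess}{movement scores and group comparison ->
#'     `assessment.csv`, `assessment.json`}
#'   \item{all}{all of the above in order}
#' }
#' Every stage writes a JSON manifest recording the config hash and seed;
#' rerunning with an identical config and seed reproduces the artifacts.
#'
#' @param command One of simulate, preprocess, graphs, train, evaluate,
#'   assess, all.
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, the primary artifact of the stage (for `evaluate` /
#'   `assess`, the computed result list).
#' @export
run_command <- function(command = c("simulate", "preprocess", "graphs",
                                    "train", "evaluate", "assess", "all"),
                        config = pipeline_config(), verbose = TRUE) {
  command <- match.arg(command)
  dir.create(config$run_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  if (command == "all") {
    for (st in c("simulate", "preprocess", "graphs", "train", "evaluate", "assess"))
      out <- run_command(st, config, verbose)
    return(invisible(out))
  }
  t0 <- Sys.time()
  out <- switch(command,
    simulate = {
      sc <- config$simulate
      groups <- sc$groups
      if (length(sc$patient_subjects))
        groups <- ifelse(sc$subjects %in% sc$patient_subjects, "patient", "healthy")
      profile <- list(healthy = generator_profile(), patient = patient_profile())
      trials <- generate_dataset(sc$n_per_class, sc$subjects, groups,
                                 profile, seed = config$seed)
      p <- file.path(config$run_dir, "dataset")
      write_dataset(trials, p)
      stage_manifest(config, "simulate", list(), list(dataset = p))
      p
    },
    preprocess = {
      ds <- require_artifact(file.path(config$run_dir, "dataset"), "simulate")
      trials <- read_dataset(ds)
      pc <- config$preprocess
      split <- split_train_test(trials, config$split$ratio, seed = config$seed)
      split_table <- data.frame(
        trial_id = c(vapply(split$train, `[[`, character(1), "trial_id"),
                     vapply(split$test, `[[`, character(1), "trial_id")),
        part = rep(c("train", "test"), c(length(split$train), length(split$test))))
      segments <- unlist(lapply(trials, preprocess_trial,
                                eeg_band = pc$eeg_band, emg_band = pc$emg_band,
                                n_segments = pc$n_segments),
                         recursive = FALSE)
      p <- file.path(config$run_dir, "segments")
      write_segments(segments, p, split_table)
      stage_manifest(config, "preprocess", list(dataset = ds), list(segments = p))
      p
    },
    graphs = {
      sp <- require_artifact(file.path(config$run_dir, "segments"), "preprocess")
      split <- utils::read.table(file.path(sp, "split.tsv"), sep = "\t",
                                 header = TRUE, colClasses = "character")
      segments <- read_segments(sp)
      gc <- config$graph
      ocfg <- ordinal_config(gc$n, gc$tau)
      graphs <- build_graphs(segments, ordinal_cfg = ocfg, q = gc$q,
                             progress = verbose)
      part <- split$part[match(vapply(graphs, `[[`, character(1), "trial_id"),
                               split$trial_id)]
      out_train <- file.path(config$run_dir, "graphs_train")
      out_test <- file.path(config$run_dir, "graphs_test")
      write_graphs(graphs[part == "train"], out_train)
      write_graphs(graphs[part == "test"], out_test)
      stage_manifest(config, "graphs", list(segments = sp),
                     list(train = out_train, test = out_test))
      out_train
    },
    train = {
      gp <- require_artifact(file.path(config$run_dir, "graphs_train"), "graphs")
      graphs <- read_graphs(gp)
      tc <- config$train
      cfg <- gin_config(K = tc$K, hidden = tc$hidden, epochs = tc$epochs,
                        batch_size = tc$batch_size,
                        learning_rate = tc$learning_rate,
                        movement_loss_weight = tc$movement_loss_weight,
                        n_positions = config$preprocess$n_segments,
                        seed = config$seed)
      model <- train_gin(graphs, cfg)
      mp <- file.path(config$run_dir, "model.json")
      save_gin(model, mp)
      utils::write.csv(model$history,
                       file.path(config$run_dir, "training_log.csv"),
                       row.names = FALSE)
      stage_manifest(config, "train", list(graphs = gp), list(model = mp))
      mp
    },
    evaluate = {
      mp <- require_artifact(file.path(config$run_dir, "model.json"), "train")
      gp <- require_artifact(file.path(config$run_dir, "graphs_test"), "graphs")
      model <- load_gin(mp)
      graphs <- read_graphs(gp)
      metrics <- evaluate_graphs(model, graphs)
      jsonlite::write_json(metrics, file.path(config$run_dir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA)
      stage_manifest(config, "evaluate", list(model = mp, graphs = gp),
                     list(evaluation = file.path(config$run_dir, "evaluation.json")))
      metrics
    },
    assess = {
      mp <- require_artifact(file.path(config$run_dir, "model.json"), "train")
      gp <- require_artifact(file.path(config$run_dir, "graphs_test"), "graphs")
      model <- load_gin(mp)
      graphs <- read_graphs(gp)
      report <- assess_movements(sequences_by_trial(model, graphs))
      write_assessment(report, file.path(config$run_dir, "assessment.csv"),
                       file.path(config$run_dir, "assessment.json"))
      stage_manifest(config, "assess", list(model = mp, graphs = gp),
                     list(assessment = file.path(config$run_dir, "assessment.csv")))
      report
    })
  say("stage %s done in %.1f s", command,
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(out)
}

#' Evaluate a model on labeled graphs
#'
#' The three evaluation quantities of the pipeline: trial-level movement
#' accuracy after the time-based ensemble, per-segment sub-action accuracy
#' (12-way), and per-segment position accuracy (position correct given the
#' segment, regardless of movement).
#'
#' @param model A trained `gin_model`.
#' @param graphs Labeled `channel_graph` list covering whole trials.
#' @return List with `movement_accuracy`, `subaction_accuracy`,
#'   `position_accuracy`, `n_trials`, `n_segments`.
#' @export
evaluate_graphs <- function(model, graphs) {
  codes <- predict_classes(model, graphs)
  truth <- vapply(graphs, `[[`, integer(1), "subaction_class")
  n_pos <- model$config$n_positions
  seqs <- sequences_by_trial(model, graphs)
  correct <- vapply(seqs, function(M)
    classify_movement(M, n_seg = nrow(M))$movement == attr(M, "true_movement"),
    logical(1))
  list(movement_accuracy = mean(correct),
       subaction_accuracy = mean(codes == truth),
       position_accuracy = mean(codes %% n_pos == truth %% n_pos),
       n_trials = length(seqs), n_segments = length(graphs))
}

#' Predicted sequences grouped by trial
#'
#' @param model A trained `gin_model`.
#' @param graphs Labeled graphs; each trial must contribute exactly one
#'   graph per position.
#' @return List of `prediction_sequence` objects, one per trial.
#' @export
sequences_by_trial <- function(model, graphs) {
  ids <- vapply(graphs, `[[`, character(1), "trial_id")
  lapply(split(seq_along(graphs), ids), function(ii) {
    ord <- ii[order(vapply(graphs[ii], `[[`, integer(1), "position"))]
    predict_sequence(model, graphs[ord])
  })
}
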