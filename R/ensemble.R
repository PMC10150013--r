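#' Sub-action label similarity
#'
#' Similarity between two `(movement, position)` sub-action labels: 0 when
#' the movements differ, otherwise `1 - |pos_a - pos_b| / n_seg`. Symmetric
#' and in `[0, 1]`.
#'
#' @param a,b Sub-action labels: lists or data-frame rows with `movement`
#'   and `position`.
#' @param n_seg Segments per trial (default 6).
#' @return Scalar in `[0, 1]`.
#' @export
similarity <- function(a, b, n_seg = 6L) {
  pa <- as.integer(a$position)
  pb <- as.integer(b$position)
  if (pa >= n_seg || pb >= n_seg || pa < 0L || pb < 0L)
    stop(sprintf("positions must be in 0..%d", n_seg - 1L))
  if (a$movement != b$movement) return(0)
  1 - abs(pa - pb) / n_seg
}

label_seq <- function(movement, positions) {
  data.frame(movement = movement, position = as.integer(positions))
}

#' Canonical sub-action sequence of a movement
#'
#' The in-order ground-truth sequence `(m, 0), (m, 1), ..., (m, n_seg - 1)`
#' a correctly executed movement should produce.
#'
#' @param movement `"push"` or `"pull"`.
#' @param n_seg Segments per trial.
#' @return Data frame with `movement`, `position` columns.
#' @export
canonical_sequence <- function(movement, n_seg = 6L) {
  movement <- match.arg(movement, movement_levels)
  label_seq(movement, seq_len(n_seg) - 1L)
}

#' Movement quality score of a predicted sequence
#'
#' Mean similarity between the ground-truth sequence `G` and the predicted
#' sequence `M`, position by position: 1 for a perfect prediction, 0 when
#' every predicted segment belongs to the other movement. Reported on a
#' 0-100 scale as `scaled = round(100 * value)`.
#'
#' @param G,M Label sequences (data frames with `movement`, `position`) of
#'   equal length.
#' @param n_seg Segments per trial (defaults to `nrow(G)`).
#' @return A `movement_score`: list with `value` in `[0, 1]` and integer
#'   `scaled`.
#' @export
movement_score <- function(G, M, n_seg = nrow(G)) {
  if (nrow(G) != nrow(M)) stop("sequence length mismatch")
  sims <- vapply(seq_len(nrow(G)), function(i)
    similarity(G[i, ], M[i, ], n_seg), numeric(1))
  value <- mean(sims)
  structure(list(value = value, scaled = as.integer(round(100 * value))),
            class = "movement_score")
}

#' @export
print.movement_score <- function(x, ...) {
  cat(sprintf("<movement_score> %.4f (%d/100)\n", x$value, x$scaled))
  invisible(x)
}

#' Classify a whole movement from its predicted sub-action sequence
#'
#' The time-based ensemble: scores the predicted sequence against the
#' canonical sequence of every candidate movement and returns the movement
#' with the highest score. Ties are broken by the fixed movement order
#' (push before pull) and flagged in the result.
#'
#' @param M Predicted sequence (data frame with `movement`, `position`),
#'   e.g. a [predict_sequence()] result.
#' @param movements Candidate movements (default both).
#' @param n_seg Segments per trial.
#' @return List with `movement`, `score` (a `movement_score`), `tie`
#'   (logical), and the per-candidate `scores` vector.
#' @export
classify_movement <- function(M, movements = movement_levels, n_seg = nrow(M)) {
  if (length(movements) == 0L) stop("empty candidate movement set")
  scores <- vapply(movements, function(m)
    movement_score(canonical_sequence(m, n_seg), M, n_seg)$value, numeric(1))
  best <- which.max(scores)  # first max: fixed-order tie-break
  tie <- sum(scores == scores[best]) > 1L
  best_val <- unname(scores[best])
  list(movement = movements[best],
       score = structure(list(value = best_val,
                              scaled = as.integer(round(100 * best_val))),
                         class = "movement_score"),
       tie = tie, scores = scores)
}

#' Categorize per-segment predictions as close / far / wrong
#'
#' Each predicted segment falls in exactly one category: `wrong` if its
#' movement differs from the label's, `close` if the movement matches and
#' the position distance is at most `close_max` (default 3 segments), `far`
#' if the movement matches but the distance exceeds it. Proportions sum
#' to 1.
#'
#' @param G,M Label sequences of equal length.
#' @param close_max Largest position distance still counted close.
#' @return Named numeric vector `c(close, far, wrong)` of proportions.
#' @export
categorize_predictions <- function(G, M, close_max = 3L) {
  if (nrow(G) != nrow(M)) stop("sequence length mismatch")
  wrong <- G$movement != M$movement
  dist <- abs(as.integer(G$position) - as.integer(M$position))
  close <- !wrong & dist <= close_max
  far <- !wrong & dist > close_max
  c(close = mean(close), far = mean(far), wrong = mean(wrong))
}

#' Compare movement scores between two groups
#'
#' Two-sided independent-samples t-test on per-trial movement scores
#' (pooled-variance Student test by default, Welch optionally).
#'
#' @param scores_a,scores_b Numeric score vectors, each of length >= 2.
#' @param welch Use the Welch (unequal-variance) test (default FALSE).
#' @return List with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(scores_a, scores_b, welch = FALSE) {
  if (length(scores_a) < 2L || length(scores_b) < 2L)
    stop("each group needs >= 2 scores")
  if (stats::var(c(scores_a - mean(scores_a), scores_b - mean(scores_b))) == 0)
    stop("degenerate variance: all scores identical within groups")
  tt <- stats::t.test(scores_a, scores_b, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_a = mean(scores_a), mean_b = mean(scores_b))
}

#' Score and assess a set of predicted trials
#'
#' Applies the time-based ensemble to every trial's predicted sequence:
#' classifies the movement, scores it against the true movement's canonical
#' sequence, and categorizes the segments. Aggregates per subject and, when
#' both groups are present, adds the healthy-vs-patient group comparison.
#'
#' @param sequences List of [predict_sequence()] results (each carries its
#'   true movement and metadata as attributes).
#' @param welch Passed to [compare_groups()].
#' @return An `assessment_report`: list with `trials` (per-trial data
#'   frame: subject, group, true/predicted movement, score, close/far/wrong),
#'   `subjects` (per-subject means, score sd, category proportions), and
#'   `group_test` (t, p; NULL with fewer than two groups).
#' @export
assess_movements <- function(sequences, welch = FALSE) {
  rows <- lapply(sequences, function(M) {
    true_mv <- attr(M, "true_movement")
    n_seg <- nrow(M)
    G <- canonical_sequence(true_mv, n_seg)
    cls <- classify_movement(M, n_seg = n_seg)
    sc <- movement_score(G, M, n_seg)
    cats <- categorize_predictions(G, M)
    data.frame(trial_id = attr(M, "trial_id"), subject_id = attr(M, "subject_id"),
               group = attr(M, "group"), movement = true_mv,
               predicted = cls$movement, correct = cls$movement == true_mv,
               score = sc$value, score_scaled = sc$scaled,
               close = cats["close"], far = cats["far"], wrong = cats["wrong"],
               row.names = NULL)
  })
  trials <- do.call(rbind, rows)
  subjects <- do.call(rbind, lapply(split(trials, trials$subject_id), function(d)
    data.frame(subject_id = d$subject_id[1L], group = d$group[1L],
               n_trials = nrow(d), accuracy = mean(d$correct),
               mean_score = mean(d$score), sd_score = stats::sd(d$score),
               close = mean(d$close), far = mean(d$far), wrong = mean(d$wrong),
               row.names = NULL)))
  group_test <- NULL
  if (length(unique(trials$group)) == 2L) {
    healthy <- trials$score[trials$group == "healthy"]
    patient <- trials$score[trials$group == "patient"]
    group_test <- tryCatch(compare_groups(patient, healthy, welch),
                           error = function(e) NULL)
  }
  structure(list(trials = trials, subjects = subjects, group_test = group_test),
            class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("<assessment_report> %d trials, %d subject(s)\n",
              nrow(x$trials), nrow(x$subjects)))
  cat(sprintf("  movement accuracy %.3f | mean score %.3f\n",
              mean(x$trials$correct), mean(x$trials$score)))
  if (!is.null(x$group_test))
    cat(sprintf("  patient vs healthy: t = %.3f, p = %.3g\n",
                x$group_test$t, x$group_test$p))
  invisible(x)
}

#' Write an assessment report (CSV + JSON summary)
#'
#' @param report An `assessment_report`.
#' @param csv_path Per-subject CSV path.
#' @param json_path Optional JSON summary path (group test and overall
#'   means).
#' @return `csv_path`, invisibly.
#' @export
write_assessment <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(report$subjects, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    summary <- list(n_trials = nrow(report$trials),
                    movement_accuracy = mean(report$trials$correct),
                    mean_score = mean(report$trials$score))
    if (!is.null(report$group_test)) summary$group_test <- report$group_test
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
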