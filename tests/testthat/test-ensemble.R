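lab <- function(m, p) list(movement = m, position = p)

test_that("similarity follows the distance rule within a movement and is zero across", {
  expect_equal(similarity(lab("push", 2), lab("push", 2)), 1)
  expect_equal(similarity(lab("push", 2), lab("pull", 2)), 0)
  expect_equal(similarity(lab("push", 1), lab("push", 4), n_seg = 6), 0.5)
  # symmetric and bounded
  set.seed(1)
  for (i in 1:20) {
    a <- lab(sample(c("push", "pull"), 1), sample(0:5, 1))
    b <- lab(sample(c("push", "pull"), 1), sample(0:5, 1))
    s <- similarity(a, b)
    expect_identical(s, similarity(b, a))
    expect_true(s >= 0 && s <= 1)
  }
  expect_error(similarity(lab("push", 6), lab("push", 1)), "positions")
})

test_that("movement scores average per-segment similarities", {
  G <- canonical_sequence("push")
  expect_equal(movement_score(G, G)$value, 1)
  all_wrong <- data.frame(movement = "pull", position = 0:5)
  expect_equal(movement_score(G, all_wrong)$value, 0)
  # worked sequence: (1 + 1 + 5/6 + 1 + 0 + 1) / 6 = 29/36
  M <- data.frame(movement = c("push", "push", "push", "push", "pull", "push"),
                  position = c(0L, 1L, 1L, 3L, 2L, 5L))
  sc <- movement_score(G, M)
  expect_equal(sc$value, 29 / 36)
  expect_identical(sc$scaled, 81L)  # round(100 * 29/36)
  expect_error(movement_score(G, M[1:4, ]), "length mismatch")
  # monotone: correcting one segment never lowers the score
  M2 <- M; M2$movement[5] <- "push"; M2$position[5] <- 4L
  expect_gt(movement_score(G, M2)$value, sc$value)
  # symmetric in its sequence arguments
  expect_equal(movement_score(M, G)$value, sc$value)
})

test_that("movement classification picks the best-scoring canonical sequence", {
  M_pull <- canonical_sequence("pull")
  res <- classify_movement(M_pull)
  expect_identical(res$movement, "pull")
  expect_equal(res$score$value, 1)
  expect_false(res$tie)
  # 5 push segments at correct positions, 1 pull: push wins
  M <- data.frame(movement = c("push", "push", "push", "push", "pull", "push"),
                  position = c(0L, 1L, 2L, 3L, 4L, 5L))
  res2 <- classify_movement(M)
  expect_identical(res2$movement, "push")
  expect_equal(unname(res2$scores["push"]),
               movement_score(canonical_sequence("push"), M)$value)
  # canonical sequences of each movement classify as themselves with score 1
  for (mv in c("push", "pull")) {
    r <- classify_movement(canonical_sequence(mv))
    expect_identical(r$movement, mv)
    expect_equal(r$score$value, 1)
  }
  expect_error(classify_movement(M, movements = character(0)), "empty")
})

test_that("close/far/wrong categories partition the segments", {
  G <- canonical_sequence("push")
  expect_equal(categorize_predictions(G, G),
               c(close = 1, far = 0, wrong = 0))
  all_wrong <- data.frame(movement = "pull", position = 0:5)
  expect_equal(categorize_predictions(G, all_wrong),
               c(close = 0, far = 0, wrong = 1))
  # worked case: distances 0,2,3 close; two pull wrong; |0-4| = 4 far
  M <- data.frame(movement = c("push", "push", "push", "pull", "push", "pull"),
                  position = c(0L, 3L, 5L, 3L, 0L, 5L))
  cats <- categorize_predictions(G, M)
  expect_equal(unname(cats), c(3, 1, 2) / 6)
  expect_equal(sum(cats), 1)
  expect_error(categorize_predictions(G, M[1:3, ]), "length mismatch")
})

test_that("group comparison matches the closed-form pooled t-test", {
  a <- c(1, 1, 1, 0.9)
  b <- c(0.2, 0.3, 0.25, 0.35)
  res <- compare_groups(a, b)
  # independent textbook computation of the pooled-variance statistic
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_hand <- 2 * pt(-abs(t_hand), df = length(a) + length(b) - 2)
  expect_equal(res$t, t_hand, tolerance = 1e-6)
  expect_equal(res$p, p_hand, tolerance = 1e-6)
  expect_identical(res$df, 6)
  # antisymmetry
  swapped <- compare_groups(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  # identical groups: t = 0, p = 1
  same <- compare_groups(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # Welch variant runs and degenerate input is refused
  expect_type(compare_groups(a, b, welch = TRUE)$t, "double")
  expect_error(compare_groups(c(1, 1), c(1, 1)), "degenerate")
  expect_error(compare_groups(1, c(1, 2)), ">= 2 scores")
})

test_that("assessment reports aggregate trials, subjects and the group contrast", {
  mk_seq <- function(mv, pred_mv, subject, group, id) {
    structure(data.frame(movement = pred_mv, position = 0:5),
              true_movement = mv, trial_id = id, subject_id = subject,
              group = group, class = c("prediction_sequence", "data.frame"))
  }
  seqs <- c(
    lapply(1:4, function(i) mk_seq("push", "push", "h1", "healthy",
                                   paste0("h", i))),
    lapply(1:4, function(i) mk_seq("push", c("pull", "push")[1 + i %% 2],
                                   "p1", "patient", paste0("p", i))))
  rep <- assess_movements(seqs)
  expect_identical(nrow(rep$trials), 8L)
  expect_identical(nrow(rep$subjects), 2L)
  expect_equal(rep$subjects$mean_score[rep$subjects$subject_id == "h1"], 1)
  expect_true(all(abs(rep$trials$close + rep$trials$far + rep$trials$wrong - 1)
                  < 1e-12))
  expect_s3_class(rep, "assessment_report")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_assessment(rep, csv, js)
  expect_identical(nrow(read.csv(csv)), 2L)
  expect_true(jsonlite::read_json(js)$movement_accuracy <= 1)
})
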