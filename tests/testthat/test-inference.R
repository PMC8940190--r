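test_that("majority vote picks the most frequent frame argmax", {
  # 60 frames favor class 3, 40 favor class 2
  p <- rbind(matrix(rep(c(0.1, 0.2, 0.6, 0.1), 60), 60, 4, byrow = TRUE),
             matrix(rep(c(0.1, 0.6, 0.2, 0.1), 40), 40, 4, byrow = TRUE))
  v <- majority_vote(p)
  expect_identical(v$label, 3L)
  expect_identical(v$vote_counts, c(0L, 40L, 60L, 0L))
})

test_that("vote ties fall back to mean posterior, then lowest index", {
  p <- rbind(c(0.9, 0.1), c(0.2, 0.8))  # one vote each; class 1 mean higher
  expect_identical(majority_vote(p)$label, 1L)
  p2 <- rbind(c(0.3, 0.7), c(0.9, 0.1))  # class 1 mean 0.6 vs 0.4
  expect_identical(majority_vote(p2)$label, 1L)
  p3 <- rbind(c(0.6, 0.4), c(0.4, 0.6))  # fully symmetric -> lowest index
  expect_identical(majority_vote(p3)$label, 1L)
  expect_error(majority_vote(matrix(0, 0, 3)), "at least one frame")
})

test_that("unanimous frames give full vote counts", {
  p <- matrix(rep(c(0.05, 0.05, 0.85, 0.05), 25), 25, 4, byrow = TRUE)
  v <- majority_vote(p)
  expect_identical(v$label, 3L)
  expect_identical(v$vote_counts[3], 25L)
})

test_that("majority vote is invariant to frame order", {
  set.seed(60)
  p <- matrix(runif(50 * 4), 50, 4)
  p <- p / rowSums(p)
  v1 <- majority_vote(p)
  v2 <- majority_vote(p[sample(50), ])
  expect_identical(v1$label, v2$label)
  expect_identical(v1$vote_counts, v2$vote_counts)
})

test_that("confusion matrix matches a brute-force tally", {
  set.seed(61)
  truths <- sample(1:4, 200, replace = TRUE)
  preds <- sample(1:4, 200, replace = TRUE)
  cm <- confusion_matrix(preds, truths, 4)
  brute <- matrix(0L, 4, 4)
  for (i in 1:200) brute[truths[i], preds[i]] <- brute[truths[i], preds[i]] + 1L
  expect_identical(cm, brute)
  expect_identical(sum(cm), 200L)
  expect_identical(confusion_matrix(rep(1, 8), rep(1:4, 2), 4)[, 1],
                   c(2L, 2L, 2L, 2L))
  expect_error(confusion_matrix(c(1, 5), c(1, 2), 4), "out of range")
})

test_that("metrics match the worked two-class example exactly", {
  cm <- rbind(c(8, 2), c(4, 6))
  m <- compute_metrics(cm)
  expect_equal(m$accuracy, 70)
  expect_equal(unname(m$sensitivity), c(80, 60))
  expect_equal(m$uar, 70)
  expect_identical(m$K, 2L)
})

test_that("metrics agree exactly with brute-force tallies on random matrices", {
  set.seed(62)
  for (i in 1:1000) {
    K <- sample(2:5, 1)
    n <- sample(20:60, 1)
    truths <- sample(K, n, replace = TRUE)
    # ensure every true class occurs
    truths[seq_len(K)] <- seq_len(K)
    preds <- sample(K, n, replace = TRUE)
    m <- compute_metrics(confusion_matrix(preds, truths, K))
    b <- brute_force_metrics(truths, preds, K)
    expect_identical(m$accuracy, b$accuracy)
    expect_identical(unname(m$sensitivity), b$sensitivity)
    expect_identical(m$uar, b$uar)
  }
})

test_that("permuting class indices permutes sensitivities, not accuracy or UAR", {
  set.seed(63)
  cm <- matrix(sample(0:20, 16, replace = TRUE), 4, 4) + diag(4)
  m <- compute_metrics(cm)
  perm <- c(3, 1, 4, 2)
  m2 <- compute_metrics(cm[perm, perm])
  expect_equal(unname(m2$sensitivity), unname(m$sensitivity)[perm])
  expect_equal(m2$accuracy, m$accuracy)
  expect_equal(m2$uar, m$uar)
})

test_that("UAR equals accuracy on class-balanced symmetric confusions", {
  cm <- matrix(2, 3, 3) + diag(10, 3)
  m <- compute_metrics(cm)
  expect_equal(m$uar, m$accuracy)
})

test_that("degenerate confusion matrices raise errors", {
  expect_error(compute_metrics(matrix(0, 2, 2)), "empty")
  expect_error(compute_metrics(rbind(c(5, 1), c(0, 0))), "undefined")
})

test_that("perfect prediction scores 100 everywhere", {
  m <- compute_metrics(diag(10L, 4))
  expect_equal(m$accuracy, 100)
  expect_equal(m$uar, 100)
  expect_true(all(m$sensitivity == 100))
})

test_that("the one-vs-rest macro accuracy differs from trace accuracy as expected", {
  cm <- rbind(c(8, 2), c(4, 6))
  # per-class binary accuracies both (8+6)/20 in the 2-class case
  expect_equal(compute_metrics(cm, accuracy = "ovr_macro")$accuracy, 70)
  cm3 <- diag(5L, 3); cm3[1, 2] <- 5L
  expect_gt(compute_metrics(cm3, accuracy = "ovr_macro")$accuracy,
            compute_metrics(cm3)$accuracy)
})

test_that("end-to-end prediction rejects unvoiced input and is deterministic", {
  toy <- toy_feature_set(n_per_class = 4, n_frames = 10, K = 2)
  fit <- voice_classifier(toy$features, toy$labels, kind = "dnn", epochs = 5,
                          seed = 3)
  silent <- structure(list(samples = numeric(44100), fs = 44100,
                           label = "fd", speaker_id = "s", mode = "test"),
                      class = "waveform")
  expect_error(predict_utterance(fit, silent), "unvoiced input")
  set.seed(64)
  w <- synth_utterance(utterance_spec("sustained_vowel", duration_s = 1),
                       disorder_profiles()$fd)
  p1 <- predict_utterance(fit$model, w)
  p2 <- predict_utterance(fit$model, w)
  expect_identical(p1, p2)
})

test_that("a pipeline trained on separable profiles recovers the class", {
  profs <- scale_profile_separation(disorder_profiles(), 2)
  counts <- c(fd = 6L, neoplasm = 6L, phonotrauma = 6L, vocal_palsy = 6L)
  corp <- generate_corpus(corpus_config(counts, seed = 9), profs,
                          utterance_spec("sustained_vowel", duration_s = 1.5))
  cf <- corpus_features(corp)
  fit <- voice_classifier(cf$features, cf$labels, kind = "dnn", epochs = 15,
                          seed = 9)
  target <- pathovoice:::with_seed(123,
    synth_utterance(utterance_spec("sustained_vowel", duration_s = 1.5),
                    profs$phonotrauma))
  pred <- predict_utterance(fit, target)
  expect_identical(fit$classes[pred$label], "phonotrauma")
})
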