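truth_stub_fit <- function(features, labels, kind, speakers) {
  structure(list(), class = "truth_stub")
}

test_that("the comparison harness wiring gives a perfect score to a truth stub", {
  counts <- c(fd = 4L, neoplasm = 4L, phonotrauma = 4L, vocal_palsy = 4L)
  tab <- run_condition_comparison(counts,
                                  model_kinds = c("bilstm", "gru", "lstm",
                                                  "dnn", "rf"),
                                  seed = 2, fit_fun = truth_stub_fit)
  expect_identical(nrow(tab), 10L)
  expect_identical(sort(unique(tab$model_kind)),
                   sort(c("bilstm", "gru", "lstm", "dnn", "rf")))
  expect_identical(sort(unique(tab$condition)), c("continuous", "vowel"))
  expect_true(all(tab$accuracy == 100))
  expect_true(all(tab$uar == 100))
})

test_that("mismatched class sets between counts and profiles are rejected", {
  expect_error(run_condition_comparison(c(unknown = 4L), seed = 1),
               "class sets")
})

test_that("the pipeline harness is deterministic under fixed seeds", {
  counts <- c(fd = 4L, phonotrauma = 4L)
  corp <- generate_corpus(
    corpus_config(counts, seed = 5),
    spec_template = utterance_spec("sustained_vowel", duration_s = 1))
  cf <- corpus_features(corp)
  r1 <- run_pipeline(cf, kind = "dnn", epochs = 3, seed = 4)
  r2 <- run_pipeline(cf, kind = "dnn", epochs = 3, seed = 4)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("sentence selection ranks script variants and flags the best", {
  counts <- c(fd = 6L, phonotrauma = 6L)
  tab <- run_sentence_selection(script_ids = c(1, 2, 5), class_counts = counts,
                                seed = 3, epochs = 4, kind = "dnn")
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$rank, 1:3)
  expect_true(all(diff(tab$uar) <= 0))
  expect_setequal(tab$script_id, c(1, 2, 5))
  expect_error(run_sentence_selection(script_ids = 2, class_counts = counts),
               "at least two")
})

test_that("a variant with doubled inter-class separation ranks first", {
  counts <- c(fd = 8L, neoplasm = 8L, phonotrauma = 8L, vocal_palsy = 8L)
  profs <- list(scale_profile_separation(disorder_profiles(), 0.4),
                scale_profile_separation(disorder_profiles(), 2))
  tab <- run_sentence_selection(script_ids = c(3, 4), class_counts = counts,
                                profiles = profs, seed = 6, epochs = 8)
  expect_identical(tab$script_id[tab$rank == 1], 4)
})

test_that("increasing class separation never lowers median test UAR", {
  counts <- c(fd = 6L, neoplasm = 6L, phonotrauma = 6L, vocal_palsy = 6L)
  med_uar <- vapply(c(0.25, 1, 2.5), function(sep) {
    profs <- scale_profile_separation(disorder_profiles(), sep)
    uars <- vapply(1:3, function(s) {
      corp <- generate_corpus(corpus_config(counts, seed = 100 + s), profs,
                              utterance_spec("continuous", script_id = 2))
      run_pipeline(corpus_features(corp), kind = "bilstm", epochs = 8,
                   seed = 200 + s)$metrics$uar
    }, numeric(1))
    median(uars)
  }, numeric(1))
  expect_true(all(diff(med_uar) >= 0))
})

test_that("PCA projection matches an SVD oracle and orders its axes", {
  set.seed(71)
  X <- matrix(rnorm(20 * 50), 20, 50)
  labs <- rep(c("a", "b"), 10)
  pr <- pca_project(X, labs)
  expect_identical(dim(pr$coords), c(20L, 2L))
  expect_gte(pr$explained_variance[1], pr$explained_variance[2])
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  oracle <- sv$u[, 1:2] %*% diag(sv$d[1:2])
  for (j in 1:2) {
    expect_true(max(abs(pr$coords[, j] - oracle[, j])) < 1e-8 ||
                  max(abs(pr$coords[, j] + oracle[, j])) < 1e-8)
  }
  expect_error(pca_project(X[1:2, ], labs[1:2]), "at least 3")
})

test_that("pooled hidden features of a trained model separate classes in PCA", {
  counts <- c(fd = 8L, neoplasm = 8L, phonotrauma = 8L, vocal_palsy = 8L)
  profs <- scale_profile_separation(disorder_profiles(), 2)
  corp <- generate_corpus(corpus_config(counts, seed = 31), profs,
                          utterance_spec("continuous", script_id = 2))
  cf <- corpus_features(corp)
  fit <- voice_classifier(cf$features, cf$labels, kind = "bilstm",
                          epochs = 10, seed = 31)
  pooled <- t(vapply(cf$features, function(f)
    extract_hidden_features(fit, f)$pooled, numeric(50)))
  pr <- pca_project(pooled, cf$labels)
  sil <- cluster::silhouette(as.integer(pr$labels), dist(pr$coords))
  expect_gte(mean(sil[, "sil_width"]), 0.3)
})
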