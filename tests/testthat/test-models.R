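test_that("the DNN has the expected parameter count and architecture", {
  set.seed(50)
  m <- build_model(model_config("dnn", n_classes = 4), input_dim = 26)
  # 26*200+200 + 2*(200*200+200) + 200*4+4
  expect_identical(pathovoice:::n_params(m), 86604L)
  expect_identical(dim(m$params$W1), c(26L, 200L))
  expect_identical(dim(m$params$Wo), c(200L, 4L))
})

test_that("recurrent architectures follow the configured geometry", {
  set.seed(51)
  b <- build_model(model_config("bilstm", n_classes = 4), input_dim = 26)
  # directional outputs are summed, so the head consumes width 50
  expect_identical(dim(b$params$Wo), c(50L, 4L))
  expect_identical(dim(b$params$l1$fwd$Wx), c(26L, 200L))
  expect_identical(dim(b$params$l2$fwd$Wx), c(50L, 200L))
  g <- build_model(model_config("gru", n_classes = 3), input_dim = 26)
  expect_identical(dim(g$params$l1$Wx), c(26L, 150L))
  expect_identical(model_config("rf")$n_trees, 26L)
  expect_error(model_config("cnn"), "arg")
})

test_that("zero-weight models emit uniform posteriors and rows always sum to 1", {
  set.seed(52)
  for (kind in c("dnn", "lstm", "bilstm", "gru")) {
    m <- build_model(model_config(kind, n_classes = 4, cells = 8,
                                  layer_sizes = c(10, 10, 10)), input_dim = 26)
    m$params <- rapply(m$params, function(x) x * 0, how = "replace")
    p <- forward_frames(m, matrix(rnorm(5 * 26), 5, 26))
    expect_equal(unname(p), matrix(0.25, 5, 4), tolerance = 1e-12)
  }
  m <- build_model(model_config("lstm", n_classes = 4, cells = 8), 26)
  p <- forward_frames(m, matrix(rnorm(40 * 26), 40, 26))
  expect_equal(rowSums(p), rep(1, 40), tolerance = 1e-9)
  expect_error(forward_frames(m, matrix(0, 3, 10)), "dimension")
})

test_that("bilstm forward pass matches the gate-equation oracle", {
  set.seed(53)
  for (trial in 1:10) {
    T_ <- sample(1:5, 1)
    H <- sample(1:3, 1)
    D <- sample(2:4, 1)
    m <- build_model(model_config("bilstm", n_classes = 3, cells = H,
                                  n_layers = 2, dropout = 0), input_dim = D)
    X <- matrix(rnorm(T_ * D), T_, D)
    expect_equal(unname(forward_frames(m, X)),
                 unname(bilstm_oracle(m$params, X, 2)), tolerance = 1e-6)
  }
})

test_that("reversing input and swapping directional weights reverses bilstm output", {
  set.seed(54)
  m <- build_model(model_config("bilstm", n_classes = 3, cells = 4,
                                n_layers = 2, dropout = 0), input_dim = 6)
  X <- matrix(rnorm(7 * 6), 7, 6)
  p1 <- forward_frames(m, X)
  m2 <- m
  for (l in c("l1", "l2")) {
    tmp <- m2$params[[l]]$fwd
    m2$params[[l]]$fwd <- m2$params[[l]]$bwd
    m2$params[[l]]$bwd <- tmp
  }
  p2 <- forward_frames(m2, X[7:1, , drop = FALSE])
  expect_equal(p1, p2[7:1, , drop = FALSE], tolerance = 1e-10)
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(55)
  reorder_tree <- function(template, tree) {
    if (is.list(template)) {
      out <- lapply(names(template), function(nm)
        reorder_tree(template[[nm]], tree[[nm]]))
      names(out) <- names(template)
      out
    } else tree
  }
  for (kind in c("dnn", "lstm", "gru", "bilstm")) {
    cfg <- model_config(kind, n_classes = 3, cells = 4, n_layers = 2,
                        dropout = 0, layer_sizes = c(5, 5, 5))
    model <- build_model(cfg, input_dim = 6)
    X <- matrix(rnorm(5 * 6), 5, 6)
    y <- c(1, 2, 3, 1, 2)
    loss_fn <- function(m) {
      p <- forward_frames(m, X)
      -sum(log(p[cbind(1:5, y)])) / 5
    }
    cache <- if (kind == "dnn") pathovoice:::fwd_dnn(model$params, X, 3)
             else pathovoice:::fwd_recurrent(model, X, train = FALSE)
    Y <- matrix(0, 5, 3); Y[cbind(1:5, y)] <- 1
    dl <- (cache$probs - Y) / 5
    g <- if (kind == "dnn") pathovoice:::bwd_dnn(model$params, cache, dl, 3)
         else pathovoice:::bwd_recurrent(model, cache, dl)
    flat_g <- rapply(reorder_tree(model$params, g), identity, how = "unlist")
    flat_p <- rapply(model$params, identity, how = "unlist")
    rebuild <- function(fp) {
      m2 <- model; pos <- 0
      m2$params <- rapply(model$params, function(a) {
        k <- length(a); out <- fp[(pos + 1):(pos + k)]; pos <<- pos + k
        if (is.matrix(a)) matrix(out, nrow(a), ncol(a)) else out
      }, how = "replace")
      m2
    }
    eps <- 1e-6
    l0 <- loss_fn(model)
    for (i in sample(length(flat_g), 15)) {
      up <- flat_p; up[i] <- up[i] + eps
      dn <- flat_p; dn[i] <- dn[i] - eps
      l_up <- loss_fn(rebuild(up)); l_dn <- loss_fn(rebuild(dn))
      # a perturbation across a ReLU kink leaves a first-order term in the
      # second difference; skip such leaves (smooth leaves give ~eps^2)
      if (abs(l_up + l_dn - 2 * l0) > 1e-9) next
      ng <- (l_up - l_dn) / (2 * eps)
      ok <- abs(ng - flat_g[i]) < 5e-6 ||
        abs(ng - flat_g[i]) / (abs(ng) + abs(flat_g[i])) < 1e-4
      expect_true(ok)
    }
  }
})

test_that("training separates well-separated synthetic classes", {
  toy <- toy_feature_set(n_per_class = 8, n_frames = 15, K = 3, sep = 2)
  fit <- voice_classifier(toy$features, toy$labels, kind = "dnn",
                          epochs = 30, seed = 1)
  p <- lapply(toy$features, function(f) forward_frames(fit, f))
  frame_preds <- unlist(lapply(p, max.col))
  frame_truth <- rep(as.integer(toy$labels),
                     each = nrow(toy$features[[1]]))
  expect_gte(mean(frame_preds == frame_truth), 0.99)
  expect_true(all(diff(fit$history[1:5]) <= 0))
})

test_that("training is deterministic under a fixed seed", {
  toy <- toy_feature_set(n_per_class = 4, n_frames = 8, K = 2)
  f1 <- voice_classifier(toy$features, toy$labels, kind = "gru", cells = 8,
                         epochs = 3, seed = 7)
  f2 <- voice_classifier(toy$features, toy$labels, kind = "gru", cells = 8,
                         epochs = 3, seed = 7)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("single-class training data is rejected and defaults are per kind", {
  toy <- toy_feature_set(n_per_class = 3, K = 2)
  one <- toy$labels == "class1"
  expect_error(voice_classifier(toy$features[one], toy$labels[one]),
               "single class")
  expect_identical(pathovoice:::default_lr("dnn"), 1e-3)
  expect_identical(pathovoice:::default_lr("gru"), 1e-3)
  expect_identical(pathovoice:::default_lr("lstm"), 5e-4)
  expect_identical(pathovoice:::default_lr("bilstm"), 5e-4)
})

test_that("random forest predictions are invariant to frame order", {
  toy <- toy_feature_set(n_per_class = 5, n_frames = 12, K = 3)
  fit <- voice_classifier(toy$features, toy$labels, kind = "rf", seed = 5)
  X <- toy$features[[1]]
  p1 <- forward_frames(fit, X)
  perm <- sample(nrow(X))
  p2 <- forward_frames(fit, X[perm, ])
  expect_equal(p1[perm, ], p2, tolerance = 1e-12)
  expect_identical(fit$model$rf$ntree, 26L)
})

test_that("hidden-feature extraction pools the last recurrent layer", {
  set.seed(56)
  m <- build_model(model_config("bilstm", n_classes = 4), input_dim = 26)
  X <- matrix(rnorm(9 * 26), 9, 26)
  hf <- extract_hidden_features(m, X)
  expect_identical(dim(hf$frame_features), c(9L, 50L))
  expect_identical(length(hf$pooled), 50L)
  one <- extract_hidden_features(m, X[1, , drop = FALSE])
  expect_equal(one$pooled, as.numeric(one$frame_features[1, ]))
  mz <- m
  mz$params <- rapply(mz$params, function(x) x * 0, how = "replace")
  expect_true(all(extract_hidden_features(mz, X)$frame_features == 0))
  d <- build_model(model_config("dnn"), 26)
  expect_error(extract_hidden_features(d, X), "recurrent")
})

test_that("cross-validation reports per-fold UAR", {
  toy <- toy_feature_set(n_per_class = 6, n_frames = 10, K = 2, sep = 2)
  fit <- voice_classifier(toy$features, toy$labels, kind = "dnn", epochs = 10,
                          seed = 2, cv_folds = 3)
  expect_identical(nrow(fit$cv), 3L)
  expect_true(all(fit$cv$uar >= 0 & fit$cv$uar <= 100, na.rm = TRUE))
})
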