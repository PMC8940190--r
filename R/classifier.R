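# Training: frame-level cross-entropy minimized with Adam over minibatches of
# utterances (variable-length sequences are processed one by one, so no
# padding ever enters the loss). The random forest is fitted on the pooled
# frames with bootstrap samples of the full training-frame count.

tree_add <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- tree_add(a[[nm]], b[[nm]])
    a
  } else a + b
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

adam_step <- function(params, grads, st, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^t)
      vh <- v / (1 - b2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, st$m, st$v)
  list(params = r$p, state = list(m = r$m, v = r$v))
}

default_lr <- function(kind) {
  switch(kind, dnn = 1e-3, gru = 1e-3, lstm = 5e-4, bilstm = 5e-4, rf = NA_real_)
}

#' Fit a frame-level voice-disorder classifier
#'
#' The central fitting function. Takes per-utterance MFCC+delta matrices and
#' utterance-level diagnosis labels (each frame inherits its utterance's
#' label), and trains one of five classifiers: `"dnn"` (three ReLU layers of
#' 200), `"lstm"`/`"gru"` (two recurrent layers of 50 cells, dropout 0.2),
#' `"bilstm"` (two blocks, each a forward and a backward 50-cell LSTM whose
#' outputs are summed), or `"rf"` (26-tree bootstrap forest on single
#' frames). Neural models minimize the frame-level cross-entropy with Adam
#' (learning rate 0.001 for DNN/GRU, 0.0005 for LSTM/BiLSTM). Training is
#' deterministic given `seed`.
#'
#' @param features list of frames x 26 MFCC matrices, one per utterance
#' @param labels factor (or character) of utterance diagnoses
#' @param kind classifier kind
#' @param learning_rate Adam step size; NULL picks the kind's default
#' @param epochs training epochs
#' @param batch_size minibatch size in utterances
#' @param seed RNG seed controlling initialization, shuffling and dropout
#' @param cv_folds if > 0, additionally run k-fold cross-validation inside
#'   the training data (speaker-disjoint when `speakers` is given) and
#'   report per-fold validation UAR
#' @param speakers optional speaker id per utterance, used to keep
#'   cross-validation folds speaker-disjoint
#' @param dropout,cells,n_layers,layer_sizes,n_trees architecture settings,
#'   see [model_config()]
#' @param verbose print per-epoch loss
#' @return an object of class `voice_classifier` with `print`, `summary`,
#'   `predict` and `plot` methods
#' @export
voice_classifier <- function(features, labels,
                             kind = c("bilstm", "lstm", "gru", "dnn", "rf"),
                             learning_rate = NULL, epochs = 30L,
                             batch_size = 16L, seed = 1L, cv_folds = 0L,
                             speakers = NULL, dropout = 0.2, cells = 50L,
                             n_layers = 2L, layer_sizes = c(200L, 200L, 200L),
                             n_trees = 26L, verbose = FALSE) {
  kind <- match.arg(kind)
  if (!is.list(features)) stopf("features must be a list of MFCC matrices")
  labels <- factor(labels)
  if (length(features) != length(labels))
    stopf("features and labels lengths differ")
  if (nlevels(labels) < 2L)
    stopf("training data contains a single class; at least two are required")
  K <- nlevels(labels)
  D <- ncol(features[[1]])
  cfg <- model_config(kind, n_classes = K, layer_sizes = layer_sizes,
                      cells = cells, n_layers = n_layers, dropout = dropout,
                      n_trees = n_trees)
  if (is.null(learning_rate)) learning_rate <- default_lr(kind)

  cv <- NULL
  if (cv_folds > 0L) {
    cv <- run_cv_folds(features, labels, kind, learning_rate, epochs,
                       batch_size, seed, cv_folds, speakers, cfg)
  }

  fit <- with_seed(seed, {
    if (kind == "rf") {
      X <- do.call(rbind, features)
      colnames(X) <- paste0("f", seq_len(D))
      y <- factor(rep(as.character(labels), vapply(features, nrow, 0L)),
                  levels = levels(labels))
      rf <- randomForest::randomForest(x = as.data.frame(X), y = y,
                                       ntree = cfg$n_trees)
      model <- build_model(cfg, D)
      model$rf <- rf
      model$rf_feature_names <- colnames(X)
      list(model = model, history = NULL)
    } else {
      model <- build_model(cfg, D)
      st <- list(m = tree_zero(model$params), v = tree_zero(model$params))
      y_idx <- as.integer(labels)
      n <- length(features)
      history <- numeric(epochs)
      t_step <- 0L
      for (ep in seq_len(epochs)) {
        ord <- sample(n)
        ep_loss <- 0; ep_frames <- 0L
        for (b0 in seq(1L, n, by = batch_size)) {
          batch <- ord[b0:min(b0 + batch_size - 1L, n)]
          total_frames <- sum(vapply(features[batch], nrow, 0L))
          grads <- NULL
          for (u in batch) {
            X <- features[[u]]
            T_ <- nrow(X)
            if (model$kind == "dnn") {
              cache <- fwd_dnn(model$params, X, length(cfg$layer_sizes))
            } else {
              cache <- fwd_recurrent(model, X, train = TRUE)
            }
            p <- cache$probs
            yy <- rep(y_idx[u], T_)
            ep_loss <- ep_loss + sum(-log(pmax(p[cbind(seq_len(T_), yy)], 1e-12)))
            Y <- matrix(0, T_, K); Y[cbind(seq_len(T_), yy)] <- 1
            dlogits <- (p - Y) / total_frames
            g <- if (model$kind == "dnn")
              bwd_dnn(model$params, cache, dlogits, length(cfg$layer_sizes))
            else bwd_recurrent(model, cache, dlogits)
            grads <- if (is.null(grads)) g else tree_add(grads, g)
          }
          t_step <- t_step + 1L
          upd <- adam_step(model$params, grads, st, learning_rate, t_step)
          model$params <- upd$params
          st <- upd$state
          ep_frames <- ep_frames + total_frames
        }
        history[ep] <- ep_loss / ep_frames
        if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
      }
      list(model = model, history = history)
    }
  })
  fit$model$classes <- levels(labels)
  structure(list(model = fit$model, kind = kind, classes = levels(labels),
                 history = fit$history, cv = cv,
                 config = list(learning_rate = learning_rate, epochs = epochs,
                               batch_size = batch_size, cfg = cfg),
                 seed = seed, n_train = length(features)),
            class = "voice_classifier")
}

run_cv_folds <- function(features, labels, kind, learning_rate, epochs,
                         batch_size, seed, cv_folds, speakers, cfg) {
  n <- length(features)
  groups <- if (is.null(speakers)) as.character(seq_len(n)) else as.character(speakers)
  fold_of <- with_seed(seed + 7919L, {
    g <- sample(unique(groups))
    f <- stats::setNames(rep_len(seq_len(cv_folds), length(g)), g)
    unname(f[groups])
  })
  res <- lapply(seq_len(cv_folds), function(k) {
    tr <- which(fold_of != k); va <- which(fold_of == k)
    if (!length(va) || nlevels(droplevels(labels[tr])) < 2L)
      return(data.frame(fold = k, uar = NA_real_))
    fit <- voice_classifier(features[tr], labels[tr], kind = kind,
                            learning_rate = learning_rate, epochs = epochs,
                            batch_size = batch_size, seed = seed + k,
                            cv_folds = 0L, dropout = cfg$dropout,
                            cells = cfg$cells, n_layers = cfg$n_layers,
                            layer_sizes = cfg$layer_sizes,
                            n_trees = cfg$n_trees)
    preds <- vapply(va, function(i)
      majority_vote(forward_frames(fit, features[[i]]))$label, 0L)
    truth <- as.integer(factor(labels[va], levels = levels(labels)))
    keep <- sort(unique(truth))
    cm <- confusion_matrix(match(preds, keep), match(truth, keep), length(keep))
    data.frame(fold = k, uar = compute_metrics(cm)$uar)
  })
  do.call(rbind, res)
}

#' @rdname voice_classifier
#' @param ... arguments passed to [voice_classifier()]
#' @export
train_model <- function(features, labels, kind = "bilstm", ...) {
  voice_classifier(features, labels, kind = kind, ...)
}

#' @export
print.voice_classifier <- function(x, ...) {
  cat(sprintf("Voice-disorder classifier (%s)\n", toupper(x$kind)))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  if (x$kind == "rf") {
    cat(sprintf("  trees: %d\n", x$config$cfg$n_trees))
  } else {
    cat(sprintf("  parameters: %s\n", format(n_params(x$model), big.mark = ",")))
    cat(sprintf("  trained %d epochs (final frame cross-entropy %.4f)\n",
                x$config$epochs, utils::tail(x$history, 1)))
  }
  invisible(x)
}

#' @export
summary.voice_classifier <- function(object, ...) {
  print(object)
  if (!is.null(object$history))
    cat(sprintf("  loss: first %.4f -> last %.4f over %d epochs\n",
                object$history[1], utils::tail(object$history, 1),
                length(object$history)))
  if (!is.null(object$cv)) {
    cat("  cross-validation UAR by fold:\n")
    print(object$cv, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.voice_classifier <- function(x, ...) {
  if (is.null(x$history)) stopf("no training history to plot for kind 'rf'")
  plot(seq_along(x$history), x$history, type = "b", pch = 16,
       xlab = "epoch", ylab = "frame cross-entropy",
       main = sprintf("%s training loss", toupper(x$kind)), ...)
  invisible(x)
}

#' Predict disorder labels
#'
#' `newdata` may be a single MFCC matrix, a list of MFCC matrices, a
#' `waveform`, or a list of waveforms (including a `voice_corpus`'s
#' `utterances`); waveforms are passed through VAD and feature extraction
#' first. Utterance labels come from the frame-level majority vote.
#'
#' @param object fitted [voice_classifier()]
#' @param newdata input utterance(s)
#' @param type `"class"` (factor of labels), `"prob"` (utterance-mean
#'   posterior matrix) or `"frames"` (frame posteriors, single utterance)
#' @param vad_threshold likelihood-ratio threshold for speech detection
#' @param cfg framing configuration for waveform input
#' @param ... unused
#' @export
predict.voice_classifier <- function(object, newdata,
                                     type = c("class", "prob", "frames"),
                                     vad_threshold = 0.9,
                                     cfg = framing_config(), ...) {
  type <- match.arg(type)
  to_feats <- function(x) {
    if (inherits(x, "waveform")) {
      vad <- detect_speech(x, threshold = vad_threshold, cfg = cfg)
      if (!any(vad$speech_mask)) stopf("unvoiced input: no speech frames survive VAD")
      extract_mfcc(x, cfg, speech_mask = vad$speech_mask)
    } else as.matrix(x)
  }
  single <- inherits(newdata, "waveform") ||
    (is.matrix(newdata) || is.data.frame(newdata))
  items <- if (single) list(newdata) else newdata
  feats <- lapply(items, to_feats)
  if (type == "frames") {
    if (length(feats) != 1L) stopf("type = 'frames' needs a single utterance")
    return(forward_frames(object, feats[[1]]))
  }
  probs <- lapply(feats, function(f) forward_frames(object, f))
  if (type == "prob") {
    out <- t(vapply(probs, colMeans, numeric(length(object$classes))))
    colnames(out) <- object$classes
    return(out)
  }
  labs <- vapply(probs, function(p) majority_vote(p)$label, 0L)
  factor(object$classes[labs], levels = object$classes)
}
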