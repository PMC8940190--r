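#' Majority vote over frame posteriors
#'
#' Each frame votes for its argmax class; the most frequent class wins.
#' Vote ties are broken by the higher utterance-mean posterior, and any
#' residual tie by the lowest class index.
#'
#' @param probs frames x K matrix of frame-level class posteriors
#' @return object of class `utterance_prediction`: list(label (integer class
#'   index), vote_counts, mean_posterior)
#' @export
majority_vote <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) < 1L) stopf("majority_vote needs at least one frame")
  K <- ncol(probs)
  votes <- tabulate(max.col(probs, ties.method = "first"), nbins = K)
  mp <- colMeans(probs)
  winners <- which(votes == max(votes))
  label <- if (length(winners) == 1L) winners else
    winners[which.max(mp[winners])]
  structure(list(label = as.integer(label), vote_counts = votes,
                 mean_posterior = mp),
            class = "utterance_prediction")
}

#' End-to-end prediction for one waveform
#'
#' VAD, MFCC+delta extraction on the speech frames, frame-level forward
#' pass, majority vote. Deterministic at inference.
#'
#' @param model fitted [voice_classifier()] or `voice_model`
#' @param w a `waveform`
#' @param vad_threshold likelihood-ratio threshold
#' @param cfg framing configuration
#' @return an `utterance_prediction`
#' @export
predict_utterance <- function(model, w, vad_threshold = 0.9,
                              cfg = framing_config()) {
  vad <- detect_speech(w, threshold = vad_threshold, cfg = cfg)
  if (!any(vad$speech_mask))
    stopf("unvoiced input: no speech frames survive VAD")
  mfcc <- extract_mfcc(w, cfg, speech_mask = vad$speech_mask)
  majority_vote(forward_frames(model, mfcc))
}

#' Confusion matrix
#'
#' @param preds predicted class indices in 1..K (or a factor)
#' @param truths true class indices in 1..K (or a factor)
#' @param K number of classes
#' @return K x K integer matrix, rows = truth, columns = prediction
#' @export
confusion_matrix <- function(preds, truths, K) {
  if (is.factor(preds)) preds <- as.integer(preds)
  if (is.factor(truths)) truths <- as.integer(truths)
  if (length(preds) != length(truths)) stopf("length mismatch")
  if (any(preds < 1 | preds > K) || any(truths < 1 | truths > K))
    stopf("label out of range 1..%d", K)
  cm <- matrix(0L, K, K)
  for (i in seq_along(preds))
    cm[truths[i], preds[i]] <- cm[truths[i], preds[i]] + 1L
  cm
}

#' Accuracy, per-class sensitivity and unweighted average recall
#'
#' Overall accuracy is `100 * trace / total` (the multiclass reduction of the
#' binary TP/TN form; the alternative one-vs-rest macro-averaged binary
#' accuracy, which counts true negatives per class and therefore inflates
#' with K, is available as `accuracy = "ovr_macro"`). Sensitivity for class
#' D is `100 * TP_D / (TP_D + FN_D)` and UAR is the unweighted mean of the K
#' sensitivities.
#'
#' @param cm confusion matrix from [confusion_matrix()] (rows = truth)
#' @param accuracy which accuracy reduction to report
#' @return object of class `metrics_report`: list(accuracy, sensitivity,
#'   uar, K, n)
#' @export
compute_metrics <- function(cm, accuracy = c("overall", "ovr_macro")) {
  accuracy <- match.arg(accuracy)
  cm <- as.matrix(cm)
  K <- nrow(cm)
  n <- sum(cm)
  if (n < 1) stopf("empty confusion matrix")
  row_tot <- rowSums(cm)
  if (any(row_tot == 0))
    stopf("sensitivity undefined: true class %s has no samples",
          paste(which(row_tot == 0), collapse = ", "))
  tp <- diag(cm)
  sens <- 100 * tp / row_tot
  acc <- if (accuracy == "overall") {
    100 * sum(tp) / n
  } else {
    # per-class binary accuracy (TP+TN)/n, averaged over classes
    col_tot <- colSums(cm)
    mean(100 * (tp + (n - row_tot - col_tot + tp)) / n)
  }
  names(sens) <- rownames(cm) %||% paste0("class", seq_len(K))
  structure(list(accuracy = acc, sensitivity = sens, uar = mean(sens),
                 K = K, n = n),
            class = "metrics_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Accuracy: %.2f%%  UAR: %.2f%%  (K = %d, n = %d)\n",
              x$accuracy, x$uar, x$K, x$n))
  cat("Sensitivity (%):\n")
  print(round(x$sensitivity, 2))
  invisible(x)
}

#' Evaluate a fitted classifier on a labeled feature set
#'
#' @param object fitted [voice_classifier()]
#' @param features list of MFCC matrices
#' @param labels factor of true utterance labels (levels must match the
#'   classifier's classes)
#' @return a `metrics_report`
#' @export
evaluate_classifier <- function(object, features, labels) {
  labels <- factor(labels, levels = object$classes)
  preds <- vapply(features, function(f)
    majority_vote(forward_frames(object, f))$label, 0L)
  cm <- confusion_matrix(preds, as.integer(labels), length(object$classes))
  rownames(cm) <- colnames(cm) <- object$classes
  compute_metrics(cm)
}
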