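# Experiment harnesses: continuous-vs-vowel condition comparison across the
# five classifier kinds, script-item (sentence) selection, and PCA
# visualization of pooled hidden features.

#' Compare classifiers across recording conditions
#'
#' Generates matched continuous-speech and sustained-vowel corpora (same
#' profiles, class counts and seed lineage), trains each requested model
#' kind on each condition's speaker-disjoint training split, and evaluates
#' accuracy and UAR on the held-out test split.
#'
#' @param class_counts named per-class utterance counts
#' @param model_kinds character vector of classifier kinds
#' @param profiles disorder profile set
#' @param seed corpus/training seed
#' @param epochs,batch_size training settings passed to [voice_classifier()]
#' @param script_id script item used for the continuous condition
#' @param fit_fun optional replacement fitting function
#'   `function(features, labels, kind, speakers)`; a returned object of class
#'   `truth_stub` makes the harness echo the true labels (wiring checks)
#' @return data.frame with columns model_kind, condition, accuracy, uar
#' @export
run_condition_comparison <- function(class_counts,
                                     model_kinds = c("bilstm", "gru", "lstm",
                                                     "dnn", "rf"),
                                     profiles = disorder_profiles(),
                                     seed = 1L, epochs = 30L, batch_size = 16L,
                                     script_id = 2L, fit_fun = NULL) {
  if (!all(names(class_counts) %in% names(profiles)))
    stopf("class sets of counts and profiles do not match")
  conds <- list(
    continuous = list(
      corpus = generate_corpus(
        corpus_config(class_counts, seed = seed), profiles,
        utterance_spec("continuous", script_id = script_id)),
      NULL),
    vowel = list(
      corpus = generate_corpus(
        corpus_config(class_counts, seed = seed + 1L), profiles,
        utterance_spec("sustained_vowel")),
      NULL))
  feats <- lapply(conds, function(cn) corpus_features(cn$corpus))
  rows <- list()
  for (kind in model_kinds) {
    for (cond in names(feats)) {
      cf <- feats[[cond]]
      tr <- cf$split == "train"; te <- !tr
      if (is.null(fit_fun)) {
        res <- run_pipeline(cf, kind = kind, epochs = epochs,
                            batch_size = batch_size, seed = seed)
        m <- res$metrics
      } else {
        fit <- fit_fun(cf$features[tr], droplevels(cf$labels[tr]), kind,
                       cf$speakers[tr])
        truth <- factor(as.character(cf$labels[te]),
                        levels = levels(cf$labels))
        preds <- if (inherits(fit, "truth_stub")) as.integer(truth) else
          vapply(cf$features[te], function(f)
            majority_vote(forward_frames(fit, f))$label, 0L)
        cm <- confusion_matrix(preds, as.integer(truth), nlevels(cf$labels))
        m <- compute_metrics(cm)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model_kind = kind, condition = cond,
        accuracy = m$accuracy, uar = m$uar)
    }
  }
  do.call(rbind, rows)
}

#' Rank script items by classification performance
#'
#' Trains and tests a BiLSTM system per continuous-speech script variant and
#' ranks the variants by UAR (ties broken by accuracy, then by script id).
#'
#' @param script_ids which script variants to evaluate (>= 2)
#' @param class_counts named per-class utterance counts
#' @param profiles disorder profile set (or a list of per-script profile
#'   sets, for controlled separation experiments)
#' @param seed corpus/training seed
#' @param epochs,batch_size,kind training settings
#' @return data.frame (script_id, accuracy, uar, rank), best first
#' @export
run_sentence_selection <- function(script_ids = 1:7, class_counts,
                                   profiles = disorder_profiles(), seed = 1L,
                                   epochs = 30L, batch_size = 16L,
                                   kind = "bilstm") {
  if (length(script_ids) < 2L) stopf("need at least two script variants")
  rows <- lapply(seq_along(script_ids), function(i) {
    sid <- script_ids[i]
    prof <- if (is.null(names(profiles))) profiles[[i]] else profiles
    corp <- generate_corpus(
      corpus_config(class_counts, seed = seed), prof,
      utterance_spec("continuous", script_id = sid))
    res <- run_pipeline(corp, kind = kind, epochs = epochs,
                        batch_size = batch_size, seed = seed)
    data.frame(script_id = sid, accuracy = res$metrics$accuracy,
               uar = res$metrics$uar)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$uar, -tab$accuracy, tab$script_id)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Project pooled hidden features to two principal components
#'
#' Mean-centered PCA (no whitening) of utterance-level feature vectors,
#' keeping the top two axes for visualization.
#'
#' @param features n x H matrix of pooled hidden features (one row per
#'   utterance)
#' @param labels class label per utterance
#' @return object of class `pca_projection`: list(coords (n x 2), labels,
#'   explained_variance (length 2, shares of total variance))
#' @export
pca_project <- function(features, labels) {
  features <- as.matrix(features)
  if (nrow(features) < 3L) stopf("need at least 3 utterance vectors")
  if (ncol(features) < 2L) stopf("feature dimension must be >= 2")
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coords = unname(pc$x[, 1:2, drop = FALSE]),
                 labels = labels, explained_variance = ev[1:2]),
            class = "pca_projection")
}

#' @export
plot.pca_projection <- function(x, ...) {
  lab <- factor(x$labels)
  plot(x$coords, col = as.integer(lab), pch = 16,
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained_variance[2]), ...)
  graphics::legend("topright", legend = levels(lab), col = seq_len(nlevels(lab)),
                   pch = 16, cex = 0.8)
  invisible(x)
}
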