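#' Extract MFCC features for every utterance of a corpus
#'
#' Runs voice activity detection and the MFCC+delta front end over each
#' utterance. Utterances where no frame survives VAD are dropped with a
#' warning (none should, for the default synthesis settings).
#'
#' @param corpus a `voice_corpus` with audio
#' @param cfg a [framing_config()]
#' @param vad_threshold likelihood-ratio threshold; NA disables VAD
#' @return list with `features` (list of matrices), `labels` (factor),
#'   `speakers`, `split` (train/test), `ids`
#' @export
corpus_features <- function(corpus, cfg = framing_config(),
                            vad_threshold = 0.9) {
  if (is.null(corpus$utterances)) stopf("corpus has no audio (audio = FALSE)")
  man <- corpus$manifest
  feats <- vector("list", nrow(man))
  keep <- logical(nrow(man))
  for (i in seq_len(nrow(man))) {
    w <- corpus$utterances[[i]]
    mask <- NULL
    if (!is.na(vad_threshold)) {
      vad <- detect_speech(w, threshold = vad_threshold, cfg = cfg)
      if (!any(vad$speech_mask)) {
        warning(sprintf("utterance %s has no speech frames; dropped", man$id[i]))
        next
      }
      mask <- vad$speech_mask
    }
    feats[[i]] <- extract_mfcc(w, cfg, speech_mask = mask)
    keep[i] <- TRUE
  }
  list(features = feats[keep],
       labels = factor(man$label[keep], levels = unique(man$label)),
       speakers = man$speaker_id[keep],
       split = man$split[keep],
       ids = man$id[keep])
}

#' Train on the training split and evaluate on the held-out test split
#'
#' Convenience wrapper tying the whole pipeline together: speaker-disjoint
#' split from the corpus manifest, classifier training on the training
#' portion, majority-vote evaluation on the test portion.
#'
#' @param corpus a `voice_corpus` with audio (or a precomputed
#'   [corpus_features()] list)
#' @param kind classifier kind
#' @param ... passed to [voice_classifier()]
#' @param cfg framing configuration
#' @param vad_threshold VAD threshold
#' @return list(fit, metrics, confusion)
#' @export
run_pipeline <- function(corpus, kind = "bilstm", ...,
                         cfg = framing_config(), vad_threshold = 0.9) {
  cf <- if (inherits(corpus, "voice_corpus"))
    corpus_features(corpus, cfg, vad_threshold) else corpus
  tr <- cf$split == "train"
  if (!any(tr) || !any(!tr)) stopf("corpus lacks a train or test split")
  fit <- voice_classifier(cf$features[tr], droplevels(cf$labels[tr]),
                          kind = kind, speakers = cf$speakers[tr], ...)
  te <- !tr
  labels_te <- factor(as.character(cf$labels[te]), levels = fit$classes)
  preds <- vapply(cf$features[te], function(f)
    majority_vote(forward_frames(fit, f))$label, 0L)
  cm <- confusion_matrix(preds, as.integer(labels_te), length(fit$classes))
  rownames(cm) <- colnames(cm) <- fit$classes
  list(fit = fit, metrics = compute_metrics(cm), confusion = cm)
}
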