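#' Corpus configuration
#'
#' @param class_counts named integer vector of utterance counts per disorder
#'   label (names must match the profile set)
#' @param fs sampling rate in Hz
#' @param bit_depth bits per sample for file output
#' @param seed integer seed; the same seed yields a bit-identical corpus
#' @param split_fraction train share of the speaker-disjoint partition
#' @param speakers_per_class number of distinct speakers per class; defaults
#'   to one speaker per utterance (each patient contributes one recording)
#' @return an object of class `corpus_config`
#' @export
corpus_config <- function(class_counts, fs = 44100, bit_depth = 16L, seed = 1L,
                          split_fraction = 0.8, speakers_per_class = NULL) {
  if (is.null(names(class_counts)) || any(!nzchar(names(class_counts))))
    stopf("class_counts must be a named vector")
  if (any(class_counts < 0) || any(class_counts != round(class_counts)))
    stopf("class_counts must be non-negative integers")
  if (split_fraction <= 0 || split_fraction >= 1)
    stopf("split_fraction must be in (0, 1)")
  if (is.null(speakers_per_class))
    speakers_per_class <- stats::setNames(as.integer(class_counts),
                                          names(class_counts))
  structure(list(class_counts = class_counts, fs = fs,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed),
                 split_fraction = split_fraction,
                 speakers_per_class = speakers_per_class),
            class = "corpus_config")
}

#' Replica configuration of the full clinical voice-disorder corpus
#'
#' Class counts follow the published corpus statistics: continuous speech
#' 100 FD / 103 neoplasm / 718 phonotrauma / 124 vocal palsy (1,045 total);
#' sustained vowel 100 / 102 / 735 / 124 (1,061 total).
#'
#' @param mode `"continuous"` or `"sustained_vowel"`
#' @param seed integer seed
#' @return a [corpus_config()]
#' @export
femh_replica_config <- function(mode = c("continuous", "sustained_vowel"),
                                seed = 1L) {
  mode <- match.arg(mode)
  counts <- if (mode == "continuous")
    c(fd = 100L, neoplasm = 103L, phonotrauma = 718L, vocal_palsy = 124L)
  else
    c(fd = 100L, neoplasm = 102L, phonotrauma = 735L, vocal_palsy = 124L)
  cfg <- corpus_config(counts, seed = seed)
  cfg$mode <- mode
  cfg
}

#' Replica configuration of the balanced three-class challenge corpus
#'
#' 40 neoplasm / 60 phonotrauma / 50 vocal palsy utterances per recording
#' mode (150 speakers, each contributing both modes in the source corpus).
#'
#' @param mode recording mode
#' @param seed integer seed
#' @return a [corpus_config()]
#' @export
challenge_replica_config <- function(mode = c("sustained_vowel", "continuous"),
                                     seed = 1L) {
  mode <- match.arg(mode)
  cfg <- corpus_config(c(neoplasm = 40L, phonotrauma = 60L, vocal_palsy = 50L),
                       seed = seed)
  cfg$mode <- mode
  cfg
}

#' Generate a labeled synthetic voice corpus
#'
#' Draws per-speaker vocal-tract and source effects, assigns utterances to
#' speakers, partitions speakers into train/test so that no speaker appears
#' in both splits, and (optionally) synthesizes the audio. Continuous-mode
#' entries carry all seven script items per speaker in the manifest
#' (`script_items`); the synthesized signal uses the script selected in
#' `spec_template`.
#'
#' @param config a [corpus_config()]
#' @param profiles named list of disorder profiles covering the classes in
#'   `config$class_counts`
#' @param spec_template an [utterance_spec()] used for every utterance
#' @param audio if FALSE, only the manifest (labels, speakers, split) is
#'   generated, which is sufficient for corpus-structure checks
#' @return an object of class `voice_corpus`: list(manifest, utterances,
#'   config, profiles)
#' @export
generate_corpus <- function(config, profiles = disorder_profiles(),
                            spec_template = utterance_spec("continuous"),
                            audio = TRUE) {
  if (!inherits(config, "corpus_config")) stopf("config must be a corpus_config")
  labels <- names(config$class_counts)
  missing <- setdiff(labels, names(profiles))
  if (length(missing))
    stopf("no profile for class(es): %s", paste(missing, collapse = ", "))
  n_spk <- config$speakers_per_class
  if (length(n_spk) == 1L) n_spk <- stats::setNames(rep(n_spk, length(labels)), labels)
  with_seed(config$seed, {
    manifest <- NULL
    speakers <- list()
    for (lab in labels) {
      n_utt <- config$class_counts[[lab]]
      if (n_utt == 0) next
      ns <- min(n_spk[[lab]], n_utt)
      if (ns < 2)
        stopf("speakers_per_class too small for a speaker-disjoint split (class %s)", lab)
      spk <- lapply(seq_len(ns), function(i) draw_speaker(lab, i))
      names(spk) <- vapply(spk, `[[`, "", "speaker_id")
      speakers <- c(speakers, spk)
      spk_of_utt <- names(spk)[(seq_len(n_utt) - 1L) %% ns + 1L]
      # speaker-disjoint split: shuffle speakers, fill the test side until it
      # holds at least (1 - split_fraction) of the class utterances
      ord <- sample(names(spk))
      utt_per_spk <- table(factor(spk_of_utt, levels = ord))
      n_test_target <- (1 - config$split_fraction) * n_utt
      cum <- cumsum(as.integer(utt_per_spk))
      k <- which(cum >= n_test_target)[1]
      k <- min(k, length(ord) - 1L)  # keep at least one training speaker
      test_spk <- ord[seq_len(k)]
      manifest <- rbind(manifest, data.frame(
        id = sprintf("%s_u%04d", lab, seq_len(n_utt)),
        label = lab, speaker_id = spk_of_utt, mode = spec_template$mode,
        script_id = if (spec_template$mode == "continuous")
          spec_template$script_id else NA_integer_,
        script_items = if (spec_template$mode == "continuous")
          paste(1:7, collapse = "|") else NA_character_,
        split = ifelse(spk_of_utt %in% test_spk, "test", "train"),
        stringsAsFactors = FALSE))
    }
    rownames(manifest) <- NULL
    utterances <- NULL
    if (audio) {
      utterances <- vector("list", nrow(manifest))
      for (i in seq_len(nrow(manifest))) {
        utterances[[i]] <- synth_utterance(
          spec_template, profiles[[manifest$label[i]]], fs = config$fs,
          speaker = speakers[[manifest$speaker_id[i]]])
      }
      names(utterances) <- manifest$id
    }
    structure(list(manifest = manifest, utterances = utterances,
                   config = config, profiles = profiles,
                   spec_template = spec_template),
              class = "voice_corpus")
  })
}

#' @export
print.voice_corpus <- function(x, ...) {
  cat(sprintf("Synthetic voice corpus: %d utterances (%s mode)%s\n",
              nrow(x$manifest), x$spec_template$mode,
              if (is.null(x$utterances)) " [manifest only]" else ""))
  print(table(x$manifest$label, x$manifest$split))
  invisible(x)
}

#' Write a corpus to WAV files plus a CSV manifest
#'
#' @param corpus a `voice_corpus` with audio
#' @param dir output directory (created if needed)
#' @return path of the manifest CSV, invisibly
#' @export
write_corpus <- function(corpus, dir) {
  if (is.null(corpus$utterances)) stopf("corpus has no audio (audio = FALSE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- corpus$manifest
  man$path <- file.path(dir, paste0(man$id, ".wav"))
  for (i in seq_len(nrow(man)))
    write_wav(corpus$utterances[[i]]$samples, corpus$config$fs, man$path[i],
              corpus$config$bit_depth)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
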