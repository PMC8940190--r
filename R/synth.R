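#' Glottal source parameters
#'
#' Parameter set for the Rosenberg-pulse glottal source model. Jitter and
#' shimmer follow the Praat-style "local" definitions: jitter is the mean
#' absolute difference between consecutive cycle periods divided by the mean
#' period (in percent); shimmer is the mean absolute dB difference between
#' consecutive cycle peak amplitudes. Per-cycle perturbations are drawn
#' i.i.d. Gaussian with standard deviations chosen so that the expected local
#' measure equals the configured value (`sd = value * sqrt(pi)/2` for the
#' underlying per-cycle draws, since `E|d| = 2*sd/sqrt(pi)` for the
#' consecutive difference `d`).
#'
#' @param f0_mean mean fundamental frequency in Hz
#' @param f0_contour optional relative f0 multiplier: a numeric vector
#'   interpolated over the utterance (e.g. one value per syllable), or NULL
#'   for a flat contour
#' @param jitter_pct cycle-to-cycle period perturbation, percent (>= 0)
#' @param shimmer_db cycle-to-cycle amplitude perturbation, dB (>= 0)
#' @param aspiration_gain linear gain of unit-RMS high-pass-filtered noise
#'   added to the unit-RMS harmonic source; `10^(-HNR_dB/20)` targets a
#'   given harmonics-to-noise ratio
#' @param tremor_hz slow f0 modulation rate in Hz (0 disables)
#' @param tremor_depth relative depth of the f0 modulation
#' @return an object of class `glottal_params`
#' @seealso [aspiration_gain_for_hnr()]
#' @export
glottal_params <- function(f0_mean = 150, f0_contour = NULL, jitter_pct = 0,
                           shimmer_db = 0, aspiration_gain = 0,
                           tremor_hz = 0, tremor_depth = 0) {
  if (!is.numeric(f0_mean) || f0_mean <= 0) stopf("f0_mean must be > 0")
  if (jitter_pct < 0 || shimmer_db < 0 || aspiration_gain < 0)
    stopf("jitter_pct, shimmer_db and aspiration_gain must be >= 0")
  structure(list(f0_mean = f0_mean, f0_contour = f0_contour,
                 jitter_pct = jitter_pct, shimmer_db = shimmer_db,
                 aspiration_gain = aspiration_gain, tremor_hz = tremor_hz,
                 tremor_depth = tremor_depth),
            class = "glottal_params")
}

#' Aspiration gain targeting a harmonics-to-noise ratio
#'
#' @param hnr_db target HNR in dB
#' @return linear noise gain for [glottal_params()]
#' @export
aspiration_gain_for_hnr <- function(hnr_db) 10^(-hnr_db / 20)

rosenberg_pulse <- function(len, open_q = 0.4, close_q = 0.16) {
  n_open <- max(2L, round(open_q * len))
  n_close <- max(2L, round(close_q * len))
  t1 <- seq_len(n_open) / n_open
  t2 <- seq_len(n_close) / n_close
  p <- numeric(len)
  p[seq_len(n_open)] <- 3 * t1^2 - 2 * t1^3
  idx <- n_open + seq_len(min(n_close, len - n_open))
  p[idx] <- 1 - t2[seq_along(idx)]^2
  p
}

#' Synthesize a glottal source signal
#'
#' Emits a Rosenberg pulse train with per-cycle period and amplitude
#' perturbations (jitter, shimmer), optional slow f0 tremor, and additive
#' high-pass-filtered aspiration noise. The harmonic part is normalized to
#' unit RMS before the noise (also unit RMS) is scaled by `aspiration_gain`
#' and added, so `HNR = -20*log10(aspiration_gain)` by construction.
#'
#' Consumes the R random number stream; seed upstream for reproducibility.
#'
#' @param params a [glottal_params()] object
#' @param duration_s duration in seconds (> 0)
#' @param fs sampling rate in Hz (> 2 * f0_mean)
#' @return numeric vector of samples (not peak-normalized)
#' @export
synth_glottal_source <- function(params, duration_s, fs) {
  if (!inherits(params, "glottal_params")) stopf("params must be glottal_params")
  if (!is.numeric(duration_s) || duration_s <= 0) stopf("duration_s must be > 0")
  if (fs <= 2 * params$f0_mean) stopf("fs must exceed 2 * f0_mean")
  n <- round(duration_s * fs)
  # per-sample relative f0 contour
  contour <- if (is.null(params$f0_contour)) rep(1, n) else
    stats::approx(seq(0, 1, length.out = max(2L, length(params$f0_contour))),
                  if (length(params$f0_contour) == 1L)
                    rep(params$f0_contour, 2) else params$f0_contour,
                  xout = seq(0, 1, length.out = n), rule = 2)$y
  sd_j <- params$jitter_pct / 100 * sqrt(pi) / 2
  sd_s <- params$shimmer_db * sqrt(pi) / 2
  x <- numeric(n + round(fs / params$f0_mean) + 8L)
  pos <- 0
  while (pos < n) {
    t_sec <- pos / fs
    f0 <- params$f0_mean * contour[min(n, floor(pos) + 1L)]
    if (params$tremor_hz > 0)
      f0 <- f0 * (1 + params$tremor_depth * sin(2 * pi * params$tremor_hz * t_sec))
    # jitter perturbs the pulse spacing only; the pulse shape keeps the
    # nominal local period so cycle peaks stay at a fixed offset and the
    # spacing carries the configured perturbation exactly
    period <- (1 / f0) * (1 + if (sd_j > 0) stats::rnorm(1, 0, sd_j) else 0)
    period <- max(period, 2 / fs)
    amp <- 10^((if (sd_s > 0) stats::rnorm(1, 0, sd_s) else 0) / 20)
    len <- max(4L, round(fs / f0))
    pulse <- amp * rosenberg_pulse(len)
    at <- round(pos) + 1L
    x[at:(at + len - 1L)] <- x[at:(at + len - 1L)] + pulse
    pos <- pos + period * fs
  }
  x <- x[seq_len(n)]
  rms <- sqrt(mean(x^2))
  if (rms > 0) x <- x / rms
  if (params$aspiration_gain > 0) {
    noise <- stats::rnorm(n)
    hp <- signal::butter(2, min(0.95, 500 / (fs / 2)), type = "high")
    noise <- as.numeric(signal::filter(hp, noise))
    noise <- noise / sqrt(mean(noise^2))
    x <- x + params$aspiration_gain * noise
  }
  x
}

# Formant targets (Hz) for the vowel inventory used by the synthesizer;
# standard adult reference values from the phonetics literature.
vowel_targets <- function() {
  list(a = c(700, 1220, 2600),
       i = c(300, 2300, 3000),
       u = c(320, 800, 2500),
       e = c(480, 1900, 2650),
       o = c(500, 900, 2550))
}

default_bandwidths <- function() c(80, 100, 120)

#' Utterance specification
#'
#' @param mode `"sustained_vowel"` or `"continuous"`
#' @param duration_s vowel-mode duration in seconds (default 3, the typical
#'   sustained-/a/ recording length)
#' @param n_syllables syllable count for continuous mode (>= 2); defaults to
#'   the syllable count of the selected script item
#' @param script_id which of the seven script items to use (continuous mode)
#' @return an object of class `utterance_spec`
#' @export
utterance_spec <- function(mode = c("sustained_vowel", "continuous"),
                           duration_s = 3.0, n_syllables = NULL,
                           script_id = 2L) {
  mode <- match.arg(mode)
  if (duration_s <= 0) stopf("duration_s must be > 0")
  if (mode == "continuous") {
    if (is.null(n_syllables)) n_syllables <- script_table()$n_syllables[script_id]
    if (n_syllables < 2) stopf("continuous mode requires n_syllables >= 2")
  }
  structure(list(mode = mode, duration_s = duration_s,
                 n_syllables = n_syllables, script_id = as.integer(script_id)),
            class = "utterance_spec")
}

#' Script variants for continuous-speech synthesis
#'
#' Seven synthetic script items stand in for a seven-sentence reading
#' passage. Variants differ in syllable count and in "transition richness"
#' (how far apart consecutive vowel targets are, which controls how much
#' formant movement the item elicits). The vowel sequence of each item is
#' generated deterministically from its id.
#'
#' @return data.frame with columns `script_id`, `n_syllables`, `richness`
#' @export
script_table <- function() {
  data.frame(script_id = 1:7,
             n_syllables = c(8L, 10L, 12L, 11L, 9L, 14L, 10L),
             richness = c(0.7, 1.0, 0.8, 0.9, 0.6, 0.75, 0.85))
}

script_vowels <- function(script_id, n_syllables = NULL) {
  tab <- script_table()
  if (!script_id %in% tab$script_id) stopf("script_id must be in 1..7")
  ns <- if (is.null(n_syllables)) tab$n_syllables[script_id] else n_syllables
  rich <- tab$richness[script_id]
  inv <- names(vowel_targets())
  # deterministic pseudo-random vowel sequence per script; richness biases
  # toward alternating open/close vowels (more formant travel)
  idx <- (script_id * 3 + (seq_len(ns) - 1) * ifelse(rich > 0.8, 3, 2)) %% length(inv) + 1
  inv[idx]
}

#' Disorder acoustic profiles
#'
#' Default per-class distributions of glottal-source parameters for the four
#' diagnoses. These values are invented for synthesis purposes (the clinical
#' classes are defined by endoscopic findings, not by any published acoustic
#' recipe); they are chosen to give the classes separable but overlapping
#' signatures: functional dysphonia is near-normal with reduced loudness
#' variation, neoplasm has high jitter with moderate noise, phonotrauma has
#' high shimmer and breathiness, vocal palsy has strong aspiration plus f0
#' tremor. `transition_slope` is the fraction of each syllable spent gliding
#' between formant targets in continuous mode; it differs by class so that
#' part of the class evidence lives in transition dynamics and is only
#' observable in continuous speech.
#'
#' @param labels character vector of class labels to include
#' @return named list of `disorder_profile` objects
#' @export
disorder_profiles <- function(labels = c("fd", "neoplasm", "phonotrauma",
                                         "vocal_palsy")) {
  base <- list(
    fd = list(f0_mean = 185, jitter_pct = 0.5, shimmer_db = 0.35,
              hnr_db = 25, tremor_hz = 0, tremor_depth = 0,
              loudness_var = 0.02, transition_slope = 0.15),
    neoplasm = list(f0_mean = 170, jitter_pct = 3.0, shimmer_db = 0.6,
                    hnr_db = 18, tremor_hz = 0, tremor_depth = 0,
                    loudness_var = 0.08, transition_slope = 0.35),
    phonotrauma = list(f0_mean = 175, jitter_pct = 1.2, shimmer_db = 1.5,
                       hnr_db = 15, tremor_hz = 0, tremor_depth = 0,
                       loudness_var = 0.08, transition_slope = 0.60),
    vocal_palsy = list(f0_mean = 160, jitter_pct = 1.8, shimmer_db = 0.8,
                       hnr_db = 8, tremor_hz = 4.5, tremor_depth = 0.035,
                       loudness_var = 0.10, transition_slope = 0.90))
  labels <- match.arg(labels, names(base), several.ok = TRUE)
  out <- lapply(labels, function(l) {
    structure(c(list(label = l), base[[l]], list(rel_spread = 0.12)),
              class = "disorder_profile")
  })
  names(out) <- labels
  out
}

#' Transition-encoded disorder profiles
#'
#' A profile set in which the four classes share nearly identical static
#' source statistics (jitter, shimmer, HNR, mean f0) and differ almost
#' entirely in their continuous-speech transition dynamics: the formant
#' glide fraction per syllable (`transition_slope`) and the direction and
#' size of the per-syllable f0 onset glide (`f0_onset_glide`). Under these
#' profiles a sustained vowel carries essentially no class information while
#' continuous speech does — the controlled condition for studying how much
#' classifiers gain from syllable transitions.
#'
#' @return named list of `disorder_profile` objects
#' @export
transition_profiles <- function() {
  shared <- list(f0_mean = 175, jitter_pct = 1.2, shimmer_db = 0.8,
                 hnr_db = 18, tremor_hz = 0, tremor_depth = 0,
                 loudness_var = 0.06)
  dyn <- list(fd = list(transition_slope = 0.08, f0_onset_glide = -0.10),
              neoplasm = list(transition_slope = 0.30, f0_onset_glide = 0.10),
              phonotrauma = list(transition_slope = 0.60, f0_onset_glide = -0.04),
              vocal_palsy = list(transition_slope = 0.92, f0_onset_glide = 0.05))
  out <- lapply(names(dyn), function(l) {
    structure(c(list(label = l), shared, dyn[[l]], list(rel_spread = 0.10)),
              class = "disorder_profile")
  })
  names(out) <- names(dyn)
  out
}

#' Scale the inter-class separation of a profile set
#'
#' Moves each class's acoustic parameters away from (factor > 1) or toward
#' (factor < 1) the cross-class mean, on a log scale for the strictly
#' positive parameters. Used to construct "well separated" or "collapsed"
#' synthetic conditions for controlled experiments.
#'
#' @param profiles list from [disorder_profiles()]
#' @param factor separation multiplier (>= 0)
#' @return modified profile list
#' @export
scale_profile_separation <- function(profiles, factor) {
  if (factor < 0) stopf("factor must be >= 0")
  pars <- c("f0_mean", "jitter_pct", "shimmer_db", "hnr_db", "transition_slope")
  for (p in pars) {
    v <- vapply(profiles, function(x) x[[p]], numeric(1))
    lv <- log(pmax(v, 1e-6))
    lv <- mean(lv) + factor * (lv - mean(lv))
    for (i in seq_along(profiles)) profiles[[i]][[p]] <- exp(lv[i])
  }
  # tremor scales linearly (it can legitimately be zero)
  td <- vapply(profiles, function(x) x$tremor_depth, numeric(1))
  td <- mean(td) + factor * (td - mean(td))
  for (i in seq_along(profiles)) profiles[[i]]$tremor_depth <- max(0, td[i])
  profiles
}

draw_speaker <- function(label, idx) {
  list(speaker_id = sprintf("%s_s%03d", label, idx),
       f0_shift = stats::rnorm(1, 0, 12),
       formant_scale = stats::rnorm(1, 1, 0.035),
       param_scale = exp(stats::rnorm(1, 0, 0.08)))
}

draw_source_params <- function(profile, speaker, contour = NULL) {
  sp <- profile$rel_spread
  pert <- function(m) max(0, m * speaker$param_scale * exp(stats::rnorm(1, 0, sp)))
  glottal_params(
    f0_mean = max(70, profile$f0_mean + speaker$f0_shift + stats::rnorm(1, 0, 6)),
    f0_contour = contour,
    jitter_pct = pert(profile$jitter_pct),
    shimmer_db = pert(profile$shimmer_db),
    aspiration_gain = aspiration_gain_for_hnr(
      profile$hnr_db + stats::rnorm(1, 0, 1.5)),
    tremor_hz = profile$tremor_hz,
    tremor_depth = max(0, profile$tremor_depth * exp(stats::rnorm(1, 0, sp))))
}

#' Synthesize one labeled utterance
#'
#' Source-filter synthesis: a perturbed glottal source is passed through a
#' cascade of formant resonators. Sustained-vowel mode uses static /a/
#' formants; continuous mode interpolates per-syllable formant targets (with
#' class-dependent transition slopes) and imposes inter-syllable amplitude
#' dips and per-syllable loudness variation. Output is peak-normalized to
#' 0.95. The first and last 100 ms of every utterance are silent margins
#' (recording lead-in/out), counted inside the stated duration; downstream
#' voice activity detection initializes its noise model on the lead-in.
#'
#' @param spec an [utterance_spec()]
#' @param profile a `disorder_profile`
#' @param fs sampling rate in Hz
#' @param speaker optional speaker-effect list (internal); NULL draws a
#'   neutral speaker
#' @return a `waveform` object: list(samples, fs, label, speaker_id, mode)
#' @export
synth_utterance <- function(spec, profile, fs = 44100, speaker = NULL) {
  if (!inherits(spec, "utterance_spec")) stopf("spec must be an utterance_spec")
  if (!inherits(profile, "disorder_profile")) stopf("profile must be a disorder_profile")
  if (is.null(speaker))
    speaker <- list(speaker_id = "anon", f0_shift = 0, formant_scale = 1,
                    param_scale = 1)
  bw <- default_bandwidths()
  pad <- round(0.1 * fs)
  if (spec$mode == "sustained_vowel") {
    n_total <- round(spec$duration_s * fs)
    n <- n_total - 2L * pad
    if (n < fs %/% 10) stopf("duration_s too short for synthesis")
    dur <- n / fs
    params <- draw_source_params(profile, speaker, contour = c(1, 0.97))
    src <- synth_glottal_source(params, dur, fs)
    ff <- matrix(rep(vowel_targets()$a * speaker$formant_scale, each = n), n, 3)
    env <- taper_env(n, fs)
  } else {
    ns <- spec$n_syllables
    vseq <- script_vowels(spec$script_id, ns)
    syl_dur <- pmax(0.12, stats::rnorm(ns, 0.18, 0.015))
    dur <- sum(syl_dur)
    n <- round(dur * fs)
    bounds <- round(c(0, cumsum(syl_dur)) / dur * n)
    # per-syllable f0 accents with overall declination; profiles may add a
    # class-dependent f0 glide into each syllable onset
    acc <- exp(stats::rnorm(ns, 0, 0.05)) * seq(1.03, 0.94, length.out = ns)
    glide <- profile$f0_onset_glide
    contour <- if (is.null(glide) || glide == 0) acc else
      as.vector(rbind(acc * (1 + glide), acc))
    params <- draw_source_params(profile, speaker, contour = contour)
    src <- synth_glottal_source(params, dur, fs)
    # formant trajectory: glide into each syllable target over a
    # class-dependent fraction of the syllable, then hold
    slope <- min(0.95, max(0.05, profile$transition_slope *
                             exp(stats::rnorm(1, 0, 0.1))))
    targets <- t(vapply(vseq, function(v) vowel_targets()[[v]], numeric(3)))
    targets <- targets * speaker$formant_scale
    bp_x <- c(); bp_y <- matrix(numeric(0), 0, 3)
    prev <- targets[1, ]
    for (s in seq_len(ns)) {
      on <- bounds[s] + 1L
      off <- bounds[s + 1L]
      glide_end <- on + max(1L, round(slope * (off - on + 1L)))
      bp_x <- c(bp_x, on, min(glide_end, off), off)
      bp_y <- rbind(bp_y, prev, targets[s, ], targets[s, ])
      prev <- targets[s, ]
    }
    ff <- apply(bp_y, 2, function(col)
      stats::approx(bp_x, col, xout = seq_len(n), rule = 2)$y)
    # inter-syllable amplitude dips + per-syllable loudness variation
    env <- taper_env(n, fs)
    lv <- exp(stats::rnorm(ns, 0, profile$loudness_var))
    for (s in seq_len(ns)) {
      seg <- (bounds[s] + 1L):bounds[s + 1L]
      env[seg] <- env[seg] * lv[s]
    }
    dip_w <- round(0.04 * fs)
    for (s in seq_len(ns - 1L)) {
      ctr <- bounds[s + 1L]
      seg <- max(1L, ctr - dip_w):min(n, ctr + dip_w)
      dip <- 1 - 0.85 * 0.5 * (1 + cos(pi * (seg - ctr) / dip_w))
      env[seg] <- env[seg] * dip
    }
  }
  src <- src[seq_len(min(length(src), nrow(ff)))]
  y <- resonator_sweep_cpp(src, ff[seq_along(src), , drop = FALSE], bw, fs)
  y <- y * env[seq_along(y)]
  peak <- max(abs(y))
  if (!is.finite(peak)) stopf("unstable filter configuration")
  if (peak > 0) y <- y / peak * 0.95
  y <- c(numeric(pad), y, numeric(pad))
  structure(list(samples = as.numeric(y), fs = fs, label = profile$label,
                 speaker_id = speaker$speaker_id, mode = spec$mode),
            class = "waveform")
}

# 20 ms raised-cosine attack/decay envelope
taper_env <- function(n, fs) {
  w <- min(n %/% 2, round(0.02 * fs))
  env <- rep(1, n)
  if (w > 1) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(w) / w))
    env[seq_len(w)] <- ramp
    env[(n - w + 1L):n] <- rev(ramp)
  }
  env
}
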