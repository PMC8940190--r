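#' Spectral frame sequence for voice activity detection
#'
#' One-sided power spectra on the same frame geometry as the MFCC front end
#' (32/16 ms Hamming frames), without pre-emphasis.
#'
#' @param w `waveform` or numeric vector
#' @param cfg a [framing_config()]
#' @param fs sampling rate for plain numeric input
#' @return object of class `spectral_frames`: list(power, fft_size, fs)
#' @export
spectral_frames <- function(w, cfg = framing_config(), fs = NULL) {
  if (is.null(fs)) fs <- if (inherits(w, "waveform")) w$fs else
    stopf("fs required for plain numeric input")
  frames <- preprocess_frames(w, cfg, fs = fs, preemph = FALSE)
  structure(list(power = power_spectrum(frames, cfg$fft_size),
                 fft_size = cfg$fft_size, fs = fs),
            class = "spectral_frames")
}

#' Per-frame likelihood ratio under the Gaussian spectral model
#'
#' For each bin, the speech-presence to speech-absence likelihood ratio is
#' `Lambda_k = exp(gamma_k xi_k / (1 + xi_k)) / (1 + xi_k)` where `gamma` is
#' the a-posteriori and `xi` the a-priori SNR. The frame-level statistic is
#' the geometric mean over bins (the exponentiated mean log ratio).
#'
#' @param xi a-priori SNR, vector or frames-x-bins matrix (>= 0)
#' @param gamma a-posteriori SNR, same shape (>= 0)
#' @return numeric vector of per-frame likelihood ratios
#' @export
frame_likelihood_ratio <- function(xi, gamma) {
  if (any(!is.finite(xi)) || any(!is.finite(gamma)) ||
      any(xi < 0) || any(gamma < 0))
    stopf("xi and gamma must be finite and non-negative")
  log_lr <- gamma * xi / (1 + xi) - log1p(xi)
  if (is.matrix(log_lr)) exp(rowMeans(log_lr)) else exp(mean(log_lr))
}

# MMSE short-time spectral-amplitude gain (compiled; scaled Bessel functions
# keep the large-SNR limit G -> xi/(1+xi) numerically stable)
mmse_stsa_gain <- function(xi, gamma) {
  as.numeric(mmse_stsa_gain_cpp(as.numeric(xi), as.numeric(gamma)))
}

# Core VAD recursion: decision-directed a-priori SNR with the MMSE-STSA
# amplitude estimate, joint per-frame log likelihood ratio (sum over bins --
# the likelihood-ratio test statistic under the independent-bin Gaussian
# model; the per-bin *mean*, i.e. the geometric-mean LR exposed by
# frame_likelihood_ratio(), hovers at 1 for any stationary noise and cannot
# reject it at a threshold near 1), first-order smoothing. Noise is adapted
# on frames judged non-speech by a FIXED internal criterion (smoothed joint
# log-LR < 0), so the user-facing threshold never feeds back into the noise
# track and the speech mask is monotone in the threshold.
#
# Noise tracking is per bin: a bin updates its variance whenever its
# a-posteriori SNR is below `gate` (speech-dominated bins are excluded), and
# the update divides by the truncated-mean factor of the exponential
# periodogram distribution, E[P | P < gate*lambda]/lambda, so the estimator
# stays unbiased for stationary Gaussian noise.
vad_core <- function(P, n_init_frames = 6L, alpha_dd = 0.98, xi_floor = 1e-3,
                     update_rate = 0.95, smooth = 0.9, eps = 1e-12,
                     gate = 8) {
  trunc_c <- (1 - (1 + gate) * exp(-gate)) / (1 - exp(-gate))
  T_ <- nrow(P)
  if (T_ < 1L) stopf("empty spectral input")
  n_init <- min(n_init_frames, T_)
  lambda <- pmax(colMeans(P[seq_len(n_init), , drop = FALSE]), eps)
  log_lr <- numeric(T_)
  s <- 0
  prev_A2 <- NULL   # lag-1 amplitude estimate (feeds the next frame's xi)
  dec_A2 <- NULL    # lag-2 amplitude estimate used for the decision SNR
  dec_gamma <- NULL # lag-2 a-posteriori SNR
  for (t in seq_len(T_)) {
    gamma <- P[t, ] / lambda
    # decision-directed a-priori SNR for the amplitude recursion (lag 1)
    xi <- if (is.null(prev_A2)) {
      alpha_dd + (1 - alpha_dd) * pmax(gamma - 1, 0)
    } else {
      alpha_dd * prev_A2$A2 / lambda + (1 - alpha_dd) * pmax(gamma - 1, 0)
    }
    xi <- pmax(xi, xi_floor)
    # decision SNR from data two frames back: with a 50% frame overlap the
    # current periodogram shares samples only with frame t-1, so a lag-2
    # estimate is independent of gamma under stationary noise and the
    # log-LR keeps its negative H0 drift instead of a positive
    # correlation-induced bias
    xi_dec <- if (is.null(dec_A2)) {
      rep(alpha_dd, length(gamma))
    } else {
      alpha_dd * dec_A2 / lambda + (1 - alpha_dd) * pmax(dec_gamma - 1, 0)
    }
    xi_dec <- pmax(xi_dec, xi_floor)
    l <- sum(gamma * xi_dec / (1 + xi_dec) - log1p(xi_dec))
    s <- if (t == 1L) l else smooth * s + (1 - smooth) * l
    log_lr[t] <- s
    dec_A2 <- prev_A2$A2
    dec_gamma <- prev_A2$gamma
    prev_A2 <- list(A2 = (mmse_stsa_gain(xi, gamma))^2 * P[t, ],
                    gamma = gamma)
    upd <- gamma < gate
    if (any(upd)) {
      lambda[upd] <- pmax(update_rate * lambda[upd] +
                            (1 - update_rate) * P[t, upd] / trunc_c, eps)
    }
    # a bin whose variance estimate collapsed would keep gamma >= gate and
    # never update again; a slow upward drift on gated bins guarantees
    # recovery while leaving genuine speech bins (gamma >> gate) untouched
    lambda[!upd] <- lambda[!upd] * 1.005
  }
  list(log_lr = log_lr, lambda = lambda)
}

#' Estimate the stationary noise spectrum
#'
#' Initializes the per-bin noise variance from the first `n_init_frames`
#' (assumed non-speech) and recursively smooths it on frames the likelihood
#' ratio judges non-speech; variances are floored at `eps`.
#'
#' @param frames a [spectral_frames()] object
#' @param n_init_frames number of leading frames used for initialization
#' @param update_rate smoothing constant of the recursive update
#' @param eps variance floor
#' @return object of class `noise_model`: list(lambda_noise, update_rate)
#' @export
estimate_noise <- function(frames, n_init_frames = 6L, update_rate = 0.95,
                           eps = 1e-12) {
  if (!inherits(frames, "spectral_frames")) stopf("frames must be spectral_frames")
  if (nrow(frames$power) < 1L) stopf("empty input")
  if (n_init_frames < 1L || n_init_frames > nrow(frames$power))
    stopf("need frames >= n_init_frames >= 1")
  core <- vad_core(frames$power, n_init_frames = n_init_frames,
                   update_rate = update_rate, eps = eps)
  structure(list(lambda_noise = core$lambda, update_rate = update_rate),
            class = "noise_model")
}

#' Statistical-model voice activity detection
#'
#' Gaussian statistical-model VAD: per-bin likelihood ratios from
#' decision-directed a-priori and a-posteriori SNR estimates (MMSE-STSA
#' amplitude recursion, alpha = 0.98), joint frame statistic (the product of
#' per-bin likelihood ratios, the LR test under the independent-bin model),
#' first-order log-LR smoothing (coefficient 0.9) and a 3-frame hangover.
#' A frame is speech when the reported (smoothed, hangover-held) joint
#' likelihood ratio is at least `threshold`.
#'
#' @param w `waveform` or numeric vector
#' @param threshold decision threshold on the likelihood ratio (default 0.9)
#' @param cfg a [framing_config()] (shared with the MFCC front end)
#' @param fs sampling rate for plain numeric input
#' @param hangover number of frames a speech decision is held
#' @return object of class `vad_decision`: list(speech_mask,
#'   likelihood_ratio, threshold)
#' @export
detect_speech <- function(w, threshold = 0.9, cfg = framing_config(),
                          fs = NULL, hangover = 3L) {
  sf <- spectral_frames(w, cfg, fs = fs)
  core <- vad_core(sf$power)
  s <- core$log_lr
  # hangover as a running max so that mask[i] <=> reported LR[i] >= threshold
  held <- s
  if (hangover > 0L && length(s) > 1L) {
    for (k in seq_len(hangover)) {
      held <- pmax(held, c(rep(-Inf, k), s[seq_len(length(s) - k)]))
    }
  }
  lr <- exp(held)
  structure(list(speech_mask = lr >= threshold, likelihood_ratio = lr,
                 threshold = threshold, log_lr_raw = s),
            class = "vad_decision")
}

#' @export
print.vad_decision <- function(x, ...) {
  cat(sprintf("VAD: %d/%d frames speech (threshold %.2f)\n",
              sum(x$speech_mask), length(x$speech_mask), x$threshold))
  invisible(x)
}
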