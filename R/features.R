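#' Framing configuration for spectral analysis
#'
#' Frame geometry shared by the voice activity detector and the MFCC front
#' end: 32 ms Hamming frames with a 16 ms hop, pre-emphasis 0.97, and an FFT
#' size of 2048 (the next power of two above the 1411-sample frame at
#' 44.1 kHz).
#'
#' @param frame_ms frame length in milliseconds
#' @param hop_ms hop size in milliseconds
#' @param preemph_coeff pre-emphasis coefficient in `y[n] = x[n] - c x[n-1]`
#' @param fft_size FFT length in samples (must cover the frame)
#' @param n_mels number of mel filters
#' @return object of class `framing_config`
#' @export
framing_config <- function(frame_ms = 32, hop_ms = 16, preemph_coeff = 0.97,
                           fft_size = 2048L, n_mels = 26L) {
  if (!(frame_ms > hop_ms && hop_ms > 0)) stopf("need frame_ms > hop_ms > 0")
  structure(list(frame_ms = frame_ms, hop_ms = hop_ms,
                 preemph_coeff = preemph_coeff, fft_size = as.integer(fft_size),
                 n_mels = as.integer(n_mels)),
            class = "framing_config")
}

frame_geometry <- function(fs, cfg) {
  list(frame_len = round(cfg$frame_ms * fs / 1000),
       hop = round(cfg$hop_ms * fs / 1000))
}

as_samples <- function(w) {
  if (inherits(w, "waveform")) w$samples else as.numeric(w)
}

#' Split a waveform into pre-emphasized, Hamming-windowed frames
#'
#' @param w a `waveform` or numeric vector
#' @param cfg a [framing_config()]
#' @param fs sampling rate (taken from `w` when it is a waveform)
#' @param preemph apply pre-emphasis before framing
#' @return matrix of `n_frames` rows, one windowed frame per row
#' @export
preprocess_frames <- function(w, cfg = framing_config(), fs = NULL,
                              preemph = TRUE) {
  x <- as_samples(w)
  if (is.null(fs)) fs <- if (inherits(w, "waveform")) w$fs else
    stopf("fs required for plain numeric input")
  g <- frame_geometry(fs, cfg)
  n <- length(x)
  if (n < g$frame_len) stopf("input shorter than one frame")
  if (g$frame_len > cfg$fft_size) stopf("fft_size smaller than frame length")
  if (preemph && cfg$preemph_coeff != 0)
    x <- c(x[1], x[-1] - cfg$preemph_coeff * x[-n])
  n_frames <- 1L + (n - g$frame_len) %/% g$hop
  idx <- outer(seq_len(g$frame_len) - 1L, (seq_len(n_frames) - 1L) * g$hop, "+") + 1L
  frames <- matrix(x[idx], nrow = n_frames, ncol = g$frame_len, byrow = TRUE)
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(g$frame_len) - 1) / (g$frame_len - 1))
  frames * rep(win, each = n_frames)
}

# one-sided power spectra, n_frames x (1 + fft_size/2)
power_spectrum <- function(frames, fft_size) {
  n_bins <- 1L + fft_size %/% 2L
  padded <- matrix(0, fft_size, nrow(frames))
  padded[seq_len(ncol(frames)), ] <- t(frames)
  spec <- stats::mvfft(padded)[seq_len(n_bins), , drop = FALSE]
  t(Mod(spec)^2)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' Filters with centers equally spaced on the mel scale
#' `m(f) = 2595 log10(1 + f/700)` spanning 0 to fs/2.
#'
#' @param fs sampling rate in Hz
#' @param fft_size FFT length
#' @param n_filters number of filters
#' @return object of class `mel_filterbank`: list(weights
#'   (`n_filters x (1 + fft_size/2)`), center_freqs)
#' @export
mel_filterbank <- function(fs, fft_size = 2048L, n_filters = 26L) {
  n_bins <- 1L + fft_size %/% 2L
  pts <- mel_to_hz(seq(0, hz_to_mel(fs / 2), length.out = n_filters + 2L))
  if (any(diff(pts) < fs / fft_size))
    stopf("n_filters too large for the FFT resolution")
  bin_hz <- (seq_len(n_bins) - 1L) * fs / fft_size
  w <- matrix(0, n_filters, n_bins)
  for (i in seq_len(n_filters)) {
    fl <- pts[i]; fc <- pts[i + 1L]; fr <- pts[i + 2L]
    w[i, ] <- pmax(0, pmin((bin_hz - fl) / (fc - fl), (fr - bin_hz) / (fr - fc)))
  }
  structure(list(weights = w, center_freqs = pts[2:(n_filters + 1L)],
                 fs = fs, fft_size = as.integer(fft_size)),
            class = "mel_filterbank")
}

# orthonormal DCT-II basis, n_out x n_in
dct_basis <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1L
  n <- seq_len(n_in) - 1L
  B <- sqrt(2 / n_in) * cos(pi * outer(k, n + 0.5) / n_in)
  B[1, ] <- B[1, ] / sqrt(2)
  B
}

#' Regression delta coefficients
#'
#' `d_t = sum_{n=1..N} n (c_{t+n} - c_{t-n}) / (2 sum n^2)` with N = 2 and
#' replication padding at the edges; the delta of a linear ramp equals its
#' slope, and of a constant sequence is zero.
#'
#' @param static matrix of frame-wise static coefficients
#' @param N regression half-window
#' @return matrix of the same shape
#' @export
delta <- function(static, N = 2L) {
  static <- as.matrix(static)
  T_ <- nrow(static)
  pad <- rbind(static[rep(1L, N), , drop = FALSE], static,
               static[rep(T_, N), , drop = FALSE])
  denom <- 2 * sum((1:N)^2)
  d <- matrix(0, T_, ncol(static))
  for (n in seq_len(N)) {
    d <- d + n * (pad[(N + n) + seq_len(T_), , drop = FALSE] -
                    pad[(N - n) + seq_len(T_), , drop = FALSE])
  }
  d / denom
}

#' Extract 26-dimensional MFCC+delta features
#'
#' Per frame: pre-emphasis and Hamming windowing, magnitude spectrum via the
#' DFT, power, mel filtering, natural log (floored at 1e-10), orthonormal
#' DCT-II keeping coefficients 0-12, then regression deltas appended, giving
#' frames x 26 (columns 1-13 static, 14-26 delta). When a VAD speech mask is
#' supplied, non-speech frames are dropped before the deltas are computed, so
#' temporal slopes are taken over the retained speech sequence.
#'
#' @param w `waveform` or numeric vector
#' @param cfg a [framing_config()]
#' @param fb a [mel_filterbank()] (built to match `cfg` and `fs` if NULL)
#' @param fs sampling rate for plain numeric input
#' @param speech_mask optional logical vector, one entry per frame
#' @return matrix with `attr(, "frame_times")` (frame centers in seconds)
#' @export
extract_mfcc <- function(w, cfg = framing_config(), fb = NULL, fs = NULL,
                         speech_mask = NULL) {
  if (is.null(fs)) fs <- if (inherits(w, "waveform")) w$fs else
    stopf("fs required for plain numeric input")
  if (is.null(fb)) fb <- mel_filterbank(fs, cfg$fft_size, cfg$n_mels)
  frames <- preprocess_frames(w, cfg, fs = fs)
  P <- power_spectrum(frames, cfg$fft_size)
  E <- P %*% t(fb$weights)
  logmel <- log(pmax(E, 1e-10))
  static <- logmel %*% t(dct_basis(13L, cfg$n_mels))
  g <- frame_geometry(fs, cfg)
  times <- ((seq_len(nrow(static)) - 1L) * g$hop + g$frame_len / 2) / fs
  if (!is.null(speech_mask)) {
    if (length(speech_mask) != nrow(static))
      stopf("speech_mask length (%d) does not match frame count (%d)",
            length(speech_mask), nrow(static))
    if (!any(speech_mask)) stopf("no voiced content: empty speech mask")
    static <- static[speech_mask, , drop = FALSE]
    times <- times[speech_mask]
  }
  out <- cbind(static, delta(static))
  colnames(out) <- c(paste0("c", 0:12), paste0("d", 0:12))
  attr(out, "frame_times") <- times
  out
}
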