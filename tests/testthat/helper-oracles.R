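# Independent measurement oracles used to validate the synthesizer and the
# classifiers. These deliberately share no code with the package internals:
# cycle lengths come from peak picking, HNR from comb-filter decomposition,
# and the BiLSTM oracle is a literal scalar transcription of the gate
# equations.

# normalized cross-correlation at a single integer lag
autocorr_at_lag <- function(x, lag) {
  n <- length(x)
  a <- x[1:(n - lag)]
  b <- x[(lag + 1):n]
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# peak-picking cycle-length estimator: one peak per glottal cycle, local
# jitter/shimmer (Praat-style) from consecutive peak spacing/amplitude
measure_cycles <- function(x, fs, f0_approx) {
  t0 <- fs / f0_approx
  thr <- 0.4 * max(x)
  above <- x > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks <- integer(0)
  amps <- numeric(0)
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    p <- seg[which.max(x[seg])]
    if (!length(peaks) || p - peaks[length(peaks)] > 0.5 * t0) {
      peaks <- c(peaks, p)
      amps <- c(amps, x[p])
    }
  }
  periods <- diff(peaks)
  list(
    peaks = peaks,
    jitter_pct = 100 * mean(abs(diff(periods))) / mean(periods),
    shimmer_db = mean(abs(diff(20 * log10(amps)))))
}

# harmonic/noise decomposition via one-period comb averaging: the harmonic
# part of a T0-periodic signal is the per-period average, the residual is
# noise
measure_hnr <- function(x, fs, f0) {
  t0 <- round(fs / f0)
  n_per <- length(x) %/% t0
  m <- matrix(x[seq_len(n_per * t0)], nrow = t0)
  harm <- rowMeans(m)
  resid <- m - harm
  ph <- mean(harm^2)
  pn <- mean(resid^2)
  if (pn < ph * 1e-6) return(60)
  10 * log10(ph / pn)
}

# frame-wise spectral centroid over a plain STFT
spectral_centroid_series <- function(x, fs, frame = 1024L, hop = 512L) {
  n_frames <- 1L + (length(x) - frame) %/% hop
  freqs <- (seq_len(frame %/% 2L) - 1L) * fs / frame
  vapply(seq_len(n_frames), function(i) {
    seg <- x[((i - 1L) * hop + 1L):((i - 1L) * hop + frame)]
    mag <- Mod(stats::fft(seg))[seq_len(frame %/% 2L)]
    if (sum(mag) == 0) return(0)
    sum(freqs * mag) / sum(mag)
  }, numeric(1))
}

# scalar transcription of the LSTM gate equations (gate order i, f, g, o)
lstm_oracle <- function(X, Wx, Wh, b) {
  H <- nrow(Wh)
  T_ <- nrow(X)
  out <- matrix(0, T_, H)
  h <- numeric(H); cc <- numeric(H)
  sig <- function(v) 1 / (1 + exp(-v))
  for (t in seq_len(T_)) {
    a <- as.numeric(X[t, ] %*% Wx) + as.numeric(h %*% Wh) + b
    i <- sig(a[1:H]); f <- sig(a[(H + 1):(2 * H)])
    g <- tanh(a[(2 * H + 1):(3 * H)]); o <- sig(a[(3 * H + 1):(4 * H)])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    out[t, ] <- h
  }
  out
}

# full bilstm stack oracle: per layer sum of forward pass and reversed
# backward pass, then linear + softmax head
bilstm_oracle <- function(params, X, n_layers) {
  Z <- X
  for (l in seq_len(n_layers)) {
    lay <- params[[paste0("l", l)]]
    fwd <- lstm_oracle(Z, lay$fwd$Wx, lay$fwd$Wh, lay$fwd$b)
    rev_idx <- rev(seq_len(nrow(Z)))
    bwd <- lstm_oracle(Z[rev_idx, , drop = FALSE], lay$bwd$Wx, lay$bwd$Wh,
                       lay$bwd$b)
    Z <- fwd + bwd[rev_idx, , drop = FALSE]
  }
  logits <- Z %*% params$Wo + matrix(params$bo, nrow(Z), length(params$bo),
                                     byrow = TRUE)
  t(apply(logits, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
}

# brute-force per-class TP/TN/FP/FN tally from raw label pairs
brute_force_metrics <- function(truths, preds, K) {
  sens <- numeric(K)
  tp_total <- 0L
  for (k in seq_len(K)) {
    tp <- sum(truths == k & preds == k)
    fn <- sum(truths == k & preds != k)
    sens[k] <- 100 * tp / (tp + fn)
    tp_total <- tp_total + tp
  }
  list(accuracy = 100 * tp_total / length(truths), sensitivity = sens,
       uar = mean(sens))
}

# small labeled feature set with linearly separable classes (fast fixture for
# classifier mechanics; no audio synthesis involved)
toy_feature_set <- function(n_per_class = 10, n_frames = 20, K = 3, d = 26,
                            sep = 3, seed = 99) {
  pathovoice:::with_seed(seed, {
    centers <- matrix(rnorm(K * d), K, d) * sep
    feats <- list(); labs <- character(0)
    for (k in seq_len(K)) {
      for (i in seq_len(n_per_class)) {
        feats[[length(feats) + 1L]] <-
          matrix(rnorm(n_frames * d), n_frames, d) +
          matrix(centers[k, ], n_frames, d, byrow = TRUE)
        labs <- c(labs, paste0("class", k))
      }
    }
    list(features = feats, labels = factor(labs))
  })
}
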