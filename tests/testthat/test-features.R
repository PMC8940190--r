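test_that("frame counts follow the framing geometry", {
  fs <- 44100
  # 3 s at 44.1 kHz: frame 1411 samples, hop 706 -> 1 + floor((132300-1411)/706)
  x <- sin(2 * pi * 150 * seq_len(132300) / fs)
  frames <- preprocess_frames(x, fs = fs)
  expect_identical(nrow(frames), 1L + (132300L - 1411L) %/% 706L)
  expect_identical(nrow(frames), 186L)
  expect_identical(ncol(frames), 1411L)
  one <- preprocess_frames(rnorm(1411), fs = fs)
  expect_identical(nrow(one), 1L)
  expect_error(preprocess_frames(rnorm(1000), fs = fs), "shorter")
})

test_that("a constant frame without pre-emphasis reproduces the Hamming window", {
  cfg <- framing_config(preemph_coeff = 0)
  frames <- preprocess_frames(rep(1, 1411), cfg, fs = 44100)
  win <- 0.54 - 0.46 * cos(2 * pi * (0:1410) / 1410)
  expect_equal(as.numeric(frames[1, ]), win, tolerance = 1e-12)
})

test_that("mel scale and filterbank geometry are correct", {
  expect_equal(pathovoice:::hz_to_mel(1000), 2595 * log10(1 + 1000 / 700),
               tolerance = 1e-12)
  expect_lt(abs(pathovoice:::hz_to_mel(1000) - 999.99), 0.005)
  fb <- mel_filterbank(44100, 2048L, 26L)
  expect_identical(dim(fb$weights), c(26L, 1025L))
  expect_true(all(diff(fb$center_freqs) > 0))
  expect_true(all(fb$weights >= 0))
  # each filter rises monotonically to one maximum then falls
  unimodal <- apply(fb$weights, 1, function(w) {
    m <- which.max(w)
    all(diff(w[seq_len(m)]) >= 0) && all(diff(w[m:length(w)]) <= 0)
  })
  expect_true(all(unimodal))
  expect_error(mel_filterbank(44100, 128L, 60L), "n_filters")
})

test_that("delta operator returns slopes for ramps and zeros for constants", {
  const <- matrix(2, 10, 13)
  expect_true(all(delta(const) == 0))
  ramp <- outer(seq_len(10) * 0.5, rep(1, 13))
  d <- delta(ramp)
  expect_equal(unname(d[3:8, ]), matrix(0.5, 6, 13), tolerance = 1e-12)
  expect_true(all(delta(matrix(rnorm(13), 1, 13)) == 0))
})

test_that("MFCC output has 26 columns and silent input gives zero deltas", {
  x <- numeric(44100)
  m <- extract_mfcc(x, fs = 44100)
  expect_identical(ncol(m), 26L)
  expect_true(all(abs(m[, 14:26]) < 1e-10))
  expect_lt(max(abs(sweep(m[, 1:13], 2, m[1, 1:13]))), 1e-8)
})

test_that("static MFCCs match the independent numpy reference to 1e-3", {
  set.seed(41)
  w <- synth_utterance(utterance_spec("sustained_vowel", duration_s = 1),
                       disorder_profiles()$fd)
  m_r <- extract_mfcc(w)[, 1:13]
  in_csv <- tempfile(fileext = ".csv")
  out_csv <- tempfile(fileext = ".csv")
  write.table(w$samples, in_csv, row.names = FALSE, col.names = FALSE)
  oracle <- system.file("oracle", "mfcc_oracle.py", package = "pathovoice")
  status <- system2("python", c(oracle, in_csv, "44100", out_csv))
  expect_identical(status, 0L)
  m_py <- as.matrix(read.csv(out_csv, header = FALSE))
  expect_identical(dim(m_py), dim(m_r))
  expect_lt(max(abs(m_py - unname(m_r))), 1e-3)
  unlink(c(in_csv, out_csv))
})

test_that("shifting the input by one hop shifts the MFCC sequence by one frame", {
  set.seed(42)
  x <- synth_glottal_source(glottal_params(f0_mean = 150, jitter_pct = 1),
                            1.5, 44100)
  m1 <- extract_mfcc(x, fs = 44100)
  m2 <- extract_mfcc(x[707:length(x)], fs = 44100)
  k <- nrow(m2) - 4L
  # interior static frames align (deltas differ at edges by construction)
  expect_lt(max(abs(m1[2 + 2:k, 1:13] - m2[1 + 2:k, 1:13])), 1e-6)
})

test_that("amplitude scaling only shifts the statics by a DCT'd constant", {
  set.seed(43)
  x <- synth_glottal_source(glottal_params(f0_mean = 150), 0.5, 44100)
  m1 <- extract_mfcc(x, fs = 44100)
  g <- 0.5
  m2 <- extract_mfcc(g * x, fs = 44100)
  shift <- as.numeric(pathovoice:::dct_basis(13, 26) %*% rep(log(g^2), 26))
  expect_lt(max(abs(sweep(m2[, 1:13], 2, shift) - m1[, 1:13])), 1e-6)
  expect_lt(max(abs(m2[, 14:26] - m1[, 14:26])), 1e-6)
})

test_that("the truncated DCT is idempotent under re-projection", {
  B <- pathovoice:::dct_basis(13, 26)
  set.seed(44)
  c13 <- matrix(rnorm(5 * 13), 5, 13)
  back <- c13 %*% B          # reconstruct 26-dim log-mel approximation
  again <- back %*% t(B)
  expect_equal(again, c13, tolerance = 1e-12)
})

test_that("an empty speech mask is rejected", {
  x <- rnorm(44100, 0, 0.01)
  n_frames <- nrow(preprocess_frames(x, fs = 44100))
  expect_error(extract_mfcc(x, fs = 44100,
                            speech_mask = rep(FALSE, n_frames)),
               "no voiced content")
  expect_error(extract_mfcc(x, fs = 44100, speech_mask = c(TRUE, FALSE)),
               "does not match")
})
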