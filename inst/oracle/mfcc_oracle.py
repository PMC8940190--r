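"""Independent MFCC reference implementation (numpy/scipy).

Reads a single-column CSV of audio samples and writes the frames x 13 static
MFCC matrix as CSV. Configured identically to the R front end (32/16 ms
frames, Hamming window, pre-emphasis 0.97 applied to the whole signal, FFT
2048, 26 triangular mel filters spanning 0..fs/2 on m(f) = 2595 log10(1+f/700),
natural log floored at 1e-10, orthonormal DCT-II keeping coefficients 0-12)
but written as an independent vectorized code path for cross-validation of
the R implementation.

Usage: python mfcc_oracle.py <in.csv> <fs> <out.csv>
"""
import sys

import numpy as np
from scipy.fft import dct


def mfcc_static(x, fs, frame_ms=32, hop_ms=16, preemph=0.97, nfft=2048,
                n_mels=26, n_ceps=13, floor=1e-10):
    frame = round(frame_ms * fs / 1000)
    hop = round(hop_ms * fs / 1000)
    y = np.concatenate([[x[0]], x[1:] - preemph * x[:-1]])
    n_frames = 1 + (len(y) - frame) // hop
    idx = np.arange(frame)[None, :] + hop * np.arange(n_frames)[:, None]
    frames = y[idx] * np.hamming(frame)
    power = np.abs(np.fft.rfft(frames, nfft, axis=1)) ** 2

    def mel(f):
        return 2595 * np.log10(1 + f / 700)

    def imel(m):
        return 700 * (10 ** (m / 2595) - 1)

    pts = imel(np.linspace(0, mel(fs / 2), n_mels + 2))
    bins_hz = np.arange(nfft // 2 + 1) * fs / nfft
    fb = np.zeros((n_mels, nfft // 2 + 1))
    for i in range(n_mels):
        fl, fc, fr = pts[i], pts[i + 1], pts[i + 2]
        fb[i] = np.maximum(0, np.minimum((bins_hz - fl) / (fc - fl),
                                         (fr - bins_hz) / (fr - fc)))
    logmel = np.log(np.maximum(power @ fb.T, floor))
    return dct(logmel, type=2, norm="ortho", axis=1)[:, :n_ceps]


def main():
    in_csv, fs, out_csv = sys.argv[1], float(sys.argv[2]), sys.argv[3]
    x = np.loadtxt(in_csv, delimiter=",")
    np.savetxt(out_csv, mfcc_static(x, fs), delimiter=",")


if __name__ == "__main__":
    main()
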