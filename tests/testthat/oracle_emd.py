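"""Independent oracle EMD used only to cross-check the R implementation.

Deliberately written as a separate code path: scipy CubicSpline (not-a-knot
boundary) envelopes, simple argrelextrema-style extrema, and reflection
padding of the signal itself rather than of the extrema list.

Usage: python oracle_emd.py input.csv output.csv n_modes
"""
import sys

import numpy as np
from scipy.interpolate import CubicSpline


def extrema(x):
    d = np.diff(x)
    up = d > 0
    mx, mn = [], []
    for i in range(1, len(x) - 1):
        if x[i] > x[i - 1] and x[i] > x[i + 1]:
            mx.append(i)
        elif x[i] < x[i - 1] and x[i] < x[i + 1]:
            mn.append(i)
    return np.array(mx), np.array(mn)


def envelope_mean(x):
    n = len(x)
    pad = n // 4
    # reflect the signal around both ends, then interpolate extrema of the
    # padded signal -- a different boundary treatment from the package's
    # mirrored-extrema approach
    xp = np.concatenate([x[pad:0:-1], x, x[-2:-pad - 2:-1]])
    t = np.arange(len(xp)) - pad
    mx, mn = extrema(xp)
    if len(mx) < 2 or len(mn) < 2:
        return None
    upper = CubicSpline(t[mx], xp[mx])(np.arange(n))
    lower = CubicSpline(t[mn], xp[mn])(np.arange(n))
    return (upper + lower) / 2.0


def sift(x, q=0.25, max_iter=100):
    s1 = x.copy()
    for _ in range(max_iter):
        m = envelope_mean(s1)
        if m is None:
            return s1
        s2 = s1 - m
        if np.sum((s2 - s1) ** 2) / np.sum(s1 ** 2) < q:
            return s2
        s1 = s2
    return s1


def emd(x, n_modes):
    modes = []
    residual = x.copy()
    for _ in range(n_modes):
        mx, mn = extrema(residual)
        if len(mx) < 2 or len(mn) < 2:
            break
        imf = sift(residual)
        modes.append(imf)
        residual = residual - imf
    return np.array(modes)


if __name__ == "__main__":
    inp, outp, k = sys.argv[1], sys.argv[2], int(sys.argv[3])
    x = np.loadtxt(inp)
    np.savetxt(outp, emd(x, k), delimiter=",")
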