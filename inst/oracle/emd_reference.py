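#!/usr/bin/env python
"""Reference empirical mode decomposition used as an independent cross-check.

Classic sifting with cubic-spline envelopes (scipy CubicSpline, not-a-knot),
simple end-point extrema extension, and the standard Cauchy SD stopping
criterion. Reads a one-column text file of samples, writes the IMFs plus
residual as whitespace-separated columns to stdout.

Usage: python emd_reference.py signal.txt
"""
import sys

import numpy as np
from scipy.interpolate import CubicSpline


def local_extrema(x):
    d = np.diff(x)
    s = np.sign(d)
    nz = s != 0
    idx = np.where(nz)[0]
    if idx.size < 2:
        return np.array([], int), np.array([], int)
    ss = s[idx]
    chg = np.where(ss[:-1] != ss[1:])[0]
    mid = (idx[chg] + idx[chg + 1]) // 2 + 1
    return mid[ss[chg] > 0], mid[ss[chg] <= 0]


def envelope(idx, val, n):
    # extend with the two nearest extrema mirrored about each end
    k = min(2, idx.size)
    li = 2 * 0 - idx[:k][::-1]
    lv = val[:k][::-1]
    ri = 2 * (n - 1) - idx[-k:][::-1]
    rv = val[-k:][::-1]
    xi = np.concatenate([li, idx, ri])
    yi = np.concatenate([lv, val, rv])
    keep = np.concatenate([[True], np.diff(xi) > 0])
    cs = CubicSpline(xi[keep], yi[keep])
    return cs(np.arange(n))


def sift(x, sd_thresh=0.2, max_sift=100):
    h = x.copy()
    for _ in range(max_sift):
        mx, mn = local_extrema(h)
        if mx.size < 2 or mn.size < 2:
            break
        m = (envelope(mx, h[mx], h.size) + envelope(mn, h[mn], h.size)) / 2
        h1 = h - m
        sd = np.sum((h - h1) ** 2) / np.sum(h ** 2)
        h = h1
        if sd < sd_thresh:
            break
    return h


def emd(x, max_imf=12):
    imfs = []
    r = x.copy()
    while len(imfs) < max_imf:
        mx, mn = local_extrema(r)
        if mx.size < 2 or mn.size < 2:
            break
        c = sift(r)
        imfs.append(c)
        r = r - c
    return imfs, r


def main():
    x = np.loadtxt(sys.argv[1])
    imfs, r = emd(x)
    out = np.column_stack(imfs + [r])
    np.savetxt(sys.stdout, out, fmt="%.10e")


if __name__ == "__main__":
    main()
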