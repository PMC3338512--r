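# High-precision independent oracle for birth-death fixation probabilities.
# Reads JSON cases [{"beta": b, "delta": [d_1..d_{N-1}]}, ...] on stdin and
# writes one fixation probability per line. Each case is solved as a linear
# system: the tridiagonal absorption equations of the jump chain,
#   x_i = (1 - p_i) x_{i-1} + p_i x_{i+1},  x_0 = 0, x_N = 1,
# with p_i = 1 / (1 + exp(-beta * delta_i)), eliminated by the Thomas
# algorithm in 60-digit arithmetic so that extreme selection intensities do
# not lose precision.
import json
import math
import sys

import mpmath as mp


def solve_case(beta, delta):
    # intermediate quantities span exp(beta * (max S - min S)); give the
    # solver enough digits to resolve them, plus 50 guard digits
    S = 0.0
    smax = 0.0
    smin = 0.0
    for d in delta:
        S += d
        smax = max(smax, S)
        smin = min(smin, S)
    mp.mp.dps = 50 + int(math.ceil(beta * (smax - smin) / math.log(10.0)))
    beta = mp.mpf(beta)
    p = [1 / (1 + mp.e ** (-beta * mp.mpf(d))) for d in delta]
    n = len(p)
    # forward elimination on the tridiagonal system A x = b
    d = [mp.mpf(0)] * n
    c = [mp.mpf(0)] * n
    b = [mp.mpf(0)] * n
    d[0] = mp.mpf(1)
    c[0] = -p[0]
    b[n - 1] = p[n - 1]
    for i in range(1, n):
        w = -(1 - p[i]) / d[i - 1]
        d[i] = 1 - w * c[i - 1]
        c[i] = -p[i]
        b[i] = b[i] - w * b[i - 1]
    x = [mp.mpf(0)] * n
    x[n - 1] = b[n - 1] / d[n - 1]
    for i in range(n - 2, -1, -1):
        x[i] = (b[i] - c[i] * x[i + 1]) / d[i]
    return x[0]


cases = json.load(sys.stdin)
for case in cases:
    if len(case["delta"]) == 0:
        sys.stdout.write("1\n")
        continue
    rho = solve_case(case["beta"], case["delta"])
    sys.stdout.write(mp.nstr(rho, 25) + "\n")
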