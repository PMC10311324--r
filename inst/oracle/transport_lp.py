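"""Independent minimum-cost-transport oracle.

Reads a JSON file of instances [{"cost": [[...]], "p": [...], "q": [...]},
...] and prints one optimal transport cost per line. Each instance is solved
as an explicit linear program (HiGHS via scipy.optimize.linprog): variables
x_ij >= 0, minimize sum c_ij x_ij subject to row sums = p and column sums =
q. Used by the test suite to check that the L1 (classical) UniFrac distance
equals the 1-Wasserstein distance under tree-path costs; deliberately knows
nothing about trees or aggregation.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve(cost, p, q):
    c = np.asarray(cost, dtype=float)
    p = np.asarray(p, dtype=float)
    q = np.asarray(q, dtype=float)
    n, m = c.shape
    a_eq = []
    for i in range(n):
        row = np.zeros(n * m)
        row[i * m:(i + 1) * m] = 1.0
        a_eq.append(row)
    for j in range(m):
        col = np.zeros(n * m)
        col[j::m] = 1.0
        a_eq.append(col)
    b_eq = np.concatenate([p, q])
    res = linprog(c.ravel(), A_eq=np.vstack(a_eq), b_eq=b_eq,
                  bounds=(0, None), method="highs")
    if not res.success:
        raise RuntimeError(f"LP failed: {res.message}")
    return float(res.fun)


def main():
    with open(sys.argv[1]) as fh:
        instances = json.load(fh)
    for inst in instances:
        print(repr(solve(inst["cost"], inst["p"], inst["q"])))


if __name__ == "__main__":
    main()
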