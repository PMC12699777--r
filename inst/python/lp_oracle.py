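"""LP oracle for bounded minimum-cost circulations.

Reads a JSON list of problems (src/tgt 0-based arc endpoints, lower/upper
bounds, costs, node balances with positive = net supply), solves each as a
linear program with HiGHS (scipy.optimize.linprog), and writes a JSON list of
{feasible, objective, flow} results. Conservation is encoded as
(outflow - inflow)_v = balance_v over the node-arc incidence matrix; bounds
stay native per-variable bounds.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve_one(p):
    src = np.asarray(p["src"], dtype=int)
    tgt = np.asarray(p["tgt"], dtype=int)
    n = int(p["n_nodes"][0] if isinstance(p["n_nodes"], list) else p["n_nodes"])
    lower = np.asarray(p["lower"], dtype=float)
    upper = np.asarray(p["upper"], dtype=float)
    cost = np.asarray(p["cost"], dtype=float)
    balance = np.asarray(p["balance"], dtype=float)
    m = len(src)
    a_eq = np.zeros((n, m))
    for k in range(m):
        a_eq[src[k], k] += 1.0
        a_eq[tgt[k], k] -= 1.0
    res = linprog(cost, A_eq=a_eq, b_eq=balance,
                  bounds=list(zip(lower, upper)), method="highs")
    if res.status == 2:          # infeasible
        return {"feasible": False}
    if not res.success:
        raise RuntimeError(f"linprog failed with status {res.status}: {res.message}")
    return {"feasible": True, "objective": float(res.fun),
            "flow": [float(x) for x in res.x]}


def main(infile, outfile):
    with open(infile) as fh:
        problems = json.load(fh)
    out = [solve_one(p) for p in problems]
    with open(outfile, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
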