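"""Batch LP/MILP solving for the R front end.

Reads a JSON file holding a list of problems in sparse triplet form with
two-sided row bounds, solves each with HiGHS via scipy.optimize.milp, and
writes a JSON list of results. Values with magnitude >= 1e30 are treated
as infinite.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

BIG = 1e30
STATUS = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded"}


def deinf(arr):
    # atleast_1d: the JSON writer unboxes length-1 arrays to scalars
    a = np.atleast_1d(np.asarray(arr, dtype=float))
    a[a >= BIG] = np.inf
    a[a <= -BIG] = -np.inf
    return a


def solve_one(p):
    n = int(p["ncol"])
    m = int(p["nrow"])
    sign = -1.0 if p.get("maximize") else 1.0
    c = sign * np.atleast_1d(np.asarray(p["c"], dtype=float))
    constraints = []
    if m > 0:
        ai = np.atleast_1d(np.asarray(p.get("ai", []), dtype=int))
        aj = np.atleast_1d(np.asarray(p.get("aj", []), dtype=int))
        ax = np.atleast_1d(np.asarray(p.get("ax", []), dtype=float))
        A = sparse.csc_matrix((ax, (ai, aj)), shape=(m, n))
        constraints.append(LinearConstraint(A, deinf(p["rlb"]), deinf(p["rub"])))
    bounds = Bounds(deinf(p["lb"]), deinf(p["ub"]))
    integrality = np.atleast_1d(np.asarray(p.get("integer", [0] * n), dtype=int))
    options = {
        "presolve": True,
        "time_limit": float(p.get("time_limit", 600)),
        "mip_rel_gap": 0.0,
    }
    res = milp(c=c, constraints=constraints, bounds=bounds,
               integrality=integrality, options=options)
    out = {"status": STATUS.get(res.status, "error")}
    if res.x is not None:
        out["x"] = [float(v) for v in res.x]
        out["objective"] = sign * float(res.fun)
    bound = getattr(res, "mip_dual_bound", None)
    if bound is not None and np.isfinite(bound):
        out["bound"] = sign * float(bound)
    return out


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    results = [solve_one(p) for p in req["problems"]]
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
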