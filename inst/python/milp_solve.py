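"""Exact 0/1 ILP backend: reads a problem JSON, solves with HiGHS via
scipy.optimize.milp, writes a result JSON.

Problem JSON: {n, m, obj[], maximize, Ai[], Aj[], Av[] (1-based triplets),
rowlb[], rowub[] (|b| >= 1e29 means unbounded), timeLimit (seconds or null)}.
Result JSON: {status: optimal|infeasible|timeout|error, objective, x[], message}.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

BIG = 1e29


def main(infile, outfile):
    with open(infile) as fh:
        p = json.load(fh)
    n = p["n"]
    c = np.asarray(p["obj"], dtype=float)
    sign = -1.0 if p["maximize"] else 1.0
    A = sparse.csc_matrix(
        (np.asarray(p["Av"], dtype=float),
         (np.asarray(p["Ai"], dtype=int) - 1, np.asarray(p["Aj"], dtype=int) - 1)),
        shape=(p["m"], n))
    lb = np.asarray(p["rowlb"], dtype=float)
    ub = np.asarray(p["rowub"], dtype=float)
    lb[lb <= -BIG] = -np.inf
    ub[ub >= BIG] = np.inf
    options = {"mip_rel_gap": 0.0}
    if p.get("timeLimit") is not None:
        options["time_limit"] = float(p["timeLimit"])
    res = milp(c=sign * c,
               constraints=LinearConstraint(A, lb, ub),
               integrality=np.ones(n),
               bounds=Bounds(0, 1),
               options=options)
    status = {0: "optimal", 1: "timeout", 2: "infeasible",
              3: "error", 4: "error"}.get(res.status, "error")
    out = {"status": status, "message": str(res.message)}
    if res.x is not None:
        out["x"] = [float(round(v)) for v in res.x]
        out["objective"] = float(sign * res.fun)
    else:
        out["x"] = None
        out["objective"] = None
    with open(outfile, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
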