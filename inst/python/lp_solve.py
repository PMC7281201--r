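"""Independent LP backend: scipy.optimize.linprog (HiGHS).

Reads a JSON problem {c, A, b, lb, ub} from argv[1], writes a JSON result
{status, x, objective} to argv[2]. Used by the R package's tests as a
cross-check backend that shares no code with the internal simplex.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def main() -> None:
    with open(sys.argv[1]) as fh:
        prob = json.load(fh)
    c = np.asarray(prob["c"], dtype=float)
    A = np.asarray(prob["A"], dtype=float).reshape(len(prob["b"]), len(c))
    b = np.asarray(prob["b"], dtype=float)
    lb = np.asarray(prob["lb"], dtype=float)
    ub = np.asarray(prob["ub"], dtype=float)
    res = linprog(c, A_eq=A, b_eq=b, bounds=list(zip(lb, ub)),
                  method="highs")
    status = {0: "optimal", 2: "infeasible", 3: "unbounded"}.get(
        res.status, "error")
    out = {"status": status,
           "x": res.x.tolist() if res.x is not None else None,
           "objective": float(res.fun) if res.fun is not None else None}
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
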