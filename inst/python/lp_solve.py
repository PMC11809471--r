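"""Solve a batch of linear programs sharing one constraint matrix.

Reads a JSON problem file, solves with HiGHS through scipy.optimize
(linprog for continuous problems, milp when any variable is integral), and
writes a JSON result file.  Infinities are encoded as +/-1e30 on the wire.

Continuous problems use tightened feasibility/optimality tolerances: the
Chebyshev augmentation term is tiny (rho ~ 1e-6 per unit range) and must not
be lost to the default dual tolerance.

Usage: python lp_solve.py IN.json OUT.json
"""

import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, linprog, milp

BIG = 1e30
LP_OPTIONS = {
    "primal_feasibility_tolerance": 1e-9,
    "dual_feasibility_tolerance": 1e-9,
}


def _inf(a):
    a = np.atleast_1d(np.asarray(a, dtype=float))
    a[a >= BIG] = np.inf
    a[a <= -BIG] = -np.inf
    return a


def main(path_in, path_out):
    with open(path_in) as fh:
        spec = json.load(fh)

    n = int(spec["n"])
    lb = _inf(spec.get("lb", np.zeros(n)))
    ub = _inf(spec.get("ub", np.ones(n)))
    integrality = np.asarray(spec.get("integrality", np.zeros(n)), dtype=int)
    maximize = bool(spec.get("maximize", True))
    pure_lp = not integrality.any()

    rows = spec.get("rows", {})
    ri = np.atleast_1d(np.asarray(rows.get("ri", []), dtype=int))
    A = lower = upper = None
    if ri.size:
        ji = np.atleast_1d(np.asarray(rows["ji"], dtype=int))
        ai = np.atleast_1d(np.asarray(rows["ai"], dtype=float))
        m = int(ri.max()) + 1
        A = sparse.coo_matrix((ai, (ri, ji)), shape=(m, n)).tocsr()
        lower = _inf(rows["lower"])
        upper = _inf(rows["upper"])

    if pure_lp and A is not None:
        eq = np.where(lower == upper)[0]
        up = np.where((lower != upper) & np.isfinite(upper))[0]
        lo = np.where((lower != upper) & np.isfinite(lower))[0]
        A_eq = A[eq] if eq.size else None
        b_eq = upper[eq] if eq.size else None
        if up.size or lo.size:
            A_ub = sparse.vstack(
                ([A[up]] if up.size else []) + ([-A[lo]] if lo.size else [])
            )
            b_ub = np.concatenate(
                ([upper[up]] if up.size else []) + ([-lower[lo]] if lo.size else [])
            )
        else:
            A_ub = b_ub = None

    out = []
    for c in spec["objectives"]:
        c = np.atleast_1d(np.asarray(c, dtype=float))
        if pure_lp:
            res = linprog(
                c=-c if maximize else c,
                A_ub=A_ub if A is not None else None,
                b_ub=b_ub if A is not None else None,
                A_eq=A_eq if A is not None else None,
                b_eq=b_eq if A is not None else None,
                bounds=np.column_stack([lb, ub]),
                method="highs",
                options=LP_OPTIONS,
            )
        else:
            res = milp(
                c=-c if maximize else c,
                constraints=(LinearConstraint(A, lower, upper)
                             if A is not None else []),
                integrality=integrality,
                bounds=Bounds(lb, ub),
            )
        sol = {
            "success": bool(res.success),
            "status": int(res.status),
            "message": str(res.message),
        }
        if res.x is not None:
            sol["objective"] = float(-res.fun if maximize else res.fun)
            sol["x"] = [float(v) for v in res.x]
        out.append(sol)

    with open(path_out, "w") as fh:
        json.dump({"solutions": out}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
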