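"""Batch LP solver: reads a JSON list of LPs, solves each with scipy/HiGHS,
writes a JSON list of {status, objective}.

Problem schema (1-based sparse indices, column count n = len(c)):
  c: objective coefficients
  maximize: bool
  lb, ub: variable bounds; |x| >= 1e29 means unbounded
  Aeq: {i, j, v}, neq: equality rows (Aeq x = beq; beq defaults to 0)
  Aub: {i, j, v}, bub, nub: inequality rows (Aub x <= bub), optional
Status codes follow scipy.optimize.linprog (0 = optimal, 2 = infeasible).
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog
from scipy.sparse import coo_matrix

BIG = 1e29


def as_sparse(mat, nrow, ncol):
    if mat is None or nrow == 0:
        return None
    i = np.asarray(mat["i"], dtype=int) - 1
    j = np.asarray(mat["j"], dtype=int) - 1
    v = np.asarray(mat["v"], dtype=float)
    return coo_matrix((v, (i, j)), shape=(nrow, ncol)).tocsr()


def solve(p):
    c = np.atleast_1d(np.asarray(p["c"], dtype=float))
    n = c.size
    sense = -1.0 if p.get("maximize", True) else 1.0
    neq = int(p.get("neq", 0))
    nub = int(p.get("nub", 0))
    a_eq = as_sparse(p.get("Aeq"), neq, n)
    b_eq = None
    if a_eq is not None:
        b_eq = np.asarray(p.get("beq") or np.zeros(neq), dtype=float)
    a_ub = as_sparse(p.get("Aub"), nub, n)
    b_ub = np.asarray(p["bub"], dtype=float) if a_ub is not None else None
    lb = [None if x <= -BIG else x for x in np.atleast_1d(p["lb"])]
    ub = [None if x >= BIG else x for x in np.atleast_1d(p["ub"])]
    res = linprog(sense * c, A_ub=a_ub, b_ub=b_ub, A_eq=a_eq, b_eq=b_eq,
                  bounds=list(zip(lb, ub)), method="highs")
    obj = sense * res.fun if res.status == 0 else None
    return {"status": int(res.status), "objective": obj}


def main(inp, outp):
    with open(inp) as fh:
        problems = json.load(fh)["problems"]
    results = [solve(p) for p in problems]
    with open(outp, "w") as fh:
        json.dump({"results": results}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
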