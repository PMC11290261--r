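"""Least-absolute-deviation flux fitting as a linear program.

Reads a JSON problem description, solves one LAD LP per sample with
scipy's HiGHS backend, and writes a JSON solution. Invoked by the R
package; not a user-facing script.

Problem JSON:
  n_rxn            number of reactions
  S                {"i": [...], "j": [...], "x": [...]} 0-based triplets
  lb, ub           per-reaction flux bounds
  target_idx       0-based indices of reactions with an expression score
  ehat             list of per-sample score vectors (aligned to target_idx)
  tie_break        bool: run the second stage minimising total flux
  stage_tol        slack added to the stage-1 objective in stage 2

Each reaction is split into nonnegative forward/backward components
(vf, vb); the LAD objective compares the flux magnitude u = vf + vb with
the score, via deviation variables d >= |u - ehat|. Stage 2 re-minimises
total flux subject to the stage-1 optimum, making fluxes deterministic
across alternate optima.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import linprog


def solve_sample(A_eq, lbs, ubs, n_rxn, target_idx, ehat, tie_break, stage_tol):
    n_t = len(target_idx)
    n_var = 2 * n_rxn + n_t  # vf, vb, d

    bounds = []
    for j in range(n_rxn):  # vf_j
        bounds.append((max(lbs[j], 0.0), max(ubs[j], 0.0)))
    for j in range(n_rxn):  # vb_j
        bounds.append((max(-ubs[j], 0.0), max(-lbs[j], 0.0)))
    for _ in range(n_t):    # d_t
        bounds.append((0.0, None))

    # steady state: S vf - S vb = 0
    eq = sparse.hstack(
        [A_eq, -A_eq, sparse.csr_matrix((A_eq.shape[0], n_t))], format="csr")

    # deviations: u - d <= ehat ; -u - d <= -ehat  with u = vf + vb
    rows, cols, vals, rhs = [], [], [], []
    for t, j in enumerate(target_idx):
        r = 2 * t
        rows += [r, r, r]
        cols += [j, n_rxn + j, 2 * n_rxn + t]
        vals += [1.0, 1.0, -1.0]
        rhs.append(ehat[t])
        r += 1
        rows += [r, r, r]
        cols += [j, n_rxn + j, 2 * n_rxn + t]
        vals += [-1.0, -1.0, -1.0]
        rhs.append(-ehat[t])
    ub_mat = sparse.csr_matrix(
        (vals, (rows, cols)), shape=(2 * n_t, n_var))

    c1 = np.zeros(n_var)
    c1[2 * n_rxn:] = 1.0
    res = linprog(c1, A_ub=ub_mat, b_ub=rhs, A_eq=eq,
                  b_eq=np.zeros(eq.shape[0]), bounds=bounds, method="highs")
    if res.status != 0:
        return {"status": res.status, "message": res.message}
    objective = float(res.fun)

    if tie_break:
        c2 = np.zeros(n_var)
        c2[: 2 * n_rxn] = 1.0
        ub2 = sparse.vstack([ub_mat, sparse.csr_matrix(c1)], format="csr")
        rhs2 = list(rhs) + [objective + stage_tol]
        res2 = linprog(c2, A_ub=ub2, b_ub=rhs2, A_eq=eq,
                       b_eq=np.zeros(eq.shape[0]), bounds=bounds,
                       method="highs")
        if res2.status == 0:
            res = res2

    x = res.x
    v = x[:n_rxn] - x[n_rxn: 2 * n_rxn]
    return {"status": 0, "flux": v.tolist(), "objective": objective,
            "total_flux": float(np.sum(x[: 2 * n_rxn]))}


def as_list(x):
    """jsonlite unboxes length-1 arrays; restore list shape."""
    return x if isinstance(x, list) else [x]


def main(path_in, path_out):
    with open(path_in) as fh:
        prob = json.load(fh)
    n_rxn = int(prob["n_rxn"])
    S = sparse.csr_matrix(
        (as_list(prob["S"]["x"]),
         (as_list(prob["S"]["i"]), as_list(prob["S"]["j"]))),
        shape=(int(prob["n_met"]), n_rxn))
    out = []
    for ehat in as_list(prob["ehat"]):
        out.append(solve_sample(
            S, as_list(prob["lb"]), as_list(prob["ub"]), n_rxn,
            [int(t) for t in as_list(prob["target_idx"])], as_list(ehat),
            bool(prob.get("tie_break", True)),
            float(prob.get("stage_tol", 1e-9))))
    with open(path_out, "w") as fh:
        json.dump({"solutions": out}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
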