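"""Solve a sparse MILP written by the R side with HiGHS (scipy.optimize.milp).

Usage: python solve_milp.py <workdir>

Reads cols.csv (obj, lb, ub, integrality), rows.csv (lb, ub),
mat.csv (i, j, v; 1-based) and meta.json (ncol, nrow, mip_rel_gap,
time_limit); writes solution.csv (one column x) and info.json.
"""
import json
import os
import sys

import numpy as np
import pandas as pd
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

def main(workdir):
    with open(os.path.join(workdir, "meta.json")) as fh:
        meta = json.load(fh)
    cols = pd.read_csv(os.path.join(workdir, "cols.csv"))
    rows = pd.read_csv(os.path.join(workdir, "rows.csv"))
    mat = pd.read_csv(os.path.join(workdir, "mat.csv"))
    ncol, nrow = int(meta["ncol"]), int(meta["nrow"])
    A = sparse.csc_matrix(
        (mat["v"].to_numpy(),
         (mat["i"].to_numpy() - 1, mat["j"].to_numpy() - 1)),
        shape=(nrow, ncol))
    con = LinearConstraint(A, rows["lb"].to_numpy(), rows["ub"].to_numpy())
    bounds = Bounds(cols["lb"].to_numpy(), cols["ub"].to_numpy())
    options = {
        "presolve": True,
        "mip_rel_gap": float(meta.get("mip_rel_gap", 1e-4)),
        "disp": bool(meta.get("verbose", False)),
    }
    if meta.get("time_limit"):
        options["time_limit"] = float(meta["time_limit"])
    res = milp(c=cols["obj"].to_numpy(), constraints=con, bounds=bounds,
               integrality=cols["integrality"].to_numpy(), options=options)
    info = {
        "status": int(res.status),
        "message": str(res.message),
        "success": bool(res.success),
        "fun": None if res.fun is None else float(res.fun),
        "mip_dual_bound": None if getattr(res, "mip_dual_bound", None) is None
        else float(res.mip_dual_bound),
        "mip_gap": None if getattr(res, "mip_gap", None) is None
        else float(res.mip_gap),
        "mip_node_count": None if getattr(res, "mip_node_count", None) is None
        else int(res.mip_node_count),
    }
    if res.x is not None:
        np.savetxt(os.path.join(workdir, "solution.csv"), res.x, fmt="%.12g")
    with open(os.path.join(workdir, "info.json"), "w") as fh:
        json.dump(info, fh)

if __name__ == "__main__":
    main(sys.argv[1])
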