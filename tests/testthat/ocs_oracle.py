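"""Independent oracle for the contribution-selection program.

Solves  max u'c  s.t.  c'Gc/2 <= theta, sum(c[F]) = sum(c[M]) = 0.5,
c >= 0  with scipy's SLSQP (the problem is convex, so the local optimum is
global). Reads a JSON problem {u, G, is_male, theta} on argv[1], writes
{objective, c} as JSON to stdout.
"""
import json
import sys

import numpy as np
from scipy.optimize import minimize

with open(sys.argv[1]) as fh:
    prob = json.load(fh)

u = np.asarray(prob["u"], dtype=float)
G = np.asarray(prob["G"], dtype=float)
male = np.asarray(prob["is_male"], dtype=bool)
theta = float(prob["theta"])
n = u.size

s = male.astype(float)
d = 1.0 - s
x0 = 0.5 * (d / d.sum() + s / s.sum())

cons = [
    {"type": "eq", "fun": lambda c: c @ s - 0.5, "jac": lambda c: s},
    {"type": "eq", "fun": lambda c: c @ d - 0.5, "jac": lambda c: d},
    {"type": "ineq", "fun": lambda c: theta - 0.5 * c @ G @ c,
     "jac": lambda c: -G @ c},
]
res = minimize(lambda c: -(u @ c), x0, jac=lambda c: -u, method="SLSQP",
               bounds=[(0.0, 1.0)] * n, constraints=cons,
               options={"maxiter": 2000, "ftol": 1e-14})

# status 8 ("positive directional derivative for linesearch") at a feasible
# point means the very tight ftol cannot be improved on: the point is optimal
# to working precision
feasible = (abs(res.x @ s - 0.5) < 1e-8 and abs(res.x @ d - 0.5) < 1e-8
            and res.x.min() > -1e-8
            and 0.5 * res.x @ G @ res.x <= theta + 1e-8)
ok = bool(res.success or (res.status == 8 and feasible))

json.dump({"objective": float(u @ res.x), "c": res.x.tolist(),
           "success": ok}, sys.stdout)
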