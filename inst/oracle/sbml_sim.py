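"""Independent SBML integrator used as a cross-simulator oracle in tests.

Parses standard SBML Level 3 structure only (species, reactions, species
references with stoichiometry, modifiers, local kinetic-law parameters) and
integrates mass-action / Michaelis-Menten kinetics with scipy's stiff LSODA
solver. Deliberately shares no code with the R implementation.

Usage: python sbml_sim.py MODEL.sbml T_END N_POINTS OUT.csv
"""
import sys

import numpy as np
from lxml import etree
from scipy.integrate import solve_ivp


def local_params(rxn):
    out = {}
    for lp in rxn.iter("{*}localParameter"):
        out[lp.get("id")] = float(lp.get("value"))
    return out


def refs(rxn, tag):
    lst = rxn.find("{*}" + tag)
    if lst is None:
        return []
    out = []
    for ref in lst.findall("{*}speciesReference"):
        sto = int(float(ref.get("stoichiometry", "1")))
        out.extend([ref.get("species")] * sto)
    return out


def main(path, t_end, n_points, out_csv):
    tree = etree.parse(path)
    root = tree.getroot()
    species = []
    y0 = []
    for sp in root.iter("{*}species"):
        species.append(sp.get("id"))
        y0.append(float(sp.get("initialConcentration", "0")))
    idx = {s: i for i, s in enumerate(species)}
    n = len(species)

    processes = []  # (kind, k, indices..., stoich vector)
    for rxn in root.iter("{*}reaction"):
        pars = local_params(rxn)
        reac = [idx[s] for s in refs(rxn, "listOfReactants")]
        prod = [idx[s] for s in refs(rxn, "listOfProducts")]
        mods = [idx[m.get("species")]
                for m in rxn.iter("{*}modifierSpeciesReference")]
        if rxn.get("reversible") == "true":
            col = np.zeros(n)
            for i in reac:
                col[i] -= 1
            for i in prod:
                col[i] += 1
            processes.append(("mass", pars["kon"], reac, col))
            processes.append(("mass", pars["koff"], prod, -col))
        else:
            col = np.zeros(n)
            for i in reac:
                col[i] -= 1
            for i in prod:
                col[i] += 1
            e, s = mods[0], reac[0]
            if "Km" in pars:
                processes.append(("mm", pars["kcat"], (e, s, pars["Km"]), col))
            else:
                processes.append(("mass", pars["kcat"], [e, s], col))

    def rhs(t, y):
        dy = np.zeros(n)
        for kind, k, ix, col in processes:
            if kind == "mass":
                v = k
                for i in ix:
                    v *= y[i]
            else:
                e, s, km = ix
                v = k * y[e] * y[s] / (km + y[s])
            dy += v * col
        return dy

    t_eval = np.linspace(0.0, t_end, n_points)
    sol = solve_ivp(rhs, (0.0, t_end), np.array(y0), method="LSODA",
                    t_eval=t_eval, rtol=1e-10, atol=1e-10)
    if not sol.success:
        sys.exit("integration failed: " + sol.message)
    with open(out_csv, "w") as fh:
        fh.write("time," + ",".join(species) + "\n")
        for j, t in enumerate(sol.t):
            fh.write(",".join([repr(float(t))] +
                              [repr(float(v)) for v in sol.y[:, j]]) + "\n")


if __name__ == "__main__":
    main(sys.argv[1], float(sys.argv[2]), int(sys.argv[3]), sys.argv[4])
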