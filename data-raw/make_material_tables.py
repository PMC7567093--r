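#!/usr/bin/env python
"""Generate the embedded material coefficient tables (inst/extdata/materials).

Sources: NIST X-ray mass attenuation tables (Hubbell & Seltzer) for elemental
mu/rho and mu_en/rho at the standard grid energies; compound values by the
mixture rule over mass fractions. delta is computed from the electron density
(far from absorption edges f1 ~ Z for low-Z elements); beta from the total
linear attenuation via beta = mu * lambda / (4 pi). Knot values are densified
to a 1 keV grid with a cubic spline in log-log coordinates; the R package then
interpolates that grid log-log linearly (knot-exact).

Run from the repository root:  python data-raw/make_material_tables.py
"""

import json
import os

import numpy as np
from scipy.interpolate import CubicSpline

KEV_KNOTS = np.array([10.0, 15.0, 20.0, 30.0, 40.0, 50.0, 60.0])

# Elemental mass attenuation / mass energy-absorption coefficients, cm^2/g,
# at the knot energies (NIST standard grid).
ELEMENTS = {
    # symbol: (Z, A, mu_over_rho, mu_en_over_rho)
    "H": (1, 1.008,
          [0.3854, 0.3764, 0.3695, 0.3570, 0.3458, 0.3355, 0.3260],
          [0.009849, 0.01102, 0.01355, 0.01863, 0.02315, 0.02709, 0.03053]),
    "C": (6, 12.011,
          [2.373, 0.8071, 0.4420, 0.2562, 0.2076, 0.1871, 0.1753],
          [2.078, 0.5627, 0.2238, 0.06614, 0.03343, 0.02397, 0.02098]),
    "N": (7, 14.007,
          [3.879, 1.236, 0.6178, 0.3066, 0.2288, 0.1980, 0.1803],
          [3.534, 0.971, 0.3829, 0.1090, 0.0500, 0.0315, 0.0245]),
    "O": (8, 15.999,
          [5.952, 1.836, 0.8651, 0.3779, 0.2585, 0.2132, 0.1907],
          [5.565, 1.546, 0.6180, 0.1730, 0.0753, 0.04414, 0.0321]),
}

# Trace elements (<= 0.5 wt% of any material): photoelectric power law
# anchored at the 10 keV NIST value plus a flat Compton term.
TRACES = {
    # symbol: (Z, A, pe10, compton)
    "Na": (11, 22.990, 15.0, 0.185),
    "P": (15, 30.974, 39.5, 0.190),
    "S": (16, 32.06, 49.5, 0.190),
    "Cl": (17, 35.45, 57.3, 0.185),
}
for sym, (Z, A, pe10, c) in TRACES.items():
    mu = pe10 * (10.0 / KEV_KNOTS) ** 2.95 + c
    muen = 0.95 * pe10 * (10.0 / KEV_KNOTS) ** 2.95 + 0.02
    ELEMENTS[sym] = (Z, A, mu.tolist(), muen.tolist())

# Dry air (near sea level) kept as a direct NIST material table (the Ar
# component would otherwise dominate the mixture-rule uncertainty).
AIR_MU = [5.120, 1.614, 0.7779, 0.3538, 0.2485, 0.2080, 0.1875]
AIR_MUEN = [4.742, 1.334, 0.5389, 0.1537, 0.06833, 0.04098, 0.03041]
AIR_ZA = 0.499069  # mass-fraction-weighted Z/A of dry air

MATERIALS = {
    # name: (density g/cm^3, {element: mass fraction}, provenance note)
    "adipose": (0.93,
                {"H": 0.112, "C": 0.619, "N": 0.017, "O": 0.251, "P": 0.001},
                "Hammerstein adipose composition; NIST elemental tables"),
    "glandular": (1.04,
                  {"H": 0.102, "C": 0.184, "N": 0.032, "O": 0.677, "P": 0.005},
                  "Hammerstein glandular composition; NIST elemental tables"),
    "polyethylene": (0.93,
                     {"H": 0.143711, "C": 0.856289},
                     "(C2H4)n at rho = 0.93 g/cm^3; NIST elemental tables"),
    "breast_icru44": (1.02,
                      {"H": 0.106, "C": 0.332, "N": 0.030, "O": 0.527,
                       "Na": 0.001, "P": 0.001, "S": 0.002, "Cl": 0.001},
                      "ICRU Report 44 breast tissue; NIST elemental tables"),
    "air": (1.20479e-3, None, "NIST dry air (near sea level) material table"),
}

HC_KEV_NM = 1.2398420  # keV * nm
R_E = 2.8179403262e-15  # classical electron radius, m
N_A = 6.02214076e23

E_OUT = np.arange(10.0, 50.0 + 0.5, 1.0)


def loglog_spline(knots_y):
    cs = CubicSpline(np.log(KEV_KNOTS), np.log(np.asarray(knots_y)))
    return np.exp(cs(np.log(E_OUT)))


def mixture(fracs, which):
    tot = np.zeros_like(KEV_KNOTS)
    for sym, w in fracs.items():
        tot += w * np.asarray(ELEMENTS[sym][2 if which == "mu" else 3])
    return tot


def electron_za(fracs):
    if fracs is None:
        return AIR_ZA
    return sum(w * ELEMENTS[sym][0] / ELEMENTS[sym][1]
               for sym, w in fracs.items())


def main():
    outdir = os.path.join(os.path.dirname(__file__), "..",
                          "inst", "extdata", "materials")
    os.makedirs(outdir, exist_ok=True)
    index = {}
    for name, (rho, fracs, note) in MATERIALS.items():
        if fracs is None:
            mu_rho_k, muen_rho_k = AIR_MU, AIR_MUEN
        else:
            mu_rho_k = mixture(fracs, "mu")
            muen_rho_k = mixture(fracs, "muen")
        mu_rho = loglog_spline(mu_rho_k)
        muen_rho = loglog_spline(muen_rho_k)

        lam = HC_KEV_NM / E_OUT * 1e-9  # m
        n_e = rho * 1e6 * N_A * electron_za(fracs)  # electrons / m^3
        delta = R_E * lam ** 2 * n_e / (2.0 * np.pi)
        mu_per_m = mu_rho * rho * 100.0
        beta = mu_per_m * lam / (4.0 * np.pi)

        path = os.path.join(outdir, name + ".csv")
        with open(path, "w") as fh:
            fh.write("energy_keV,mu_over_rho_cm2_g,mu_en_over_rho_cm2_g,"
                     "delta,beta\n")
            for i, e in enumerate(E_OUT):
                fh.write("%.1f,%.6e,%.6e,%.6e,%.6e\n"
                         % (e, mu_rho[i], muen_rho[i], delta[i], beta[i]))
        index[name] = {"density_g_cm3": rho, "provenance": note}
        print("wrote", path)

    with open(os.path.join(outdir, "index.json"), "w") as fh:
        json.dump(index, fh, indent=1)
        fh.write("\n")


if __name__ == "__main__":
    main()
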