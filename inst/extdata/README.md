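# Embedded constants — provenance

`nuclear_constants.json` is the versioned, human-readable constants file
loaded once per session by `bnctsim`. Nothing is downloaded at run time.

* **Atomic masses** (`nuclides`, atomic mass units): AME2020 atomic mass
  evaluation, kept to >= 9 significant figures. Atomic (not bare-nucleus)
  masses are stored; electron masses cancel in every charge-conserving
  reaction used here.
* **Physical constants** (`physical`): CODATA 2018 (amu-to-MeV conversion,
  Avogadro constant, elementary charge, vacuum permittivity, Boltzmann
  constant).
* **Li-7 first excited level** 477.61 keV: ENSDF adopted level; this is the
  0.478 MeV de-excitation photon of the dominant B-10 capture branch.
* **B-10(n,alpha) branching** 93.9% / 6.1%: standard evaluated branching of
  the excited-state versus ground-state Li-7 exit channel at thermal energy.
* **Thermal-point cross sections** (barns at 0.025 eV): standard evaluated
  2200 m/s values — B-10(n,alpha) 3837 b, H-1(n,gamma) 0.332 b,
  N-14(n,p) 1.83 b, all treated as 1/v; free-atom elastic cross sections
  H 20.4 b, C 4.7 b, N 10.0 b, O 3.8 b, treated as constant below 10 keV
  (ENDF/B thermal region values). O-16 capture is deliberately flagged
  `negligible` (sigma = 0).
* **Tissue**: ICRU four-component soft tissue by mass (H 10.1%, C 11.1%,
  N 2.6%, O 76.2%), density 1.0 g/cm^3. B-10 loading renormalises the other
  fractions.
* **Photon first-interaction coefficients** (`gamma_attenuation_per_cm`,
  water at unit density): 0.0967 cm^-1 at 0.478 MeV and 0.0455 cm^-1 at
  2.224 MeV (NIST XCOM attenuation coefficients); used only by the optional
  `"kernel"` gamma-deposition policy.

Bump `version` whenever a number changes; run records carry the version.
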