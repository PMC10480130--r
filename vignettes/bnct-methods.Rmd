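---
title: "Models and methods: BNCT source kinematics and depth-dose transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: BNCT source kinematics and depth-dose transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bnctsim` is a desk-scale physics package for boron neutron capture therapy
(BNCT) studies: the two-body kinematics of the neutron-producing fusion
reactions and of the B-10 capture channels, the space-charge-limited
ion-extraction design relation of a compact D-D/D-T generator, and a
from-scratch Monte Carlo neutron transport engine that resolves the boron
versus non-boron depth-dose decomposition in a boron-loaded tissue
cylinder. This vignette records the models, their assumptions, the numerical
choices, and the known limitations.

## Nuclear data

All constants ship in `inst/extdata/nuclear_constants.json` (AME2020 atomic
masses, CODATA physical constants, evaluated 2200 m/s cross-section points;
see the README next to it for provenance). Q-values are recomputed from the
masses at call time rather than stored, so every energy in the package is
traceable to the mass table:

```{r}
library(bnctsim)
reaction_channels("n+B10")
```

Thermal neutron capture on B-10 proceeds through two exit channels of the
compound nucleus: 93.9% through the Li-7 first excited level (2.31 MeV to
the charged pair, then a 0.478 MeV photon) and 6.1% directly to the ground
state (2.79 MeV, no photon). Capture cross sections follow the 1/v law
anchored at 0.025 eV — B-10(n,alpha) 3837 b, H-1(n,gamma) 0.332 b,
N-14(n,p) 1.83 b — and elastic scattering uses the free-atom constants
(H 20.4, C 4.7, N 10.0, O 3.8 b) treated as energy-independent below
10 keV, which brackets every source this package models. O-16 capture is
deliberately negligible (`sigma = 0`).

The tissue is the ICRU four-component soft tissue (H 10.1%, C 11.1%,
N 2.6%, O 76.2% by mass, 1.0 g/cm^3); this composition is an assumption —
no stoichiometry is fixed by the problem statement — and it is recorded in
every run's metadata. B-10 loading in mass ppm renormalises the other
fractions; 35 ppm corresponds to a number density of about 2.1e18 cm^-3,
or ~1e9 atoms in a 10 um cell (`atoms_per_cell(35, 10)`), the loading
scale generally quoted as therapeutically necessary.

## Two-body kinematics

For a reaction at rest releasing `Q` between two products, momentum
conservation fixes `E_light = Q m_heavy / (m_light + m_heavy)`
(`partition_at_rest()`). This one formula reproduces all eight product
energies the package quotes: 1.47/0.84 and 1.78/1.01 MeV for the two
capture branches, 2.45/0.82 MeV for D-D, 14.05/3.54 MeV for D-T.

With a moving deuteron (kinetic energy `E_d`, emission angle `theta`), the
neutron energy follows the standard non-relativistic emission-angle
formula, a quadratic in `sqrt(E_n)`:

$$\sqrt{E_n} = \frac{\sqrt{m_d m_n E_d}\,\cos\theta +
\sqrt{m_d m_n E_d \cos^2\theta + (m_B + m_n)\,[m_B Q + (m_B - m_d) E_d]}}
{m_B + m_n}$$

with `m_B` the heavy product. Note the `(m_B + m_n)` factor inside the
radical: a transcription of this formula sometimes circulates with a
product `(m_B m_n)` there, which is dimensionally inconsistent; the
corrected standard form is implemented and verified, everywhere sampled,
against `conservation_oracle()` — a numeric solver that root-finds the
recoil angle on the momentum triangle and knows nothing of the closed
form. Agreement is better than 1e-6 relative on a 50 x 50 grid over
`E_d` in [0.01, 0.5] MeV and `theta` in [0, pi].

For exothermic reactions only the `+` root is physical; the `-` root is
exposed but returns `NA` here. Design choices: non-relativistic kinematics
(0.5 MeV deuterons are 0.03% of their rest mass; a relativistic variant
was judged not worth its surface), and comparisons with tabulated values
round to 2 decimals for product energies and 2 significant figures for
envelope endpoints.

`energy_envelope()` scans the surface over `E_d` in [0.2, 0.5] MeV: the
maximum, 3.5 MeV, occurs forward at the top deuteron energy, matching the
design table of the generator prototype. The scan minimum is 1.89 MeV at
(0.5 MeV, pi), while the design table quotes 1.8 MeV as its lower bound;
the package reports the computed 1.89 and does not attempt to guess which
convention produced the tabulated figure.

## Ion extraction gap (Child-Langmuir)

For the planar extraction gap of a compact generator, space-charge-limited
flow gives `J = (4/9) eps0 sqrt(2q/m) V^{3/2} / d^2`. `matched_gap()`
solves for the electrode distance `d` at which the gap just transports the
plasma-supplied current density (default 5 mA/cm^2, the prototype design
value): `d` grows as `V^{3/4}` at fixed `J` and shrinks as `m^{-1/4}` for
heavier ions. At 100 kV and 5 mA/cm^2 of D+ the matched gap is 0.156 m.
A plasma-meniscus (Boltzmann) correction is not reconstructable at this
level of description; a multiplicative `calibration` factor (default 1) is
exposed instead. `classify_beam()` labels a gap within 5% of matched as
"parallel"; which off-matched side is "convergent" versus "divergent" is a
documented convention (smaller-than-matched = convergent: the
space-charge-limited current exceeds the plasma supply and the meniscus is
concave), not asserted physics.

## Monte Carlo transport

`run_transport()` tracks monoenergetic, monodirectional neutrons (pencil
beam on the axis by default; a uniform disc beam is available) through a
homogeneous cylinder — default 10 cm long, 5 cm in diameter ("5 cm wide"
read as diameter), 0.25 cm depth bins. Analog transport, no variance
reduction:

* **Free flights** are exponential on the total macroscopic cross section
  at the current energy. The elastic constants are used as-is at all
  energies (the constant-below-10-keV model); setting
  `effective_sigma = TRUE` instead applies the free-gas effective
  (Doppler-averaged) elastic cross section below the thermal cutoff, the
  self-consistent companion of the scattering model below. The default
  follows the constant-sigma model; the thermal-beam depth-of-maximum
  moves by about one bin between the two.
* **Elastic scattering** is isotropic in the centre of mass. Above 4 eV
  the target is stationary; at or below 4 eV the target velocity is
  sampled from the collision-rate-weighted Maxwellian at 293.6 K (the
  standard free-gas rejection scheme), which permits up-scatter and drives
  the spectrum to thermal equilibrium.
* **Capture** follows 1/v and terminates the history. B-10 splits
  `Q + E_n` between the alpha and Li-7 by momentum conservation and emits
  the 0.478 MeV photon on the 93.9% branch; N-14(n,p) deposits its 0.63 MeV
  partition; H(n,gamma) emits 2.22 MeV and leaves a ~1.3 keV deuteron
  recoil.
* **Charged products deposit locally** (kerma approximation): alpha and
  Li-7 ranges are 5–9 um against 0.25 cm bins, so range transport would
  change nothing at this resolution.
* **Photons** follow a policy. Default `"discard"`: capture photons are
  produced and logged but excluded from dose, which makes the boron dose
  and every depth-of-maximum result photon-independent. `"local"` deposits
  them at the capture site; `"kernel"` transports them one exponential
  first-interaction flight using embedded water attenuation coefficients
  (0.0967 /cm at 0.478 MeV, 0.0455 /cm at 2.22 MeV) — a deliberately
  coarse model for total-dose shape studies only.

Omitted on purpose: inelastic scattering and fission (negligible below
10 keV in tissue), S(alpha,beta) molecular-binding thermal-scattering data,
3-D voxel phantoms, and RBE/CBE treatment-planning weights.

### Scoring, errors and the energy ledger

Dose is scored per depth slab over the full cylinder cross-section (no
radial scoring region is specified for the reference setup) in seven
components: `boron_alpha`, `boron_li7`, `capture_gamma`, `proton_recoil`,
`n14_proton`, `c14_recoil`, `other_recoil`; boron dose = alpha + Li-7.
Doses are Gy per source neutron; standard errors come from per-history
sums and their squares.

Every history closes an energy ledger to better than 1e-6 relative:
incident kinetic energy + released Q + thermal-bath gain = deposited +
escaped + discarded photon energy. The bath term exists because a free-gas
collision can up-scatter the neutron; that gain is booked as input energy
from the 293.6 K medium rather than as a negative recoil dose, keeping all
bin deposits non-negative. The maximum per-history residual is carried in
the run metadata and asserted in the test suite.

Reproducibility: each history owns a counter-seeded xoshiro256** stream
derived from `(seed, history index)`, so a run is bit-identical for a
fixed seed and history `i` is the same neutron regardless of batch size;
nothing touches R's global RNG.

### What the synthetic scenarios emulate — and what they do not

The `preset()` registry reproduces the reference irradiation conditions:
0.025 eV thermal and 1 eV–10 keV epithermal monodirectional beams into the
10 x 5 cm tissue cylinder at 35/50/100 ppm. Reduced-scale runs (1e4
histories, the `"ci"` profile, about 0.1 s each) exercise every code path;
the depth-of-maximum results use 2e5 histories (the `"paper"` profile,
about 1–2 s each on one CPU). Toy fixtures provide analytic oracles: a
scattering-free pure absorber whose capture depth density is exactly
`Sigma_a exp(-Sigma_a z)`, and zero-density materials that must transport
without interacting.

With these conditions the thermal 0.025 eV / 35 ppm run places the boron
dose maximum at 0.375–0.625 cm depending on seed and sigma mode (the
profile top is flat at the 4% level), consistent with the ~0.5 cm expected
for a thermal beam. The 1 eV run places it near 0.9 cm and the 10 keV run
near 2.1–2.4 cm. Reference calculations of the same geometry run with a
production code carrying molecular-binding S(alpha,beta) data place the
1 eV and 10 keV maxima deeper (about 1.5 and 3.0 cm): bound-water physics
both suppresses energy transfer per collision as neutrons approach the
molecular levels (slower 1 eV -> thermal moderation, hence deeper
thermalization) and shortens the thermal diffusion scale. A free-gas model
cannot reproduce that combination, so passing tests here validate the
free-gas transport model against its own analytic properties — they do not
certify agreement with bound-water codes for epithermal penetration
depths. The thermal-beam depth structure, the boron/total decomposition,
the ppm self-shielding (sub-linear dose growth beyond ~2 cm and
convergence of the concentration curves at depth), and the two-orders
falloff beyond 8 cm are all reproduced.

Other degrees of freedom that were left fixed deliberately: "5 cm wide"
is read as diameter (reading it as radius deepens the epithermal maximum
by roughly one bin by reducing side leakage); the beam is a pencil on the
axis (a full-face disc beam shifts maxima shallower by about one bin).

### Numerical choices and degenerate inputs

* Bin width 0.25 cm, configurable; the reported depth-of-maximum is a bin
  centre, so it is quantised to 0.125 + k * 0.25 cm.
* Free-gas cutoff 4 eV, temperature 293.6 K, both configurable.
* `partition_at_rest(0, ...)` returns (0, 0); negative Q errors (capture
  below threshold is not modeled).
* The conservation oracle brackets sign changes on an 4001-point angular
  grid before `uniroot` (tolerance 1e-12); when the quadratic admits two
  crossings the larger-energy one is the physical `+` branch.
* Zero-density materials transport to the boundary ("infinite free path")
  and score zero dose; `summarize_profile()` reports an explicit empty
  summary for all-zero profiles.
* A history is hard-capped at 1e6 collisions; reaching the cap is an
  error, not a truncation.

## Limitations

Free-gas thermal scattering versus molecular binding is the dominant model
limitation (above). Photon transport is first-interaction at best, so
total-dose curves under `"kernel"` are qualitative. Cross sections carry
no resonance structure (irrelevant below 10 keV for these nuclides).
Absolute dose levels depend on the ICRU composition assumption and on the
kerma treatment; depth structure and component decomposition are the
quantities this package is built to resolve.
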