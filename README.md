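# bnctsim

Desk-scale physics for **boron neutron capture therapy (BNCT)** source and
dose studies, aimed at medical-physics researchers prototyping a compact
accelerator-based neutron source: which neutron energies a D-D/D-T
generator can deliver, how its ion-extraction gap must be sized, and where
in tissue the therapeutic boron dose lands.

BNCT irradiates B-10-loaded tissue with low-energy neutrons; the capture
reaction

```
n + B-10 -> [B-11]* -> alpha (1.47 MeV) + Li-7 (0.84 MeV) + gamma (0.478 MeV)   (93.9%)
                    -> alpha (1.78 MeV) + Li-7 (1.01 MeV)                        (6.1%)
```

confines its high-LET charged products within roughly a cell diameter, so
the dose localises to boron-loaded cells. The package implements, from its
own embedded nuclear constants:

* **Two-body reaction kinematics** — the at-rest partition
  `E_light = Q m_heavy/(m_light + m_heavy)` for the capture channels and
  the D-D / D-T fusion sources (2.45/0.82 and 14.05/3.54 MeV), the
  emission-angle formula
  `sqrt(E_n) = [sqrt(m_d m_n E_d) cos(theta) + sqrt(m_d m_n E_d cos^2(theta) + (m_B + m_n)(m_B Q + (m_B - m_d) E_d))]/(m_B + m_n)`,
  and an independent numeric four-momentum conservation oracle
  (agreement < 1e-6 everywhere sampled).
* **Child-Langmuir extraction design** — the space-charge-matched
  electrode gap `d = sqrt((4 eps0/9J) sqrt(2q/m) V^(3/2))` with
  parallel/convergent/divergent classification.
* **Monte Carlo neutron transport** — analog transport in a boron-loaded
  ICRU soft-tissue cylinder (10 cm x 5 cm diameter): 1/v capture,
  isotropic-CM elastic scattering with free-gas target motion at 293.6 K
  below 4 eV, kerma deposition of charged products, per-history energy
  ledger, and boron versus non-boron depth-dose decomposition in 0.25 cm
  bins.

## Worked example

```r
library(bnctsim)

# capture-channel energetics from the embedded masses
ch <- reaction_channels("n+B10")
partition_at_rest(ch$Q_MeV[ch$channel == "excited"],
                  nuclide_mass_u("He-4"), nuclide_mass_u("Li-7"))
#>   E_light   E_heavy
#> 1.4723869 0.8399911        # the 1.47 MeV alpha and 0.84 MeV Li-7

# design envelope of a 0.5 MeV deuteron beam on a deuterium target
neutron_energy(0.5, 0, "dd")
#> [1] 3.512828               # forward neutrons reach 3.5 MeV

# matched extraction gap at 100 kV, 5 mA/cm^2 of D+
matched_gap(5, 1e5)
#> [1] 0.1560918              # metres

# thermal beam into 35 ppm tissue: where does the boron dose peak?
pr <- run_scenario(preset("thermal-35"), profile = "paper", seed = 424242)
pr
#> <dose_profile> 0.025 eV beam, 35 ppm B-10, 200000 histories (seed 424242)
#>   boron dose max 3.334e-13 Gy/n at 0.375 cm; total max 3.563e-13 Gy/n at 0.375 cm
#>   max energy-ledger residual: 5.89e-16 (relative)
head(as.data.frame(pr)[, c("depth_cm", "total_Gy", "boron_Gy", "boron_se")], 3)
#>   depth_cm     total_Gy     boron_Gy     boron_se
#> 1    0.125 3.457217e-13 3.220995e-13 1.108343e-14
#> 2    0.375 3.563405e-13 3.334083e-13 1.126479e-14
#> 3    0.625 3.433529e-13 3.205368e-13 1.107146e-14
```

The boron dose (alpha + Li-7 only) peaks a few millimetres inside the
phantom — thermal neutrons barely penetrate — and falls by two orders of
magnitude beyond ~8 cm; doses are Gy per source neutron with per-history
standard errors. Epithermal presets (`epi-1eV` … `epi-10keV`) peak deeper.
`report()` aligns several loadings/energies into one table;
`write_profile()` emits the CSV plus a JSON run record.

A thin CLI wraps the same functions:

```sh
exec/bnct kinematics --reaction dd --ed 0.5 --theta-deg 0
exec/bnct simulate --scenario thermal-35 --histories 10000 --seed 7 --out dose.csv
exec/bnct scenarios --action list
```

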