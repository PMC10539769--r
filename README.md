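# clusterblind

Paramagnetic NMR analysis of iron–sulfur cluster proteins: hyperfine
contact shifts of exchange-coupled [Fe2S2] spin ladders, Solomon–
Bloembergen–Morgan relaxation with r⁻⁶ linewidth calibration, distance- and
NOE-based assignment of hyperfine-shifted signals, blind-sphere mapping on
a structure, and steady-state models of the relaxation-tailored filters
(inversion-recovery and INEPT/CON) used to recover amide signals near the
cluster.

## The problem

A protein-bound [Fe2S2]²⁺ cluster broadens the NMR signals of nearby
nuclei beyond detection — a "blind sphere" around the functional site —
while pushing the signals of cluster-bound residues far downfield through
the Fermi-contact interaction. Making sense of such spectra requires a
small set of quantitative models that this package implements for
spectroscopists working on Fe–S (and similar exchange-coupled) systems:

- **Spin ladder & contact shift.** Two site spins coupled by
  H = J S₁·S₂ (J > 0 antiferromagnetic) give total-spin multiplets
  S′ = |S₁−S₂| … S₁+S₂ with E(S′) = (J/2)S′(S′+1) and per-site projection
  coefficients c₁ = [S′(S′+1)+S₁(S₁+1)−S₂(S₂+1)]/[2S′(S′+1)]. The contact
  shift of a proton with hyperfine coupling A/h is

  δ_con = 2π(A/h)·gμ_B /(3kTγ_I) · Σᵢ cᵢ S′ᵢ(S′ᵢ+1) pᵢ(T) × 10⁶ ppm,

  with Boltzmann populations pᵢ(T). A diamagnetic S′ = 0 ground state
  (two Fe³⁺, S = 5/2 each) yields the diagnostic **anti-Curie** behaviour:
  shifts grow with temperature.
- **Paramagnetic relaxation.** Dipolar (Solomon), contact and Curie-spin
  contributions to R1/R2, with the dipolar and Curie terms ∝ r⁻⁶ in the
  metal–proton distance. Because the electron relaxation time is unknown,
  headline predictions use an operational calibration: one observed signal
  of known distance anchors Δν(r) = floor + (Δν_ref − floor)(r_ref/r)⁶,
  and signals past 4 kHz are classified beyond detection.
- **Rotational correlation time.** Rigid isotropic-rotor ¹⁵N R1/R2 (N–H
  dipolar + −160 ppm CSA); the R2/R1 ratio is numerically inverted for τc.
- **Relaxation-tailored filters.** Steady-state inversion-recovery
  response M = 1 − (2 − e^(−R1·t_rec))·e^(−R1·τ_IR) (suppresses slow
  diamagnetic amides) and INEPT transfer f = sin(πJT)e^(−R2·T) with the
  closed-form relaxation-optimal delay T* = atan(πJ/R2)/(πJ).
- **Assignment logic.** Distance (< 4 Å ⇒ beyond detection), bond-count
  and exchangeability rules shortlist candidates for the hyperfine-shifted
  signals; predicted r⁻⁶ NOE patterns from the structure are matched
  exhaustively against observed 1D NOE difference peaks, with ties
  surfaced as ambiguities.
- **Blind sphere.** Radius = the largest nearest-iron distance among
  undetected amides (outliers past a cutoff set aside), rounded to 0.5 Å.

Synthetic-data generators (toy [Fe2S2] site, forward-modeled peak tables,
rigid-rotor relaxation tables, NOE peak lists with dropout) provide known
ground truth for every stage.

## Worked example

Candidate filtering on the packaged distance table of the cluster-binding
residues (Cys-72, Cys-74, Cys-83, His-87 of oxidized mitoNEET):

```r
library(clusterblind)
d <- read_distance_table(clusterblind_example("distances"))
filter_candidates(d)
#> Candidate partition:
#>   beyond_detection:     CYS-72-HA, CYS-72-HB2, CYS-74-HN, CYS-74-HB3, CYS-83-HA, CYS-83-HB2, HIS-87-HN, HIS-87-HB3, HIS-87-HE1
#>   exchange_constrained: CYS-72-HN, CYS-83-HN, HIS-87-HNE2
#>   bond_excluded:        CYS-74-HA, HIS-87-HA, HIS-87-HB2
#>   candidates:           CYS-72-HB3, CYS-74-HB2, CYS-83-HB3, HIS-87-HD2
```

Nine protons closer than 4 Å to an iron are beyond detection; the four
remaining carbon-bound, high-A/h protons are the only possible carriers of
the strongly shifted signals, and the single exchangeable candidate is the
iron-bound His ring NH (`hyperfine_exchangeable(filter_candidates(d))`
returns `HIS-87-HNE2`).

Calibrating the r⁻⁶ linewidth law on that signal (4.94 Å, 2500 Hz) shows
why closer protons are invisible:

```r
calibrated_prediction(r_ref = 4.94, dnu_ref = 2500, r_angstrom = c(3.5, 3.0))
#> [1] 19558 49271    # Hz -- far beyond the 4 kHz detection horizon
```

The inversion-recovery filter with 18 ms inversion and 27.5 ms recovery
nulls signals at R1 ≈ 19 s⁻¹, so slow diamagnetic amides are suppressed
while fast-relaxing amides near the cluster pass:

```r
print(ir_filter())
#> IR filter: inversion 18.0 ms, recovery 27.5 ms (acq 16.5 + rec 11.0)
#>   zero crossing at R1 = 18.9 s^-1
```

A 19.4 kDa dimer (empirical 0.6 ns/kDa) tumbles at τc = 11.64 ns; the
R2/R1 inversion recovers it from forward-simulated 500 MHz ¹⁵N rates:

```r
sim <- simulate_15N_relaxation(tauc_from_mass(19.4) * 1e-9, 500)
#> R1 = 1.53 s^-1, R2 = 15.57 s^-1, R2/R1 = 10.2
tauc_from_15N(sim$R1, sim$R2, 500)
#> [1] 11.6
```

A command-line interface wraps the same functions
(`inst/scripts/clusterblind`): `distances`, `blindsphere`, `predict`,
`tauc`, `filters`, `assign`, `simulate`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantity from
scratch — it forward-simulates noiseless rigid-rotor ¹⁵N relaxation for a
19.4 kDa protein at 500 MHz with the package's own generator, inverts the
R2/R1 ratio, and writes the recovered rotational correlation time (ns) as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

See `vignettes/clusterblind-methods.Rmd` for the models, parameter
choices, numerical conventions and limitations.
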