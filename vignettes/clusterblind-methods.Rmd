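---
title: "Models and methods behind clusterblind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clusterblind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterblind)
```

`clusterblind` packages the quantitative reasoning used when a protein
binds an exchange-coupled paramagnetic cofactor such as an [Fe2S2]
cluster: which signals shift, which broaden away, which residues fall
inside the "blind sphere" of an experiment, and how relaxation-tailored
pulse-sequence building blocks shrink that sphere. This vignette explains
each model, its assumptions, the tunable parameters, the numerical
conventions, and what the synthetic-data generators do and do not emulate.

## The exchange-coupled spin ladder

Two site spins `S1`, `S2` coupled by isotropic Heisenberg exchange
`H = J S1.S2` (our convention: `J > 0` antiferromagnetic, in cm⁻¹, the
spectroscopic unit customary for Fe–S work) produce total-spin multiplets
`S' = |S1-S2| ... S1+S2` with

- energy `E(S') = (J/2) S'(S'+1)` relative to the ground multiplet,
- degeneracy `2S'+1`,
- per-site projection coefficients
  `c1 = [S'(S'+1)+S1(S1+1)-S2(S2+1)] / [2 S'(S'+1)]`, `c2` by exchange of
  sites. For `S' = 0` we *define* `c1 = c2 = 0` rather than dropping the
  level: a singlet carries no electron moment but still holds population
  in the partition function.

For an oxidized cluster (two high-spin Fe³⁺, `S1 = S2 = 5/2`) the ground
state is the diamagnetic `S' = 0` singlet, and all paramagnetism lives in
thermally populated excited multiplets. `ladder()` evaluates these closed
forms; the test suite checks them against brute-force diagonalization of
the `(2S1+1)(2S2+1)` product-basis Hamiltonian for every admissible spin
pair, including the degeneracy pattern and the projection coefficients
extracted from `<S1z>/<Sz>` within each multiplet.

### Contact shift and its temperature dependence

The Fermi-contact shift of a nucleus hyperfine-coupled (constant `A/h` in
MHz) to one site of the dimer is

```
delta_con = 2*pi*(A/h) * g*muB / (3*k*T*gamma_I) * W(T) * 1e6   [ppm]
W(T) = sum_i c_site,i * S'_i(S'_i+1) * p_i(T)
```

with degeneracy-weighted Boltzmann populations `p_i(T)`. Two limits pin
the formula down. At `J = 0` the homodimer must reduce to an isolated-ion
Curie law with half weighting per site; numerically the
degeneracy-weighted average of `S'(S'+1)` over the `S1 = S2 = 5/2` ladder
is 17.5, so the effective per-site value is `8.75 = S1(S1+1)`, which the
implementation reproduces exactly. As `J -> +Inf` with an `S' = 0` ground
state the shift is quenched. In between, for `J` comparable to `kT`
(~200 cm⁻¹ at room temperature), excited-state population grows faster
with `T` than the `1/T` Curie prefactor shrinks: the shift *increases*
with temperature. `classify_T_dependence()` labels such signals
anti-Curie (threshold 0.05 ppm, below typical referencing error), the
fingerprint of an antiferromagnetic dimer with a diamagnetic ground
state.

Pseudocontact contributions are deliberately not modeled: the magnetic
susceptibility anisotropy of these clusters is negligible, so observed
hyperfine shifts are treated as purely contact in origin.

### Fitting J and A/h

`fit_coupling()` least-squares fits the contact-shift model to
shift-versus-temperature data for one or more protons sharing one `J`.
Conditional on `J` the problem is linear in each `A/h`, so the solver
profiles a 1-D objective in `J` (golden-section via `optimize`). With
only two temperatures the `(J, A/h)` surface has a flat ridge; rather
than return a spurious point estimate the fit is flagged
`under_determined` and the conditional `A/h(J)` profile along a log-spaced
`J` grid is returned. This is a design stance: two-point temperature
series constrain the *sign* of the coupling (anti-Curie implies `J > 0`)
but not its magnitude, and the package never asserts a numeric `J` for
any real system. Synthetic data use `J = 300 cm⁻¹` simply as a
representative antiferromagnetic coupling of the right order for oxidized
[Fe2S2] sites; no result depends on that choice.

## Paramagnetic relaxation and the r⁻⁶ calibration

`dipolar_R()`, `contact_R2()` and `curie_R2()` implement the standard
point-dipole (Solomon), scalar and Curie-spin expressions. Coupled
clusters enter through an effective `S(S+1)`: the Boltzmann average of
`c_i^2 S'_i(S'_i+1)` over the ladder (`effective_S_squared()`), i.e. the
same level of approximation as the contact-shift treatment, with no
level-specific electron relaxation times. Parameter conventions:

| parameter | default | units | rationale |
|---|---|---|---|
| `tau_r` | 11.6e-9 | s | tumbling of a ~19 kDa dimer (0.6 ns/kDa) |
| `tau_s` | 1e-10 | s | nominal electron relaxation of an Fe–S cluster; a *nuisance* parameter |
| `g` | 2.0 | — | isotropic g of Fe–S clusters |
| detection threshold | 4000 | Hz | linewidth beyond which 1D signals are unobservable in practice |
| diamagnetic floor | 30 | Hz | linewidth of unaffected amides at this size/field |
| ¹⁵N CSA | −160 | ppm | standard backbone amide value |
| N–H bond | 1.02 | Å | standard effective length |

Because `tau_s` is never measured, all headline linewidth predictions
route through `calibrated_prediction()`: one observed signal of known
metal–proton distance anchors
`dnu(r) = floor + (dnu_ref - floor) * (r_ref/r)^6`, which is exact for
any mixture of dipolar and Curie broadening (both pure r⁻⁶) and entirely
independent of `tau_s`. The full SBM path is kept for component analysis
(e.g. locating the distance where the distance-independent contact term
overtakes the dipolar term); a property test checks the two paths agree
on linewidth *ratios* to 1e-9. A unit note: the Curie-spin rate carries
`omega_I^2 = (gamma_I B0)^2`, which is what produces its quadratic field
dependence (ratio 1.96 between 700 and 500 MHz in the `4*tau_r`-dominated
regime).

`detectability()` uses a strict `>` at the threshold, so a signal at
exactly 4 kHz counts as observable; the boundary convention is tested and
documented rather than important.

## Correlation time from ¹⁵N relaxation

`simulate_15N_relaxation()` evaluates rigid isotropic-rotor `R1`, `R2`
and heteronuclear NOE from N–H dipolar and CSA spectral densities
(`J(w) = (2/5) tau/(1+w^2 tau^2)`); `tauc_from_15N()` inverts the
monotone `R2/R1` ratio by `uniroot` on a 1–50 ns bracket. Ratios at or
below 1 (extreme narrowing) or outside the bracket raise a regime error
instead of extrapolating. The estimator assumes a rigid molecule: in real
data, residues with chemical exchange (raised `R2`) or fast internal
motion (lowered NOE) must be excluded before averaging — the package
takes per-residue rates and leaves that curation to the caller, reporting
a median across residues in the CLI. No anisotropic diffusion tensor and
no model-free order parameters are fitted (out of scope).

## Relaxation-tailored filter models

The inversion-recovery block is modeled on longitudinal magnetization
only, as the cyclic steady state
`M(R1) = 1 - (2 - exp(-R1*t_rec)) * exp(-R1*tau_IR)` with
`t_rec = acquisition + recycle`. With the tailored delays (18 ms
inversion, 16.5 + 11 ms recovery) the null sits at `R1 = 18.9 s⁻¹`:
slower-relaxing (diamagnetic) amides are inverted or suppressed,
fast-relaxing ones near the metal pass almost unattenuated. One shape
subtlety is worth recording: because `t_rec > tau_IR` here, `M` first
dips *negative* as `R1` grows from zero before rising through its single
null — the filter's suppression band is a trough, not a monotone ramp.
The model predicts peak signs as `sign(M)`; measured sign boundaries can
differ from this simple steady-state picture (cross-relaxation and
exchange during the delays are not modeled), so the package reports `|M|`
and the model sign without asserting any particular experimental sign
threshold.

INEPT-type coherence transfer under transverse relaxation is
`f = sin(pi*J*T) * exp(-R2*T)` with the *total* transfer time convention
`T = 2*delta` (delays are stored one-sided as configured and converted
once). The relaxation-optimal transfer time has the closed form
`T* = atan(pi*J/R2)/(pi*J)`, verified against grid search. `J(C'N)`
defaults to 15 Hz, the standard one-bond carbonyl–nitrogen coupling;
with it, a shortened 8 ms delay overtakes the standard 12.5 ms delay at
`R2* = 33.3 s⁻¹`, and at `R2 > 10 s⁻¹` the standard delay already loses
over 20 % of its relaxation-free transfer — the regime where shortening
becomes mandatory. Incomplete in-phase/antiphase homodecoupling at
shortened delays is *not* modeled; it matters only for narrow signals,
which are not the ones these filters target.

## Assignment logic

`filter_candidates()` partitions the protons of cluster-bound residues by
three rules, in order: (1) nearest-iron distance `< 4 Å` ⇒ broadened
beyond detection; (2) nitrogen-bound protons are exchange-constrained —
they may only explain exchangeable signals; (3) protons more than 3
covalent bonds from the metal are excluded from the strongly shifted
candidate set *unless* they sit on the coordinating aromatic ring. The
ring exception is the package's operationalization of the physical
argument that sigma-bond hyperfine transmission dies off within ~3 bonds
(so Cβ protons of a thiolate ligand, 3 bonds via sulfur, stay; aliphatic
protons of a ring-coordinated His, 4–5 bonds via the ring nitrogen, are
excluded), while pi-delocalization keeps ring protons strongly coupled at
4 bonds. On the packaged distance table this yields exactly four
candidates for the strongly shifted signals, one exchangeable ring-NH
candidate, nine beyond-detection protons, and a two-way ambiguity
(bond-excluded pair) for the weakly shifted extra signal — all surfaced,
none silently resolved.

`predict_noe_partners()` ranks all hydrogens within 5 Å by r⁻⁶ intensity
normalized to the strongest partner; `match_assignments()` enumerates
injective signal-to-candidate mappings exhaustively (candidate sets here
have ≤ 6 members, so enumeration is exact and cheap), scoring each
observed peak that falls within 0.05 ppm of a predicted partner shift by
the predicted intensity. The 0.05 ppm tolerance is a typical 1D ¹H
resolution choice; equally scoring mappings are returned as alternatives
and the affected signals reported as ambiguous.

The combined amide perturbation is `delta_HN = sqrt(dH^2 + (dN/5)^2)`
(nitrogen scaled by its ~5× wider shift dispersion), with significance at
mean + 1 SD over all residues.

## Blind-sphere estimation

`blind_sphere_radius()` takes the set of amides undetected in an
experiment and returns the largest nearest-iron distance among them,
after setting aside undetected amides farther than 12 Å (default) as
non-paramagnetic dropouts (exchange broadening, disorder, overlap) that
are listed separately. The radius is rounded to 0.5 Å — the granularity
at which such radii are physically meaningful, given that they summarize
a shell, not a sharp boundary. Monotonicity in the undetected set (more
missing amides can only grow the sphere, after outlier removal) is
enforced by construction and property-tested.

## Geometry conventions

PDB ATOM/HETATM records are parsed at fixed columns; alternate locations
resolve to the highest-occupancy conformer; elements missing from columns
77–78 are inferred from atom names. Backbone amide protons are built at
1.01 Å along the direction opposing the bisector of N–CA and N–C(i−1)
(in-plane, equal H–N–CA and H–N–C angles); prolines, N-termini and
residues lacking the upstream carbonyl are skipped. Side-chain
protonation is accepted from external tools, not re-implemented.
Covalent connectivity for bond counting uses distance thresholds —
1.9 Å between light atoms, 2.6 Å for metal coordination bonds — which is
adequate for the cluster-plus-ligand neighbourhoods the bond rules need;
no residue topology dictionary is consulted. Irons within 3.5 Å of each
other are grouped into one cluster (Fe–Fe in [Fe2S2] is ~2.7 Å).

## What the synthetic generators emulate — and what they do not

`make_toy_structure()` builds a fully determined [Fe2S2] site: Fe–Fe
2.7 Å, bridging sulfides at ~2.2 Å, three Cys-like S ligands (2.3 Å), one
His-like N ligand (2.1 Å), and probe protons at chosen nearest-iron
distances (default 2.98–5.18 Å, the range spanned by cluster-ligand
protons in a real site), each with a geminal-like companion 1.75 Å
further out so that NOE patterns exist. Placement directions are random
but seeded; a 0.8 Å clash floor is enforced and the requested distances
are reproduced to 1e-3 Å. `make_peak_table()` forward-models shifts
(contact + diamagnetic offset) and calibrated linewidths;
`make_relaxation_table()` adds multiplicative Gaussian noise (default
5 %, a typical relaxation-measurement precision) to rigid-rotor rates;
`make_noe_observations()` drops partner peaks at a configurable rate,
mimicking the very sparse NOEs measurable from fast-relaxing signals.

A green synthetic test therefore establishes internal consistency — the
estimators invert the generators under the stated noise — but not
fidelity to any real protein: the toy site has no protein frame, no
side-chain proton forest, no chemical-exchange broadening, no anisotropic
tumbling, and its NOE "spectra" have perfect shift accuracy apart from
dropout. Checks against a real crystal structure (iron counts per dimer,
the ~24 amides within 10 Å, published blind-sphere radii) require the
actual PDB entry, which cannot be shipped; the package runs them when the
file is supplied locally.

## Numerical choices and degenerate inputs

- Root finding (`ir_zero_crossing`, `tauc_from_15N`, crossover location)
  uses `uniroot` with explicit brackets; `fit_coupling` profiles `J` on
  `[1, 2000] cm⁻¹` by `optimize`.
- CODATA constants live in one record (`physical_constants()`); cm⁻¹ is
  converted to Joules in exactly one place.
- A proton coincident with a metal (distance 0) is flagged degenerate
  with a warning, not silently kept; empty hydrogen selections warn and
  return an empty table; an empty undetected set gives a zero-radius
  blind sphere.
- All generators take explicit seeds and are byte-reproducible; no hidden
  random state.
- Temperatures must be positive; duplicate temperatures in a
  classification are an error (they make the trend undefined).

## Known limitations

No pseudocontact shifts, zero-field splitting or anisotropic exchange; no
cross-correlated relaxation or diffusion anisotropy; no density-matrix
pulse simulation (filters are steady-state amplitude models); no general
protonation engine; no crystallographic symmetry expansion; no automated
sequence-specific assignment. These are deliberate scope boundaries — the
package models the arithmetic a spectroscopist actually does when reading
a paramagnetic spectrum against a structure.
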