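---
title: "Interpreting malonyl-caffeoylquinic acid MS/MS, oxidation and NMR data with quinateMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting malonyl-caffeoylquinic acid MS/MS, oxidation and NMR data with quinateMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quinateMS)
```

# The problem

Malonyl-dicaffeoylquinic acids (MDiCQAs) are quinic acid cores esterified
with two caffeic and one malonic acid. Twelve regiochemical arrangements of
those three esters over the four acylatable hydroxyls (positions 1, 3, 4, 5)
share one molecular formula, C~28~H~26~O~15~, one deprotonated-ion m/z
(601.1199) and, to a first approximation, one fragment-ion inventory — so
neither exact mass nor a fragment list identifies an isomer. What does
differ between isomers is the *intensity distribution* over the shared
fragments, and how that distribution moves with collision energy. quinateMS
implements that interpretation logic end to end: formula arithmetic,
regioisomer enumeration, a neutral-loss fragment grammar, in-source
oxidation handling, the two-stage collision-energy decision key,
coupling-constant core assignment, and the surrounding assay plumbing
(IC50 fits, tissue summaries), plus seeded generators that make every stage
testable without instrument data.

# Mass model

Masses are sums of pinned most-abundant-isotope masses (IUPAC values,
hard-coded so results are bit-stable). Ion m/z includes the electron mass:

$$ m/z_{[M-H]^-} = M - m_H + m_e, \qquad m/z_{[M+H]^+} = M + m_H - m_e $$

At the 4-decimal precision of Orbitrap-class data the electron
(0.00054858 Da) is not negligible: the reference values 601.1199, 687.1203
and 619.0941 only reproduce with the correction included. Only singly
charged ions are modelled; these metabolites show no multiply charged
species. Nominal m/z is round-half-up of the exact m/z, the convention
under which every printed nominal fragment value reproduces.

```{r}
mzIon("C28H26O15", "negative")
```

# Fragmentation grammar

Negative-mode CID of these esters is a sequential-neutral-loss process over
a five-word vocabulary:

| loss | formula | mass (Da) | budget |
|---|---|---|---|
| malonyl residue | C3H2O3 | 86.0004 | one per malonyl ester |
| caffeoyl residue | C9H6O3 | 162.0317 | one per caffeoyl ester |
| glucosyl residue | C6H10O5 | 162.0528 | one per glycosidic bond |
| CO2 | CO2 | 43.9898 | one, while a free carboxyl exists |
| H2O | H2O | 18.0106 | one |

Two modelling points deserve emphasis. First, the malonyl group leaves as
the 86.0004 Da ketene-type residue C3H2O3, not as malonic acid (104 Da):
the observed 601→515 and 549→463 deltas force this choice, and the 104 loss
is simply not generated. Second, on malonylated glucosides the glucosyl
residue can only leave after all malonyl esters on the sugar are gone,
reproducing the demalonylation-first cascades 619→533→447 and 549→463→301.

`generateFragments()` expands this grammar breadth-first under the per-
structure budget, deduplicating by remaining formula (losses commute, so a
formula determines the residual budget). For acyl-quinates three terminal
marker ions are appended — deprotonated quinic acid (191), caffeic acid
(179) and dehydrated quinic acid (173) — because they terminate every
decomposition cascade regardless of path. Because the grammar consumes only
*counts* of ester groups, the nominal fragment set is provably identical
across all twelve MDiCQA regioisomers; the package's tests assert this,
which is exactly why intensities, not masses, must carry the
identification.

The loss vocabulary contains a near-degeneracy: caffeoyl and glucosyl
residues both have nominal mass 162 but differ by 21 mDa.
`explainLoss()`'s default 10 mDa tolerance keeps them separable;
`annotatePeaks()` matches at 5 ppm.

# In-source catechol oxidation

Each catechol unit can oxidize in the ion source, losing two hydrogen atoms
(exact offset 2 × 1.0078250 = 2.01565 Da; "2 Da" only nominally). A
two-catechol MDiCQA therefore shows up to three ions: intact, −2H and −4H.
`detectOxidationSeries()` searches exactly `nCatechol` satellite positions
at 10 ppm; a satellite-shaped peak beyond the catechol budget is flagged as
an anomaly rather than claimed, guarding against isotope misassignment.
The eluent presets in the generator encode the observed acidity dependence:
with 0.1% formic acid the intact ion dominates (satellites at the midpoints
of the reported ranges, 60% and 7.5% relative intensity); with water-only
eluent the pattern inverts and the doubly oxidized ion dominates; 0.3%
formic acid suppresses satellites further (no values are reported for this
condition; 15%/2% were fixed once as plausible suppressed levels). A known
limitation: at this resolution model the −2H satellite is not deconvolved
from M−2 isotope structure; the detector matches positions only.

# The two-stage isomer key

All intensities are *fractions of total ion current* (TIC), never
base-peak-relative — the diagnostic percentages are fractions of total
intensity, and TIC normalisation is what makes the key invariant to
detector scale. Key ions are read by nominal bin (round-half-up), which is
sufficient at the 0.1 Da scale separating them.

**Stage 1 (25 eV).** The m/z 233 ion (quinate − 2 caffeoyl − CO2) carries
about 70% of the TIC for compounds 4 and 7, which stage 1 cannot separate;
m/z 395 (quinate − caffeoyl − CO2) carries ~35% with 233 in traces for
compound 5; both ions are comparably high (~30%/~35%) for compound 6. The
encoded rules: `group_4_or_7` if I233 ≥ 0.5 and I395 below the 0.05 trace
threshold; `cpd5` if I395 ≥ 0.25 and I233 below trace; `cpd6` if both
≥ 0.2 with ratio in [0.5, 2]; otherwise inconclusive. The trace threshold
of 5% sits between the 1–2% trace signals and the ≥20% diagnostic
signals; "comparably high" is encoded as a symmetric two-fold band.

**Stage 2 (45 eV).** Compounds 4 and 7 separate by the I173/I233 ratio:
approximately 40%/30% ≈ 1.3 for compound 7 versus 8%/30% ≈ 0.3 for
compound 4. The decision uses a dead band: ratio ≥ 0.7 calls `cpd7`,
≤ 0.5 calls `cpd4`, and values inside (0.5, 0.7) — which straddle the
geometric midpoint (~0.62) of the two observed ratios — stay inconclusive
rather than overclaiming near the boundary. Because stage 2 is a pure
ratio, it is invariant to intensity units.

`classifyIsomer()` composes the stages and reports `high` confidence only
when every fired rule cleared its threshold with ≥20% relative margin.

```{r}
tpl <- spectrumTemplates()
classifyIsomer(genMSMS(tpl[["cpd7_25"]]), genMSMS(tpl[["cpd7_45"]]))
```

# NMR coupling keys

The H-4 proton of the quinate core is the stereochemical reporter. In
DMSO-d6 a large trans-diaxial ³J(4,5) (~9 Hz) indicates the quinic
configuration; a smaller value (< 8 Hz) indicates epi-quinic, whose two
chair conformers equilibrate. `assignCore()` encodes this as a monotone
step function with a deliberate indeterminate gap: J ≥ 8.5 Hz → quinic,
J < 8.0 Hz → epi-quinic, 8.0–8.5 Hz → indeterminate. The gap exists
because the two diagnostic regimes (~9 and < 8 Hz) do not meet; a value
inside the gap — e.g. 8.3 Hz, observed for one compound whose quinic
assignment rested on additional 2D evidence — is deferred to human review
rather than guessed by a hard threshold. The D2O consistency check demands
that the diagnostic vicinal coupling *increase* on solvent change (the
conformational equilibrium shifts toward the double-diaxial chair: 8.8 →
10.1 Hz for a quinic core; the ³J(3,4) analogue for epi-quinic). The
anomeric key calls β-configuration at J ≥ 7.0 Hz, covering the observed
anomeric doublets (7.3–8.1 Hz) with margin against the α-range (~3–4 Hz).
Inputs are extracted J values; FID processing and chemical-shift
interpretation are out of scope, as is absolute configuration (genuinely
unresolved for this compound class).

# Dose-response fitting

`fitIC50()` fits the four-parameter logistic by Levenberg-Marquardt,
parameterised in log(IC50) so the reported standard error (delta method)
lives on the scale where the estimator is closest to normal. Box
constraints keep the fit on a percent scale — bottom in [−10, 45], top in
[55, 120], hill in [0.1, 20] — because unconstrained 4PL fits on sparse
noisy curves can slide into degenerate asymptote solutions; the bounds
state only what "percent inhibition crossing 50%" already means
physically. Curves whose maximal effect stays below 50% are censored
(status `censored_above_max`), not extrapolated. Viability data are
handled by the `direction` flag (effect = 100 − response), sharing all
machinery. `interpolateIC50()` provides a model-free log-linear
interpolation cross-check. The generator's default design is eight
two-fold dose steps centred on the IC50 with four parallel replicates per
dose and Gaussian noise in percentage points — the standard plate layout
for these assays (the cytostatic data this mirrors were quadruplicate
measurements). The recovery simulations in the test suite run 200 curves
at 3% noise (and 100-curve sweeps over hill ∈ {0.8, 2}), sizes chosen to
estimate bias and coverage stably while keeping the suite fast.

# Synthetic data: what it does and does not emulate

The generators produce: MS/MS spectra from the four isomer templates
(exact theoretical fragment m/z; Gaussian ppm jitter; mean-preserving
lognormal intensity noise; optional uniform decoy peaks excluded from
±0.5 Da of key ions so robustness results stay interpretable), MS1
oxidation patterns per eluent preset, 4PL dose-response tables, and
lognormal tissue-abundance tables. All are pure functions of (parameters,
seed); the global RNG stream is saved and restored. Template TIC fractions
encode the diagnostic percentages; the residual mass is spread uniformly
over the seven background fragments (557/515/439/377/353/191/179) because
their individual proportions are not reported — uniform allocation is a
documented modelling choice, not data. The 45 eV templates for compounds
5 and 6 are placeholders (no reported values exist); the key never
consults them. Not emulated: chromatographic peak shape and retention
time, isotope envelopes, detector saturation, co-eluting isomer mixtures
(resolved chromatographically, not computationally) and real inter-scan
intensity drift. Passing tests on these generators therefore demonstrate
the correctness and noise-robustness of the decision logic under the
stated noise model, not performance on raw instrument files.

# Numerical choices, in one place

- Isotope and electron masses pinned in source; no runtime dependency.
- Nominal m/z: round-half-up.
- Tolerances: 5 ppm MS2 annotation, 10 ppm precursor/oxidation matching,
  10 mDa loss explanation.
- Trace threshold 0.05 TIC; stage-2 dead band (0.5, 0.7); cpd6 band
  [0.5, 2]; confidence margin 20%.
- Core-assignment gap 8.0–8.5 Hz; anomeric floor 7.0 Hz.
- Oxidation offset 2.01565 Da per state; satellites beyond the catechol
  count flagged, never claimed.
- 4PL bounds as above; ≥ 5 dose levels required; non-convergence returns
  `failed` with the solver message rather than an error.
- Ties in `dominantState()` resolve to the lower oxidation state with a
  tie flag.
- Pipeline pairing: 25/45 eV spectra joined by precursor m/z within
  10 ppm and shared title stem; unpaired 45 eV spectra warn.

# Limitations

Stereochemistry is a label, not a 3D model; only caffeoyl and malonyl acyl
groups are implemented (the enum is extensible); positive-mode fragment
trees are out of grammar scope (positive mode serves precursor/aglycone
confirmation only); the isomer key covers the four isolated isomers, not
the eight never observed; satellite-vs-isotope overlap is not deconvolved;
and IC50 reporting conventions (SD vs SEM of the ± values) follow the
quadruplicate-assay reading, which is unspecified for the DPPH data.
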