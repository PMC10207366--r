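---
title: "Field-based 3D-QSAR pharmacophores: models, parameters and design choices"
author: "fieldpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-based 3D-QSAR pharmacophores: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

`fieldpharm` relates the three-dimensional distribution of atomic
properties around a set of aligned ligands to their inhibitory potency
(pIC~50~).  The central assumption is strong and should be checked before
use: **all molecules share one coordinate frame that is biologically
meaningful** — docked poses in a common receptor, or congeneric analogues
superposed on a parent crystallographic ligand.  The package never aligns;
it asserts alignment by construction (`frameNote` records the provenance).
A second assumption is that per-atom descriptors arrive precomputed
(quantum-chemical atomic log P contributions, H-bond donor/acceptor
values, ESP or Gasteiger charges, force-field radii); their derivation is
upstream of this package and they travel in a sidecar CSV because atomic
properties have no portable SDF encoding.

## Fields

A regular lattice is built over the union bounding box of all atoms,
expanded by at least the padding on every face:

* `spacing` — 1.0 Å by default.  Finer grids grow the design cubically
  and mostly add collinear columns.
* `padding` — 4.0 Å by default, a guaranteed *minimum*: the upper face is
  extended to the next lattice plane when the padded extent is not a
  multiple of the spacing.  The origin is the padded corner itself; we do
  not snap to integer coordinates, so results are reproducible without a
  hidden rounding convention.

For the descriptor recipes the field is an exponential decay
$F_q = \sum_i w_i e^{-\alpha\, r_{iq}}$ with $\alpha = 0.3$ and $r_{iq}$
the Euclidean atom–gridpoint distance.  Two choices deserve comment:

* **Decay argument.**  The distance enters linearly.  A Gaussian-type
  $e^{-\alpha r^2}$ variant is available through
  `fieldConfig(decayPower = 2)` for users who prefer the sharper
  localization; the linear form is the default because it decays slowly
  enough that no distance cutoff is needed — far contributions are
  negligible but not discarded, which keeps the field exactly linear in
  the atomic weights and exactly translation-equivariant.
* **Steric weights.**  The `R3` field uses the cubed van der Waals radius,
  computed at projection time from the stored radius rather than stored
  separately — one source of truth per atom.

The `QG_LJ` recipe instead places a probe atom (+1 e, sp³-carbon
Lennard-Jones parameters from `inst/extdata/probe_params.csv`) at every
lattice point.  The Coulomb term uses the distance-dependent dielectric
$\varepsilon = r$, the classical choice for grid fields computed without
explicit solvent; `fieldConfig(dielectricMode = "constant")` switches to a
fixed permittivity.  Both probe energies are clamped **per grid point,
per field** to ±`energyCutoff` (10 kcal/mol by default) — interpreted in
kcal/mol — which is what makes grid points inside an atom harmless: the
distance is floored at 10⁻⁶ Å and the resulting huge energy collapses to
the finite clamp bound with its sign preserved.

Columns whose across-molecule standard deviation is ≤ `minColumnSD`
(default 0, i.e. only strictly constant columns) are masked out before
regression and the mask is stored in the model, so prediction-time
projection reduces new poses to exactly the training columns.

## Regression

The PLS engine is a deterministic single-response NIPALS with centering
only.  No autoscaling is applied by default: the field blocks are in
physically comparable units within a recipe, and the per-field
contribution percentages $\sum_j |b_j| s_j$ (coefficient × training column
standard deviation, normalized to 100) are only meaningful on raw units.
`fitPLS(..., scale = TRUE)` enables autoscaling for experimentation.

Component selection scans $N_c = 1 \ldots$ `nMax` (default 10) under
leave-one-out cross-validation and takes the highest
$q^2 = 1 - \mathrm{PRESS}/\sum_i (y_i - \bar y)^2$, breaking ties by lower
$S_\mathrm{press} = \sqrt{\mathrm{PRESS}/(n - N_c - 1)}$ and then by the
smaller $N_c$.  Two conventions are fixed here and switchable:

* $\bar y$ in the $q^2$ denominator is the **full-set** mean, the dominant
  convention; `looCV(..., foldMean = TRUE)` gives the per-fold variant.
* $S_\mathrm{press}$ uses the $n - N_c - 1$ degrees-of-freedom correction.

Each fold recenters on its own $n-1$ molecules, and one NIPALS pass per
fold serves every component count in the scan, so the scan costs a single
cross-validation.  Rank deficiencies surface as errors when a component
count is requested beyond the design rank, and folds that lose rank fall
back to their largest feasible model during the scan.

Regression diagnostics come in two orientations.  Training-set
cross-validated diagnostics regress the LOO predictions on the
experimental values (`pred_on_obs`); external-validation tables regress
observed on predicted (`obs_on_pred`, the default of
`regressionValidation()`), which is the orientation that reproduces the
packaged 46-compound reference table.  Both the ordinary line
$y = mx + n$ and the through-origin line $y = cx$ are reported: a
predictive model shows the two lines nearly coincident with slopes close
to 1.

## Validation metrics

ROC analysis ranks by descending score and uses the pair-counting
(Mann–Whitney) convention — a tied active–decoy pair contributes ½ — which
is provably identical to the trapezoidal area under the threshold-sweep
curve; the test suite asserts that identity to 10⁻¹².  Early enrichment is
reported in two readings because the phrase "enrichment in the first x%"
is genuinely ambiguous: TPR at FPR = x divided by x (`mode = "roc"`, the
default) and the actives fraction in the top x% of the list divided by x
(`mode = "top_fraction"`).

Group summaries report the sample (n−1) standard deviation, and the
"more potent than 20 nM" count applies the strict rule pIC~50~ > 7.7 on
one-decimal values: 20 nM corresponds to pIC~50~ = 7.70, which is itself
excluded.  One-decimal rounding before comparison makes the count stable
for activity tables printed at one decimal, the common reporting
precision.

## Screening workflow

The urea filter uses SMARTS `[NX3][CX3](=O)[NX3]` — trivalent neutral
nitrogens flanking a carbonyl — which keeps ureas and acyl-ureas while
excluding carbamates, plain amides and thioureas.  The generic pattern is
the default since the anchoring interaction needs only the urea core; the
stricter 1,3-disubstituted variant is `disubstituted = TRUE`.  Unparsable
SMILES are dropped with a logged count rather than failing a whole
library.  Best-pose selection takes the minimum (most negative) docking
score across targets with ties going to the first declared target, and
reranking is a deterministic, stably-sorted function of its input: top
`topIn` (100) molecules by docking score, rescored by the pharmacophore,
top `topOut` (9) reported with full provenance.  No algorithmic
internal-clash rejection is attempted — in the workflows this package
supports that step is a visual one, and no published criterion exists to
encode.

## The synthetic generator

`generateDataset()` emulates the geometry of a congeneric inhibitor
series: a rigid scaffold of 6 atoms shared by every molecule (two pinned
at opposite corners of the `boxExtent` = 8 Å cube so the lattice is
identical across seeds), plus variable atoms placed on a per-molecule
subset of 16 fixed attachment sites with freshly drawn descriptors.  The
site structure is deliberate: substituents in a real series change, but
attachment positions do not, and fixing the sites bounds the
dimensionality of the field vectors so that noiseless leave-one-out
recovery is numerically exact (the test suite requires trained q² ≥ 0.999
at zero noise).  With fully random atom positions the field manifold is
higher-dimensional than any desk-scale training set and even a noiseless
model cannot extrapolate a held-out molecule perfectly.

Descriptor distributions: log P contributions Normal(0, 0.5); H-bond
donor/acceptor flags Bernoulli(0.15) on scaffold atoms and
Bernoulli(0.04) on variable atoms — hydrogen bonding concentrates in the
conserved anchor moiety of a series (the urea core, in the motivating
chemistry) while variable decorations are predominantly apolar; charges
Normal(0, 0.2) e; van der Waals radii Uniform(1.2, 2.0) Å.

The true activity is a linear functional of the molecule's projected
field values at `nProbes` = 4 fixed lattice points (a binding site with a
few interaction hotspots), standardized to mean 7 and spread 1.5 pIC~50~
units — a realistic potency range for an inhibitor series — plus
Normal(0, `noiseSD`) noise.  Defining the truth through field values at
lattice points, rather than directly through atoms, puts the ground truth
inside the PLS model class, which is what makes parameter recovery a fair
test of the whole pipeline rather than of the generator.  All randomness
flows from the single integer seed through one generator stream, and the
global RNG state is restored afterwards.

What the generator does **not** emulate — and hence what passing recovery
tests do not show about real data: chemically valid topology and
conformers, descriptor error from the upstream quantum-chemical
derivation, alignment noise from docking, activity-cliff nonlinearity,
and inter-assay noise in the activities.  Real-data performance is
benchmarked instead with the packaged reference tables (the 46-compound
external set and the 18-compound prospective panel).

## Numerical choices

* NIPALS stops a component when the covariance norm or score variance
  falls below 10⁻¹² of its first-component value; requesting more
  components than that rank is an error.
* Atom–gridpoint distances are floored at 10⁻⁶ Å in probe-energy
  evaluation only; exponential fields need no floor.
* Sorting of scored molecules and reranked candidates is stable, so equal
  predictions preserve input order.
* Model JSON is written at full double precision; a reloaded model scores
  any dataset to within 10⁻¹⁰.  Volumetric exports use 9 significant
  digits and round-trip to 10⁻⁶.
* SDF records are written with a single-bond chain connecting consecutive
  atoms: projections are bond-agnostic, but standard SDF tooling (and the
  reader used here) expects a bond block.

## Problem sizes

The test suite and the acceptance script run, by design, at desk scale:
training sets of 16–60 molecules (plus 20 hold-out) on 15³–17³ lattices
(3 375–14 739 design columns across blocks), 10-instance LOO oracle
checks at n = 12, p = 30, and 20-permutation y-scrambling controls.
These sizes were chosen so that a full parameter-recovery experiment over
five seeds completes in about a minute while still exercising the p ≫ n
regime that grid-field QSAR lives in.

## Known limitations

* **Field attribution has a finite-sample floor.**  With two extra field
  blocks of the same column count as the informative one, the
  $\sum_j |b_j| s_j$ percentages assign roughly 10–20% of the total to
  non-informative blocks at n = 60 — correlation noise, not signal.  In
  recovery experiments where the truth uses only the log P field, its
  reported share is typically 80–91%, not 100%.  Interpret contribution
  percentages as dominance indicators, not as exact variance
  decompositions.
* The prose convention "q² of a model" always means leave-one-out q² on
  the training set; no y-randomized or external q² is folded into model
  selection.
* Single-atom molecules round-trip poorly through the SDF toolchain and
  are outside the intended domain (real ligands have many atoms).
* Contour map export writes stdev×coefficient values; isocontour *levels*
  for display are a user choice, as no universal convention exists for
  their units.
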