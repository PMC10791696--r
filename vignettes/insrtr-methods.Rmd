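---
title: "Methods: insertion-site prediction and switch equilibria in insrtr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: insertion-site prediction and switch equilibria in insrtr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insrtr)
```

## The system being modelled

A coiled-coil (CC) allosteric switch is built by inserting a short,
intrinsically unstructured CC-forming peptide into a solvent-exposed loop
of a host protein. Alone, the insert leaves fold and function intact. When
its designed partner peptide binds, the insert folds into an
alpha-helix whose termini sit roughly 4 nm apart — far more than a typical
loop spans — and the resulting strain perturbs the active site and
switches the protein off. Tethering a weak CC partner to a terminus
instead gives an autoinhibited ON-switch that protease cleavage or a
soluble competitor reactivates, and combinations of tethered and
protease-released peptides implement two-input Boolean logic.

`insrtr` covers the computational side of this programme:

1. finding and ranking candidate insertion sites in a 3D structure
   (structure I/O, secondary structure, SASA, descriptors, heuristic
   rules, a gradient-boosted classifier);
2. quantifying the mechanical coupling of an insert at a site (strain
   geometry);
3. simulating switch constructs at equilibrium (competition binding,
   protease inputs, gate truth tables, Hill fits).

## Site enumeration and the admissibility rules

Candidate sites are peptide bonds inside loop segments: a site "after
residue *i*" means the insert is spliced between *i* and *i + 1*. Author
numbering from the input file is preserved verbatim — published site
labels are author positions, so nothing is ever renumbered. Terminal
loops are excluded by default; termini are where inhibitory fusions go,
not inserts.

Secondary structure comes from a hydrogen-bond assignment in the
Kabsch–Sander style, simplified to three states because only the
loop/non-loop distinction is consumed downstream. A backbone H-bond
between donor NH(*i*) and acceptor CO(*j*) is declared when

E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) < -0.5 kcal/mol,

with the amide hydrogen placed 1 Å from N along the preceding C=O
direction. A helix requires two consecutive (i, i+4) turns; the minimal
helix from turns at *j* and *j + 1* covers residues *j + 1 … j + 4*. An
isolated turn is deliberately not a helix: the residue that follows an
ideal helix always inherits one last (i, i+4) H-bond from the helical
geometry, and the two-turn rule is what keeps such junction residues in
the loop. One boundary convention is added: a chain-terminal residue
participating in the adjacent helix's H-bond network belongs to the
helix. Bridge (strand) states use the standard parallel/antiparallel
bridge patterns. Residues with incomplete backbones are coil.

The admissibility rules are applied as flags, not silent filters:

* **(a) exposure** — relative SASA of the site residue at least 0.25.
  The literature states "solvent-exposed" qualitatively; 0.25 is the
  conventional exposed/buried cut for relative accessibility and is a
  config default.
* **(b) functional-site involvement** — neither flanking residue in, or
  within 0.5 nm of, the user-declared active-site set.
* **(c) orthologue variability** — with an aligned FASTA of orthologues,
  the fraction of loop columns with variable occupancy must reach 0.5;
  without an alignment the flag is `NA` ("not evaluated") and never
  vetoes, because the rule is preferential, not mandatory.
* **(d) distance window** — minimum CA–CA distance from the flanking
  residues to the active site between 1 and 4 nm.
* **(e) connectivity** — reported descriptively (raw distance and contact
  count within 1 nm); no published quantification exists, so it is not a
  veto.

## Solvent accessibility

SASA uses the Shrake–Rupley construction: each atom's sphere is expanded
by the probe radius (1.4 Å water), sampled with a deterministic
golden-section spiral (960 points by default), and a point is exposed if
outside every neighbouring expanded sphere. The deterministic point set
makes values bit-stable across runs; tests compare against a closed-form
single sphere, the two-sphere spherical-cap formula, and an independent
latitude–longitude quadrature on random clusters (agreement within 2%).
Relative SASA divides by the Tien et al. theoretical maxima per residue
type.

## Descriptors and the classifier

The default descriptor schema computes, per site: total and mean loop
SASA, site relative SASA, minimum CA distance to the active site (nm),
anchor gap (nm), loop length, fractional position in the loop, CA contact
density within 1 nm, mean loop B-factor and a flanking-helix indicator.
The two features that dominate prediction in practice — loop SASA and
active-site distance — are mandatory schema entries. The schema is
pluggable; missing values are masked and median-imputed at training time,
with the medians stored in the model (medians are robust at the n ≈ 47
scale this classifier is built for).

The classifier is a gradient-boosted tree ensemble with the binary
log-loss objective (xgboost backend). Three hyperparameters are tuned:
learning rate, minimum samples to split, and number of trees, over a
config-exposed grid (defaults 0.01–0.2, 2–8, 50–400). xgboost expresses
node-size control as a hessian bound, so `min_samples_split` is mapped to
`min_child_weight = min_samples_split / 4` — the count-to-hessian
conversion at p = 0.5, where the logistic hessian attains its maximum of
1/4 per sample.

The tuning protocol is nested: a stratified 80% tuning split, LOOCV
within it, per-fold selection of the grid point with the best held-out
log-loss, and a per-parameter majority vote across folds. Ties — within a
fold and in the vote — break toward lower complexity: fewer trees, larger
minimum split, smaller learning rate. Final evaluation is LOOCV over the
whole table: accuracy at threshold 0.5 and a single AUC pooled over the
held-out probabilities (per-fold AUC is undefined for one sample, so
pooling is the only defined choice). Permutation importance is the mean
accuracy drop over repeated shuffles of one feature; constant features
are exactly zero and flagged. Ranking of new candidates is by predicted
permissive probability, ties broken by increasing active-site distance.

## The synthetic study conditions

The generator mirrors the statistical shape of the training data the
method was developed on — 47 labeled sites with two dominant descriptors
— without claiming its values. Features are drawn from fixed
distributions (log-normal loop SASA around 300 Å², uniform active-site
distances 0.5–5 nm, integer loop lengths 3–15); labels come from a
planted linear model on theoretically standardized features with weights
+4 on loop SASA and −4 on active-site distance. Labels are deterministic
(sign of the predictor) with a margin of 2 on the standardized predictor:
rows inside the margin are redrawn. The margin was fixed by requiring
that a brute-force 1-nearest-neighbour classifier — a model-free oracle —
recovers the labels with LOOCV accuracy above 0.9; it encodes the
strength of the planted signal, not a property of the classifier under
test. The package's quantitative checks then ask that the boosted
pipeline reach a median LOOCV accuracy of at least 0.9 over seven such
tables and that permutation importance rank the two planted features
first and second in at least 95 of 100 seeds.

What passing these checks shows: the nested-LOOCV protocol, imputation,
evaluation and importance machinery recover a known signal at the
published data scale. What it does not show: performance on real
insertion-site data, whose descriptors are correlated, noisy and not
linearly separable — on such data accuracies in the 0.6–0.8 range are the
realistic expectation, and users with a labeled table should drop it into
`read_site_table()` and judge by their own LOOCV report.

## Strain geometry

The helical span of an n-residue insert is (n − 1) × 1.5 Å (canonical
rise); 27 residues — the CC length consistent with the ~4 nm figure —
give 3.9 nm, and an explicitly built ideal helix (phi = −57, psi = −47,
Engh–Huber geometry) agrees within 0.2 nm. The strain report compares
that span with the site's anchor gap: Delta = span − gap is the extension
the folded insert imposes. Flexible linkers add slack at 0.35 nm per
residue (extended-chain maximum) per side; when slack ≥ Delta the insert
is classified "decoupled" — consistent with the observation that long
linkers weaken inhibition — otherwise "coupled". The default linker is 5
residues per side, the experimentally favoured compromise.

## The equilibrium switch model

The literature gives the mechanism but no equations; the model here is
the simplest equilibrium mass-action picture that reproduces every
qualitative behaviour. A construct carries the in-loop insert plus
tethered peptides, each presenting an effective intramolecular
concentration Ceff (default 100 µM) to its partners; soluble species (the
regulator, or protease-released peptides at a default 1 µM) bind from the
bath. The single-construct state space — every matching of construct
elements to each other (weight Ceff/Kd) or to bath species (weight
[free]/Kd) — is enumerated exactly, and activity is the probability that
the insert is in no CC dimer. Soluble species are treated as in excess
(free ≈ total); `solve_mass_balance()` is the depletion-aware fixed-point
solver used as the general oracle, and the two agree to better than 1e-8
in the dilute-construct regime.

Default affinities respect the experimental rank of the designed CC
pairs: Kd(N7:N8) = 5 nM < Kd(P7A:N8) = 50 nM < Kd(P7:N8) = 200 nM <
Kd(P7N:N8) = 1 µM (`validate_affinity_rank()` checks any user table).
The exact values live in prior work on the peptide toolbox, so these are
model parameters, not measurements; every qualitative claim the model is
tested on (autoinhibition despite micromolar affinity, because
Ceff/Kd = 100; competitive release; dose-ordered inhibition) is
insensitive to their precise magnitudes. Two auxiliary blocker pairs
(B1:P7N, B2:P7, 0.1 nM) are introduced for the inverted gates.

Cleavage is binary and complete — the model describes the post-protease
steady state, matching end-point readouts; cleavage kinetics are out of
scope. Gates use three architectural motifs: tethers severed by any of
their sites (series sites — OR-type removal), elements tethered at both
ends severed only when all sites are cut (AND-type removal), and
protease-released trans peptides with any/all triggers (inversion). The
shipped library realizes 12 two-input functions (AND, OR, NOT-A, NOT-B,
A∧¬B, B∧¬A, NAND, NOR, XOR, XNOR and both implications); each passes its
truth table at default parameters and under two-fold perturbation of all
Kd/Ceff values. These architectures realize the same Boolean functions as
the published constructs but are not claimed to be identical to them.

Hill fits (Y = Vmax·X^h / (Khalf^h + X^h)) use Levenberg–Marquardt least
squares with the deterministic initialization Vmax0 = max(y), Khalf0 = x
at half-maximum, h0 = 1, and bounds Khalf, h > 0. Noiseless
generate-and-refit recovers parameters to 1e-6 relative; with 5% Gaussian
noise the median Khalf bias over 100 replicates stays within ±5%.

## Numerical and degenerate-input choices

* Coordinates are Å internally; every user-facing distance is nm (÷10).
* Altlocs resolve to highest occupancy, ties alphabetically; model 1 of
  multi-model files is the default.
* Unknown elements get a 1.8 Å radius with a warning; unknown residue
  types get `NA` relative SASA.
* A residue missing its CA raises a descriptor-unavailable error rather
  than silently contributing 0.
* One-residue loops have no internal bond and therefore no candidate
  site; structures with no loops yield an empty candidate list, not an
  error.
* All stochastic steps (splits, shuffles, generators) take explicit
  seeds; identical inputs give bit-identical outputs.

## Problem sizes used by the checks

The bundled checks run entirely on generated data: 29–38-residue toy
structures, 47-row labeled tables (7 for the accuracy median, 100 seeds
for importance recovery), 5–20-atom SASA clusters against a 64,800-point
quadrature, 12 gates × 3 parameter settings, and 100 noisy Hill curves.
The worked example on firefly luciferase (PDB entry 1BA3, insertion
position 490 vs the substrate pocket, ~2 nm) needs that structure file,
which is not redistributed; `luciferase_site_distance()` runs it once the
user downloads the entry.

## Known limitations

* Secondary structure is 3-state and hydrogen-bond based; no 3-10/pi
  distinction, no chain breaks healed, no hydrogens read even if present.
* The classifier ships without training data; headline accuracies
  reported for this class of method were estimated on experimental
  insertion-site tables that are not redistributed here and are therefore
  not asserted by the package's own checks.
* The equilibrium model ignores soluble-species cross-binding and
  expression/degradation dynamics; the regulator-in-excess closed form is
  exact only in the dilute-construct regime the solver can check.
* Loop variability scoring assumes the first MSA sequence is the target
  chain aligned end-to-end.
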