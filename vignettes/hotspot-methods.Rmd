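---
title: "Predicting hot-spot residues on protein-nucleic-acid interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hot-spot residues on protein-nucleic-acid interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnhot)
```

## The problem

A small number of interface residues — hot spots — carry most of the
binding free energy of a protein–DNA or protein–RNA complex.
Experimentally they are found by alanine scanning: a residue whose
mutation to alanine raises the binding free energy by at least
2.0 kcal/mol (the cutoff used throughout this package, applied
inclusively: ddG >= 2.0) is a hot spot.  Because alanine-scanning data
for nucleic-acid complexes are scarce, a classifier trained on the
available mutations is the practical way to flag candidate hot spots on
new interfaces.

`pnhot` implements that classifier end to end: a 97-feature
structural/sequence characterization of each interface residue, a
two-step feature selection (CART screening, then a beam sequential
forward search), and a radial-basis-function SVM evaluated by
leave-one-residue-out and leave-one-complex-out cross-validation.

## Interface definition

A residue is an interface residue when its solvent accessible surface
area (SASA) buried on binding is strictly positive: buried SASA =
SASA(unbound) − SASA(bound), with the unbound state obtained by
deleting the nucleic-acid chains without moving any protein atom.  All
protein chains are treated jointly as one unbound unit.  Because two
sampled SASA values are never exactly equal, "larger than 0" is
implemented as "larger than 1e-6 squared Angstrom".

## The 97 features

Each interface residue is described by seven families (the full ordered
registry is returned by `feature_registry()`):

* **10 physicochemical constants** of the wild-type amino acid
  (heavy-atom count, net side-chain charge, hydrogen-bonding capacity,
  Kyte–Doolittle hydropathy, Hopp–Woods hydrophilicity, Grantham
  polarity, isoelectric point, residue mass, Zamyatnin volume,
  extended-state exposure).  The table is assembled from standard
  published scales and frozen in the package source.
* **16 depth/protrusion features.**  The depth index of an atom is 0
  when the atom is solvent accessible (SASA > 1 squared Angstrom) and
  otherwise its distance to the nearest accessible atom; the
  protrusion index is the empty-to-occupied volume ratio in a 10
  Angstrom sphere with a mean heavy-atom volume of 20.1 cubic
  Angstrom.  Residue means (entire residue and side chain) are taken
  in both states, together with the unbound-minus-bound differences
  and the differences divided by the unbound value (defined as 0 when
  the unbound value is 0).  For glycine the side-chain mean falls back
  to the entire-residue mean.
* **54 SASA features**: absolute and relative exposure of five atom
  classes (all, side chain, backbone, polar, nonpolar) in both states,
  the buried (unbound − bound) values, and the buried values raised to
  the powers 0.5, 1.5 and 2.0.  Buried values are clamped at 0 before
  the fractional power.  Relative exposure divides by the residue's
  reference exposure in an extended Gly-X-Gly tripeptide, computed
  once with the package's own surface engine and atom model and
  memoised — a self-consistent convention rather than a transcription
  of an external reference table.
* **5 electrostatic summaries** (esp1–esp5) of a screened-Coulomb
  (Debye–Hückel) potential of the unbound protein, in kT/e: target
  mean, target side-chain mean, patch mean over the target plus all
  residues within 10 Angstrom, neighbour-only mean, and target
  maximum.  Charges come from a coarse united-atom table embedded in
  the source; screening defaults to 150 mM (kappa = 0.1274 per
  Angstrom) with a dielectric of 78.5.  These definitions are the
  package's own, chosen so that esp3 is a surface-patch summary; they
  are deterministic, additive in the charges, and documented as
  provisional.
* **2 hydrogen-bond counts** between the residue and the nucleic acid
  (all atoms, and side-chain atoms only): donor–acceptor heavy-atom
  pairs within 3.5 Angstrom, with a D–H...A angle of at least 120
  degrees whenever the donor hydrogen can be placed from idealized
  geometry (backbone amides); otherwise the pair is kept on distance
  alone.  Water-mediated bonds are not counted.
* **5 secondary-structure indicators** from a Kabsch–Sander
  re-implementation (H-bond energy
  E = 0.084 * 332 * (1/rON + 1/rCH − 1/rOH − 1/rCN) kcal/mol, bond when
  E < −0.5): the eight classes H, G, I, E, B, T, S, blank are recoded
  as H, E, turn (B/T/S), helix1 (G/I) and loop (blank) and one-hot
  encoded.  Pi-helix priority sits below alpha.
* **5 conservation features** from a PSI-BLAST ASCII PSSM: the
  information entropy of the position's weighted observed percentages
  (renormalized per position, natural log by default, configurable to
  log2), two +1-smoothed percentage ratios (actual residue / alanine
  and maximum residue / alanine), and the corresponding raw score
  differences.  The maximum residue is the one with the highest
  percentage, ties resolved in PSI-BLAST column order.

## Labelling, selection and evaluation

`label_hotspot()` applies the 2.0 kcal/mol cutoff inclusively: the
published class counts that this rule must reproduce (86/207 training,
14/110 test) force ties at exactly 2.0 to count as hot spots.

Feature selection is two-step.  `cart_select()` grows a CART tree
(Gini, minimum bucket 1) and returns the features used in at least one
split, ordered by impurity decrease.  The fully grown tree is used by
default: the screening step is meant to be generous, and
cost-complexity pruning (available via `prune = "cv"`) removes
genuinely informative features along with noise, which the forward
search can no longer recover.  `sfs_beam_select()` then runs a beam
search of width 3: each round extends every surviving set by every
unused candidate, scores each extension by leave-one-out F1 of an
RBF-SVM at fixed (G, C) = (0.1, 40), keeps the best three, and stops at
the first round whose best F1 fails to improve (ties are stops, and
equal-F1 sets are ordered alphabetically).  The grid is not re-tuned
inside selection; `tune_and_train()` afterwards searches G in {0.01,
0.05, 0.1, 0.5, 1, 2} and C in {1, 5, 10, 20, 40}, resolving ties
toward smaller C then smaller G.  No class weighting is applied despite
the 86:207 imbalance.

Inside the selection scorer the standardizer is fit once on the full
matrix (as when features are z-scored up front) — this also permits an
exact leave-one-out shortcut: removing a point whose dual coefficient
is zero leaves the SVM solution unchanged, so only support-vector folds
are refit.  `crossvalidate()`, used for reported results, defaults to
re-fitting the standardizer inside every training fold to avoid
leakage; both modes are exposed.  Metrics follow the standard
definitions; specificity is TN/(TN+FP).  Ratios with zero denominators
are defined as 0 and flagged.  AUROC uses the rank statistic (ties
count one half); the precision-recall area is integrated step-wise.

## What the synthetic generators emulate

The package is fully testable without downloads:

* `make_toy_complex()` builds an ideal helix or strand (exact backbone
  torsions via natural-extension chain building) with simplified side
  chains (CB plus one typed pseudo-atom) and a phosphate-backbone
  nucleic-acid trace at a controlled gap, and returns ground-truth
  contact and helix annotations.  It emulates interface geometry, not
  real packing: side-chain rotamers, base pairing and crystallographic
  artefacts are absent, so passing tests demonstrate correctness of
  the descriptors, not accuracy on real complexes.
* `make_synthetic_pssm()` writes valid PSI-BLAST ASCII profiles with
  planted conserved positions; scores are a monotone log-odds
  transform of the percentages.
* `make_planted_dataset()` draws class-conditional Gaussian
  informative features (default: 5 informative among 45 noise
  features, a 1.5-sigma shift, n = 293 rows at the 86:207 imbalance,
  20 complexes), optionally with per-complex offsets on the
  informative features (`group_sd`) to emulate the within-complex
  correlation that makes leave-one-complex-out harder than
  leave-one-residue-out.

All generators are pure functions of their seed.

## Numerical choices

* SASA: Shrake–Rupley sampling on a deterministic golden-angle
  lattice (960 points per atom by default, probe 1.4 Angstrom); no
  RNG, so results are bit-stable.  At 960 points the summed SASA of a
  fixture differs from a 4x denser lattice by well under 0.5 percent.
* Depth-index accessibility threshold: 1.0 squared Angstrom,
  configurable.
* Protrusion: occupied volume floored at one atom volume, capped at
  the sphere volume, so the index is always finite and non-negative.
* Hydrogens: all descriptors are heavy-atom based; amide hydrogens are
  inferred geometrically where needed (Kabsch–Sander energies, H-bond
  angles).
* Modified residues (MSE and friends) map to their parent residue in
  lenient mode; unknown residues are skipped with a warning, or raise
  an error in strict mode.  Only model 1 of multi-model files is used;
  alternate locations resolve to the highest-occupancy copy.
* Degenerate cases: a training fold with one class votes for that
  class; constant features standardize to 0; a residue with no exposed
  atoms gets an all-zero electrostatic record with a warning.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script benchmarks run the full two-step
selection on the planted design (n = 293, 5 informative + 45 noise,
1.5-sigma shift, 86:207) over 20 and 10 seeds respectively, and the
cross-validation-ordering comparison (group_sd = 1, shift = 1.0) over
20 and 10 seeds.  These sizes mirror the scale of the curated
alanine-scanning dataset the method targets while keeping a full run
inexpensive on one CPU.

## Known limitations

* The electrostatic model is a screened Coulomb sum, not a
  Poisson–Boltzmann solution; esp values correlate with, but do not
  equal, grid-solver potentials.  The five summary definitions beyond
  the patch summary (esp3) are provisional.
* The relative-SASA convention is self-referential (package engine on
  extended tripeptides); values are not comparable with external
  normalisations at the second decimal.
* The secondary-structure re-implementation covers the canonical
  n-turn and bridge patterns; rare edge cases (chain breaks inside
  ladders, bulges) may differ from reference implementations.
* Real-data performance figures require curated complex structures,
  per-chain PSI-BLAST profiles and experimental ddG tables, which are
  not shipped; the planted benchmarks characterize the pipeline's
  behaviour, not its accuracy on real interfaces.
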