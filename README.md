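# pnhot

Hot-spot residue prediction on protein–nucleic-acid interfaces.

Alanine-scanning experiments show that a handful of interface residues
— *hot spots*, defined as residues whose mutation to alanine raises
the binding free energy by at least 2.0 kcal/mol — dominate the
affinity of protein–DNA and protein–RNA complexes.  `pnhot` is for
structural bioinformaticians who want to flag candidate hot spots on a
solved complex: it computes a 97-feature description of every
interface residue, selects a compact feature subset with a two-step
procedure, and classifies residues with an RBF-kernel support vector
machine.

## The method in brief

* **Interface residues**: residues whose buried SASA
  (SASA<sub>unbound</sub> − SASA<sub>bound</sub>, unbound = protein
  with the nucleic acid deleted) is > 0.  SASA is Shrake–Rupley
  sampling on a deterministic spherical lattice (probe 1.4 Å).
* **Features (97)**: 10 amino-acid physicochemical constants; 16
  depth-index (DPX) and protrusion-index (CX) features in bound and
  unbound states with Δ = unbound − bound and rel = Δ/unbound; 54 SASA
  features (five atom classes × absolute/relative × two states, buried
  differences, and buried values at powers 0.5/1.5/2.0, e.g.
  ΔSASsa<sup>1/2</sup>); 5 screened-Coulomb electrostatic summaries
  (esp1–esp5, esp3 = surface-patch mean); 2 interface hydrogen-bond
  counts; 5 one-hot secondary-structure indicators from a
  Kabsch–Sander assignment; 5 PSSM conservation features (entropy and
  smoothed relative-conservation ratios/differences).
* **Selection**: a CART tree screens the 97 features; a beam (width 3)
  sequential forward search, scored by leave-one-out F1 of an RBF-SVM
  at (G, C) = (0.1, 40), picks the final subset, stopping when the
  best F1 stops improving.
* **Model and evaluation**: RBF-SVM with G ∈ [0, 2], C ∈ [0, 40]
  selected by grid search on LOO F1; metrics SEN, SPE = TN/(TN+FP),
  ACC, PRE, F1 = 2TP/(2TP+FN+FP), MCC, plus AUROC (rank statistic) and
  AUPRC (step-wise integration); leave-one-residue-out and
  leave-one-complex-out cross-validation.

## Worked example

Everything below runs on synthetic inputs generated by the package
itself (no downloads):

```r
library(pnhot)

## a toy helix-DNA complex with a known contact face
tc <- make_toy_complex(n_res = 12, na_len = 4, gap = 4, seed = 1,
                       path = tempfile(fileext = ".pdb"))
cx <- load_complex(tc$path, "TOYC")
identify_interface_residues(cx)
#>   chain resno icode resname   key buried_sasa
#> 1     A     3           ASN  A_3_   16.729367
#> 2     A     6           ASN  A_6_    7.389026
#> 3     A    10           LYS A_10_   27.519893

## the full 97-feature table (PSSM profile also synthetic)
pssm <- parse_pssm(make_synthetic_pssm(12, conserved_positions = 3,
  seed = 2, query_seq = "VSNARNGRGKAL"))  # the toy chain's sequence
ft <- interface_feature_table(cx, pssms = list(A = pssm))
dim(ft$features)
#> [1]  3 97

## fit the classifier on a planted benchmark dataset
d <- make_planted_dataset(n = 120, n_informative = 3, n_noise = 10,
                          shift = 2, group_count = 8, seed = 7)
fit <- pnhot(d$x, d$y, groups = d$groups, seed = 7)
fit
#> Hot-spot classifier (RBF-SVM after two-step feature selection)
#>   n = 120 residues, 35 hot spots / 85 non-hot spots
#>   selected features: INF01, INF03
#>   SVM parameters: G = 0.1  C = 5
#>   LOO CV: F1 0.909  REC 0.857  PRE 0.968  SPE 0.988  ACC 0.950  MCC 0.878
#>   LOO CV: AUROC 0.976  AUPRC 0.959
predict(fit, d$x)[1:5]
#> [1] FALSE FALSE  TRUE FALSE FALSE
```

The planted benchmark has three informative features; out-of-fold F1
of 0.909 and AUROC of 0.976 say the selected model separates the
planted signal, not that any real interface would score this high.
`summary(fit)` adds the
round-by-round selection trace and, when `groups` are supplied, the
leave-one-complex-out report; `plot(fit)` draws the cross-validated
ROC and precision–recall curves.

A thin command-line wrapper ships in `inst/scripts/pnhot.R`
(`interface`, `label`, `features`, `registry`, `fixtures`,
`evaluate`).

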