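---
title: "Detecting and classifying short hydrogen bonds in protein-ligand complexes"
author: "shbligand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying short hydrogen bonds in protein-ligand complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shbligand)
```

## The problem

Short hydrogen bonds (SHBs) are hydrogen bonds whose donor and acceptor
heteroatoms sit substantially closer than the sum of their van der Waals
radii — a donor-acceptor distance $R$ of 2.3–2.7 Å, versus 2.8–3.2 Å for a
normal hydrogen bond (NHB). In this compact regime the interaction acquires
covalent character: the proton-transfer barrier drops toward the zero-point
energy of the O–H/N–H stretch, and the proton can become shared between the
heteroatoms. SHBs between amino-acid side chains and small-molecule ligands
(cofactors, carbohydrates, drugs) are common in enzyme active sites, but
they can only be resolved directly in atomic-resolution structures, and
force-field-based refinement actively suppresses them. A classifier that
predicts from chemical and sequence features whether a given protein–ligand
hydrogen bond is short therefore has practical value for structure
refinement and ligand design.

This package implements that pipeline end to end:

1. **Geometric detection** of hydrogen bonds in a structure, with three
   criteria applied literally: both heteroatoms are O or N; 2.3 Å $\le R
   \le$ 3.2 Å; the donor–H–acceptor angle $\theta \ge 135°$.
2. **Distance classification**: SHB for $R \le 2.7$ Å, NHB for $R \ge 2.8$
   Å; the 2.7–2.8 Å gap is reported as AMBIGUOUS and excluded from
   training, mirroring the two disjoint definition windows.
3. **Featurization** of each protein–ligand bond with 14 predictors: the
   charge, residue type and side-chain heteroatom of the amino acid; the
   group charge, functional group, $pK_a$, $pK_b$ and logP of the ligand;
   and the residue codes of the three sequence neighbors on each side of
   the hydrogen-bonded residue.
4. **Classification** with an undersampling ensemble of gradient-boosted
   tree models, averaging member probabilities and calling SHB when the
   averaged probability is at least the threshold (default 0.870).

## Detection model and its assumptions

Only **side-chain** heteroatoms of the 11 polar amino acids participate on
the protein side; backbone amides are not considered. On the ligand side,
every O/N atom is a candidate, with donor/acceptor capability derived from
its functional group. Protonation states are fixed pH-7 conventions:
Asp/Glu carboxylates and ligand carboxylate/phosphate/sulfate oxygens are
deprotonated acceptors; Lys/Arg are fully protonated donors; His is the
neutral tautomer with the proton on NE2 (a cationic override is available);
hydroxyls carry one proton; amide nitrogens fill their valence; an
aromatic nitrogen without an explicit proton is a pyridine-like acceptor.

Hydrogens are placed by **deterministic idealized geometry** rather than
force-field optimization: X–H bond lengths of 0.96 Å (O–H) and 1.01 Å
(N–H), standard hybridization angles, and rotatable hydroxyl/amine protons
oriented toward the nearest candidate acceptor within 3.5 Å. Pre-existing
hydrogens in the input are preserved. For near-linear bonds the 135° angle
criterion is insensitive to the sub-0.1 Å proton shifts a restrained
force-field minimization would add, but users should expect small
differences for marginal geometries; this is a deliberate simplification
that removes any molecular-mechanics dependency.

When both atoms of a pair could donate, both role assignments are
evaluated and the one with the larger $\theta$ is kept; exact ties go to
the lower atom index, a purely deterministic convention.

Ligand connectivity comes from a chemical-component-dictionary CIF when
one is supplied, otherwise from covalent-radius distance bonding with a
0.4 Å tolerance, with approximate bond orders inferred from bond lengths.
Functional groups are matched on the connectivity graph alone (never
coordinates) in a fixed most-specific-first order: oxygens on S/P first,
then carboxylate before carboxyl (decided by an explicit proton), then
ester and amide, then phenol before alkyl hydroxyl. Ten named groups map
onto four propensity types (L1 phenol; L2 alkyl hydroxyl; L3 sulfate,
phosphate, carboxyl, carboxylate; L4 ester, amide, alkyl amine,
N-containing aromatic heterocycle); anything unmatched is OTHER. A known
limitation of graph-only perception without explicit hydrogens is that a
five-membered-ring N–H (pyrrole-type) cannot be distinguished from a
pyridine-type nitrogen and is treated as an acceptor.

Polyols, PEG fragments, buffers and inorganic anions — crystallization
agents rather than biological ligands — are excluded through an editable
component-code list shipped with the package; waters are always excluded,
as are ligands containing no O/N. Resolution is recorded but never used as
a filter.

## Ligand physicochemical descriptors

$pK_a$, $pK_b$ and logP are taken from a user-supplied per-component table
when available. Otherwise a built-in fallback estimates logP with a
Wildman–Crippen style atom-contribution sum over the ligand graph (implicit
hydrogens from valence), and $pK_a$/$pK_b$ from canonical per-group
constants (for instance carboxylate 4.0, phosphate 6.8, phenol 10.0; the
$pK_b$ is 14 minus the conjugate-acid $pK_a$ of the basic site). For
multi-group ligands the value of the participating group is used. The
provenance (`table` vs `estimated`) is recorded per bond, and the fallback
can be disabled, in which case missing values propagate as `NA` — the
trees handle missing values natively.

## The classifier

Training data are imbalanced (roughly two NHBs per SHB), so the model is
an ensemble over **balanced undersamples**: each of the $k = 10$ members
receives every SHB plus an equal-size NHB sample drawn without replacement
within the member (overlap across members allowed). Each member is a
gradient-boosted tree model with 5000 trees and shrinkage 0.01 under the
**exponential (AdaBoost) loss**, implemented as a custom objective on the
xgboost backend with the matching half-logit link $p = 1/(1+e^{-2f})$; a
binomial-deviance objective is available behind the `loss` flag. The tree
**interaction depth** is a hyperparameter selected per member by 10-fold
cross-validation over candidates 1–12, minimizing mean validation loss
(ties to the smallest depth), after which the member is retrained on its
full balanced dataset. Prediction averages the member probabilities; the
recommended operating threshold is 0.870, applied inclusively
($p \ge$ threshold is SHB).

Categorical features are one-hot encoded against closed vocabularies
frozen in the model archive (20 residues + the terminus token `XTR` + an
`UNK` sink for unseen levels); indicator-column importances are folded back
onto their parent feature, normalized to 100% per member and averaged
across members, so importance is reported on the original 14 features.
Evaluation reports precision/recall over a threshold grid (all distinct
probabilities plus 0 and 1, or a uniform 0.001 grid), the ROC curve, and
the AUC in its rank-statistic form with ties counted one half — identical
to trapezoidal integration of the empirical curve.

A no-undersampling variant (`undersample = FALSE`), which trains every
member on the full table and behaves more conservatively toward the NHB
majority, is exposed as configuration rather than a separate code path.

## What the synthetic generators emulate

`synth_complex()` builds a schematic extended peptide with one donor or
acceptor side chain per planted contact and grows a small synthetic ligand
(hydroxyl, phenol, phosphate, carboxylate, amide or pyridine-type) so that
the planted donor–acceptor pair realizes the requested $R$ and $\theta$
**exactly** — the proton is written explicitly from the closed-form
triangle construction, so detection geometry is fully determined and a
brute-force application of the three criteria is a valid oracle. Decoy
contacts violate one criterion by construction and decoy carbon atoms
exercise ligand selection. The scaffold is deliberately schematic: bond
geometry within residues is plausible, but the fold is not physical, there
is no solvent, and secondary contacts between a ligand's other heteroatoms
and the protein can legitimately occur (the truth table therefore refers
to the planted pair, not to everything detectable).

`synth_feature_table()` draws the 14 predictors from fixed marginals —
uniform over the 11 polar residues and the 10 functional groups, sequence
neighbors uniform over the 20 amino acids, $pK_a \sim N(8,3)$,
$pK_b \sim N(10,3)$, $\mathrm{logP} \sim N(0,1.5)$ — and assigns labels
from a logistic model. The default class balance is 1019 SHBs per 3219
bonds, matching a realistic ~1:2 imbalance; a deterministic allocation
mode reproduces exact class counts for contract tests. Association
strength is specified per feature as an **odds ratio per unit of level
score**, with categorical levels scored on an even grid spanning
$[-2.5, 2.5]$ in propensity order and numeric features using their clipped
z-score. The span was fixed at design time so that an odds ratio of 9
represents a strong, near-separable association (Bayes-optimal AUC about
0.95), giving a fitted model headroom to demonstrate recovery, while an
odds ratio of 1 carries no signal; the numeric descriptors are sampled
independently of the functional group precisely so that importance
attribution in recovery tests is unconfounded. What passing these tests
shows is that the pipeline recovers planted associations under its own
generative assumptions — not that real hydrogen-bond data meet those
assumptions (real features are correlated, class balance varies, and
label noise is not logistic).

## Numerical and scale choices

* Distance classification boundaries are closed on the stated windows
  (2.7 is SHB, 2.8 is NHB); the open interval between them is AMBIGUOUS.
* Probabilities are clamped away from 0/1 only inside loss computations
  (at $10^{-12}$); predictions are reported unclamped.
* All randomness (undersampling, fold assignment, tree fitting, the
  generators) funnels through explicit integer seeds; training is
  reproducible bit for bit, and fitting is single-threaded for
  determinism.
* Test- and demonstration-scale runs use reduced configurations — a few
  hundred to 2000 records, 500 trees, a single depth candidate — chosen as
  the smallest sizes at which the recovery properties are stable; the
  5000-tree, depth-1–12-CV defaults remain the production configuration.
  The cross-validated depth selector is exercised separately on additive
  (depth-1) and XOR (depth-2) oracles, where the correct answer is known
  from the data-generating process.
* The balanced-undersample draw is without replacement within a member;
  members use sub-seeds derived deterministically from the master seed.

## Known limitations

* Corpus-scale figures (precision/recall at the recommended threshold,
  corpus AUC, corpus importance shares, propensity tables over thousands
  of bonds) require a curated set of atomic-resolution structures that is
  not shipped; the package computes all of these surfaces but documents
  no corpus values it cannot recompute.
* Graph-only functional-group perception is heuristic for exotic
  chemistry; unmatched groups fall into OTHER rather than failing.
* Idealized protonation ignores local electrostatics (e.g. shifted
  $pK_a$s in active sites); His tautomer choice and ligand amine
  protonation are conventions, overridable but not inferred.
* The fallback logP/pKa estimators are coarse screening values, not
  replacements for a dedicated property engine; supplying a measured or
  computed table is always preferred.
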