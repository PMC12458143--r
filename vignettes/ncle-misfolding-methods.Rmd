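---
title: "Methods: lasso entanglements, cut-site statistics, and misfolding mechanisms"
author: "lassomf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lasso entanglements, cut-site statistics, and misfolding mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lassomf)
```

## The problem

A non-covalent lasso entanglement (NCLE) is a topological motif of a folded
protein backbone: a loop closed by a non-covalent residue–residue contact,
threaded by one of the chain's termini. Proteins carrying native NCLEs are
hypothesised to misfold more often — the thread can fail to pass through the
loop, or pass through the wrong loop — and such misfolded states can be
near-native, soluble, and long-lived. `lassomf` implements the full desk
pipeline for studying this hypothesis:

1. detect and characterise native NCLEs in structures
   (`detect_raw_ncles()`, `cluster_ncles()`, `compute_features()`);
2. call residue-level misfolding signals from limited-proteolysis mass
   spectrometry (LiP-MS) peptide tables (`call_cutsites()`);
3. associate the two with odds ratios, propensity-score matching and
   permutation statistics (`residue_logistic_or()`, `propensity_match()`,
   `delta_or_permutation()`, ...);
4. classify protein essentiality from NCLE topology features (`lasso_cv()`);
5. classify misfolded trajectory frames and their mechanisms
   (`compute_Q()`, `compute_G()`, `classify_mechanism()`);
6. generate every input class synthetically with recorded ground truth
   (`make_lasso_curve()`, `simulate_peptide_table()`, ...).

## Entanglement geometry

### Partial Gauss linking numbers

The backbone is discretised into bonds with midpoints
$R_l = (r_l + r_{l+1})/2$ and gradients $dR_l = r_{l+1} - r_l$. For a loop
closed by a contact at residues $(i, j)$, the N-terminal partial linking
number is the double sum of the Gauss kernel

$$
g_N(i,j) \;=\; \frac{1}{4\pi} \sum_{m=6}^{i-5} \sum_{n=i}^{j-1}
\frac{R_m - R_n}{|R_m - R_n|^3} \cdot (dR_m \times dR_n),
$$

and $g_C$ runs the outer sum over $m = j+6, \dots, N-5$. The five-residue
trims at the chain ends and flanking the loop are part of the printed bound
convention and are implemented exactly as stated; an empty range contributes
zero, so a loop reaching to within ten residues of a terminus has no tail
sum on that side. A loop is flagged entangled when $|g_N| \ge 0.6$ or
$|g_C| \ge 0.6$ — the threshold is applied to the magnitude because linking
values are signed and a linking of $-0.9$ is unambiguously an entanglement.

Loop-closing contacts use the heavy-atom criterion (any pair of heavy atoms
within 4.5 Å); the trajectory order parameters use the Cα criterion (8 Å,
sequence separation ≥ 4, following the inner-sum convention $j = i + 4$; the
prose convention "at least 3 residues apart" is available via `min_sep`).

For whole-structure scans the kernel matrix is computed once and turned into
2-D prefix sums, making the partial linking of any loop an O(1) rectangle
query (`linking_prefix()` internally); the per-loop implementation and the
prefix-sum implementation are cross-checked in the tests against a naive
double-loop oracle.

### Crossings

Where the thread pierces the loop is found by spanning the closed loop
(backbone $i..j$ plus the closing segment) with a triangle fan from the loop
centroid and intersecting tail bonds with that surface (Möller–Trumbore).
The sign is the right-hand-rule orientation of the bond against the loop
traversal. Tail bonds immediately flanking the loop are excluded using the
same bounds as the Gauss tail sums; without this, bonds that graze the
surface right at the loop boundary produce spurious single crossings that
fragment the clustering. A piercing landing exactly on a shared triangle
edge is deduplicated by its position along the bond.

This fan-surface construction is exact for planar loops and degrades
gracefully for non-planar ones; it does not attempt minimal-surface
optimisation (a stated non-goal).

### Clustering and features

Raw entangled loops describing the same topology are merged
(single-linkage) when they have the same crossing terminus and sign pattern
and matched crossings within ±10 residues — the same window used for thread
regions elsewhere in the pipeline. The representative of a cluster is the
member with the minimal loop length. Each unique NCLE gets an 18-element
feature vector (loop length and relative position, tail lengths, |g| values,
crossing counts and depths per terminus, net crossing sign, loop–thread
separation, cluster size, protein length, spread of |g| across members).
This is **feature-set v1**, this package's documented stand-in for an
upstream feature list that is not printed in full anywhere we could pin it
to; analyses depending on the exact feature identities (e.g. which features
the essentiality classifier selects) are therefore comparable only within
this package's versioned definition.

### SASA

Solvent-accessible surface area uses Shrake–Rupley with probe 1.4 Å, 960
deterministic golden-spiral points per atom, and a pinned van der Waals
radii table. Translation invariance is exact; rotation re-samples the fixed
lab-frame point grid, so rotational invariance holds only to the grid's
angular discretisation error (< 1 % at 960 points) — an intrinsic property
of every fixed-grid Shrake–Rupley implementation, tested at that tolerance.

## LiP-MS cut-site statistics

A significant proteinase-K cut-site must change abundance at least two-fold
(boundary inclusive, on condition means of log2 abundances) **and** pass
Benjamini–Hochberg FDR at α = 0.05 in at least one refolding timepoint
(1 min, 5 min, 2 h). The per-timepoint test is a Welch t-test on log2
abundances across replicates — the upstream pipeline's exact statistic is
not restated in our sources, and Welch-on-log2 is the standard label-free
choice; it is symmetric in the two conditions. BH families are per
timepoint by default (`bh_family = "global"` is available). Sites with
all-zero untreated abundance have undefined fold changes and are excluded
rather than imputed; isolated zeros are imputed at half the protein's
smallest positive abundance. A protein is *refoldable* iff it has zero
significant cut-sites.

Protein abundance is controlled by the summed peptide ion abundance (SPA):
proteins are rank-ordered, percentile thresholds swept every 10th
percentile, and results reported at the 50th; ties share the lower
percentile rank so "≥ threshold" subsets are stable, and only proteins with
≥ 50 % sequence coverage are retained.

## Association statistics

* `fisher_or()` reports the sample cross-product OR with the exact
  conditional p-value and conditional-likelihood CI (Woolf interval above
  total 1000 for speed). The tests verify the p-value against full
  hypergeometric enumeration.
* `residue_logistic_or()` fits
  $\mathrm{logit}\, p = \beta_0 + \beta_{\text{region}} X_{\text{region}} +
  \sum_{AA} \beta_{AA} X_{AA}$ with alanine as the reference level and
  reports $e^{\beta_{\text{region}}}$ with Wald inference; on a
  region-only model this reduces (and is tested to reduce) to the collapsed
  2×2 cross-product OR. Perfect separation raises an error rather than a
  divergent estimate.
* `propensity_match()` matches NCLE to non-NCLE residues 1:1 without
  replacement on the logit propensity fitted from SASA, caliper 0.2 SD,
  treated units matched in decreasing propensity order. Balance is reported
  as the standardized mean difference of SASA and asserted below 0.1 in all
  generator scenarios with overlapping support.
* `delta_or_permutation()` permutes the buffer label **over proteins** —
  keeping a protein's residues together preserves within-protein
  correlation, which residue-level shuffling would destroy; the p-value is
  one-sided toward rescue (negative ΔOR) with (r+1)/(n+1) smoothing.
* DnaK motif scanning uses the expanded Bukau-like class word `BHHHHHB`
  with B = {R, K} and H = {A, V, L, I, M, F, W, Y}; other motif definitions
  are configurable pattern entries. Motif density is per 100 residues of
  the full protein length for every pool (whole sequence, loops,
  threads), as the density definition prescribes.
* The hydrophobic set defaults to {A,V,L,I,M,F,W,Y,C,G,P} and is
  deliberately a configurable argument: published hydrophobic fractions in
  the 62–64 % range imply a broad set whose exact membership we could not
  pin down.
* All permutation and bootstrap routines take an explicit seed and are
  bit-reproducible; permutation p-values use (r+1)/(n+1) smoothing so they
  are never exactly zero.

## Essentiality classifier

`lasso_cv()` is an L1-penalised logistic regression over a grid of inverse
regularization strengths C (default 1e-5 to 10 in 1000 **linear** steps, as
printed in the protocol this follows; log spacing is available but off by
default), evaluated by mean balanced accuracy over 5 stratified folds at a
0.5 posterior threshold. C maps to the glmnet penalty as
$\lambda = 1/(nC)$. Standardization is fitted inside each training fold and
applied to the held-out fold — the conservative reading that prevents
leakage. The optimal C maximises balanced accuracy with the fewest non-zero
coefficients (ties → smaller C, tolerance 1e-4). Permutation significance
re-runs the fold evaluation on label-permuted data at the selected C; the
statistic is |BA − 0.5|, two-sided.

## Trajectory misfolding analysis

Q is the fraction of reference native contacts whose current Cα distance is
≤ 1.2 × the reference distance, restricted to contacts inside the
secondary-structure assignment when one is supplied (the assignment is
consumed, not computed). G is the fraction of native contacts whose N- or
C-terminal partial linking, **rounded to the nearest integer**, differs
from the reference state. The rounding is a deliberate discretisation: a
literal `!=` on real-valued linking numbers is almost surely always true,
so "a change in entanglement status" is read as a change of the integer
linking state (magnitude or sign), consistent with how these order
parameters are used in the prior literature.

Thresholds come from reference (native-state) simulations: consecutive
15-ns windows, the mode of each order parameter per window (binned at
1/N_ref, a fraction's natural resolution; ties to the smaller value), then
$Q_{\text{thr}} = \overline{Q_{\text{mode}}} - 3\sigma$ and
$G_{\text{thr}} = \overline{G_{\text{mode}}} + 3\sigma$, with σ the sample
SD of the window-mode series per order parameter. A frame is native iff
$Q \ge Q_{\text{thr}}$ and $G \le G_{\text{thr}}$ (boundaries inclusive).

Misfolding propensity is the non-native fraction over the last 10 % of each
quench trajectory (configurable), pooled, with a basic bootstrap CI over
trajectories. The misfolded-state lifetime is the mean run length of
consecutive non-native frames × 0.075 ns; the alternative literal reading
(a *fraction* × 0.075 ns) cannot produce the ~100 ns median lifetimes the
approach is meant to separate, so the run-length reading is used and
documented here as an interpretation.

Mechanism classification compares each frame's integer linking states on
the native-contact loops against the reference: a *loss* is a reference
unique NCLE whose state changed; a *gain* is a loop entangled in the frame
but not in the reference (gains are clustered before counting). Mechanism
probabilities are normalised within each trajectory and averaged over
trajectories; structural interdependence asks whether a loss shares
loop-contact ± 3 or crossing ± 3 windows with a gain in the same structure.

## What the generators emulate — and what they do not

The synthetic module provides the study conditions for every test:

* `make_lasso_curve()` builds an ideal threaded loop with pseudo heavy
  atoms (four per residue on a fixed local frame) so contact logic runs
  without side-chain modelling. `make_interlocked_rings()` is the classic
  Hopf-link oracle whose linking number is known exactly.
* `simulate_peptide_table()` plants log-normal abundances
  (meanlog 10, sdlog 1 — chosen only to exercise SPA percentile logic),
  a 4-fold effect at planted sites, a region odds ratio on site
  significance, and a 72 % shared-across-timepoints fraction mirroring the
  reported overlap of observed non-native structure across refolding
  timepoints.
* `simulate_residue_dataset()` draws outcomes from the exact logistic model
  the estimator fits, with an optional burial channel (region residues 15 Å²
  more buried on average, burial adding 0.8 log-odds per 25 Å²) used to
  demonstrate de-confounding by matching.
* `simulate_trajectory()` scripts discrete conformational events (thread
  retraction, re-threading through a second loop, uniform expansion) on a
  two-loop curve with 0.05 Å Gaussian jitter. Events are instantaneous
  switches, so planted frame classes are recovered exactly; the connector
  between the two loops can be lengthened (`conn2_length`) to plant
  non-interdependent loss–gain pairs.

Passing these tests shows the estimators are correct on data generated by
their own model assumptions and on exactly scripted topology changes. It
does **not** show robustness to what real data add: misassigned peptides,
correlated abundance noise, non-log-normal intensity distributions,
structural disorder, partial occupancy, force-field artefacts, or gradual
(rather than scripted) conformational transitions. Conclusions about real
proteomes still require the real structures, peptide tables and
trajectories this package consumes.

## Numerical choices and degenerate inputs

* Problem sizes in the shipped checks: 50,000 residues × 100 seeds for OR
  coverage, 10,000 residues for matching, 500 replicates × 500 permutations
  for calibration, 40-frame scripted trajectories, a 50-value C grid —
  sizes at which every estimate is stable yet the whole suite runs on one
  CPU in minutes.
* Logistic fits run on prebuilt model matrices via IRLS (`glm.fit`);
  fitted probabilities within 1e-10 of 0/1 are treated as separation.
* Loops shorter than two bonds, collinear loop polygons, structures without
  heavy atoms, empty peptide families, all-zero untreated sites, windows
  longer than a trajectory, and trajectories with no misfolded frames all
  raise errors or documented exclusions rather than returning silent
  numbers.
* Chains with missing interior residues are split at gaps; loops spanning a
  gap are discarded (Gauss sums need a continuous curve).
* Interfaces are plain data frames; detection on a set of structures
  returns one tidy table per unique NCLE (`ncle_feature_table()`).

## Known limitations

* The 18-feature set is a versioned stand-in (above), so feature-selection
  results are defined relative to it.
* The crossing surface is a centroid fan, which can misplace crossings for
  strongly non-planar loops; the Gauss threshold, not the crossing count,
  decides entanglement.
* Greedy 1:1 caliper matching leaves a small residual imbalance when group
  SASA distributions are extremely separated; balance is always reported
  and asserted.
* `permutation_significance()` evaluates permuted datasets at the selected
  C rather than re-running the full grid, trading a slightly conservative
  null for tractability.
* No knot detection, no structure prediction, no spectrum-level
  quantification, no molecular-dynamics engine: those stages are upstream
  of this package by design.
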