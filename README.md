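# lassomf

Non-covalent lasso entanglements (NCLEs) and protein misfolding: detection,
statistics, and mechanism analysis.

A **non-covalent lasso entanglement** is a backbone loop, closed by a
residue–residue contact, threaded by one of the chain's termini. Proteins
that carry native NCLEs are prone to a characteristic failure mode: after
unfolding, the thread fails to re-pierce its loop (a *loss*) or pierces a
wrong loop (a *gain*), producing soluble, near-native, long-lived misfolded
states. `lassomf` is an R toolkit for studying this hypothesis end to end,
for structural bioinformaticians and proteomics analysts working with
protein structures, limited-proteolysis mass-spectrometry (LiP-MS) tables,
and coarse-grained folding trajectories.

## What it computes

**Entanglement geometry.** For a loop closed by a contact at residues
(i, j), the partial Gauss linking numbers of the terminal tails with the
loop are discrete double sums of the Gauss kernel,

    g_N(i,j) = (1/4π) Σ_{m=6..i−5} Σ_{n=i..j−1}
               (R_m − R_n)/|R_m − R_n|³ · (dR_m × dR_n),

with g_C summing tail bonds m = j+6..N−5. A loop is entangled when
|g_N| ≥ 0.6 or |g_C| ≥ 0.6; crossing residues are located by intersecting
tail bonds with a triangle-fan surface over the loop, raw entanglements are
clustered into unique NCLEs (±10-residue crossing window, minimal-loop
representative), and each gets an 18-feature topology vector and
Shrake–Rupley SASA.

**LiP-MS cut-sites.** A proteinase-K cut-site is significant if its
abundance changes ≥ 2-fold with Benjamini–Hochberg FDR < 0.05 in at least
one refolding timepoint (1 min / 5 min / 2 h). Proteins with zero
significant sites are *refoldable*. Abundance is controlled by SPA
percentile sweeps and a 50 % coverage floor.

**Association statistics.** Fisher exact and logistic odds ratios
(OR = e^β_region from `logit p = β₀ + β_region·X_region + Σ β_AA·X_AA`),
propensity-score matching on SASA (1:1 nearest neighbour, 0.2-SD caliper),
a protein-level permutation test for the chaperone change in OR (ΔOR),
DnaK-motif densities per 100 residues, loop-closing-contact amino-acid-pair
enrichment, and bootstrap/permutation group comparisons.

**Essentiality classifier.** L1-penalised logistic regression of
essentiality on the 18 NCLE features across a C grid (1e-5..10, linear),
scored by balanced accuracy over 5 stratified folds, with a permutation
null and a sparsity-first rule for the optimal C.

**Trajectory misfolding.** Q (fraction of native contacts within 1.2× the
native Cα distance) and G (fraction of native-contact loops whose integer
linking state changed), native-band thresholds from reference-simulation
window modes ± 3σ, misfolding propensity over the final trajectory window,
misfolded-state lifetimes, loss/gain mechanism probabilities, and the
structural interdependence of losses with gains (±3-residue windows).

**Synthetic data.** Seeded generators with recorded ground truth for every
input class: threaded/unthreaded lasso curves, Hopf-link rings, peptide
tables with planted fold changes and region odds ratios, residue datasets
with planted log-odds effects and burial confounding, feature tables with
planted class separation, and scripted-event trajectories.

## Worked example

Detect the entanglement planted in a synthetic lasso curve, then recover a
planted region effect from a synthetic residue dataset:

```r
library(lassomf)

lasso <- make_lasso_curve(loop_radius = 8, n_loop_points = 40,
                          thread_length = 15, pierce_offset = 0)
raw <- detect_raw_ncles(lasso$structure)
cluster_ncles(raw)[[1]]
#> <unique_ncle> cluster 1: 11 member(s), representative <raw_ncle> loop (20, 56)  gN=-0.764 gC=0.000  crossings: -9
```

One unique entanglement (eleven raw loop-closing contacts collapse into a
single cluster): a loop closed near residues 20–56 whose N-terminal thread
pierces it at residue 9 with negative chirality — the planted topology
(`lasso$ground_truth`). Now the association stage:

```r
d <- simulate_residue_dataset(50000, beta_region = log(1.44), seed = 7)$data
residue_logistic_or(d)
#> OR = 1.403 (95% CI 1.329-1.482), p = 3.27e-34 [logistic]
#>   n_proteins = 250
#>   n_residues = 50000
```

The fitted odds ratio of observing a cut-site in an NCLE region (1.40, CI
1.33–1.48) covers the planted 1.44: residues inside entangled regions are
~1.4× more likely to carry a misfolding signal, after amino-acid
composition.

```r
sim <- simulate_trajectory(n_frames = 40, events = list(
  list(time_ns = 0.9, kind = "retract_thread"),
  list(time_ns = 1.8, kind = "rethread", crossing_residue = 22)),
  conn2_length = 10)
ncs  <- native_contact_set(sim$reference)
refn <- reference_ncles(sim$reference, ncs)
calls <- lapply(sim$trajectory$frames, classify_mechanism,
                ncs = ncs, ref_ncles = refn)
table(vapply(calls, function(x) x$class, ""))
#>      both loss_only    native
#>        16        12        12
```

The scripted thread retraction (a loss of the native NCLE) and re-threading
through the second loop (a gain) are recovered frame by frame.

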