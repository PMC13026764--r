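---
title: "Assessing conformational ensembles with ensdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing conformational ensembles with ensdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdyn)
```

## The problem

Generative models and coarse-grained samplers now produce protein
conformational ensembles directly from sequence, at a fraction of the cost of
molecular dynamics (MD). Before such an ensemble can stand in for an MD
trajectory, one has to ask *in which respects* it reproduces the reference:
per-residue flexibility, correlated inter-residue motion, local contacts,
the relative population of known end states, and fitness of its frames for
downstream tasks such as ensemble docking. `ensdyn` implements that
assessment battery, plus seeded synthetic-ensemble generators with known
ground truth so that every stage of the battery can be validated without any
external trajectory data.

All coordinates are in Angstrom throughout; XTC input (stored in nm) is
converted at read time.

## Models and statistics

**Superposition.** Every comparison starts by removing rigid-body degrees of
freedom: each frame is superposed onto a reference with the Kabsch
algorithm (closed-form least squares via the SVD of the 3x3 covariance of
the centered point sets). Reflections are excluded by flipping the sign of
the smallest singular-vector pair whenever the naive solution has
determinant -1. Configurations whose covariance has rank < 2 (collinear or
coincident points) have no well-defined rotation and are rejected rather
than silently resolved. The fit uses C-alpha atoms by default because every
downstream statistic is defined on C-alpha coordinates.

**Flexibility (RMSF).** For atom $i$ with displacement
$\Delta x_i^t = x_i^t - \bar{x}_i$ about the ensemble mean,
$\mathrm{RMSF}_i = \sqrt{\tfrac{1}{N}\sum_t \lVert\Delta x_i^t\rVert^2}$.
Two ensembles of the same protein are compared by the Pearson correlation of
their RMSF profiles rather than by absolute error, so that a global scale
difference (e.g. different sampling timescales) does not mask agreement in
*which* regions are flexible.

**Motion correlation (DCCM).** The dynamic cross-correlation matrix has
entries
$C_{ij} = \sum_t \Delta x_i^t\!\cdot\!\Delta x_j^t \,/\,
\sqrt{\sum_t \lVert\Delta x_i^t\rVert^2 \sum_t \lVert\Delta x_j^t\rVert^2}$,
a symmetric matrix with unit diagonal and entries in $[-1,1]$. Agreement
between two DCCMs is the element-wise mean absolute error (MAE).

**Contacts.** The distance contact map entry $D_{ij}$ is the mean over
frames of the *minimum* distance between any selected atom of residue $i$
and any of residue $j$. The default selection is backbone + C-beta
(N, CA, C, O, CB), the atom set available from coarse-grained model output;
glycine contributes four atoms.

**Distribution shift.** To compare a wild-type ensemble with sequence
variants, all ensembles are aligned to one common reference, pooled, and a
single 2-component PCA of the flattened C-alpha coordinates is fitted on the
pool. Each ensemble is projected with that one model, histogrammed on a
shared grid, and compared by
$\mathrm{KL}(\mathrm{WT}\Vert\mathrm{Mut}) =
\sum_i B_i^{WT}\ln(B_i^{WT}/B_i^{Mut})$ in nats.

**Two-state bias.** Given matched apo and holo reference structures, each
frame is independently superposed onto each reference and its two RMSDs
recorded. Frames within a cutoff (default 3 A, strict inequality) of a
reference count as occupying that state; the summary also reports the
fraction of frames lying closer to holo than to apo, an axis-order-free
statement of "biased towards holo".

**Pocket-based structure selection.** Pocket-detection output (grid-point
clouds with energies) is scored per frame as the fraction of
reference-ligand atoms within a radius of any grid point, maximized over
pockets. Frames pass an adaptive exposure cutoff, their pocket-atom
coordinates (protein heavy atoms within a radius of the ligand) are reduced
to two principal components, partitioned by k-means, and each cluster
contributes its lowest-energy frame as a docking receptor.

**Screening evaluation.** With per-ligand labels and docking scores
(lower = better), the ROC sweeps thresholds over unique scores with ties
grouped; AUC is trapezoidal (equal to the midrank Mann-Whitney statistic);
the enrichment factor at a false-positive rate $f$ is
$\mathrm{TPR}(f)/f$ with TPR linearly interpolated on the curve; top-$N$
hits counts actives among the $N$ best scores.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| fit/metric selection | `calpha` | -- | all statistics defined on C-alpha |
| contact selection | `backbone_cb` | -- | atom set of coarse-grained output |
| close-contact cutoff | 5 | A | conventional contact criterion at C-beta resolution |
| sequence-separation strata | <20%, 20--80%, >80% | chain length | short/mid/long-range split; boundaries exclusive |
| terminal length | max(5, 10% of chain) | residues | per terminus |
| histogram bins | 50 x 50 | -- | resolves landscape structure at a few thousand frames |
| KL pseudocount | 1e-6 of total mass | per bin | keeps KL finite; negligible for populated bins |
| state cutoff | 3 | A | strict `<`; boundary frames are outside the state |
| exposure radius | 1 | A | tight shell; widen via the `radius` argument |
| exposure cutoff walk | start 0.5, step 0.1, >100 frames | -- | floor at 0 retains everything |
| clusters (k) | 5 | -- | receptor count for ensemble docking |
| k-means restarts | 10 | -- | best inertia kept; seeded, deterministic |
| score aggregation | `best` (minimum) | -- | standard ensemble-docking convention |
| enrichment FPR | 0.01 | -- | early-recognition level |

Every one of these is an explicit function argument (and CLI flag), and the
CLI echoes them into its JSON reports, because quantities such as KL depend
on the binning and pseudocount as part of their definition.

## The synthetic generators: what they do and do not emulate

The generators reproduce the *statistical* structure the metrics measure,
not force-field physics:

* `make_harmonic_ensemble()` adds zero-mean Gaussian displacements to a
  reference, each residue moving rigidly, with per-residue scale
  $\sigma_i$ per coordinate. The expected C-alpha RMSF is exactly
  $\sigma_i\sqrt{3}$. Inter-residue correlation $\rho$ is induced by a
  shared standard-normal latent factor per block and axis,
  $\Delta x = \sqrt{1-\rho}\,\varepsilon_i + \sqrt{\rho}\,\varepsilon_s$,
  which yields pairwise correlation exactly $\rho$ and is positive definite
  by construction (blocks must be disjoint).
* `make_two_state_ensemble()` mixes jittered copies of two references with
  a Bernoulli weight and returns the true per-frame labels.
* `make_shifted_ensemble()` displaces the reference along one fixed unit
  mode by chosen multiples of the noise scale, emulating
  variant-induced distribution shifts of controlled size.
* `make_pocket_scene()` places grid points on exactly $k$ of $n$ ligand
  atoms so the designed exposure $k/n$ is recovered *exactly*, plus a decoy
  pocket far from the ligand.
* `make_screening_table()` draws active scores from $N(-\delta,1)$ and
  decoys from $N(0,1)$, so the expected AUC is $\Phi(\delta/\sqrt{2})$ in
  closed form.

They do **not** emulate anharmonicity, secondary-structure-dependent
motion, solvent effects, side-chain packing, or realistic pocket geometry.
Passing the recovery suite therefore demonstrates that the *estimators* are
correct and well-calibrated at realistic sample sizes, not that any
particular generative model is accurate on real proteins.

Test problem sizes were chosen so every distributional claim sits well
inside its sampling error at desk scale: 5000 frames for RMSF/DCCM recovery
on 30--32 residues (relative RMSF error ~0.6%, correlation error ~0.01),
2000 frames per ensemble for KL and occupancy (binomial error ~1%), and
10000 + 10000 ligands for the binormal AUC check (error ~0.003).

## Numerical choices and conventions

* **Alignment and recovery tests.** Superposing every frame removes six
  rigid degrees of freedom, which for an $n$-residue C-alpha set removes
  roughly $6/(3n)$ of the displacement variance and induces weak spurious
  anticorrelations of order $-2/n$. The synthetic generators emit frames in
  a common reference frame already, so the recovery suites measure the
  estimators without this fitting artifact; with real trajectories the
  alignment step is required and these small biases are inherent to the
  statistics themselves.
* **Residue indexing** in all outputs is 1-based (the R convention), with
  original PDB residue numbers carried as labels.
* **MAE denominator.** Whole-matrix MAE averages over all $n^2$ elements,
  diagonal included, matching a plain element-wise mean; `diagonal = FALSE`
  and the stratified variant (unique $i<j$ pairs) are reported alongside in
  the CLI because the convention changes the value.
* **Boundary conventions.** Sequence-separation strata: `close` is strict
  `<`, `far` strict `>`, ties fall to `middle`. State membership and
  top-$N$ ranking: strict `<` at the cutoff; equal-energy cluster
  representatives break ties to the lower frame index; equal scores at the
  top-$N$ boundary break by ligand id.
* **PCA determinism.** Components are eigenvectors of the coordinate
  covariance via SVD; each component's sign is fixed so its
  largest-magnitude entry is positive, making projections reproducible
  across platforms.
* **KL zero bins.** The ratio is undefined where a variant bin is empty, so
  both tables get an additive pseudocount and are renormalized. The
  divergence is reported in nats.
* **ER interpolation.** The discrete ROC rarely has a vertex exactly at
  FPR = 0.01; TPR is linearly interpolated between vertices (recorded in
  the report metadata).
* **Exposure filter boundary.** A frame scoring exactly the cutoff is
  retained; the cutoff decreases while no more than `min_retained` frames
  survive. The two readings of the boundary differ only for scores exactly
  at a cutoff value.
* **Altlocs and insertion codes.** PDB reading keeps the
  highest-occupancy altloc and drops insertion-coded residues with a
  warning, so topology indexing is deterministic.
* **Trajectory formats.** DCD is read through bio3d. XTC has no R reader,
  so the package implements the xdrfile integer-compression scheme
  (3dfcoord) natively; it is validated in the test suite against files
  written by an independent implementation. XTC is lossy at its stored
  precision (0.01 A at the common precision setting), which bounds
  achievable round-trip agreement.

## Design choices where the procedure was open

* Ensembles are compared using **all frames**; no subsampling is applied.
* The PCA for pocket clustering is fitted on the **retained** frames'
  pocket-atom coordinates only (the filtered set is what gets clustered),
  with 2 components by default.
* Secondary-structure classes (H/E/C) are **consumed from an annotation
  file**; the package does not assign secondary structure.
* Matching of apo/holo residues is the **caller's responsibility**
  (curated, equally-sized coordinate sets); no internal sequence alignment
  is attempted.
* The aggregation of per-structure docking scores is per-ligand
  **minimum**; `mean`/`median` are provided for sensitivity checks.

## Known limitations

* The contact-map inner loop enumerates atom pairs per residue pair; it is
  exact but quadratic, sized for chains of a few hundred residues rather
  than large complexes.
* The native XTC reader is pure R and therefore slower than compiled
  readers on very long trajectories.
* KL estimates on 2D histograms carry a sample-size- and bin-dependent
  positive bias; compare divergences only across ensembles of similar size
  on one shared grid (as `ensemble_shift()` enforces), and report the bin
  count and pseudocount with any value.
* Periodic-boundary unwrapping, mmCIF input and hydrogens are out of scope;
  inputs are assumed whole.
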