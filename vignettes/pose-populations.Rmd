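---
title: "Methods: pose populations, docking triage, and competition-binding analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose populations, docking triage, and competition-binding analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posepop)
```

## The scientific problem

Small thiourea-scaffold fragments bind the m6A-recognition pocket of the
YTHDF2 reader domain. Because the thiourea ring is pseudo-symmetric, each
compound can occupy the pocket in two orientations — pose A and pose B —
related by a 180° rotation about the exocyclic S=C double bond. The flip
preserves the number of polar contacts but swaps partners: the two ring NH
groups donate to the C433 backbone carbonyl and the D422 carboxylate in both
poses, while the carbonyl oxygen hydrogen-bonds the Y418 backbone NH in pose
A and the conserved structural water in pose B. Crystallography often cannot
resolve which orientation dominates, so relative pose populations are
inferred from molecular-dynamics ensembles. This package implements that
inference, together with the two other quantitative legs of a fragment
campaign: triage of docking hits and analysis of competition-binding assays.

## Pose inference from trajectories

The pipeline (`cluster_poses()`) is a fixed chain of five operations.

**Subsampling** (`subsample()`). Only the second half of each run is
analysed, on a 1 ns grid, so the ligand has relaxed in the pocket and
successive frames are approximately decorrelated. Both window ends are
included: a 200 ns run sampled every 1 ns retains 101 frames from the
[100, 200] ns window. The boundary rule is documented rather than
consequential — one frame in a hundred does not move any estimate.

**Bound-frame selection** (`select_bound()`). A frame is bound when the
distance between the ligand's exocyclic sulfur and the C433 backbone
nitrogen is *strictly* below 5 Å. A frame at exactly 5.0 Å is excluded;
the strictness matters only on a set of measure zero but makes the
behaviour testable. Subsampling precedes bound-frame selection.

**Featurization** (`featurize()`). Ten pocket–ligand distances: four to
C433 (the S–N criterion distance, both ring NH groups to the backbone
carbonyl, and the carbonyl O to the backbone N), two ring-NH distances to
the D422 carboxylate oxygens, and one each from the exocyclic sulfur to the
Y418 backbone N and to the ring centroids of W432, W486 and W491. Atom
pairs are configuration-driven (`default_feature_pairs()`); the defaults
follow the hydrogen-bond partners seen in the crystal structures of the
series. Because the flip exchanges N1 with N2 and the carbonyl O with the
thiophene S, five of the ten distances differ sharply between poses — this
is what makes the two poses separable in feature space.

**Projection** (`project_2d()`). Principal components on mean-centered but
*unscaled* distances (all features share units of Å, so variance weighting
is meaningful as-is). Each component's sign is fixed so its
largest-magnitude loading is positive, which makes projections reproducible
across linear-algebra backends. A rank-0 matrix (no variance at all) is an
error; a rank-1 matrix — e.g. noise-free frames of the two templates, which
collapse to exactly two points — is legal and projects with PC2 ≡ 0 and a
warning. We deliberately resolved the degenerate case in favour of
projecting, because two-point geometry is exactly the idealised limit of
the two-pose hypothesis and must remain representable.

**Mixture fit** (`fit_mixture()`). A full-covariance Gaussian mixture in the
2-D PC space, fitted by expectation–maximization: k-means++ seeding, 10
restarts under one seed, best log-likelihood kept, tolerance 1e-6 on the
log-likelihood, 500-iteration cap, and a 1e-8 ridge on each covariance for
numerical safety. k defaults to 2 — the two poses are the hypothesis under
test, not a quantity to estimate; `fit_mixture()` accepts other k for
information-criterion exploration. Non-convergence is flagged on the result
(`converged = FALSE`), never silenced. Populations are hard-assignment
fractions (maximum responsibility). The EM is authored in this package
because its initialisation and restart policy are part of the method's
reproducibility contract; `mclust` serves as an independent cross-check in
the test suite and agrees to a fraction of a percentage point on separated
mixtures.

**Labelling and centroids.** Cluster identity is *never* taken from fit
order. The cluster whose centroid frame places the ligand carbonyl oxygen
closer to the Y418 backbone N than to the structural water is pose A, the
other pose B; ties break toward A (`label_clusters()`). The centroid frame
of a cluster is the assigned bound frame closest (Euclidean, PC space) to
the cluster mean, ties broken toward the earliest `(replicate, frame)` —
an arbitrary but deterministic rule. The test suite checks the centroid
against an exhaustive nearest-frame scan.

**RMSD stability** (`ligand_rmsd()`). Every frame is rigidly superposed on
the reference using protein Cα atoms (for the stylised pocket: all protein
anchors) via the Kabsch fit in `bio3d::fit.xyz`; RMSD is then computed over
ligand heavy atoms with no re-fitting on the ligand, so genuine ligand
excursions are not absorbed into the superposition. Across replicates the
median and one *unscaled* median absolute deviation are reported per time
point — the band drawn around median-RMSD traces. The reference is the
first analysed frame, treating "first frame" and "equilibrated starting
structure" as the same thing, which they are by construction here.
`compare_pose_stability()` reports time-averaged median RMSD per pose and
declares the lower one more stable; it attaches no significance claim,
because eight replicates do not support one.

## The synthetic-data generator

`generate_trajectory()` emulates exactly the statistical structure the
pipeline assumes: bound frames form a two-component mixture of the pose-A
and pose-B templates with isotropic Gaussian positional noise (default
0.3 Å per coordinate) on the ligand atoms, and a controllable fraction of
frames (default 10%) is rigidly displaced so the S–C433(N) distance exceeds
the 5 Å criterion by a safety margin. The templates are constructed
geometrically — pose B is pose A rotated 180° about the S=C axis — and the
pocket anchors are fixed pseudo-atoms placed so that every hydrogen-bond
relation of the real pocket holds (carbonyl-O→Y418 in A, carbonyl-O→water
in B, NH→C433/D422 in both). Defaults are 8 replicates × 200 frames at
1 ns: the production-MD sampling the analysis was designed for (after
subsampling to [100, 200] ns this yields ~100 frames per replicate).

Two deliberate simplifications:

* **Composition is exact, not Bernoulli.** The numbers of pose-A, pose-B
  and unbound frames are the rounded products of the requested fractions
  with the frame count, allocated across frames by a seeded permutation.
  Parameter-recovery tests therefore measure the *inference* error of the
  pipeline, not the generator's binomial sampling noise. Residual spread in
  recovered populations (~1.3 percentage points s.d. at ≈730 bound frames)
  comes from which frames fall inside the subsampling window.
* **No conformational realism.** Unbound excursions are rigid translations,
  noise is isotropic and (by default) uncorrelated between frames — an
  optional AR(1) term exists but is off, mirroring the 1 ns subsampling
  whose purpose is decorrelation. Passing tests on this generator show the
  statistical machinery is correct; they do not show robustness to slow
  conformational drift, partial unbinding, or force-field artefacts in real
  trajectories.

`generate_dose_response()` produces four-parameter-logistic signals with
multiplicative Gaussian noise (default CV 2%, ten half-log dilutions, four
replicates — typical FP-assay practice). `generate_docking_poses()` plants
a chosen number of poses that satisfy the pharmacophore by construction and
gives them more favourable energies than the displaced decoys.

## Docking triage

Docking energies are *inputs* — the package does not re-implement any
scoring function. `rank_poses()` builds two independent ascending rankings
(total binding energy; electrostatics-minus-desolvation) and shortlists the
union of the two top-n lists, because the selection procedure draws from
both rankings rather than from a composite score. Ties break by pose id.
`pharmacophore_filter()` keeps a pose only if a ligand donor hydrogen-bonds
the C433 backbone carbonyl — the interaction that mimics the natural
ligand's N6–H — *and* at least one of: a ligand acceptor receiving the
Y418 backbone NH, a ligand donor reaching D422, or a water-mediated
hydrogen bond in either direction. Hydrogen-bond geometry defaults to
donor–acceptor ≤ 3.5 Å with a D–H–A angle ≥ 120° when hydrogens are
present, and a plain 3.5 Å heavy-atom cutoff otherwise — standard
structural-biology practice. Aromatic stacking is not part of the filter:
the selection rule names only polar contacts.

## Competition-binding analytics

* `normalize_residual()` / `triage()`: percent of the DMSO control;
  compounds strictly below 60% residual signal at the screening dose
  advance. The cutoff is strict — 60.0% does not advance.
* `fit_dose_response()`: four-parameter logistic fitted by
  Levenberg–Marquardt (`minpack.lm::nlsLM`), parameterised in log10(IC50);
  Hill slope free by default (an option fixes it at 1). Fits that fail to
  converge, have no signal window, or put the IC50 outside the tested
  concentration range are returned *flagged* with a reason, never dropped —
  every compound appears in `fit_affinity_panel()` output with a status.
* `cheng_prusoff()`: Kd = IC50 / (1 + [L]/Kd_probe), with the FP probe at
  3 nM and probe Kd 5 nM (DF2), 7 nM (DC2), 5 nM (DC1); the DF2 divisor is
  therefore exactly 1.6.
* `ligand_efficiency()`: LE = −RT ln(IC50)/HAC in kcal/(mol·HAC) with
  R = 1.987×10⁻³ kcal/(mol·K). Assay temperature is not part of the
  printed conversion, so T defaults to 300 K (configurable); at 300 K the
  18 µM, 11-heavy-atom parent scaffold gives 0.59, a ~0.01 offset against
  values tabulated at slightly different conventions.
* `selectivity()`: fold-ratios Kd[p]/Kd[reference]; censored affinities
  ("Kd > 400 µM") are first-class and propagate as lower-bound ratios
  (label ">308" rather than a fabricated point value).
* `screen_summary()`: hit rate as rounded percent of actives (= IC50
  determined) among tested, with per-campaign breakdown.

Interference and solubility flags are explicit QC statuses set by the user;
the package never infers them from the data.

## Problem sizes and determinism

The test suite runs in a few seconds: pipeline tests use 2–4 replicates of
80–100 frames, which is ample for the well-separated synthetic clusters;
the acceptance-style checks use the full 8 × 200-frame default, and each
such run (generation + clustering) takes well under a second. All
randomness flows through explicit seeds (`with_seed` restores the caller's
RNG state), and the whole chain is deterministic given a seed — the same
configuration reproduces byte-identical cluster reports.

## Known limitations

* The stylised pocket is a set of fixed pseudo-atoms; protein flexibility,
  water exchange, and real Cα superposition noise are absent.
* Population estimates use hard assignments; for strongly overlapping
  clusters, responsibility-weighted populations would differ. The studied
  pose separation is large, so the difference is negligible here.
* The 4PL fit reports Wald confidence intervals on log IC50; profile
  intervals would be better behaved for shallow curves.
* Pose labelling assumes the carbonyl-O/Y418-vs-water geometry
  distinguishes the poses; for scaffolds without that hydrogen-bond swap a
  different labelling rule must be supplied.
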