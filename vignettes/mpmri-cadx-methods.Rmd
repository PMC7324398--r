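---
title: "Methods: multiparametric breast MRI CADx with deep transfer learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparametric breast MRI CADx with deep transfer learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

`mpcadx` implements a computer-aided diagnosis (CADx) pipeline that estimates
the probability that a breast lesion seen on multiparametric MRI is
malignant. Each lesion is observed in two sequences acquired in the same
exam: a dynamic contrast-enhanced (DCE) T1-weighted series (one pre-contrast
volume and at least two post-contrast volumes at 60 s intervals), whose
enhancement kinetics differ between benign and malignant lesions, and a
T2-weighted (T2w) volume, on which some benign lesion types (notably
fibroadenomas) appear bright relative to malignancies. The pipeline runs:

1. **Seeded segmentation.** Fuzzy C-means (FCM) clustering of voxel
   intensities on the second post-contrast subtraction volume, started from
   a single seed point per lesion.
2. **ROI construction.** A transverse maximum intensity projection (MIP) of
   the subtraction volume for the DCE branch; the slice containing the
   largest lesion area for the T2w branch, bicubic-resampled to the DCE
   in-plane resolution; both cropped with a common square box (lesion
   maximum dimension plus a 3-pixel parenchyma margin per side), each box
   centred on its own lesion footprint.
3. **Optional rigid registration.** The resampled T2w centre slice can be
   registered to the corresponding DCE slice (mutual information,
   translation + rotation only) before cropping.
4. **Deep features.** A frozen 19-layer VGG-architecture convolutional
   network; the activation maps of the five max-pooling layers are
   average-pooled over space, L2-normalised per layer, and concatenated into
   a 1,472-element descriptor (64 + 128 + 256 + 512 + 512). Because pooling
   removes the spatial axes, ROIs are used at their natural size — never
   resized.
5. **Classification.** Class-weighted RBF-kernel SVMs under nested
   patient-grouped five-fold cross-validation, calibrated to posterior
   probabilities of malignancy (PMs) and rescaled to a 50% prior.
6. **Fusion.** Three multiparametric schemes: *image fusion* (DCE MIP in the
   red channel, T2w centre slice in green, blue blank), *feature fusion*
   (concatenation of the DCE and T2w descriptors), and *classifier fusion*
   (soft voting: the average of the DCE and T2w PMs).
7. **Evaluation.** Empirical ROC/AUC, 2000-sample case bootstrap CIs,
   paired DeLong tests of each fusion scheme against each single-sequence
   scheme with Bonferroni–Holm correction, operating points minimising
   m = (1 − sensitivity)² + (1 − specificity)², and AUC equivalence testing
   with a ±0.05 margin.

## The synthetic phantom: what it emulates and what it does not

Clinical breast-MRI cohorts cannot be redistributed, so the package ships a
phantom generator that reproduces the *class-conditional structure* the
pipeline exploits, with known ground truth:

* **Cohort composition.** 78.5% malignant prevalence; roughly 1.5 lesions
  per patient (1 + Poisson), so patient-grouped cross-validation is
  genuinely exercised.
* **Lesion size.** Effective diameters are lognormal per class, truncated to
  the observed clinical ranges (benign 3.38–42.8 mm, malignant
  3.37–73.7 mm). The log-median is fixed at the clinical median (7.33 /
  14.9 mm) and the log-sd is calibrated numerically so the *truncated* mean
  equals the clinical mean (8.86 / 17.9 mm).
* **Kinetics.** Lesion voxels enhance relative to the pre-contrast
  parenchyma level: malignant lesions rise fast and plateau by the second
  post-contrast point (post1/post2 fractions 1.00/1.05), benign lesions
  enhance more slowly and persistently (0.45/0.75). Parenchyma enhances
  faintly (0.08).
* **T2w contrast.** Benign lesions are T2-bright (ratio 1.8 to parenchyma),
  malignant lesions T2-dark (0.65).
* **Class overlap.** Per-lesion Gaussian variability on the post2 fraction
  (SD 0.15 benign / 0.25 malignant) and the T2w ratio (SD 0.25 / 0.12)
  makes each sequence individually imperfect while keeping the two signals
  partially independent — the regime in which fusion can beat either alone.
  These SDs were fixed when the generator was designed. The post2 fraction
  is floored at 0.30: every included lesion enhances visibly, which mirrors
  the clinical precondition that a lesion must be seen on DCE to be seeded.
* **Shape.** Ellipsoids with volume-preserving random anisotropy; malignant
  lesions additionally get degree-2 directional-harmonic radial
  perturbations (amplitude 0.30) producing lobulated, still star-shaped and
  hence connected masks; benign lesions stay near-smooth (0.03).
* **Geometry.** DCE voxels 2.0 × 0.7 × 0.7 mm, T2w 2.0 × 0.55 × 0.55 mm —
  the in-plane resolution mismatch the T2w resampling step exists for. A
  configurable true inter-sequence offset supports registration tests;
  it defaults to zero.
* **Noise.** Additive Gaussian with SD 0.04 of the parenchyma level.
  Magnitude-MRI noise is Rician, but at the simulated contrast the Gaussian
  approximation is adequate for testing pipeline contracts, which is the
  phantom's purpose.

The phantom deliberately omits anatomy: no ducts, vessels, bias fields,
motion, or fat signal. Passing tests therefore certify the *mechanics* of
the pipeline (contracts, information flow, statistics) and the *recoverable
ordering* of its schemes on data with known structure — not clinical
performance. Clinical AUCs depend on real lesion morphology and scanner
physics that no desk-scale phantom reproduces.

## Segmentation details

FCM minimises \(\sum_{ik} u_{ik}^m (x_i - c_k)^2\) with
\(\sum_k u_{ik} = 1\), here on scalar intensities within a cuboid search box
of 30 mm half-width around the seed. Defaults: K = 2 clusters, fuzziness
m = 2, membership cut 0.5, convergence when the largest membership change
falls below 1e-5 (a scale-invariant criterion), 200-iteration cap. The
lesion cluster is the one with the highest centroid; the mask is the
26-connected component containing the seed.

Two numerical choices matter in practice:

* **Initialisation.** Centroids start at evenly spaced intensity quantiles,
  except the top centroid, which starts at the intensity maximum. A lesion
  occupying a fraction of a percent of the search box lies beyond any bulk
  quantile; anchoring the top centroid at the maximum lets the bright tail
  form its own cluster. The initialisation is deterministic and
  affine-equivariant, so segmentation is invariant to intensity rescaling.
* **Background-split guard.** With few clusters, splitting a large noisy
  background can lower the objective more than isolating a small lesion.
  A candidate component is accepted only when it is decisively brighter
  than the remaining box voxels (mean difference ≥ 3 remainder-SDs; a split
  noise floor or a lesion bloated by connectivity percolation through noise
  sits well below that) and, if it fills more than 25% of the search box,
  shows the stronger contrast (> 4 remainder-SDs) only a genuinely large
  lesion produces; otherwise the cluster count escalates (up to 6). If no cluster
  count works — for very small lesions the background's sheer voxel mass
  drags every centroid into the noise bulk regardless of K — the search box
  is halved (down to a 5 mm half-width) and the escalation retried. The
  per-iteration objective is checked to be non-increasing on every run.

The original clinical workflow used an FCM variant on enhancement kinetics;
its parameters are not published, so this intensity-based variant with the
same seed-point interface is a documented substitution, and all its
parameters are exposed in `fcm_params()`.

## Registration details

The rigid metric is mutual information on a 32-bin joint histogram with
partial-volume (bilinear) weighting: hard binning makes the metric surface
jagged under sub-pixel transforms and derails continuous optimisation,
while partial-volume weighting yields a smooth, sharply peaked optimum. The
search is a 7×7×7 coarse grid over (±10 mm, ±10 mm, ±10°); the three best
coarse cells are each refined on a local grid (a smooth metric can rank a
wrong cell first at coarse resolution) and the winner is polished by
Nelder–Mead. A tiny quadratic penalty (weight 1e-4 per mm²/deg²) on the
transform breaks metric ties toward the identity: a single round lesion on
homogeneous parenchyma leaves rotation unidentified, and an arbitrary
returned angle would needlessly perturb downstream ROIs. The penalty at a
genuine optimum (≲0.004 for a 3 mm / 5° transform) is two orders of
magnitude below typical metric differences. On slices above ~9,000 pixels
the metric is evaluated on a stride-2 pixel subsample; the MI estimate
saturates well below full density. The metric is computed over the overlap
region only, so border fill cannot drive it. Only the overlap rule, the
penalty and the multi-start refinement distinguish this from a textbook
MI registration; all three are motivated above and covered by
parameter-recovery tests (0.5 mm / 1° bounds).

## ROI and normalisation choices

"Maximum dimension" is read as the larger side of the lesion's axis-aligned
2D bounding box; the box is square to avoid aspect distortion; the margin is
3 pixels per side. Near image borders boxes are shifted, never shrunk, so
the side length stays comparable across sequences. The mask is carried to
the T2w frame by physical-coordinate nearest-neighbour lookup (spacings and
origins), not by re-segmentation. Before the backbone, each channel is
min–max rescaled to [0, 1] per ROI — removing scanner-gain dependence — and
standardised with the backbone's channel normalisation constants. Feature
extraction is therefore invariant to affine intensity changes of the raw
ROI.

Bicubic resampling uses the Catmull–Rom kernel (a = −0.5) with
centre-aligned physical extents, edge clamping and exact row-normalised
weights, so constants reproduce exactly and linear ramps survive to within
floating-point error away from borders.

## Backbone

The 16 convolutional layers (3×3, ReLU) in five blocks of 64/128/256/512/512
channels with 2×2 max-pooling form the classical 19-layer VGG architecture.
The forward pass is an im2col + BLAS matrix multiplication per layer.
Weights are frozen; the default source is seed-deterministic He-initialised
random weights, which need no download and suffice for every structural
contract (descriptor length, block norms, determinism, size-independence) as
well as for signal recovery on phantoms — randomly initialised convolutional
features are well known to preserve discriminative image structure.
Pretrained weights can be supplied as an RDS file and used
interchangeably. ROIs smaller than 32 px per side are zero-padded
symmetrically (never resized) so five 2× poolings leave at least one
spatial cell. Euclidean normalisation is applied per layer block, not over
the concatenation; the per-block reading keeps every depth's contribution
at unit scale regardless of channel count.

## Classification details

* **Grouped, stratified CV.** Patients (not lesions) are partitioned;
  per-fold lesion-level prevalence must stay within 5 percentage points of
  the cohort's (seeded reshuffles; error if unattainable). Inner folds on
  small training subsets use the best-balanced plan found instead of
  erroring. One outer partition realises the 64%/16%/20%
  train/validation/test split.
* **Per outer fold:** standardise to training mean/SD; PCA fit on training
  only with 95% retained variance (component count data-driven); (γ, C)
  selected on a 7 × 7 log-spaced grid (γ ∈ 10⁻⁵…10¹, C ∈ 10⁻²…10⁴) by inner
  five-fold patient-grouped CV maximising the mean inner AUC — AUC being
  the pipeline's figure of merit; class weights n/(2 n_c); sigmoid (Platt
  style) calibration fit by logistic regression on training decision values
  (chosen over libsvm's built-in probability machinery for exact
  run-to-run determinism); PMs rescaled from the training prevalence to a
  50% prior by the odds identity pm = (p/π) / (p/π + (1−p)/(1−π)), which is
  strictly rank-preserving, so AUCs are unaffected.
* **No leakage by construction:** every statistic applied to test folds is
  a function of training-fold data only, and test patients never appear in
  training folds.

## Statistics

AUC is the Mann–Whitney statistic computed via midranks (identical to
pairwise enumeration with half-credit ties). The paired DeLong test uses
structural components; its component means equal the Mann–Whitney AUCs
exactly, and its variance agrees with a leave-one-out jackknife to within
10% on small samples — both asserted in tests, alongside agreement with an
independent implementation (pROC). Bootstrap CIs are percentile with
case resampling (B = 2000), redrawing degenerate resamples. Holm correction
delegates to `stats::p.adjust`. Equivalence is CI inclusion in the open
interval (−0.05, 0.05). The empirical ROC is used throughout; fitted
parametric ROC curves are presentation devices and out of scope.

## Problem sizes used in the shipped experiments

The acceptance experiments run on an 80-patient cohort (~110–125 lesions at
~1.5 lesions/patient), the package's default `phantom_params()`. The
reproducibility check repeats the feature-fusion classifier — the scheme
whose run-to-run stability the pipeline reports — over 10 CV seeds; the
permuted-label control and the repeated runs use a reduced 3 × 3 (or 4 × 4)
hyperparameter grid, which the grid-search design allows since the
selection procedure, not the grid extent, is what those experiments probe.
The registration parameter-recovery scene combines the T2w centre slices of
two phantom lesions at a 15 mm offset, because a single centred
near-ellipsoidal lesion is rotationally almost symmetric and cannot
identify the rotation any registration method would need to recover. The registration-equivalence
experiment uses a smaller zero-offset cohort (30 patients, ~45 lesions) and
the T2w scheme, the scheme most affected by registration; the cohort is
sized so the paired DeLong interval of a genuinely null registration effect
has the precision the ±0.05 margin requires. The DeLong type-I
experiment uses 2,000 replicates of paired, latently correlated,
identically distributed scores at n = 100 (40 positive / 60 negative).

## Known limitations

* Random-weight features are weaker than pretrained ones; phantom AUCs
  certify ordering and machinery, not clinical accuracy, and the relative
  strength of the DCE and T2w branches on phantoms need not match clinic.
* The FCM variant operates on single subtraction intensities, not kinetic
  vectors.
* Registration is 2D (slice-wise), matching the ROI construction; no
  volumetric or deformable registration.
* The phantom's parenchyma is homogeneous; segmentation difficulty on real
  parenchyma is underrepresented.
* `fcm_segment` assumes one lesion per seed; multiple confluent lesions are
  returned as a single component.
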