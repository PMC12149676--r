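---
title: "Prior-conditioned auto-segmentation for adaptive radiotherapy: models, phantom and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-conditioned auto-segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During adaptive radiotherapy (ART) of the head and neck, anatomical change
— tumor shrinkage, weight loss — forces mid-course replanning, and the
primary gross tumor volume (GTVp) and organs-at-risk (OARs) must be
re-delineated on a fresh CT.  At that moment the patient's pre-treatment
planning CT and its clinically approved contours already exist.  This
package studies how that prior should be used by an automatic segmentation
method, comparing four regimes that differ only in *where* the prior
enters:

* **RM** (reference): no prior data; a 3D U-Net sees only the
  mid-treatment image.
* **PSM** (patient-specific): the prior enters at *training* time — test
  patients' pre-treatment images are pooled into the training set, which
  implies retraining for every new cohort.
* **GAM** (general adaptive): the prior enters at *inference* time as
  extra input channels (aligned pre-treatment image plus its label masks),
  so one trained model serves any new patient.
* **RIR**: no learning at all; rigid registration of pre to mid followed
  by contour propagation.

## Model

All learned regimes share one 3D U-Net: four down/upsampling levels, two
convolution blocks per level (3x3x3 convolution, stride 1, padding 1 →
instance normalization → ReLU), 2x max-pooling down, 2x2x2 stride-2
transposed convolutions up with skip concatenation, and a final 1x1x1
convolution to one channel per structure.  Channel width doubles per level
from a configurable base (default 8 at desk scale; clinical-scale networks
would use 32+).  Grid dimensions must be divisible by 2^4.

Design points the architecture description leaves open, and how this
package resolves them:

* **Output activation** is a per-channel sigmoid (multi-label), not a
  softmax: anatomical structures can overlap, and labels are missing per
  structure per case, both of which softmax's mutual exclusivity would
  forbid.
* **Convolution bias** is omitted wherever instance norm follows (its
  shift parameter absorbs it); the final convolution keeps a bias,
  initialized to -2 so the initial foreground probability is small —
  foreground is rare in multi-organ maps and a neutral start destabilizes
  the dice term.
* **Input normalization**: CT-analog intensities are clipped to
  [-1024, 3071] and scaled to [0, 1]; GAM label channels enter as {0, 1}.
  A consequence of instance norm directly after bias-free convolutions is
  that the network is exactly invariant to global rescaling of its input
  intensities — a calibration-robustness property worth knowing about
  (the tests assert it); nonlinear intensity changes such as clipping, and
  shifts (whose effect enters through the zero boundary padding), do alter
  predictions.
* **Channel order is contractual**: mid image, then (GAM) aligned pre
  image, then the S pre-treatment labels in fixed cohort structure order.

## Loss and training

The loss is a hybrid of soft dice and focal terms, aggregated as a
weighted mean over the structures present in the sample:

    L = sum_s present_s w_s u_s (lambda_d D_s + lambda_f F_s) / sum_s present_s w_s u_s

with `D_s = 1 - (2 Σ p t + eps)/(Σ p + Σ t + eps)` (eps = 1e-6) and
`F_s = mean_v [-(1 - p_t)^gamma log p_t]`.  Defaults `lambda_d = lambda_f
= 1` and `gamma = 2` follow the focal-loss family's convention; both are
configurable because the mix is not pinned down by the method description.
Class weights `w_s` are inverse presence frequencies over the training
samples ("inverse frequency" is read as per-sample label counts, the unit
in which the cohort's imbalance is expressed, not voxel frequency) and are
normalized to mean 1; a structure present in no training sample is
excluded with a warning.  Volume weights `u_s` are inverse mean volumes
(cm^3), also mean-normalized, and are applied only for the first 200 of
1000 epochs at clinical scale — early support for tiny structures (a lens
is ~4500x smaller than the brain) without permanently distorting the
loss.  Desk-scale runs keep the same 1:5 ratio (e.g. 12 of 60 epochs).

Optimization is Adam at learning rate 0.001, one sample per step, sample
order reshuffled per epoch, for a fixed number of epochs without early
stopping; the delivered weights are those of the epoch with the best mean
validation DSC.  Augmentation samples one spatial transform per sample
per epoch — translation, rotation, isotropic scale — applied identically
to every channel (linear for images, nearest for labels).  The published
ranges (+/-50 mm, +/-5 deg, 0.8-1.2x) are the defaults; desk-scale phantom
runs use +/-5 mm because +/-50 mm would push most of a 96 mm phantom out
of the field of view.

Training-set construction per cross-validation run (k folds, patient
level, equal sizes; validation patients drawn from the non-test
remainder):

* RM: every pre- and mid-treatment image of every non-test patient is a
  sample (110 patients, 22-patient test fold → 176 samples).
* PSM: RM's samples plus the test patients' *pre*-treatment images, with
  an equal number of other samples removed by a seeded uniform draw so
  counts match RM (176).
* GAM: one paired sample per non-test patient (prior pre → target mid)
  plus its time-reversed twin (prior mid → target pre), doubling the count
  (176) and using every label both as input and as target.

No regime ever sees a test patient's mid-treatment data; this no-leakage
invariant is asserted programmatically on every sample list.  One
published count is internally ambiguous: 176 = 88 non-test patients x 2
images, yet the split is also described as 70 training + 18 validation
patients.  The default (`mode = "paper"`) includes validation patients'
images in the sample pool, reproducing the 176; `mode = "strict"` restricts
samples to the 70 training patients (140 samples) for users who want the
validation set fully held out.

## Preprocessing and registration

Label cleanup interpolates missing axial slices — interior gaps of at
most 5 slices are filled by blending the flanking slices' signed-distance
fields and thresholding at zero (the bound is ours: unbounded filling
across distant fragments is unsafe, and the midpoint of two identical
shapes is exactly that shape) — followed by 26-connected component
filtering that keeps the largest component.  Cleanup precedes any
resampling, so interpolation cannot bridge what filtering should have
removed and vice versa.

The pre-treatment data are then rigidly aligned to the mid-treatment grid:
a multi-resolution (factors 4, 2, 1) mutual-information registration with
50 histogram bins, 10% metric sampling at full resolution, and Gaussian
pre-smoothing per pyramid level.  Two numerical choices matter here.
First, the MI estimate interpolates the moving intensity trilinearly and
spreads it linearly over the two adjacent bins, keeping the objective
continuous in the transform parameters.  Second, on noisy images the
interplay of interpolation and independent noise biases the rotation
optimum by one to two degrees unless both images are smoothed first; a
(1,2,1)/4 separable pass per level (doubling at coarser levels, where it
also acts as the anti-aliasing filter) removes the bias.  Per-level
optimization is quasi-Newton (L-BFGS on central-difference gradients) with
a derivative-free simplex polish at full resolution: a plain first-order
descent with a scalar step — the minimal reading of the published
optimizer settings, which leave the rotation-versus-translation parameter
scaling unspecified — stalls in the shallow rotation valley of the sampled
metric and was replaced after it repeatedly left ~2 degree rotation
residuals on phantom ground truth.  Transforms map fixed-frame world
points into the moving frame (`y = R (x - c) + c + t`, ZYX Euler angles,
voxel-center world coordinates, canonical RAS axes); masks are always
warped nearest-neighbour and stay strictly binary.  Near-identity
registrations (< 0.05 mm / 0.05 deg) snap to the identity so that
standardization is exactly idempotent on already-standard cases.

RIR as a *segmentation method* is exactly this registration followed by
warping all present pre-treatment masks; structures missing at
pre-treatment are marked absent in the prediction.

## The phantom cohort

The clinical dataset the design targets is private, so every stage is
exercised on a synthetic paired-timepoint cohort whose statistics mirror
it.  Each patient is an anisotropic ellipsoidal "head" (soft tissue 40 HU
inside air at -1000 HU) containing a bright skull shell (+750 HU) and
randomly oriented plane-wave soft-tissue texture at 16-56 mm length
scales; both give intensity-based registration the sharp, asymmetric
structure real CT has — with a blank interior, rotation recovery is
ill-posed and no registration method could be validated.  Into this
background go three analytic ellipsoid structures chosen to span the
regimes that matter clinically:

* `bone` — high contrast (+700 HU), rigid, large and low-variability: the
  mandible/vertebra analog every method should segment well (its size,
  ~10 cm^3, keeps the voxelization share of its surface small at 2 mm
  voxels, as for the clinical high-contrast structures at 1x1x2 mm);
* `plexus` — low contrast (+80 HU), deformable, elongated and small: the
  brachial-plexus/spinal-cord analog on which rigid propagation fails;
* `tumor` — near-floor contrast (+30 HU, the order of the noise and
  texture amplitude, mirroring how poorly the primary tumor contrasts with
  soft tissue on CT), high positional variability (12 mm sd) and size
  variability, shrinking between timepoints: the GTVp analog that defeats
  models without prior data.

The mid-treatment timepoint is generated analytically from the same
shapes: a global rigid transform (uniform +/-5 mm, +/-3 deg about the grid
centre) applied to everything; a band-limited random displacement field
(6^3 Gaussian control grid upsampled trilinearly, 3 mm sd per component —
a few mm of local motion, the regime in which rigid propagation degrades
without being destroyed) applied only to deformable structures; tumor
radii scaled by s^(1/3) for a volume
ratio s drawn from (0.4, 0.8); fresh additive Gaussian noise (20 HU) per
timepoint; and per-structure label dropout (5-15% for organs) per
timepoint.  Because shapes are re-evaluated analytically rather than
resampled, labels follow their structures exactly and the sampled rigid
transform is exact ground truth for rigid structures — which is what makes
registration-recovery tests and RIR baselines meaningful.  Defaults are a
48^3 grid at 2 mm spacing: trainable in minutes on one CPU.

What the phantom does *not* emulate: real anatomical shape detail and
inter-structure topology, contrast agents, CT artifacts, and volume change
in normal organs (shrinkage applies to the tumor only).  Passing tests
therefore validate the machinery and the *direction* of method
differences — prior-conditioned models beating a no-prior model on a
variable tumor, rigid propagation failing under local deformation — not
clinical performance levels.

## Evaluation

DSC is `2|A∩B|/(|A|+|B|)`; two empty masks score 1 (correctly predicted
absence) and are flagged.  MSD is the symmetric mean over both directions
of nearest-boundary distances in mm, with the boundary defined as
foreground voxels with a face-adjacent background neighbour (the volume
edge counts as background); it is undefined when either mask is empty, and
such cases are excluded-and-counted rather than assigned a penalty
distance, which would distort means unpredictably.  Both metrics are
verified against brute-force oracles (exhaustive voxel counting; all-pairs
surface distances via an exact anisotropic Euclidean distance transform).
Predictions are nearest-neighbour resampled to the reference grid before
scoring.

A structure "converged" for a run when its validation DSC exceeded 0.01 at
any epoch — the operational reading of "non-zero validation DSC" against
binarization noise; both the threshold and the any-epoch choice are
configurable surface area, since the source description does not pin the
epoch down.

Cross-validated comparisons use the corrected resampled t-test: per-fold
mean score differences `d_j`, statistic `t = mean(d) / sqrt((1/k + n2/n1)
var(d))` on k-1 degrees of freedom, two-sided, where the `n2/n1` term
inflates the variance to account for overlapping training sets across
folds.  The comparison report averages per fold, then reports mean +/- sd
over folds per structure and method, marks significant pairs at p < 0.05
without multiplicity correction (matching the annotation style of the
clinical tables it mirrors), and omits the sd when fewer than two folds
contribute.

## Problem sizes and reproducibility

All randomness — phantom sampling, fold plans, weight initialization,
sample order, augmentation, metric sampling — flows from explicit integer
seeds, and every stochastic component is deterministic given them.  The
test suite replicates the headline checks at deliberately small sizes
chosen as the smallest that still show the effects cleanly: metric-oracle
equivalence on random 14^3-20^3 blobs; 20 rigid recoveries within 1 mm /
1 deg on a 48^3 phantom; t-test calibration with 2000 simulated nulls; and
a 20-patient, 48^3, 2-fold, width-8, 60-epoch training comparison in which
the GAM's test DSC on the shrinking tumor exceeds the RM's by a clear
margin and exceeds RIR on the locally deformed structure.
`scripts/acceptance.R` recomputes the same families of quantities at a
12-patient, 30-epoch scale (about ten minutes on one CPU).

## Known limitations

Single-sample Adam steps (no batching) and float32 accumulation are tuned
for CPU-scale experiments, not GPU throughput.  The registration module is
rigid only — deliberately, since the rigid baseline is one of the methods
under comparison.  The phantom's deformation field is globally smooth;
it does not model sliding interfaces or articulated motion.  And the
corrected resampled t-test inherits its known conservatism: it trades
power for type-I control under fold correlation.
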