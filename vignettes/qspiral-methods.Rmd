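---
title: "Methods: a dual-track hybrid quantum-classical classifier for handwriting exams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a dual-track hybrid quantum-classical classifier for handwriting exams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Parkinson's disease (PD) impairs fine motor control, and one of the cheapest
non-invasive probes of that impairment is a drawing exam: the subject traces a
printed spiral or meander template with a colored pen, and tremor shows up as
oscillation of the drawn trace around the template. Public collections of such
exams pair each image with structured metadata -- demographics plus
trace-derived statistics such as the root-mean-square (RMS) deviation between
trace and template.

`qspiral` implements a dual-track classifier over these two modalities:

* **TVSFE** (image track): an attention-augmented convolutional encoder that
  produces a 256-dimensional unit-norm embedding, which is amplitude-embedded
  into an 8-qubit variational circuit; the readout is the vector of per-qubit
  Pauli-Z expectations.
* **VQFMN** (tabular track): six structured features (gender, handedness,
  age, RMS, MRT, std. dev. of deviations), normalized to $[0, \pi]$, encoded
  one-per-qubit by RY rotations and processed by strongly entangling layers,
  again read out as Pauli-Z expectations.
* **Fusion**: both readouts are layer-normalized, concatenated and passed
  through two dense layers and a softmax over {healthy, PD}.

All quantum circuits are simulated exactly on the statevector (no shot
noise), and the whole network -- convolutions, attention gates, batch/layer
normalization and both circuits -- is trained end-to-end by reverse-mode
automatic differentiation; circuit gradients use the adjoint method, which is
exact for unitary circuits.

# The synthetic exam generator

Real exam collections require downloads and ethics-bound redistribution, so
the package ships a generator that emulates their layout end to end and gives
every downstream stage a testable ground truth.

* **Templates.** Spirals are Archimedean curves $r = a + b\theta$ sampled
  densely over `n_turns` revolutions; meanders are square waves sweeping the
  canvas. A per-exam seed perturbs phase and scale so exams differ.
* **Tremor model.** The subject's trace displaces each template point along
  the local curve normal by $A\sin(2\pi f s) + \mathcal{N}(0, \sigma^2)$,
  with $s$ the normalized arc length. This is deliberately the simplest
  model that produces the loop irregularity a saliency method should find;
  it does not attempt biomechanical realism (no drift, no speed-dependent
  smoothing, no stroke lifts).
* **Defaults as study conditions.** Controls draw with jitter only
  ($\sigma = 1$ px); patients add a sinusoid with amplitude 6 px and 24
  cycles along the trace ($\sigma = 1.5$ px) on a 512 px canvas. Ages are
  class-conditional normals (healthy $44.22 \pm 16.53$, PD $58.75 \pm 7.51$
  years) truncated to [18, 90]; gender ratios follow the source cohort
  (controls 6M/12F, patients 59M/15F); handedness is 90% right. The stroke
  is 3 px with no anti-aliasing so the grayscale-suppression predicate
  behaves crisply.
* **Features.** With template and trace in point correspondence by
  construction, the deviations $d_i$ are exact; RMS $=\sqrt{\overline{d^2}}$
  and std\_diff $= \mathrm{sd}(d)$ are standard. MRT is reported in the
  source collections but never defined; the package uses the mean absolute
  first difference $\overline{|d_{i+1}-d_i|}$ as a documented stand-in that
  captures oscillation rather than offset.

Because controls have amplitude 0 and patients 6 px, the groups separate
strongly in RMS (about 1 px vs 4.5 px at the defaults). A passing end-to-end
test therefore shows that the pipeline can recover a planted, well-separated
signal -- not that the architecture reaches any particular accuracy on real
clinical data.

# Preprocessing

The image pipeline is denoise, suppress, resize:

1. **Denoise**: 3x3 mean filter then 3x3 median filter per channel, edges
   replicated. Order and size are exposed as configuration; kernel 1 is the
   identity.
2. **Grayscale suppression**: a pixel is set to white iff all three pairwise
   channel differences are strictly below 45. Near-gray pixels (printed
   template, scanner background) are removed; the saturated pen trace
   survives. The rule is idempotent and its suppressed-pixel count is
   monotone in the threshold. The complementary reading (whitening the
   *trace*) would destroy the only class-informative pixels, so the
   predicate form is taken as authoritative.
3. **Resize** bilinearly to a square side (512 default) and scale to [0, 1].
   Images stay 3-channel; the pen hue is informative and cheap to keep.

Structured features are mean/mode imputed and min-max normalized to
$[0, \pi]$ -- the domain RY encoding expects. Both the imputation statistics
and the ranges are fitted on the training split only and applied frozen to
validation/test, with out-of-range values clipped to the boundary; this
prevents leakage and keeps the encoding domain valid, at the cost of
saturating genuinely extreme test values.

# Architecture choices

The stem is a 7x7 stride-2 convolution (+BN+ReLU+3x3 max-pool). CDAB blocks
follow: a ghost module (half the output channels from a dense 3x3
convolution, half from cheap depthwise convolutions on those primary maps),
then attention -- coordinate attention followed by squeeze-and-excite in the
early stages, triplet attention in the later ones -- then batch
normalization, a residual path (identity, or 1x1 strided projection when
shapes change), and a ReLU after a post-sum batch normalization.

The default stage plan is four blocks of widths 64/128/256/512 with strides
1/2/2/2. Widths were chosen so the default model lands at about 1.2M
trainable parameters, the scale at which this architecture family is
reported; the plan is fully configurable. The embedding head is GAP -> dense
(LeakyReLU, slope 0.01) -> dense to 256, then layer normalization and L2
normalization, so the amplitude embedding receives a unit vector by
construction. Circuit depths default to 2 (image, 8 qubits) and 4 (tabular,
6 qubits); the strongly-entangling template is RZ-RY-RZ per qubit per layer
followed by a CNOT ring whose offset cycles with depth.

Qubit ordering is fixed: qubit 0 is the most significant bit of the basis
index. The convention only affects amplitude ordering, but it must be stated
once and respected by the simulator, the readout and the test oracle alike.

The three ablations -- image-only, tabular-only, and fully classical (each
circuit replaced by a dense map of the same output width) -- are pure
configuration switches on `model_config()`, never code forks, so every shape
contract holds identically under ablation.

# Training

The loss is focal loss with $\gamma = 3$ (and $\alpha = 1$, with an
inverse-class-frequency option), optimized by Adam at learning rate 1e-4,
batch size 4, with ReduceLROnPlateau (factor 0.5, patience 3) on the
validation loss and early stopping (patience 10); the best-validation
weights are restored. These defaults mirror the tuned recipe for the
full-size data regime.

The package's own end-to-end recovery experiment runs at desk scale: 80
synthetic subjects (40 per class, 4 draws each), 128x128 inputs, a reduced
two-stage model (~27k parameters), learning rate 1e-3, at most ~10 epochs.
The higher learning rate is a deliberate choice for this regime: the
synthetic set is two orders of magnitude smaller than real collections and
focal loss with $\gamma = 3$ damps gradients heavily while predictions are
still uncertain, so the published 1e-4 rate would spend most of the budget
in the flat region. Validation splits are grouped by patient (no patient
spans train and validation); an ungrouped mode exists for compatibility with
per-sample splitting.

Evaluation reports accuracy and macro-averaged precision/recall/F1 plus the
confusion matrix. Cross-validation is stratified 5-fold (optionally
patient-grouped); per-sample predictions pooled over folds feed a 10,000
resample percentile bootstrap for the 95% CI of mean accuracy.

# Explainability

**Grad-CAM** runs on any CDAB stage (default: the last): channel weights are
spatial means of the class-score gradient, the map is
$\mathrm{ReLU}(\sum_k w_k A_k)$, bilinearly upsampled to the input side and
min-max normalized, with the all-zero map left untouched rather than
divided by zero. On synthetic patient exams the package checks that at
least half of the top-5% saliency pixels fall within a 5 px dilation of the
exact pen-trace mask the generator recorded. This localization check is run
on the image-only ablation: a saliency claim is only meaningful for a model
whose decision actually flows through the image track, and at desk scale
the fused model reaches ceiling accuracy from the structured features
before its image branch becomes informative (see Known limitations).

**Perturbation sensitivity** scores each structured feature by the mean drop
in accuracy (optionally: in true-class probability) when that column alone
is perturbed -- permuted by default, which preserves marginals and needs no
noise scale; a Gaussian-noise mode (sd = column sd) is available. Negative
drops are clipped to zero. The recovery property is calibrated as a
parameter-recovery simulation: in 20 seeded trials with a single planted
signal feature, the planted feature must rank first in at least 19.

# Numerical choices

* Statevector simulation is exact; expectations carry no sampling noise.
  The simulator is cross-checked against an independent dense-matrix oracle
  (explicit Kronecker-product gate matrices, up to 4 qubits) to 1e-10, and
  adjoint gradients against central finite differences to 1e-5.
* `focal_loss` clamps $p_t$ at 1e-8; softmax is computed with the max-shift
  trick.
* Batch normalization uses batch statistics in training (momentum 0.1) and
  running statistics in evaluation, so evaluation is deterministic.
* Amplitude embedding rejects zero vectors; upstream L2 normalization makes
  the renormalization a no-op but the Jacobian of the normalization is kept
  in the gradient.
* All randomness (generation, initialization, shuffling, resampling,
  permutation) flows through explicit seeds; derived seeds stay within the
  32-bit integer range.
* Tensors are `H x W x C x N` arrays; convolutions run as im2col + BLAS
  matrix products with compiled gather/scatter kernels.

# Known limitations

* The tremor model is geometric, not biomechanical; transfer of any
  accuracy figure to real exams is explicitly out of scope.
* MRT uses a stand-in definition (see above).
* The generator draws template and subject traces in point correspondence,
  sidestepping the alignment problem real data has; the preprocessing module
  accordingly does not implement template registration.
* Statevector simulation scales as $2^n$; the package is written for the
  8-qubit regime, not for large circuits, and does not model hardware noise.
* At desk scale the structured features carry most of the class signal, so
  the fused model can reach ceiling accuracy before the image track is
  fully informative; the image-only ablation isolates the visual pathway
  when that matters.
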