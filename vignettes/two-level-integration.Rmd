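---
title: "Methods: heterogeneous texture features and two-level stacked-autoencoder integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterogeneous texture features and two-level stacked-autoencoder integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its own methods: the model at each
stage, the assumptions behind it, the tunable parameters and their defaults,
the numerical conventions, and what the synthetic test bed does and does not
establish about real immunohistochemistry (IHC) data.

## 1. Stain separation

IHC brightfield images mix two chromogens: a nuclear counterstain
(hematoxylin-type, called the *DNA* stain here) and the antibody-linked
chromogen (DAB-type, the *protein* stain). Under the Beer–Lambert law the
optical density of each RGB channel is linear in the per-stain
concentrations, so separation is a per-pixel linear least-squares solve
against the 3 × 2 matrix of stain absorbance vectors.

Conventions, chosen for robustness and testability:

* `OD_c = -log((p_c + 1) / (I0 + 1))`, the +1 offset avoiding `log(0)` at
  fully absorbed pixels; OD is clipped below at 0 (pixels brighter than the
  background carry no absorbance information).
* Negative least-squares concentrations are clipped to 0 — concentrations
  are physical quantities.
* The default basis is the canonical hematoxylin
  (0.650, 0.704, 0.286) / DAB (0.269, 0.568, 0.778) pair, unit-normalized,
  with background intensity `I0 = 255`. Both vectors and `I0` are
  configuration keys (`stain.*`): other scanners or chromogens need other
  vectors, and the method makes no attempt to estimate them blindly.

The assumptions are those of colour deconvolution generally: exactly two
stains, a spatially constant basis, and no chromatic saturation. The
separation is strictly per-pixel (translation-invariant by construction).

## 2. The five heterogeneous feature sets

Each separated image yields five descriptors. SLFs use both channels; the
four local descriptors see only the protein channel, min–max rescaled to
8-bit (a constant channel maps to all zeros — code descriptors need integer
gray levels, and the convention makes degenerate images testable). All
descriptors are computed on interior pixels only, with no padding, so no
artificial edge codes enter the histograms; every constituent histogram is
L1-normalized.

* **SLFs (840)** — four DNA-distribution statistics (fraction of
  above-threshold protein overlapping the above-threshold DNA region, with
  Otsu thresholds per channel; in/out protein signal ratio; normalized
  centre-of-mass distance in image-diagonal units; protein/DNA total signal
  ratio; ratio statistics return 0 on empty denominators, never NaN)
  concatenated with **836 Haralick values**. The published total of 836 is
  decomposed here as 19 co-occurrence statistics (Haralick's 13 plus
  autocorrelation, dissimilarity, cluster shade, cluster prominence,
  maximum probability, inverse difference) × 4 directions × distances 1–11
  at 32 gray levels, a single `haralick_config()` object that the
  dimensionality tests pin exactly. GLCMs are symmetric and normalized;
  0/0-form statistics (correlation, information measures) take their
  defined limits on degenerate matrices.
* **LBP (256)** — raw 8-neighbour radius-1 codes. The printed
  dimensionality 256 = 2^8 forces the unmapped code histogram (no
  uniform/rotation-invariant mapping). Bit 0 sits at the east neighbour,
  bits proceed counter-clockwise, comparison is `neighbour >= centre`, and
  non-integer neighbour positions are sampled bilinearly.
* **CLBP (906)** — the completed-LBP decomposition into sign, magnitude and
  centre operators. Layout: two scales (P, R) = (8, 1) and (16, 3); per
  scale a joint S/M/C histogram ((P+2)² × 2 riu2 bins) plus marginal S and
  M histograms; one global 2-bin C histogram, counted once because the
  centre operator (centre vs global mean) does not depend on P or R:
  220 + 684 + 2 = 906. The magnitude threshold is the image mean of the
  absolute differences, the classic adaptive choice.
* **RICLBP (408)** — 4-neighbour LBP codes (16 patterns) paired at a fixed
  displacement along the four axis directions; each pair is
  rotation-normalized (both codes cyclically shifted so the displacement
  points east, then identified with its 180°-reading), which collapses the
  256 ordered pairs to 136 classes — the structure behind the published
  408 = 3 × 136 over scales (radius, displacement) = (1,2), (2,4), (4,8).
* **LET (413)** — a locally encoded transform histogram: at Gaussian scales
  σ = 1, 2, 4 the gradient magnitude m of derivative-of-Gaussian responses
  is passed through the bounded transform u = m/(m + c) (c = 16 on the
  8-bit scale) and quantized to 7 levels; codes are histogrammed jointly
  across the three scales (343), jointly for the finest/coarsest pair (49)
  and marginally per scale (21): 413 total.

The Haralick, CLBP and LET decompositions are genuinely open design choices
— only the totals are pinned externally — so each lives in one configuration
object and the package treats the printed total as the contract.

## 3. Stepwise discriminant feature selection

Each raw set is reduced by classical stepwise discriminant analysis on
Wilks' lambda, `Λ(s) = det(W_s)/det(T_s)` (within-group over total scatter,
restricted to subset s). Forward steps enter the candidate with the largest
partial `F = (N − C − |s|)/(C − 1) · (Λ(s)/Λ(s ∪ {q}) − 1)` while it exceeds
`f_enter`; backward steps remove any member whose partial F falls below
`f_remove`. Implementation notes:

* Candidate Λ-ratios for all d features at once come from Schur complements
  of W and T on the selected subset (`O(d·k²)` per step), so the procedure
  scales to the 906-column CLBP set; the test suite checks the full greedy
  trajectory against a naive determinant-based implementation at d ≤ 6.
* Defaults `f_enter = 3.84`, `f_remove = 2.71` are the classical χ²-derived
  conventions; ties break to the lowest index for determinism; if nothing
  passes `f_enter` the single best feature is returned with a warning
  rather than an empty set.
* Columns are z-scored on the training rows before scatter accumulation
  (conditioning); the stored means/SDs transform test rows identically. The
  selected set itself is a pure column subset — no rotation or projection.
* `max_features` is always capped at `N − C − 1`, where the within-group
  scatter turns singular; singular scatters met earlier (e.g. perfectly
  separating features) fall back to a ridge-stabilized determinant with a
  warning.
* The pipeline-level default caps `max_features` at 40: beyond that the
  scatter solves condition poorly at desk-scale N and the downstream
  network gains nothing from further columns.

## 4. The SAE-SM classifier

Each optimal set feeds a stacked autoencoder with softmax head: two sigmoid
encoders pretrained greedily as sparse autoencoders, then fine-tuned
end-to-end under the softmax cross-entropy.

Pretraining loss per layer: mean squared reconstruction error (sigmoid
decoder, discarded afterwards; decoder weights untied) plus the KL sparsity
penalty `β Σ_u KL(ρ ‖ ρ̂_u)` on mean hidden activations plus L2 weight decay.
Defaults: ρ = 0.05, β = 3, λ = 1e-4, hidden sizes `max(⌈d/2⌉, C)` and
`max(⌈d/4⌉, C)` (the floor at the class count keeps the bottleneck from
collapsing below the label space when selection returns few features),
pretraining 100 epochs, fine-tuning 200 epochs. Inputs are min–max scaled
to [0, 1] per feature on the training rows (sigmoid reconstruction targets
must live there); constant features map to 0 and test rows are clipped into
the training range.

Optimization is deterministic full-batch back-propagation, seeded Glorot
initialization. Plain gradient descent at small fixed rates cannot leave
the uniform-softmax plateau of this architecture in any reasonable epoch
budget (the cross-entropy sits at log C essentially unchanged after
hundreds of epochs), so the updates use classical momentum (default 0.9)
with a bold-driver rate schedule: the step size grows 5% on every epoch
that improves the loss and, on an increase, the step is undone, the rate
halved and the momentum reset. This keeps training strictly monotone in the
recorded loss trace, deterministic given the seed, and convergent at the
default rate of 1.0 across the test fixtures. Analytic gradients of both
losses are verified against central finite differences to 1e-5 relative
error.

## 5. Two-level integration

T first-level SAE-SMs (one per optimal set) emit intermediate decision sets
`p_t` — N × C class-probability matrices. The mean ensemble
`F_ME = (1/T) Σ_t p_t` (element-wise, simplex-preserving,
permutation-invariant) is the input feature set of a second-level SAE-SM
with input dimension C and default hidden sizes (C, C).

How the second level's training inputs are produced matters: resubstitution
decisions from first-level models that saw the same rows would leak labels
into the fusion layer. The package uses out-of-fold stacking — the standard
leak-free construction: training rows are split into `stacking_folds`
(default 5; 3 in the desk-scale runs) stratified folds, and for each fold a
fold-specific selection + SAE-SM is fitted on the remaining folds to score
the held-out rows, so every `p_t` row comes from a model that never saw it.
Selection is re-run inside every stacking fold, mirroring the per-fold
selection discipline of the evaluation harness. The deployed first-level
models are then refitted on all training rows.

## 6. Evaluation

`compute_metrics()` reports overall accuracy, macro one-vs-rest
precision/recall/F1 (0/0 conventions return 0), the multiclass Matthews
correlation as Gorodkin's R_K on the confusion matrix, and per-class
one-vs-rest ROC AUC (trapezoid over all unique thresholds) and PR AUPR
(step-wise precision interpolation), summarized as mean and *population*
standard deviation over the classes — a descriptive spread over a fixed
class set, stated so the tests can pin it. Classes absent from the truth
are excluded from the AUC block with a warning. Whether headline CV numbers
should be fold-averaged or pooled over concatenated held-out predictions is
genuinely ambiguous; the harness reports both, and the acceptance script
quotes the pooled values.

`stratified_kfold_cv()` (k = 10 by default) deals shuffled per-class
indices round-robin, so per-class test counts differ by at most one; within
every fold the entire training procedure — selection, scalers, pretraining,
fine-tuning — is re-run on the training rows only. An audit collector
(`audit_enable()`) lets tests record exactly which sample ids every fitting
stage saw and assert they are disjoint from the held-out rows.

## 7. The synthetic test bed

The generator emulates the structure the pipeline exploits: a DNA
concentration map of random soft-edged nuclei plus a class-specific protein
map, rendered to RGB through the inverse Beer–Lambert map with the same
stain basis the separator assumes, plus Gaussian pixel noise (default sd 1
gray level). The seven default classes are texture archetypes — nuclear
(granular, DNA-overlapping), diffuse, fine spots, large spots, perinuclear
rings, fine stripes, coarse stripes — chosen to span the micro-pattern
families the descriptors detect; they share only the class count with a
real subcellular panel and make no biological claim. Stripe frequencies
(0.20 and 0.06 cycles/px) sit well below Nyquist so orientation jitter
cannot alias one class into the other.

What it does not emulate: tissue morphology, stain variability across
slides, chromatic saturation, focus gradients, multi-cell heterogeneity,
or class-ambiguous intermediate patterns. Passing the end-to-end tests
therefore establishes that the machinery is correct and leak-free — not
that the accuracies transfer to real IHC corpora, which are substantially
harder.

Problem sizes are the package's stated desk-scale study conditions: the
generator default is 256 × 256 with 35 images per class; the test suite
instantiates 64 × 64 with 14 images per class and the acceptance script
96 × 96 with 20 images per class, both with reduced epochs (pretrain 40,
fine-tune 200) and `stacking_folds = 3`, which a single CPU handles in
minutes while leaving the textures comfortably separable.

## 8. Known limitations

* The stain basis is assumed known; blind (NMF-style) estimation is out of
  scope.
* Full-batch training limits practical sample sizes to a few thousand rows
  per set; the bold-driver schedule assumes a deterministic loss.
* The Haralick/CLBP/LET decompositions are configuration-pinned
  reconstructions of published totals; alternative decompositions with the
  same totals exist and would change feature values (not dimensions).
* The serial-concatenation baseline is available only as a comparison mode
  (train a single SAE-SM on column-bound sets); it is not a tuned
  competitor.
* Single-label multiclass only; multi-label localization needs a different
  head and metrics.
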