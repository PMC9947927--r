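# subloc2l

Bioimage-based prediction of protein subcellular localization from
brightfield immunohistochemistry (IHC) images, built around a two-level
stacked-autoencoder integrator for heterogeneous texture feature sets.

## The problem

IHC images of human tissue are optical mixtures of a nuclear (hematoxylin)
stain and a protein (DAB) stain; the spatial texture of the protein signal
carries the protein's subcellular compartment (cytoplasm, ER, Golgi,
lysosome, mitochondrion, nucleus, vesicles). No single handcrafted texture
descriptor captures all of that structure, so practical classifiers extract
several *heterogeneous* feature sets — each describing the image from a
different angle — and must then integrate them. Plain serial concatenation
of the sets is the usual baseline; this package implements the stronger
decision-level alternative: train one classifier per feature set and fuse
their class-probability outputs with a mean ensemble feeding a second-level
classifier.

## The method

For each image the pipeline computes:

1. **Stain separation.** Per-pixel Beer–Lambert optical densities
   `OD_c = -log((p_c + 1) / (I0 + 1))` are solved in least squares against
   the two stain absorbance vectors (defaults: canonical hematoxylin / DAB),
   giving non-negative DNA and protein density maps.
2. **Five feature sets** (dimensions fixed by configuration):
   SLFs (4 DNA-distribution statistics + 836 Haralick co-occurrence
   statistics, 840 total), LBP (raw 256-bin local binary patterns), CLBP
   (completed LBP sign/magnitude/center histograms, 906), RICLBP
   (rotation-invariant co-occurrence of adjacent LBPs, 3 × 136 = 408) and
   LET (a locally encoded multiscale transform histogram, 413).
3. **Feature selection.** Stepwise discriminant analysis per set: forward
   selection with backward elimination on Wilks' lambda
   `Λ = det(W)/det(T)`, entering the feature with the largest partial
   `F = (N − C − |s|)/(C − 1) · (Λ(s)/Λ(s ∪ {q}) − 1)` while `F > F_enter`,
   removing features whose partial F falls below `F_remove`. The optimal
   subset `S_t^opt` is a pure column subset of `S_t`.
4. **SAE-SM classifier.** Two sigmoid encoders pretrained layer-wise as
   sparse autoencoders (reconstruction MSE + KL sparsity penalty
   `β Σ_u KL(ρ ‖ ρ̂_u)` + L2 decay), stacked under a softmax head and
   fine-tuned end-to-end on the categorical cross-entropy.
5. **Two-level integration.** T first-level SAE-SMs produce intermediate
   decision sets `p_t` (N × C class probabilities); the mean ensemble
   `F_ME = (1/T) Σ_t p_t` is the input of a second-level SAE-SM. Its
   training inputs are built out-of-fold so no first-level model scores a
   row it was trained on.
6. **Evaluation.** Overall accuracy, macro precision/recall/F1, multiclass
   Matthews correlation, per-class one-vs-rest ROC AUC and PR AUPR
   (mean/std over classes), under stringent stratified k-fold
   cross-validation in which selection, scaling and training are re-run
   inside every fold.

A seeded synthetic generator renders two-stain RGB images with
class-specific protein textures (nuclear, diffuse, spots, rings, stripes)
so the whole chain is testable without any external data.

## Worked example

```r
library(subloc2l)

# 1. synthesize a labeled 7-class IHC-like dataset (desk scale)
spec <- synthetic_spec(n_classes = 7, images_per_class = 14,
                       image_size = c(64, 64), seed = 5)
ds <- generate_dataset(spec)

# 2. separate stains and extract the five heterogeneous feature sets
sets <- extract_feature_sets(ds$images, ds$labels)
sapply(sets, function(fs) ncol(fs$matrix))
#>   SLFs    LBP   CLBP RICLBP    LET
#>    840    256    906    408    413

# 3. stringent 10-fold CV of the two-level integrator
cfg <- two_level_config(
  sda = list(max_features = 30),
  sae_first = sae_config(pretrain_epochs = 40, finetune_epochs = 200, seed = 7),
  stacking_folds = 3, seed = 11)
res <- stratified_kfold_cv(unname(sets), k = 10, cfg = cfg)
res$pooled
#> multiclass metrics (N = 98):
#>   OA      1.0000
#>   Prec_M  1.0000
#>   Rec_M   1.0000
#>   F1_M    1.0000
#>   MCC     1.0000
#>   meanAUC 1.0000 (std 0.0000)   meanAUPR 1.0000 (std 0.0000)
```

The seven synthetic texture archetypes are fully separable at this noise
level, so the pooled cross-validated accuracy reaches 1.0: every held-out
image is assigned to its true class, and every per-class ROC/PR curve is
perfect. On harder data the interesting quantity is the gap between the
two-level integrator and the best single feature set — the package's
complementary-views fixture (two feature sets that each resolve only half
the classes) shows the fusion gain directly (about 99% vs 80% accuracy).

A thin command-line wrapper is installed at `inst/cli/subloc2l`
(`subloc2l <extract|select|train|predict|cv|make-fixtures> --config cfg.yaml
[--seed N] [--out DIR]`).

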