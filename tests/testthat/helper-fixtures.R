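# Shared, lazily built fixtures cached across test files (generation and
# feature extraction are the slow steps; every consumer reuses one build).

.fix_cache <- new.env(parent = emptyenv())

# 7-class labeled image fixture at desk scale with all five feature sets.
get_image_fixture <- function() {
  if (is.null(.fix_cache$img)) {
    spec <- synthetic_spec(images_per_class = 14, image_size = c(64, 64), seed = 5)
    ds <- generate_dataset(spec)
    sets <- extract_feature_sets(ds$images, ds$labels)
    .fix_cache$img <- list(spec = spec, ds = ds, sets = sets)
  }
  .fix_cache$img
}

get_complementary_fixture <- function() {
  if (is.null(.fix_cache$comp))
    .fix_cache$comp <- complementary_feature_sets(n_classes = 7, n_per_class = 20, seed = 3)
  .fix_cache$comp
}

# Reduced-epoch training configuration used by end-to-end tests.
test_tl_config <- function(seed = 11) {
  two_level_config(
    sda = list(max_features = 30),
    sae_first = sae_config(pretrain_epochs = 40, finetune_epochs = 200, seed = 7),
    stacking_folds = 3, seed = seed)
}

# Small random channel pair for descriptor tests.
random_channel_pair <- function(n = 32, seed = 1) {
  set.seed(seed)
  structure(list(dna = matrix(runif(n * n, 0, 1), n, n),
                 protein = matrix(runif(n * n, 0, 1), n, n),
                 source_id = "random"),
            class = "channel_pair")
}
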