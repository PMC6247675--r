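# mplexmorph

Multiplex patch-correlation networks for structural brain MRI.

## What it does, and for whom

Localized atrophy — gray matter receding in favor of cerebrospinal fluid,
as in Alzheimer's disease — changes the *spatial pattern* of intensities
in a structural MRI long before it is obvious to the eye. `mplexmorph`
models a cohort of co-registered, intensity-normalized T1 volumes as a
**multiplex network**: the shared node set is a grid of rectangular
patches (default 10×15×20 voxels) tiling the two hemispheres, each
subject is one **layer** whose edges are thresholded pairwise Pearson
correlations between patch intensity vectors,

```
w_ij = 0        if |r_ij| <= tau        (tau = 0.3)
       r_ij     otherwise               (|r_ij| in the default abs mode)
```

and disease is read off the network geometry. Per node i and layer a the
package computes the strength `s_i = sum_j w_ij`, the inverse
participation ratio `Y_i = sum_j (w_ij / s_i)^2`, their degree-conditional
means `s(k)`, `Y(k)`, and four multiplex counterparts driven by the
aggregate adjacency `a_ij = 1 iff some layer connects i and j` — an
M × 8N feature matrix, built blind to diagnosis. A repeated 5-fold
random-forest wrapper (Gini importance, 500 trees, 1000 rounds) with an
exact binomial **occurrence test** (p < 0.01) selects the stable
features; a final forest classifies held-out subjects (test layers are
appended to the training multiplex without touching training features),
with bootstrap uncertainty, label-permutation and voxel-shuffle
robustness experiments, and back-mapping of significant patches to an
atlas. A seeded synthetic **atrophy phantom** exercises every stage
without any data download.

Intended users: neuroimaging methods researchers who have co-registered
volumes plus a brain mask (and optionally an atlas) and want a
patch-level, anatomy-agnostic atrophy signature with honest uncertainty.

## Worked example

A complete run on the built-in phantom (20 + 20 training subjects, five
lesioned left-hemisphere boxes, effect size 0.6):

```r
library(mplexmorph)

shape <- c(64, 72, 60)
template <- generate_template(shape, seed = 1)
grid <- build_patch_grid(shape, patch_spec(8, 9, 10), template$mask)
grid
#> patch_grid: 200 retained of 384 candidate 8x9x10 boxes on a 64x72x60 grid (min_overlap 0.1)

boxes <- pick_affected_boxes(grid, template, n = 5, hemisphere = "L")
cohort <- generate_cohort(phantom_config(shape, n_per_class = 20,
                                         effect_size = 0.6,
                                         affected_boxes = boxes, seed = 7))
layers <- lapply(seq_along(cohort$volumes), function(i)
  build_layer(cohort$volumes[[i]], grid, correlation_config(),
              cohort$subject_ids[i]))
layers[[1]]
#> layer_network: 200 nodes, 7183 edges (tau = 0.3)

sel <- select_features(layers, cohort$labels,
                       selection_config(n_rounds = 50, seed = 3))
#> cv accuracy 1.000 +- 0.000, 398 of 1600 features selected (p0 = 0.30)
```

The cross-validated accuracy is the mean validation accuracy over the 50
selection rounds; 398 of the 1600 node features occur significantly more
often than the pooled null rate 0.30. Held-out classification appends
each fresh subject's layer to the training multiplex:

```r
test <- generate_cohort(phantom_config(shape, n_per_class = 10,
                                       effect_size = 0.6,
                                       affected_boxes = boxes, seed = 8))
test_layers <- lapply(seq_along(test$volumes), function(i)
  build_layer(test$volumes[[i]], grid, correlation_config(),
              test$subject_ids[i]))
mux <- multiplex(layers)
model <- train_final(feature_matrix(mux), cohort$labels,
                     selected_features(sel), selection_config(), seed = 5)
evaluate_test(model, mux, test_layers, test$labels, n_boot = 100, seed = 9)
#> accuracy 1.000 +- 0.000 | sensitivity 1.000 +- 0.000 | specificity 1.000 +- 0.000 (n_boot = 100)

head(as.data.frame(region_report(sel, mux, grid, cohort$atlas,
                                 cohort$atlas_names))[
  , c("region", "p_value", "n_patches", "hemisphere_l", "hemisphere_r")], 3)
#>                    region      p_value n_patches hemisphere_l hemisphere_r
#> 1 left_posterior_inferior 1.030212e-26        21           21            0
#> 2  left_anterior_inferior 1.030212e-26        20           20            0
#> 3 left_posterior_superior 1.030212e-26        20           20            0
```

The top-ranked regions are exactly the left-hemisphere octants carrying
the injected lesions: the phantom's atrophy is recovered, localized and
lateralized. On this strong, noise-free-by-construction phantom the
held-out metrics saturate at 1.0; real cohorts will not.

A thin CLI wraps the same functions
(`Rscript inst/cli/mplexmorph.R run --seed 1 --out results/run1`); see
`vignettes/multiplex-morphometry.Rmd` for the model, design decisions and
known limitations.

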