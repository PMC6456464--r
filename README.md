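# mammotriage

Automatic triage of **special diagnostic mammography views** — spot
compression, magnification, stereotactic, specimen, and wire-localization
(WL) images — so they can be removed before a large archive of clinical
mammograms is turned into a machine-learning training set. Special views are
heavily enriched for cancers; leaving them in teaches a downstream model to
recognize the *acquisition artifacts* of diagnostic workup instead of
malignancy. DICOM headers alone are not a reliable flag (wire-localization
images in particular are technically ordinary full-field acquisitions), so
the package combines metadata and pixel evidence.

Intended users: imaging-informatics and ML teams curating mammography
archives, and anyone who needs a fully synthetic, self-contained testbed for
DICOM metadata/image pipelines.

## Method

Three classifiers produce a per-image probability *s* of being a special
view:

1. **Header model** — DICOM tags are filtered (fields with > 10% missing
   values and date/time, device-identifier, and demographic fields are
   dropped), numeric fields are median-imputed with missing-flag columns,
   categorical fields are one-hot encoded, and a gradient-boosted tree
   ensemble is trained with a stratified fivefold cross-validated grid
   search selected on auROC. An elastic-net logistic regression and a
   single-field baseline on `ViewModifierCode` (Laplace-smoothed category
   rates) are available for comparison.
2. **General image model** — a truncated Inception-style CNN (stem, four
   inception blocks, global average pooling, dropout, one dense sigmoid
   unit) on 99 × 99 bilinearly downscaled images, all layers trained.
3. **Wire-localization detector** — the full-depth topology at 299 × 299
   with only the final dense layer trained on frozen-trunk features,
   targeting the thin bright guide wire that headers cannot see.

Image models use horizontal-flip **test-time augmentation**: the general
model averages the two scores, the WL detector takes their maximum. Scores
are fused by fixed algebra:

```
s_combined_image = max(s_img, s_wire)
s_final          = max(s_wire, (s_img + s_hdr) / 2)
```

The operating threshold is the **largest** cutoff whose sensitivity on
labeled data meets a target (default 99%); everything scoring at or above
it is removed from the corpus. Evaluation statistics — Mann–Whitney auROC
with DeLong variance, confidence intervals and the paired DeLong test,
average precision, thresholded precision/recall/F1/accuracy, the exact
McNemar test, and Bonferroni adjustment — are implemented from first
principles (`pROC` serves only as an independent cross-check in the tests).

Because no public mammography archive with these labels exists, the package
ships a **synthetic phantom generator**: schematic DICOM files whose pixels
carry class-discriminating artifacts (collimation circle, guide wire,
fiducial grid, specimen container) and whose headers are statistically
correlated with view class, with configurable missingness and decoy fields.
The whole pipeline is exercisable offline on these phantoms.

## Worked example

```r
library(mammotriage)

dir <- tempfile()
manifest <- generate_corpus(dir, benchmark_composition(), seed = 0)
manifest <- augment_wire_cases(manifest, dir, total = 17, seed = 0)

cfg    <- run_config(manifest, target_sensitivity = 0.99)
bundle <- run_train(cfg)
print(bundle)
#> <model_bundle>
#>   schema: 24 fields
#>   threshold: 0.5164
#>   validation ensemble auROC: 0.9998
#>   holdout ensemble auROC: 0.9973

sort(bundle$header_model$feature_importance, decreasing = TRUE)[1:3]
#>                        ViewModifierCode=
#>                                    45.5
#> EstimatedRadiographicMagnificationFactor
#>                                    21.2
#>                        BodyPartThickness
#>                                     9.5
```

The bundle's validation ensemble auROC of 0.9998 means the fused score
almost perfectly ranks special views above full-field views on held-out
phantoms; the header model's most influential feature is the (empty vs.
coded) view modifier indicator, and the printed threshold is the largest
score cutoff that still catches at least 99% of special views. Applying the
bundle to unlabeled files partitions them into keep/remove lists:

```r
res <- run_filter(bundle, unlabeled_paths, out_dir = "filtered/")
length(res$removed) / (length(res$kept) + length(res$removed))
#> [1] 0.09
```

A thin command-line front end over the same functions is installed at
`inst/cli/mammotriage.R` (subcommands `simulate`, `train`, `filter`,
`evaluate`).

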