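# netbrainage

Which brain networks drive brain-age prediction, and what is their
molecular signature? `netbrainage` is an R package plus analysis workflow
answering that question on gray-matter morphometry:

1. **Brain age.** Gaussian process regression predicts chronological age
   from regional gray-matter volumes (mean GMV per atlas ROI) under
   repeated 10-fold cross-validation. Performance is summarized by the
   mean absolute error (MAE) and the Pearson correlation *r* between
   chronological and predicted age; each subject's brain-predicted age
   difference (brain-PAD = predicted − chronological) is tested against
   sex (controlling for age and age²) and total intracranial volume.
2. **Computational lesion analysis.** The prediction is re-run once per
   brain network with that network's ROIs removed, on identical fold
   partitions. Network importance is scored with Steiger's Z for two
   dependent correlations sharing one variable —
   Z = (z_full − z_lesioned)·√(n−3)/√(2−2c) with z = artanh r — so a
   positive Z means the lesion degraded performance; p = 2(1 − Φ(|Z|)).
3. **Transcriptomic annotation.** The decisive network is annotated with
   genes from a multi-donor spatial expression dataset: 6-mm sphere ROIs
   map each sample into the network (admitted when > 50% of sphere voxels
   fall in the brain mask), expression is normalized per donor by
   (x − median)/median, genes are tested by label permutation with
   max-statistic family-wise-error control, and the significant gene list
   is summarized by hypergeometric over-representation analysis against
   GMT gene sets with Benjamini–Hochberg FDR.

Synthetic-data generators (atlas parcellation, aging cohort, spatial
expression, gene sets) provide known ground truth, so every stage is
testable end to end without external downloads. See the methods vignette
(`vignettes/brain-age-networks.Rmd`) for the model details and design
choices.

## Worked example

The numbered drivers under `analysis/` run the whole study at desk scale
(68 ROIs in 17 networks, 250 subjects, age signal planted in network 5):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_predict.R
Rscript analysis/03_lesion.R
Rscript analysis/04_annotate.R
Rscript analysis/05_enrich.R
```

Output of a run:

```
simulated: 250 subjects x 68 ROIs (signal in network 5), 200 genes x 326 samples, 40 gene sets
brain age: r = 0.837 (per-repeat mean 0.835), MAE = 7.72 years
brain-PAD covariates: sex p = 0.308, TIV p = 0.745
top network by lesion importance: 5 (Z = 4.588, p = 0.0000)
7 of 17 networks decline with age (all expected negative in network 5)
annotating network 5: 313/326 samples admitted, 9 in cluster
18 genes FWE-significant; 18/20 planted signal genes recovered
1/40 terms enriched at q < 0.05; top term: PLANTED (k/K = 18/20, q = 4.1e-22)
```

Reading this: the cohort's age signal lives in network 5 only, so the
predictor reaches r = 0.84 from those four ROIs alone, brain-PAD shows no
sex or TIV association (none was planted), and lesioning network 5 — and
only network 5 decisively — degrades the prediction (Z = 4.59). The
annotation stage recovers 18 of the 20 genes whose expression was shifted
in network-5 samples, and the enrichment stage flags exactly the planted
term. (Only the planted network is constructed to atrophy here; a cohort
generated with default all-network atrophy shows all 17 networks
declining with age.) Tables land under `results/`.

The same machinery is available programmatically:

```r
library(netbrainage)
atlas  <- generate_atlas(246, 17, seed = 1)
cohort <- generate_cohort(atlas, 492, truth = cohort_truth(17, seed = 2))
cv     <- run_cv(cohort$gmv, cohort$phenotypes$age, k = 10, repeats = 5,
                 seed = 3)
cv$r          # 0.899 — near the generator's design ceiling of 0.89
lesion <- run_lesion_analysis(cohort, atlas, repeats = 5, seed = 3,
                              full = cv)
head(lesion$table)
```

Or as one call: `run_pipeline(pipeline_config(seed = 42), "out/")` writes
every stage's tables plus a manifest with config, seeds and checksums.

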