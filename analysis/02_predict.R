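#!/usr/bin/env Rscript
# Stage 2 — brain-age prediction.
#
# GP regression on the ROI volumes under 10-fold cross-validation (5
# repeats); reports MAE, the age-prediction correlation, and brain-PAD
# covariate checks (sex controlling age + age^2; TIV correlation).

source("analysis/common.R")

gmv <- read_gmv_table(file.path(DATA_DIR, "gmv.tsv"))
phen <- read.delim(file.path(DATA_DIR, "phenotypes.tsv"))

cv <- run_cv(gmv, phen$age, k = 10L, repeats = 5L, seed = SEED + 4L)

write.table(data.frame(subject_id = phen$subject_id, age = phen$age,
                       predicted = cv$mean_predicted,
                       brain_pad = cv$brain_pad),
            file.path(RESULTS, "predictions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sex <- test_sex_difference(cv$brain_pad, phen$sex, phen$age)
tiv <- test_tiv_association(cv$brain_pad, phen$tiv)
metrics <- list(n = nrow(gmv), k = 10, repeats = 5, kernel = cv$kernel,
                mae = cv$mae, r = cv$r,
                r_per_repeat_mean = mean(cv$r_per_repeat),
                sex_t = sex$statistic, sex_p = sex$p,
                tiv_r = tiv$statistic, tiv_p = tiv$p)
jsonlite::write_json(metrics, file.path(RESULTS, "prediction_metrics.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("brain age: r = %.3f (per-repeat mean %.3f), MAE = %.2f years\n",
            cv$r, mean(cv$r_per_repeat), cv$mae))
cat(sprintf("brain-PAD covariates: sex p = %.3f, TIV p = %.3f\n",
            sex$p, tiv$p))
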