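#!/usr/bin/env Rscript
# Stage 7: what drives the models?
#
# An extended clock (markers + sex + smoking status, smokers included in
# training) is probed with permutation feature importance — the MAE
# increase when one input column is shuffled — and with the partial
# dependence of predicted age on the binary smoking input. Note the PD
# direction: because the synthetic markers encode *accelerated* biological
# age, a smoker with the same blood profile as a nonsmoker must be
# chronologically younger, so the model learns a negative smoking
# adjustment (the published study reports the opposite on real data, where
# survivorship — excluded from this generator by design — is in play).

suppressPackageStartupMessages(library(bloodclock))
recon <- read_cohort("results/cohort_reconstructed.csv")
sets <- jsonlite::read_json("results/feature_sets.json",
                            simplifyVector = TRUE)
markers <- sets$markers[[length(sets$markers)]]
usable <- markers[vapply(markers, function(m) !anyNA(recon[[m]]),
                         logical(1))]
features <- c(usable, "sex", "smoking")

spec <- split_spec(seed = 70L, train_population = "all_with_smoking_feature")
parts <- split_train_test(recon, spec)
clock <- train_age_model(parts$train, features, spec, arch_config())
rep <- regression_metrics(predict_age(clock, parts$test))
cat("extended clock held-out:\n"); print(rep)

pfi <- permutation_importance(clock, parts$test, metric = "mae",
                              n_repeats = 10, seed = 71)
utils::write.table(as.data.frame(pfi), "results/importance.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("\ntop features by permutation importance (MAE increase, years):\n")
print(utils::head(as.data.frame(pfi), 8), digits = 3, row.names = FALSE)
cat("smoking-status rank:", pfi$rank[pfi$feature == "smoking"], "of",
    nrow(pfi), "\n")

pd <- partial_dependence(clock, "smoking", background = parts$test)
utils::write.table(as.data.frame(pd), "results/pd_smoking.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat(sprintf("\npartial dependence: PD(smoking=0) = %.1f y, PD(smoking=1) = %.1f y\n",
            pd$mean_prediction[pd$grid == 0],
            pd$mean_prediction[pd$grid == 1]))
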