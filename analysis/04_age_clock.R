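#!/usr/bin/env Rscript
# Stage 4: train the aging clock on nonsmokers and predict everyone else.
#
# The clock is a small two-hidden-layer network minimizing MAE, width
# selected by five-fold cross-validation, trained on 80% of the nonsmokers
# with markers z-scored by training-set statistics. Smokers never enter
# training, so their predicted ages read off how much "older" their blood
# chemistry looks.

suppressPackageStartupMessages(library(bloodclock))
recon <- read_cohort("results/cohort_reconstructed.csv")
sets <- jsonlite::read_json("results/feature_sets.json",
                            simplifyVector = TRUE)
markers <- sets$markers[[length(sets$markers)]]
usable <- markers[vapply(markers, function(m) !anyNA(recon[[m]]),
                         logical(1))]
features <- c(usable, "sex")
cat("clock features:", length(features), "(", length(usable),
    "markers + sex )\n")

nonsmokers <- recon[recon$smoking == 0, ]
spec <- split_spec(seed = 40L)
parts <- split_train_test(nonsmokers, spec)
clock <- train_age_model(parts$train, features, spec, arch_config())
cat("chosen hidden width:", clock$fit$width, "\n")

heldout <- rbind(parts$test, recon[recon$smoking == 1, ])
pred <- predict_age(clock, heldout)
utils::write.table(pred, "results/predictions.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

rep_ns <- regression_metrics(pred[pred$smoking == 0, ])
rep_sm <- regression_metrics(pred[pred$smoking == 1, ])
cat("\nheld-out nonsmokers:\n"); print(rep_ns)
cat("\nsmokers (never trained on):\n"); print(rep_sm)
jsonlite::write_json(list(nonsmokers = unclass(rep_ns),
                          smokers = unclass(rep_sm)),
                     "results/age_clock_metrics.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)
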