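#!/usr/bin/env Rscript
# Stage 6: classify smoking status from blood markers and sex.
#
# A binary-cross-entropy network (smoker = positive class, threshold 0.5)
# trained on blood markers and sex, never seeing the smoking label as
# input. The arbitrage ranking optimizes for *age* signal, so it leaves out
# the four markers carrying the direct smoking signature (HDL down;
# hemoglobin, RDW, MCV up — which have no age response by design); they are
# added back here, mirroring the study's observation that exactly those
# markers dominate its smoking classifier. Below age 55 the classifier
# also sees the acceleration signature; at and above the plateau only the
# direct offsets remain, so errors concentrate in the older bins.

suppressPackageStartupMessages(library(bloodclock))
recon <- read_cohort("results/cohort_reconstructed.csv")
sets <- jsonlite::read_json("results/feature_sets.json",
                            simplifyVector = TRUE)
markers <- sets$markers[[length(sets$markers)]]
usable <- markers[vapply(markers, function(m) !anyNA(recon[[m]]),
                         logical(1))]
signature <- c("hdl", "hemoglobin", "rdw", "mcv")
features <- c(union(usable, signature), "sex")

spec <- split_spec(seed = 60L, train_population = "all_with_smoking_feature")
parts <- split_train_test(recon, spec)
clf <- train_smoking_model(parts$train, features, spec, arch_config())
lab <- predict(clf, parts$test, type = "class")
rep <- classification_metrics(parts$test$smoking, lab)
print(rep)
jsonlite::write_json(unclass(rep), "results/smoking_metrics.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)

conf <- confusion_by_age_group(parts$test$smoking, lab, parts$test$age)
utils::write.table(conf, "results/confusion_by_age.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("\nerror rate by age group:\n")
print(conf[, c("age_group", "n", "error_rate")], digits = 2,
      row.names = FALSE)
wrong <- lab != parts$test$smoking
cat(sprintf("\nerror rate < 55: %.3f   error rate >= 55: %.3f\n",
            mean(wrong[parts$test$age < 55]),
            mean(wrong[parts$test$age >= 55])))
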