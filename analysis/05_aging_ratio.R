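#!/usr/bin/env Rscript
# Stage 5: quantify smoking-associated age acceleration.
#
# The per-sample statistic is log2(predicted / chronological age): 0 means
# on-clock, 1 means predicted twice as old. Cells are (age group x sex x
# smoking) with a two-tailed Mann-Whitney test of smokers vs nonsmokers
# within each (age group x sex) stratum. The generator plants factors of
# 2.0 (females) and 1.5 (males) below age 55, so the recovered smoker means
# should sit near log2(2) = 1 and log2(1.5) = 0.585 there and near 0 at and
# above the plateau. A cholesterol-ratio x fasting-glucose quadrant
# breakdown mirrors the cardiovascular-risk view.

suppressPackageStartupMessages(library(bloodclock))
pred <- utils::read.delim("results/predictions.tsv")
class(pred) <- c("prediction_set", "data.frame")
recon <- read_cohort("results/cohort_reconstructed.csv")

tab <- group_aging_summary(pred)
utils::write.table(tab, "results/aging_ratio.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("aging-ratio cells (populated):\n")
print(tab[tab$n > 0, ], digits = 3, row.names = FALSE)

ratio <- log2_aging_ratio(pred)
below <- pred$age < 55
cat(sprintf("\nmean log2 ratio, female smokers < 55: %.3f (planted 1.000)\n",
            mean(ratio[below & pred$smoking == 1 & pred$sex == 0])))
cat(sprintf("mean log2 ratio, male smokers   < 55: %.3f (planted %.3f)\n",
            mean(ratio[below & pred$smoking == 1 & pred$sex == 1]),
            log2(1.5)))
cat(sprintf("mean log2 ratio, smokers       >= 55: %.3f (planted 0)\n",
            mean(ratio[!below & pred$smoking == 1])))

# risk quadrants need the three risk markers for the held-out rows;
# rebuild the held-out frame with the same seeded split as stage 4
nonsmokers <- recon[recon$smoking == 0, ]
spec <- split_spec(seed = 40L)
parts <- split_train_test(nonsmokers, spec)
heldout <- rbind(parts$test, recon[recon$smoking == 1, ])
stopifnot(nrow(heldout) == nrow(pred))
risk <- assign_risk_groups(heldout)
rtab <- risk_group_aging_summary(pred, risk)
utils::write.table(rtab, "results/risk_ratio.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
pop <- rtab[rtab$n >= 10 & rtab$age_group %in% c("<31", "31-40", "41-50"), ]
cat("\nyoung cells by risk quadrant (n >= 10): smokers minus nonsmokers\n")
for (qd in unique(pop$quadrant)) {
  sm <- pop[pop$quadrant == qd & pop$smoking == 1, "mean_ratio"]
  ns <- pop[pop$quadrant == qd & pop$smoking == 0, "mean_ratio"]
  if (length(sm) && length(ns))
    cat(sprintf("  %-22s delta = %+.3f\n", qd, mean(sm) - mean(ns)))
}

# robust marker-age association for the top-ranked markers
rank <- utils::read.delim("results/feature_rank.tsv")
top <- utils::head(rank$marker, 5)
bc <- vapply(top, function(m) {
  ok <- !is.na(recon[[m]])
  biweight_midcorrelation(recon[[m]][ok], recon$age[ok])
}, numeric(1))
bc_tab <- data.frame(marker = top, bicor_with_age = round(bc, 3))
utils::write.table(bc_tab, "results/bicor_top_markers.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("\nbiweight midcorrelation with age, top-ranked markers:\n")
print(bc_tab, row.names = FALSE)
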