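Package: bloodclock
Title: Blood-Biochemistry Aging Clocks and Smoking-Associated Age Acceleration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds and evaluates hematological aging clocks from routine blood
    biochemistry and cell-count panels. Generates synthetic cohorts with a
    planted, recoverable smoking effect on biological age; ranks markers by an
    arbitrage feature-importance statistic aggregated over many tree-ensemble
    models trained on distinct feature spaces; expands usable feature sets by
    per-marker regression reconstruction of missing values; trains age
    regressors and smoking-status classifiers (small multilayer networks with a
    bagged-tree fallback); and quantifies smoking-associated age acceleration
    via the per-sample log2 aging ratio with stratified Mann-Whitney tests,
    cholesterol/glucose risk stratification, permutation feature importance,
    partial dependence, and biweight midcorrelation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
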