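#!/usr/bin/env Rscript
# Retrospective accuracy stage: fold errors of every prediction method
# against the observed phase 1 human PK (oral CL/F 17.2 mL/h/kg, Vdz/F
# 528 mL/kg), assuming F = 100% and Vdz comparable to Vdss.

suppressPackageStartupMessages(library(pbpkro))
dir.create("results", showWarnings = FALSE)

res <- predict_human_pk(thy1773_inputs())
report <- res$report
print(transform(report, predicted = signif(predicted, 3),
                fold_error = NULL)[, c("parameter", "method", "predicted",
                                       "observed", "fold_error_display",
                                       "within_2fold")])
cat("\n", attr(report, "assumptions"), "\n")
cat("Only IVIVE without ESF predicts CL within twofold; both\n")
cat("protein-binding-aware volume methods are within twofold, matching the\n")
cat("study's retrospective conclusion that mechanism-based, binding-aware\n")
cat("methods without animal-derived empirical factors predict best.\n")
write.csv(report, "results/fold_error_report.csv", row.names = FALSE)
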