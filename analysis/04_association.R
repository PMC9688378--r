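#!/usr/bin/env Rscript

# Stage 4: the factor and association models.
#
# Fits the stage-wise MRBD linear mixed models (condition x group x
# hemisphere x region, all interactions, backward stepwise), then the
# MRBD-behavior association model (12 regional MRBD predictors + group +
# condition, MRBD x group interactions), and the per-group Spearman
# correlation between right-central planning MRBD and tracking error.

library(betatrack)

behavior <- read.csv("results/behavior.csv")
mrbd <- read.csv("results/mrbd.csv")

for (stage in c("planning", "execution")) {
  fit <- stage_model(mrbd, stage)
  cat("\n==", stage, "model ==\nretained:",
      paste(fit$spec$fixed, collapse = ", "), "\n")
  print(fit$fit$term_tests)
  write.csv(fit$fit$term_tests,
            sprintf("results/stage_model_%s.csv", stage), row.names = FALSE)
}

assoc <- association_model(mrbd, behavior, interactions = "group")
cat("\n== association model ==\nretained:",
    paste(assoc$spec$fixed, collapse = ", "), "\n")
cf <- assoc$fit$coefficients
print(cf[grep("planning_central_right", cf$term), ])
write.csv(cf, "results/association_coefficients.csv", row.names = FALSE)

correlations <- mrbd_behavior_correlation(mrbd, behavior)
cat("\nSpearman correlation, right-central planning MRBD vs tracking error:\n")
print(correlations)
write.csv(correlations, "results/correlations.csv", row.names = FALSE)
cat("wrote results/stage_model_*.csv, association_coefficients.csv, correlations.csv\n")
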