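#!/usr/bin/env Rscript
# Longitudinal stability: per-junction coefficient of variation of JRPM
# within participants sampled >= 5 times versus across the whole cohort,
# compared by a two-sided rank-sum test; plus inter-tool Pearson
# correlation of expression profiles.

source("analysis/00_common.R")

res <- get_pipeline_result()

for (fluid in c("plasma", "urine")) {
  r <- res[[fluid]]
  st <- r$stability
  cat("\n==", fluid, "==\n")
  cat("CV summary by scope (participants with >= 5 visits, then global):\n")
  print(as.data.frame(st$summary), row.names = FALSE)
  cat(sprintf(
    "pooled within-participant vs global CV: W = %g, p = %.3g (%s)\n",
    st$test$statistic, st$test$p.value, st$test$method
  ))
  cat("per-participant tests:\n")
  print(as.data.frame(st$per_participant_tests), row.names = FALSE)
  cat("inter-tool Pearson correlation of mean JRPM profiles:\n")
  print(round(r$tool_correlation, 3))
}
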