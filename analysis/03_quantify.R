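#!/usr/bin/env Rscript
# Quantify consensus circRNA expression: JRPM per junction per sample and
# the circular-to-linear ratio against the flanking linear splice sites,
# with the fraction of circles out-expressing their linear host.

source("analysis/00_common.R")

res <- get_pipeline_result()

for (fluid in c("plasma", "urine")) {
  r <- res[[fluid]]
  cat("\n==", fluid, "==\n")
  cat("expression records (count > 0):", nrow(r$expression), "\n")
  cat("JRPM quartiles:\n")
  print(stats::quantile(r$expression$jrpm))
  s <- r$clr_summary$overall
  cat(sprintf(
    "circles above their linear host (CLR > 1): %.1f%% of expressed junctions\n",
    100 * s$frac_gt1
  ))
  cat(sprintf("  1- to 5-fold: %.1f%%   > 5-fold: %.1f%%\n",
              100 * s$frac_1_to_5, 100 * s$frac_gt5))
  if (!is.null(r$prefilter)) {
    cat("expression pre-filters (>=150 junctions/sample, >=50% prevalence):",
        length(r$prefilter$kept_samples), "samples,",
        length(r$prefilter$kept_junctions), "junctions kept\n")
  }
}
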