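# Shared paths and lazy loaders for the analysis drivers. Each numbered
# script can be run on its own; anything missing is built on demand.

library(circbiofluid)

SEED <- 1
DATA_DIR <- "scratch/synthetic_data"
CACHE <- "scratch/pipeline_result.rds"
RESULTS <- "results/analysis"

dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

get_manifest <- function() {
  simulate_truth(generator_config(), seed = SEED)
}

get_input_tree <- function() {
  if (!file.exists(file.path(DATA_DIR, "samples.tsv"))) {
    message("emitting synthetic study to ", DATA_DIR)
    emit_files(get_manifest(), DATA_DIR)
  }
  DATA_DIR
}

get_pipeline_result <- function() {
  if (file.exists(CACHE)) return(readRDS(CACHE))
  res <- run_pipeline(get_input_tree(), qc_min_circ = 150)
  saveRDS(res, CACHE)
  res
}
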