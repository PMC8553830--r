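# Shared fixtures: simulated studies (memoized across test files) and
# small hand-built objects.

.fixture_cache <- new.env(parent = emptyenv())

noiseless_config <- function() {
  generator_config(
    dropout = stats::setNames(rep(0, 6), supported_tools()),
    fp_rate = stats::setNames(rep(0, 6), supported_tools())
  )
}

# manifest under noise-free observation (dropout 0, FP 0), seed 101
noiseless_manifest <- function() {
  if (is.null(.fixture_cache$noiseless)) {
    .fixture_cache$noiseless <- simulate_truth(noiseless_config(), seed = 101)
  }
  .fixture_cache$noiseless
}

# manifest under the default noise model, seed 202
default_manifest <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- simulate_truth(generator_config(), seed = 202)
  }
  .fixture_cache$default
}

# emitted file tree + full pipeline result for the noiseless manifest
noiseless_run <- function() {
  if (is.null(.fixture_cache$run)) {
    dir <- file.path(tempdir(), "circbiofluid-noiseless")
    emit_files(noiseless_manifest(), dir)
    .fixture_cache$run_dir <- dir
    .fixture_cache$run <- run_pipeline(dir)
  }
  .fixture_cache$run
}

noiseless_run_dir <- function() {
  noiseless_run()
  .fixture_cache$run_dir
}

# consensus catalog computed in memory from a manifest's observed calls
manifest_consensus <- function(manifest, fluid,
                               config = filter_config()) {
  samples <- manifest$samples[manifest$samples$biofluid == fluid, ]
  dms <- lapply(supported_tools(), function(tool) {
    detect(manifest$observed[[fluid]][[tool]], samples, config,
           tool = tool, biofluid = fluid)
  })
  names(dms) <- supported_tools()
  sets <- lapply(dms, function(d) retain_tool_junctions(d)$retained)
  list(dms = dms, sets = sets, intersection = intersect_tools(sets))
}

# two adjacent single-isoform transcript models on one chromosome:
#   GENEA chr1:+  exons [1000,1200) [1700,1900) [2400,2600) [3100,3300)
#         CDS [1700, 2600)
#   GENEB chr1:-  exons [5000,5200) [5700,5900), CDS [5700,5900) so the
#         whole first exon (genomic left) is 3' UTR on the minus strand
tiny_transcripts <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1"),
    tx_start0 = c(1000, 5000),
    tx_end0 = c(3300, 5900),
    name = c("GENEA", "GENEB"),
    strand = c("+", "-"),
    cds_start0 = c(1700, 5700),
    cds_end0 = c(2600, 5900),
    exon_start0 = list(c(1000, 1700, 2400, 3100), c(5000, 5700)),
    exon_end0 = list(c(1200, 1900, 2600, 3300), c(5200, 5900))
  )
}
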