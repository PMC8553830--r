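# Cross-platform validation inputs: the published qRT-PCR vs RNA-Seq
# expression table for the most highly expressed circRNA per biofluid
# (shipped as a plain-text fixture), and helpers for checking a run
# against an externally deposited consensus catalog.

#' Published qRT-PCR / RNA-Seq expression table
#'
#' The 15 most highly expressed circRNA per biofluid with their mean
#' qRT-PCR Ct, mean sequencing JRPM, and the published ranks on each
#' platform (Ct ascending; JRPM descending; missing Ct ranked last).
#' Used as the worked example for [rank_concordance()].
#'
#' @param biofluid Optional filter, `"plasma"` or `"urine"`.
#' @return Tibble `biofluid`, `circrna`, `mean_ct`, `qpcr_rank`,
#'   `mean_jrpm`, `rnaseq_rank`.
#' @export
qpcr_rank_table <- function(biofluid = NULL) {
  path <- system.file("extdata", "qpcr_rnaseq_ranks.tsv",
                      package = "circbiofluid", mustWork = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(biofluid)) tab <- tab[tab$biofluid == biofluid, ]
  tab
}

#' Summarize an externally deposited consensus catalog
#'
#' Given locally available copies of a deposited plasma catalog, urine
#' catalog, and (optionally) an expression matrix, reports the catalog
#' sizes and cross-biofluid overlap in the same form the pipeline
#' computes them, so a run can be compared against the deposit. Catalog
#' files are expected to carry one junction per row with coordinates in
#' the first columns (`chrom`, `start`, `end`) or a single key column.
#'
#' @param plasma_path,urine_path Paths to the deposited per-biofluid
#'   junction lists (TSV/BED-like text).
#' @return List with `n_plasma`, `n_urine`, `n_shared`, `frac_of_urine`.
#' @export
deposited_catalog_counts <- function(plasma_path, urine_path) {
  read_keys <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) >= 3 &&
        is.numeric(tab[[2]]) && is.numeric(tab[[3]])) {
      junction_key(normalize_chrom(tab[[1]]), tab[[2]], tab[[3]])
    } else {
      as.character(tab[[1]])
    }
  }
  plasma <- unique(read_keys(plasma_path))
  urine <- unique(read_keys(urine_path))
  ov <- biofluid_overlap(plasma, urine)
  list(
    n_plasma = length(plasma), n_urine = length(urine),
    n_shared = ov$n_shared, frac_of_urine = ov$frac_of_urine
  )
}
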