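# Gene assignment and genomic-feature classification of back-splice
# junctions against BED12 transcript models.
#
# Feature taxonomy (one primary class per junction, plus optional UTR
# flags):
#   multi_exon_spanning_intron  both boundaries in exons, >= 2 exons hit
#   single_exon                 both boundaries inside one exon
#   intronic                    contained in one intron (no exon touched)
#   boundary_outside_exon       a gene overlaps but a boundary lies in no
#                               exon (or the junction spills over the
#                               transcript ends)
#   intergenic                  no overlapping gene

#' Genes overlapping a set of junctions
#'
#' A gene is assigned when its transcript interval overlaps the junction
#' interval (both 0-based half-open) by at least 1 bp — the default
#' behaviour of standard interval intersection.
#'
#' @param junctions Data frame with `key`, `chrom`, `start0`, `end0`.
#' @param transcripts Tibble from [read_bed12()].
#' @return Tibble `key`, `genes` (comma-joined sorted names; `""` when
#'   intergenic), `n_genes`.
#' @export
assign_genes <- function(junctions, transcripts) {
  hits <- .junction_tx_overlaps(junctions, transcripts)
  genes <- vapply(seq_len(nrow(junctions)), function(i) {
    g <- sort(unique(transcripts$name[hits[[i]]]))
    paste(g, collapse = ",")
  }, "")
  tibble::tibble(
    key = junctions$key,
    genes = genes,
    n_genes = vapply(strsplit(genes, ",", fixed = TRUE), function(x) {
      sum(nzchar(x))
    }, 1L)
  )
}

# list (per junction) of transcript row indices overlapping it
.junction_tx_overlaps <- function(junctions, transcripts) {
  jr <- GenomicRanges::GRanges(
    junctions$chrom,
    IRanges::IRanges(start = junctions$start0 + 1, end = junctions$end0)
  )
  tr <- GenomicRanges::GRanges(
    transcripts$chrom,
    IRanges::IRanges(start = transcripts$tx_start0 + 1,
                     end = transcripts$tx_end0)
  )
  ov <- GenomicRanges::findOverlaps(jr, tr, ignore.strand = TRUE)
  split(
    S4Vectors::subjectHits(ov),
    factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(junctions)))
  )
}

#' Classify junctions into genomic-feature categories
#'
#' For each junction the overlapping transcript is chosen by preferring
#' (1) transcripts holding both junction boundaries inside exons, then
#' (2) the most exons intersected, then (3) the lexicographically smallest
#' name. The chosen transcript determines the exon span and the primary
#' class; UTR flags are set when the junction intersects the transcript
#' region outside the CDS (5'/3' oriented by transcript strand).
#'
#' @inheritParams assign_genes
#' @return Tibble `key`, `genes`, `chosen_transcript`, `n_exons_spanned`,
#'   `class` (primary), `utr5`, `utr3`, `classes` (semicolon-joined
#'   primary class plus UTR flags).
#' @export
classify_junctions <- function(junctions, transcripts) {
  hits <- .junction_tx_overlaps(junctions, transcripts)
  gene_tab <- assign_genes(junctions, transcripts)
  n <- nrow(junctions)
  chosen <- character(n)
  n_exons <- integer(n)
  class <- character(n)
  utr5 <- logical(n)
  utr3 <- logical(n)

  for (i in seq_len(n)) {
    idx <- hits[[i]]
    if (length(idx) == 0) {
      chosen[i] <- NA_character_
      class[i] <- "intergenic"
      next
    }
    s0 <- junctions$start0[i]
    e0 <- junctions$end0[i]
    cand <- lapply(idx, function(t) .tx_features(transcripts[t, ], s0, e0))
    both_in_exon <- vapply(cand, `[[`, logical(1), "both_in_exon")
    n_hit <- vapply(cand, `[[`, integer(1), "n_exons_hit")
    nm <- transcripts$name[idx]
    ord <- order(-both_in_exon, -n_hit, nm)
    best <- cand[[ord[1]]]
    chosen[i] <- nm[ord[1]]
    n_exons[i] <- best$n_exons_hit
    class[i] <- best$class
    utr5[i] <- best$utr5
    utr3[i] <- best$utr3
  }

  classes <- vapply(seq_len(n), function(i) {
    cl <- class[i]
    if (utr5[i]) cl <- c(cl, "five_prime_utr")
    if (utr3[i]) cl <- c(cl, "three_prime_utr")
    paste(cl, collapse = ";")
  }, "")

  tibble::tibble(
    key = junctions$key,
    genes = gene_tab$genes,
    chosen_transcript = chosen,
    n_exons_spanned = n_exons,
    class = class,
    utr5 = utr5,
    utr3 = utr3,
    classes = classes
  )
}

# features of one junction relative to one transcript (all 0-based
# half-open); boundaries are the first base (start0) and last base
# (end0 - 1) of the circRNA
.tx_features <- function(tx, s0, e0) {
  es <- tx$exon_start0[[1]]
  ee <- tx$exon_end0[[1]]
  exon_hit <- which(es < e0 & ee > s0)
  b1_exon <- which(es <= s0 & ee > s0)
  b2_exon <- which(es <= (e0 - 1) & ee > (e0 - 1))
  both_in_exon <- length(b1_exon) > 0 && length(b2_exon) > 0
  n_exons_hit <- length(exon_hit)

  cls <- if (both_in_exon && n_exons_hit == 1 &&
             b1_exon[1] == b2_exon[1]) {
    "single_exon"
  } else if (both_in_exon && n_exons_hit >= 2) {
    "multi_exon_spanning_intron"
  } else if (n_exons_hit == 0 && s0 >= tx$tx_start0 && e0 <= tx$tx_end0) {
    "intronic"
  } else {
    "boundary_outside_exon"
  }

  # UTR flags: intersection with the exonic region outside the CDS
  utr_left <- FALSE
  utr_right <- FALSE
  if (tx$cds_end0 > tx$cds_start0) {
    utr_left <- any(pmin(ee, tx$cds_start0, e0) > pmax(es, s0))
    utr_right <- any(pmin(ee, e0) > pmax(es, tx$cds_end0, s0))
  }
  if (tx$strand == "-") {
    tmp <- utr_left
    utr_left <- utr_right
    utr_right <- tmp
  }
  list(
    both_in_exon = both_in_exon,
    n_exons_hit = n_exons_hit,
    class = cls,
    utr5 = utr_left,
    utr3 = utr_right
  )
}

#' Tabulate primary feature classes
#'
#' @param annotation Tibble from [classify_junctions()].
#' @return Tibble `class`, `n_junctions`, sorted by count.
#' @export
feature_class_counts <- function(annotation) {
  tab <- table(annotation$class)
  out <- tibble::tibble(
    class = names(tab),
    n_junctions = as.integer(tab)
  )
  out[order(-out$n_junctions), ]
}
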