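# circRNA expression: junction reads per million (JRPM), flanking linear
# splice support, and the circular-to-linear ratio (CLR).

#' Junction reads per million
#'
#' `JRPM = count / total_junction_reads * 1e6`, where the denominator is
#' the sample's total junction reads (canonical linear plus chimeric, as
#' counted by the aligner).
#'
#' @param count Back-spliced read count(s).
#' @param total_junction_reads Sample total junction reads (> 0).
#' @return Numeric JRPM value(s).
#' @export
#' @examples
#' jrpm(5, 1e6)      # 5
#' jrpm(7, 350000)   # 20
jrpm <- function(count, total_junction_reads) {
  if (any(total_junction_reads <= 0)) {
    stop("total_junction_reads must be positive")
  }
  count / total_junction_reads * 1e6
}

#' Circular-to-linear ratio
#'
#' The back-spliced read count divided by the larger of the two flanking
#' linear splice-read counts. When neither flank has linear reads, a
#' pseudocount of 1 is used as the denominator, so `clr(count, 0, 0)`
#' equals `count`.
#'
#' @param count Back-spliced read count(s).
#' @param linear5,linear3 Linear unique-read counts at the 5' and 3'
#'   flanking splice sites.
#' @return Numeric CLR value(s).
#' @export
#' @examples
#' clr(10, 5, 2)  # 2
#' clr(3, 0, 0)   # 3 (pseudocount)
clr <- function(count, linear5, linear3) {
  if (any(count < 0 | linear5 < 0 | linear3 < 0)) {
    stop("counts must be non-negative")
  }
  denom <- pmax(linear5, linear3)
  denom[denom == 0] <- 1
  count / denom
}

#' Linear splice support at a circRNA's flanking splice sites
#'
#' Sums unique linear spliced reads over all linear junctions sharing the
#' circRNA's acceptor splice site (5' flank) and, separately, its donor
#' site (3' flank). Multiple linear junctions at one splice site
#' (alternative partners) are summed, since reads — not junctions — are
#' being counted.
#'
#' @param junctions Data frame with `key`, `chrom`, `start0`, `end0`.
#' @param linear Tibble from [read_star_sj()] for one sample.
#' @return Tibble `key`, `linear5`, `linear3` (zero where nothing
#'   matches).
#' @export
linear_flank_counts <- function(junctions, linear) {
  if (is.null(linear) || nrow(linear) == 0) {
    return(tibble::tibble(
      key = junctions$key,
      linear5 = rep(0, nrow(junctions)),
      linear3 = rep(0, nrow(junctions))
    ))
  }
  l5 <- stats::aggregate(
    linear$unique_reads,
    by = list(chrom = linear$chrom, pos = linear$intron_end1), FUN = sum
  )
  l3 <- stats::aggregate(
    linear$unique_reads,
    by = list(chrom = linear$chrom, pos = linear$intron_start1 - 1), FUN = sum
  )
  k5 <- paste(l5$chrom, l5$pos)
  k3 <- paste(l3$chrom, l3$pos)
  m5 <- l5$x[match(paste(junctions$chrom, junctions$start0), k5)]
  m3 <- l3$x[match(paste(junctions$chrom, junctions$end0), k3)]
  tibble::tibble(
    key = junctions$key,
    linear5 = ifelse(is.na(m5), 0, m5),
    linear3 = ifelse(is.na(m3), 0, m3)
  )
}

#' Per-junction per-sample expression records
#'
#' Computes JRPM and CLR for every (junction, sample) pair of a count
#' matrix, pulling each sample's flanking linear support from its linear
#' splice-junction table.
#'
#' @param counts Junction-by-sample count matrix (rownames = junction
#'   keys).
#' @param junctions Data frame mapping `key` to `chrom`, `start0`, `end0`
#'   (e.g. from [parse_junction_key()]).
#' @param sample_meta Tibble from [read_sample_table()] covering the
#'   matrix's samples.
#' @param sj_by_sample Named list of linear-junction tibbles (one per
#'   sample id).
#' @param keep_zero Keep records with zero back-spliced count?
#'   (default FALSE).
#' @return Tibble `junction_key`, `sample_id`, `count`, `jrpm`, `linear5`,
#'   `linear3`, `clr`.
#' @export
expression_records <- function(counts, junctions, sample_meta, sj_by_sample,
                               keep_zero = FALSE) {
  stopifnot(all(colnames(counts) %in% sample_meta$sample_id))
  junctions <- junctions[match(rownames(counts), junctions$key), ]
  totals <- sample_meta$total_junction_reads[
    match(colnames(counts), sample_meta$sample_id)
  ]
  res <- vector("list", ncol(counts))
  for (j in seq_len(ncol(counts))) {
    sid <- colnames(counts)[j]
    sj <- sj_by_sample[[sid]]
    if (is.null(sj)) {
      stop("no linear splice-junction table for sample ", sid)
    }
    fl <- linear_flank_counts(junctions, sj)
    cnt <- unname(counts[, j])
    rec <- tibble::tibble(
      junction_key = rownames(counts),
      sample_id = sid,
      count = cnt,
      jrpm = jrpm(cnt, totals[j]),
      linear5 = fl$linear5,
      linear3 = fl$linear3
    )
    rec$clr <- clr(rec$count, rec$linear5, rec$linear3)
    if (!keep_zero) rec <- rec[rec$count > 0, ]
    res[[j]] <- rec
  }
  dplyr::bind_rows(res)
}

#' Summary of circular-to-linear dominance
#'
#' Per sample, the fraction of expressed junctions (back-spliced count
#' > 0) whose CLR exceeds 1 — i.e. circles more abundant than their linear
#' host — split into the 1-to-5-fold and above-5-fold bands; fractions are
#' then averaged across samples.
#'
#' @param records Expression records from [expression_records()].
#' @return List with `per_sample` (tibble: `sample_id`, `n_expressed`,
#'   `frac_gt1`, `frac_1_to_5`, `frac_gt5`) and `overall` (one-row tibble
#'   of the across-sample means).
#' @export
clr_summary <- function(records) {
  records <- records[records$count > 0, ]
  per_sample <- dplyr::summarise(
    dplyr::group_by(records, .data$sample_id),
    n_expressed = dplyr::n(),
    frac_gt1 = mean(.data$clr > 1),
    frac_1_to_5 = mean(.data$clr > 1 & .data$clr <= 5),
    frac_gt5 = mean(.data$clr > 5),
    .groups = "drop"
  )
  overall <- tibble::tibble(
    frac_gt1 = mean(per_sample$frac_gt1),
    frac_1_to_5 = mean(per_sample$frac_1_to_5),
    frac_gt5 = mean(per_sample$frac_gt5)
  )
  list(per_sample = per_sample, overall = overall)
}

#' JRPM matrix from a count matrix
#'
#' @param counts Junction-by-sample count matrix.
#' @param sample_meta Sample table with `total_junction_reads`.
#' @return Matrix of the same shape with JRPM values.
#' @export
jrpm_matrix <- function(counts, sample_meta) {
  totals <- sample_meta$total_junction_reads[
    match(colnames(counts), sample_meta$sample_id)
  ]
  if (anyNA(totals)) stop("sample missing from sample table")
  sweep(counts, 2, totals, "/") * 1e6
}
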