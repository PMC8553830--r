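# Readers for the native output dialects of the six circRNA callers, for
# STAR SJ.out.tab, the per-sample junction-totals table and BED12 models,
# plus the fixed-schema writers used by the analysis drivers.
#
# Dialect contracts (columns the analysis needs; extra columns pass through
# opaquely in `extras`):
#   circexplorer: no header, 0-based; cols 1-3 chrom/start/end, col 6 strand,
#                 col 13 readNumber
#   ciri2:        headered, 1-based; col 2 chr, 3 circRNA_start,
#                 4 circRNA_end, 5 junction_reads, 11 strand
#   dcc:          headered CircRNACount, 1-based; Chr/Start/End/Strand then
#                 one count column per sample (or a single count column)
#   find_circ:    BED-like, no header, 0-based; cols 1-4 chrom/start/end/name,
#                 col 5 n_reads, col 6 strand
#   knife:        headered, 0-based; col 1 junction string
#                 "chrom|gene:pos|gene:pos|type|strand", col 2 read count
#   mapsplice:    no header, 1-based; col 1 "chrom~chrom", cols 2-3
#                 coordinates (donor-first order allowed), col 5 coverage,
#                 col 6 two-character strand

# vectorized basis conversion with per-row validity instead of a hard stop
.normalize_rows <- function(chrom, start_in, end_in, strand, basis) {
  chrom <- normalize_chrom(chrom)
  s <- suppressWarnings(as.numeric(start_in))
  e <- suppressWarnings(as.numeric(end_in))
  lo <- pmin(s, e)
  hi <- pmax(s, e)
  valid <- !is.na(lo) & !is.na(hi)
  if (basis == "one_based") {
    valid <- valid & lo > 0
    start0 <- lo - 1
    end0 <- hi
  } else {
    valid <- valid & lo >= 0
    start0 <- lo
    end0 <- hi
  }
  valid <- valid & !is.na(start0) & !is.na(end0) & (end0 - start0) >= 2
  strand <- as.character(strand)
  strand[!strand %in% c("+", "-", ".")] <- "."
  start0[!valid] <- NA_real_
  end0[!valid] <- NA_real_
  tibble::tibble(
    chrom = chrom, start0 = start0, end0 = end0, strand = strand,
    valid = valid
  )
}

.split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

.field <- function(rows, i) {
  vapply(rows, function(r) if (length(r) >= i) r[[i]] else NA_character_, "")
}

# Heuristic header detection: the coordinate field of a header line is
# non-numeric.
.has_header <- function(rows, coord_col) {
  if (length(rows) == 0) return(FALSE)
  is.na(suppressWarnings(as.numeric(rows[[1]][coord_col])))
}

#' Read one caller's native output into harmonized tool calls
#'
#' Parses a single per-sample output file of one of the six supported
#' circRNA callers, converts its coordinates to the canonical 0-based
#' half-open convention, and returns one row per well-formed back-splice
#' junction call. Malformed rows (wrong field count, non-numeric
#' coordinates or counts, degenerate junctions, trans-chromosomal records)
#' are skipped with a warning; if more than half the data rows are
#' malformed the file is assumed to be in the wrong dialect and reading
#' aborts.
#'
#' @param path Path to the tool output file (tab-delimited text).
#' @param dialect One of `"circexplorer"`, `"ciri2"`, `"dcc"`,
#'   `"find_circ"`, `"knife"`, `"mapsplice"`.
#' @param sample_id Sample identifier recorded on every call; for the DCC
#'   multi-sample `CircRNACount` layout it also selects the count column.
#' @return Tibble with columns `tool`, `sample_id`, `chrom`, `start0`,
#'   `end0`, `strand`, `key`, `count`, `extras`. Attribute `n_skipped`
#'   carries the malformed-row count. An empty file yields zero rows.
#' @export
read_tool_output <- function(path, dialect, sample_id) {
  dialect <- match.arg(dialect, supported_tools())
  basis <- tool_coordinate_basis()[[dialect]]
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  empty <- tibble::tibble(
    tool = character(), sample_id = character(), chrom = character(),
    start0 = double(), end0 = double(), strand = character(),
    key = character(), count = double(), extras = character()
  )
  if (length(lines) == 0) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  rows <- .split_fields(lines)

  parsed <- switch(dialect,
    circexplorer = {
      ok_len <- lengths(rows) >= 13
      list(
        chrom = .field(rows, 1), s = .field(rows, 2), e = .field(rows, 3),
        strand = .field(rows, 6), count = .field(rows, 13),
        ok = ok_len, header = FALSE
      )
    },
    ciri2 = {
      header <- .has_header(rows, 3)
      ok_len <- lengths(rows) >= 11
      list(
        chrom = .field(rows, 2), s = .field(rows, 3), e = .field(rows, 4),
        strand = .field(rows, 11), count = .field(rows, 5),
        ok = ok_len, header = header
      )
    },
    dcc = {
      header <- .has_header(rows, 2)
      count_col <- 5L
      if (header) {
        hdr <- rows[[1]]
        hit <- which(hdr == sample_id)
        if (length(hit) == 1) {
          count_col <- hit
        } else if (length(hdr) != 5) {
          stop(sprintf(
            "dcc file %s has %d count columns and none named '%s'",
            path, length(hdr) - 4L, sample_id
          ))
        }
      }
      ok_len <- lengths(rows) >= count_col
      list(
        chrom = .field(rows, 1), s = .field(rows, 2), e = .field(rows, 3),
        strand = .field(rows, 4), count = .field(rows, count_col),
        ok = ok_len, header = header
      )
    },
    find_circ = {
      ok_len <- lengths(rows) >= 6
      list(
        chrom = .field(rows, 1), s = .field(rows, 2), e = .field(rows, 3),
        strand = .field(rows, 6), count = .field(rows, 5),
        ok = ok_len, header = FALSE
      )
    },
    knife = {
      header <- is.na(suppressWarnings(as.numeric(.field(rows, 2)[1])))
      jstr <- .field(rows, 1)
      pieces <- strsplit(jstr, "|", fixed = TRUE)
      ok_len <- lengths(rows) >= 2 & lengths(pieces) >= 5
      pos_of <- function(p, i) {
        if (length(p) < i) return(NA_character_)
        seg <- strsplit(p[[i]], ":", fixed = TRUE)[[1]]
        seg[length(seg)]
      }
      list(
        chrom = vapply(pieces, function(p) if (length(p) >= 1) p[[1]] else NA_character_, ""),
        s = vapply(pieces, pos_of, "", i = 2L),
        e = vapply(pieces, pos_of, "", i = 3L),
        strand = vapply(pieces, function(p) if (length(p) >= 5) p[[5]] else ".", ""),
        count = .field(rows, 2),
        ok = ok_len, header = header
      )
    },
    mapsplice = {
      chrom2 <- strsplit(.field(rows, 1), "~", fixed = TRUE)
      same_chrom <- vapply(chrom2, function(p) {
        length(p) == 2 && p[[1]] == p[[2]]
      }, logical(1))
      ok_len <- lengths(rows) >= 6 & same_chrom
      list(
        chrom = vapply(chrom2, function(p) if (length(p) >= 1) p[[1]] else NA_character_, ""),
        s = .field(rows, 2), e = .field(rows, 3),
        strand = substr(.field(rows, 6), 1, 1),
        count = .field(rows, 5),
        ok = ok_len, header = FALSE
      )
    }
  )

  keep <- rep(TRUE, length(rows))
  if (isTRUE(parsed$header)) keep[1] <- FALSE
  n_data <- sum(keep)
  if (n_data == 0) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }

  norm <- .normalize_rows(
    parsed$chrom[keep], parsed$s[keep], parsed$e[keep], parsed$strand[keep],
    basis
  )
  count <- suppressWarnings(as.numeric(parsed$count[keep]))
  good <- parsed$ok[keep] & norm$valid & !is.na(count) & count >= 0
  n_skipped <- sum(!good)
  if (n_skipped > 0) {
    warning(sprintf(
      "%s (%s): skipped %d malformed row(s) of %d", path, dialect,
      n_skipped, n_data
    ))
    if (n_skipped > n_data / 2) {
      stop(sprintf(
        "%s: more than half the rows are malformed for dialect '%s'; wrong dialect?",
        path, dialect
      ))
    }
  }

  extras <- vapply(
    rows[keep], function(r) paste(r, collapse = "\t"), ""
  )
  out <- tibble::tibble(
    tool = dialect,
    sample_id = sample_id,
    chrom = norm$chrom,
    start0 = norm$start0,
    end0 = norm$end0,
    strand = norm$strand,
    count = count,
    extras = extras
  )[good, , drop = FALSE]
  out$key <- junction_key(out$chrom, out$start0, out$end0, out$strand)
  out <- out[, c(
    "tool", "sample_id", "chrom", "start0", "end0", "strand", "key",
    "count", "extras"
  )]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a STAR SJ.out.tab linear splice-junction file
#'
#' STAR reports one linear splice junction per row with 1-based inclusive
#' intron coordinates; column 7 is the uniquely-mapping read count, the
#' only count used for quantification.
#'
#' @param path Path to an `SJ.out.tab` file (9 tab-separated columns).
#' @return Tibble with `chrom`, `intron_start1`, `intron_end1`,
#'   `unique_reads`.
#' @export
read_star_sj <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      chrom = character(), intron_start1 = double(),
      intron_end1 = double(), unique_reads = double()
    ))
  }
  rows <- .split_fields(lines)
  if (any(lengths(rows) != 9)) {
    stop(sprintf("%s: expected 9 columns in SJ.out.tab layout", path))
  }
  tibble::tibble(
    chrom = normalize_chrom(.field(rows, 1)),
    intron_start1 = as.numeric(.field(rows, 2)),
    intron_end1 = as.numeric(.field(rows, 3)),
    unique_reads = as.numeric(.field(rows, 7))
  )
}

#' Read the sample metadata / junction-totals table
#'
#' @param path TSV with header columns `sample_id`, `participant_id`,
#'   `biofluid`, `visit`, `canonical_junction_reads`,
#'   `chimeric_junction_reads`.
#' @return Tibble with those columns plus `total_junction_reads`
#'   (canonical + chimeric), the JRPM denominator.
#' @export
read_sample_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c(
    "sample_id", "participant_id", "biofluid", "visit",
    "canonical_junction_reads", "chimeric_junction_reads"
  )
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("sample table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id in sample table: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  }
  tab$total_junction_reads <-
    tab$canonical_junction_reads + tab$chimeric_junction_reads
  if (any(tab$total_junction_reads <= 0)) {
    stop("sample with non-positive total junction reads")
  }
  tab
}

#' Read BED12 transcript models
#'
#' Uses `rtracklayer` for the BED parsing and flattens each transcript to
#' the fields the annotation step needs: 0-based half-open transcript and
#' CDS (thick) extents plus per-exon genomic intervals.
#'
#' @param path Path to a BED12 file.
#' @return Tibble with `chrom`, `tx_start0`, `tx_end0`, `name`, `strand`,
#'   `cds_start0`, `cds_end0`, and list-columns `exon_start0`, `exon_end0`
#'   (sorted, 0-based half-open).
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- S4Vectors::mcols(gr)$blocks
  thick <- S4Vectors::mcols(gr)$thick
  n <- length(gr)
  exon_start0 <- vector("list", n)
  exon_end0 <- vector("list", n)
  tx_start0 <- GenomicRanges::start(gr) - 1
  for (i in seq_len(n)) {
    if (!is.null(blocks)) {
      b <- blocks[[i]]
      # blocks are transcript-relative 1-based ranges
      es <- tx_start0[i] + IRanges::start(b) - 1
      ee <- tx_start0[i] + IRanges::end(b)
    } else {
      es <- tx_start0[i]
      ee <- GenomicRanges::end(gr)[i]
    }
    ord <- order(es)
    exon_start0[[i]] <- es[ord]
    exon_end0[[i]] <- ee[ord]
  }
  cds_start0 <- tx_start0
  cds_end0 <- tx_start0
  if (!is.null(thick)) {
    w <- IRanges::width(thick)
    cds_start0 <- ifelse(w > 0, IRanges::start(thick) - 1, tx_start0)
    cds_end0 <- ifelse(w > 0, IRanges::end(thick), tx_start0)
  }
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tx_start0 = tx_start0,
    tx_end0 = GenomicRanges::end(gr),
    name = if (!is.null(S4Vectors::mcols(gr)$name)) {
      S4Vectors::mcols(gr)$name
    } else {
      sprintf("tx%04d", seq_len(n))
    },
    strand = as.character(GenomicRanges::strand(gr)),
    cds_start0 = as.numeric(cds_start0),
    cds_end0 = as.numeric(cds_end0),
    exon_start0 = exon_start0,
    exon_end0 = exon_end0
  )
}

#' Write junctions as BED6
#'
#' @param records Data frame with `chrom`, `start0`, `end0`, `key`,
#'   `strand`, and optionally `count` (written to the score column).
#' @param path Output path.
#' @export
write_junction_bed <- function(records, path) {
  score <- if ("count" %in% names(records)) records$count else 0
  out <- data.frame(
    chrom = records$chrom,
    start0 = as.integer(records$start0),
    end0 = as.integer(records$end0),
    name = records$key,
    score = score,
    strand = records$strand,
    stringsAsFactors = FALSE
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED6 junction file written by [write_junction_bed()]
#' @param path Path to the BED6 file.
#' @return Tibble with `chrom`, `start0`, `end0`, `key`, `count`, `strand`.
#' @export
read_junction_bed <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_names = c("chrom", "start0", "end0", "key", "count", "strand"),
    show_col_types = FALSE, progress = FALSE
  )
  tibble::as_tibble(tab)
}

#' Write / read a junction-by-sample matrix as TSV
#'
#' The first column `junction_key` holds row names; remaining columns are
#' samples.
#'
#' @param mat Numeric matrix with junction keys as rownames and sample ids
#'   as colnames.
#' @param path Output path.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(
    junction_key = rownames(mat), mat,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @return `read_matrix()`: the matrix.
#' @export
read_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$junction_key
  mat
}
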