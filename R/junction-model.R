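#' @importFrom rlang .data
NULL

#' Coordinate basis of each supported circRNA caller
#'
#' The six supported callers report back-splice junction coordinates in two
#' conventions: CIRCexplorer, KNIFE and find_circ emit 0-based (BED-style)
#' coordinates, while CIRI2, MapSplice and DCC emit 1-based inclusive
#' coordinates. All downstream analysis uses the 0-based half-open
#' convention, so 1-based callers are shifted on read-in.
#'
#' @return Named character vector mapping tool identifier to
#'   `"zero_based"` or `"one_based"`.
#' @export
#' @examples
#' tool_coordinate_basis()[["ciri2"]]
tool_coordinate_basis <- function() {
  c(
    circexplorer = "zero_based",
    knife        = "zero_based",
    find_circ    = "zero_based",
    ciri2        = "one_based",
    mapsplice    = "one_based",
    dcc          = "one_based"
  )
}

#' Supported tool identifiers
#' @return Character vector of the six caller identifiers.
#' @export
supported_tools <- function() names(tool_coordinate_basis())

#' Normalize chromosome names to the chr-prefixed dialect
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector with a `"chr"` prefix guaranteed.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(startsWith(chrom, "chr"), chrom, paste0("chr", chrom))
}

#' Convert caller coordinates to the canonical 0-based half-open convention
#'
#' The canonical representation of a back-splice junction is 0-based
#' half-open: `start0` is the 0-based index of the back-splice acceptor base
#' (the first base of the circRNA) and `end0` is the 0-based half-open end,
#' i.e. the 1-based index of the back-splice donor base (the last base).
#' A 1-based inclusive pair `[s, e]` maps to `(s - 1, e)`; 0-based input is
#' returned unchanged. Coordinates arriving donor-first are reordered
#' numerically before conversion.
#'
#' @param chrom Chromosome name(s); a `"chr"` prefix is added if missing.
#' @param start_in,end_in Input coordinates in the tool's own basis
#'   (vectorized).
#' @param strand Strand, one of `"+"`, `"-"`, `"."`.
#' @param basis `"zero_based"` or `"one_based"`.
#' @return A tibble with columns `chrom`, `start0`, `end0`, `strand`, `key`.
#' @export
#' @examples
#' normalize_coordinates("chr1", 101, 200, "+", "one_based")  # -> 100, 200
#' normalize_coordinates("chr1", 100, 200, "+", "zero_based") # unchanged
normalize_coordinates <- function(chrom, start_in, end_in, strand = ".",
                                  basis = c("zero_based", "one_based")) {
  basis <- match.arg(basis)
  chrom <- normalize_chrom(chrom)
  start_in <- as.numeric(start_in)
  end_in <- as.numeric(end_in)
  # reorder donor-first records by numeric value
  lo <- pmin(start_in, end_in)
  hi <- pmax(start_in, end_in)
  if (basis == "one_based") {
    if (any(lo <= 0 | hi <= 0)) {
      stop("non-positive coordinate under one_based basis")
    }
    start0 <- lo - 1
    end0 <- hi
  } else {
    if (any(lo < 0)) stop("negative coordinate under zero_based basis")
    start0 <- lo
    end0 <- hi
  }
  # a circle narrower than 2 bp (donor base == acceptor base) is degenerate
  bad <- end0 - start0 < 2
  if (any(bad)) {
    stop(sprintf(
      "degenerate junction after normalization (single-base circle) in %d record(s)",
      sum(bad)
    ))
  }
  strand <- rep_len(as.character(strand), length(start0))
  strand[!strand %in% c("+", "-", ".")] <- "."
  tibble::tibble(
    chrom = chrom, start0 = start0, end0 = end0, strand = strand,
    key = junction_key(chrom, start0, end0, strand)
  )
}

#' Canonical junction key string
#'
#' Keys identify a back-splice junction by position. With
#' `strand_aware = FALSE` (the default throughout the package) the key is
#' `"chrom:start0-end0"`; with `strand_aware = TRUE` the strand is appended
#' (`"chrom:start0-end0:+"`). Strand-blind matching is the default because
#' the callers disagree on strand inference (find_circ is annotation-blind).
#'
#' @param chrom,start0,end0,strand Junction fields (vectorized).
#' @param strand_aware Include strand in the key?
#' @return Character vector of keys.
#' @export
junction_key <- function(chrom, start0, end0, strand = ".",
                         strand_aware = FALSE) {
  base <- sprintf("%s:%d-%d", chrom, as.integer(start0), as.integer(end0))
  if (strand_aware) paste0(base, ":", strand) else base
}

#' Parse junction keys back to coordinate fields
#' @param key Character vector of keys from [junction_key()].
#' @return Tibble with `chrom`, `start0`, `end0`, `strand` (`"."` when the
#'   key carries no strand).
#' @export
parse_junction_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1L)
  range <- vapply(parts, `[[`, "", 2L)
  strand <- vapply(parts, function(p) if (length(p) >= 3) p[[3]] else ".", "")
  se <- strsplit(range, "-", fixed = TRUE)
  tibble::tibble(
    chrom = chrom,
    start0 = as.integer(vapply(se, `[[`, "", 1L)),
    end0 = as.integer(vapply(se, `[[`, "", 2L)),
    strand = strand
  )
}

#' Match linear splice junctions to a circRNA's flanking splice sites
#'
#' A linear (forward-spliced) junction shares the circRNA's acceptor splice
#' site — the 5' flank — when its 1-based intron end equals `start0`
#' (the intron ends immediately before the circRNA's first base). It shares
#' the donor site — the 3' flank — when its 1-based intron start minus one
#' equals `end0` (the intron begins immediately after the circRNA's last
#' base). Chromosomes must match; the two predicates are mutually exclusive
#' for any valid junction since `end0 > start0`.
#'
#' @param junction One-row data frame or list with `chrom`, `start0`, `end0`.
#' @param linear Data frame of linear junctions with `chrom`,
#'   `intron_start1`, `intron_end1` (from [read_star_sj()]).
#' @return List of two logical vectors over rows of `linear`: `flank5`,
#'   `flank3`.
#' @export
flank_site_match <- function(junction, linear) {
  same_chrom <- linear$chrom == junction$chrom
  list(
    flank5 = same_chrom & linear$intron_end1 == junction$start0,
    flank3 = same_chrom & (linear$intron_start1 - 1) == junction$end0
  )
}
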