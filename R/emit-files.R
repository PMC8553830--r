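# Serialization of a truth manifest into the on-disk file tree the
# pipeline consumes: per-sample caller outputs in each tool's native
# dialect and coordinate basis, per-sample SJ.out.tab files, the sample
# table, the BED12 annotation, and truth TSVs for inspection.

.tool_file <- function(dir, fluid, tool, sample_id) {
  ext <- c(
    circexplorer = "txt", ciri2 = "tsv", find_circ = "bed",
    knife = "txt", mapsplice = "txt"
  )
  if (tool == "dcc") {
    file.path(dir, fluid, "dcc", "CircRNACount")
  } else {
    file.path(dir, fluid, tool, paste0(sample_id, ".", ext[[tool]]))
  }
}

.write_lines <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_lines(lines, path)
}

# per-dialect serializers; `calls` holds canonical 0-based fields
.emit_circexplorer <- function(calls, path) {
  s0 <- as.integer(calls$start0)
  e0 <- as.integer(calls$end0)
  .write_lines(sprintf(
    "%s\t%d\t%d\tcircular_RNA/%d\t0\t%s\t%d\t%d\t0,0,0\t1\t%d\t0\t%d",
    calls$chrom, s0, e0, seq_len(nrow(calls)),
    calls$strand, s0, e0, e0 - s0, as.integer(calls$count)
  ), path)
}

.emit_ciri2 <- function(calls, path) {
  header <- paste(
    "circRNA_ID", "chr", "circRNA_start", "circRNA_end",
    "#junction_reads", "SM_MS_SMS", "#non_junction_reads",
    "junction_reads_ratio", "circRNA_type", "gene_id", "strand",
    "junction_reads_ID", sep = "\t"
  )
  s1 <- as.integer(calls$start0) + 1L
  e1 <- as.integer(calls$end0)
  body <- sprintf(
    "%s:%d|%d\t%s\t%d\t%d\t%d\t0_0_0\t0\t1.0\texon\tn/a\t%s\t.",
    calls$chrom, s1, e1, calls$chrom,
    s1, e1, as.integer(calls$count), calls$strand
  )
  .write_lines(c(header, body), path)
}

.emit_find_circ <- function(calls, path) {
  .write_lines(sprintf(
    "%s\t%d\t%d\tcirc_%d\t%d\t%s",
    calls$chrom, as.integer(calls$start0), as.integer(calls$end0),
    seq_len(nrow(calls)), as.integer(calls$count), calls$strand
  ), path)
}

.emit_knife <- function(calls, path) {
  header <- "junction\treads"
  body <- sprintf(
    "%s|GENEA:%d|GENEB:%d|reg|%s\t%d",
    calls$chrom, as.integer(calls$start0), as.integer(calls$end0),
    calls$strand, as.integer(calls$count)
  )
  .write_lines(c(header, body), path)
}

# MapSplice reports circular junctions donor-first: column 2 carries the
# 1-based donor-side coordinate (end0), column 3 the acceptor (start0+1)
.emit_mapsplice <- function(calls, path) {
  .write_lines(sprintf(
    "%s~%s\t%d\t%d\tFUSIONJUNC_%d\t%d\t%s%s",
    calls$chrom, calls$chrom, as.integer(calls$end0),
    as.integer(calls$start0) + 1L, seq_len(nrow(calls)),
    as.integer(calls$count), calls$strand, calls$strand
  ), path)
}

# one multi-sample CircRNACount per biofluid (1-based inclusive)
.emit_dcc <- function(obs, sample_ids, path) {
  keys <- unique(obs$key)
  info <- obs[match(keys, obs$key), c("chrom", "start0", "end0", "strand")]
  cnt <- matrix(0, length(keys), length(sample_ids),
                dimnames = list(keys, sample_ids))
  if (nrow(obs) > 0) {
    cnt[cbind(match(obs$key, keys), match(obs$sample_id, sample_ids))] <-
      obs$count
  }
  header <- paste(c("Chr", "Start", "End", "Strand", sample_ids),
                  collapse = "\t")
  body <- vapply(seq_along(keys), function(i) {
    paste(c(
      info$chrom[i], as.integer(info$start0[i]) + 1L,
      as.integer(info$end0[i]), info$strand[i],
      cnt[i, ]
    ), collapse = "\t")
  }, "")
  .write_lines(c(header, body), path)
}

.emit_bed12 <- function(transcripts, path) {
  lines <- vapply(seq_len(nrow(transcripts)), function(i) {
    t <- transcripts[i, ]
    es <- t$exon_start0[[1]]
    ee <- t$exon_end0[[1]]
    paste(
      t$chrom, as.integer(t$tx_start0), as.integer(t$tx_end0), t$name, 0,
      t$strand, as.integer(t$cds_start0), as.integer(t$cds_end0), "0",
      length(es),
      paste(as.integer(ee - es), collapse = ","),
      paste(as.integer(es - t$tx_start0), collapse = ","),
      sep = "\t"
    )
  }, "")
  .write_lines(lines, path)
}

.emit_sj <- function(manifest, fluid, sample_id, path) {
  jidx <- manifest$members[[fluid]]
  j <- manifest$junctions[jidx, ]
  l5 <- manifest$linear5[[fluid]][, sample_id]
  l3 <- manifest$linear3[[fluid]][, sample_id]
  rows5 <- tibble::tibble(
    chrom = j$chrom,
    s1 = j$start0 - j$flank5_width + 1,
    e1 = j$start0,
    reads = l5
  )
  rows3 <- tibble::tibble(
    chrom = j$chrom,
    s1 = j$end0 + 1,
    e1 = j$end0 + j$flank3_width,
    reads = l3
  )
  decoy <- tibble::tibble(
    chrom = manifest$decoy_sj$chrom,
    s1 = manifest$decoy_sj$intron_start1,
    e1 = manifest$decoy_sj$intron_end1,
    reads = manifest$decoy_sj_counts[[fluid]][, sample_id]
  )
  all_rows <- dplyr::bind_rows(rows5, rows3, decoy)
  all_rows <- all_rows[all_rows$reads > 0, ]
  all_rows <- all_rows[order(all_rows$chrom, all_rows$s1), ]
  .write_lines(sprintf(
    "%s\t%d\t%d\t1\t1\t1\t%d\t0\t40",
    all_rows$chrom, as.integer(all_rows$s1), as.integer(all_rows$e1),
    as.integer(all_rows$reads)
  ), path)
}

#' Write a truth manifest as the on-disk input tree
#'
#' Produces, under `out_dir`: `annotation.bed12`, `samples.tsv`, one
#' directory per biofluid holding per-sample outputs of each caller in its
#' native dialect (`dcc/CircRNACount` is a single multi-sample file per
#' biofluid) and per-sample `sj/<sample>.SJ.out.tab` files, plus
#' `truth/truth_junctions.tsv` for inspection.
#'
#' @param manifest From [simulate_truth()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
emit_files <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .emit_bed12(manifest$transcripts, file.path(out_dir, "annotation.bed12"))

  st <- manifest$samples[, c(
    "sample_id", "participant_id", "biofluid", "visit",
    "canonical_junction_reads", "chimeric_junction_reads"
  )]
  readr::write_tsv(st, file.path(out_dir, "samples.tsv"), progress = FALSE)

  emitters <- list(
    circexplorer = .emit_circexplorer, ciri2 = .emit_ciri2,
    find_circ = .emit_find_circ, knife = .emit_knife,
    mapsplice = .emit_mapsplice
  )
  for (fluid in names(manifest$observed)) {
    fs <- manifest$samples[manifest$samples$biofluid == fluid, ]
    for (tool in supported_tools()) {
      obs <- manifest$observed[[fluid]][[tool]]
      if (tool == "dcc") {
        .emit_dcc(obs, fs$sample_id, .tool_file(out_dir, fluid, "dcc", NULL))
        next
      }
      for (sid in fs$sample_id) {
        calls <- obs[obs$sample_id == sid, ]
        emitters[[tool]](calls, .tool_file(out_dir, fluid, tool, sid))
      }
    }
    for (sid in fs$sample_id) {
      .emit_sj(
        manifest, fluid, sid,
        file.path(out_dir, fluid, "sj", paste0(sid, ".SJ.out.tab"))
      )
    }
  }

  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  truth <- manifest$junctions[, c(
    "key", "chrom", "start0", "end0", "strand", "class", "host",
    "in_plasma", "in_urine"
  )]
  readr::write_tsv(truth, file.path(out_dir, "truth", "truth_junctions.tsv"),
                   progress = FALSE)
  invisible(out_dir)
}
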