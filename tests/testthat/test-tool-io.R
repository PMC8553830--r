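# small canonical call set used to exercise every dialect writer/reader
.toy_calls <- function(sample_id = "S1") {
  tibble::tibble(
    sample_id = sample_id,
    chrom = c("chr1", "chr1", "chr2"),
    start0 = c(100, 5000, 77),
    end0 = c(200, 5600, 300),
    strand = c("+", "-", "+"),
    key = junction_key(c("chr1", "chr1", "chr2"), c(100, 5000, 77),
                       c(200, 5600, 300)),
    count = c(5, 2, 11)
  )
}

test_that("every dialect writer/reader round-trips (key, count) pairs", {
  calls <- .toy_calls()
  emitters <- list(
    circexplorer = .emit_circexplorer, ciri2 = .emit_ciri2,
    find_circ = .emit_find_circ, knife = .emit_knife,
    mapsplice = .emit_mapsplice
  )
  for (tool in names(emitters)) {
    path <- withr::local_tempfile(fileext = ".txt")
    emitters[[tool]](calls, path)
    got <- read_tool_output(path, tool, "S1")
    expect_equal(sort(got$key), sort(calls$key), label = tool)
    expect_equal(got$count[match(calls$key, got$key)], calls$count,
                 label = tool)
    expect_equal(attr(got, "n_skipped"), 0L)
  }
})

test_that("the DCC multi-sample CircRNACount resolves per-sample columns", {
  obs <- dplyr::bind_rows(.toy_calls("S1"), .toy_calls("S2")[1:2, ])
  obs$is_fp <- FALSE
  path <- withr::local_tempfile()
  .emit_dcc(obs, c("S1", "S2"), path)
  got1 <- read_tool_output(path, "dcc", "S1")
  got2 <- read_tool_output(path, "dcc", "S2")
  expect_equal(sort(got1$key[got1$count > 0]), sort(.toy_calls()$key))
  expect_equal(sum(got2$count > 0), 2)
  expect_error(read_tool_output(path, "dcc", "nonexistent"), "none named")
})

test_that("one-based dialects are shifted and zero-based pass through", {
  # CIRI2 row (1-based inclusive): start 101, end 200, 7 reads
  path <- withr::local_tempfile()
  writeLines(c(
    paste("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
          "#junction_reads", "a", "b", "c", "d", "e", "strand", "f",
          sep = "\t"),
    paste("chr1:101|200", "chr1", "101", "200", "7", "x", "0", "1", "exon",
          "g", "+", ".", sep = "\t")
  ), path)
  got <- read_tool_output(path, "ciri2", "S1")
  expect_equal(got$start0, 100)
  expect_equal(got$end0, 200)
  expect_equal(got$count, 7)

  # CIRCexplorer row (0-based): start 100, end 200, 5 reads
  path2 <- withr::local_tempfile()
  writeLines(paste(
    "chr1", "100", "200", "circular_RNA/1", "0", "+", "100", "200",
    "0,0,0", "1", "100", "0", "5", sep = "\t"
  ), path2)
  got2 <- read_tool_output(path2, "circexplorer", "S1")
  expect_equal(got2$start0, 100)
  expect_equal(got2$end0, 200)
  expect_equal(got2$count, 5)
})

test_that("mapsplice donor-first coordinates are reordered; trans-chromosomal rows dropped", {
  path <- withr::local_tempfile()
  writeLines(c(
    paste("chr1~chr1", "200", "101", "FUSIONJUNC_1", "9", "++", sep = "\t"),
    paste("chr1~chr2", "500", "300", "FUSIONJUNC_2", "4", "--", sep = "\t")
  ), path)
  expect_warning(got <- read_tool_output(path, "mapsplice", "S1"),
                 "skipped 1")
  expect_equal(nrow(got), 1)
  expect_equal(got$start0, 100)
  expect_equal(got$end0, 200)
  expect_equal(got$strand, "+")
})

test_that("malformed rows are skipped with a warning; a malformed majority aborts", {
  calls <- .toy_calls()
  path <- withr::local_tempfile()
  .emit_find_circ(calls, path)
  # append one bad row to 3 good ones
  cat("chr1\tnotanumber\t50\tx\t3\t+\n", file = path, append = TRUE)
  expect_warning(got <- read_tool_output(path, "find_circ", "S1"),
                 "skipped 1 malformed")
  expect_equal(nrow(got), 3)
  expect_equal(attr(got, "n_skipped"), 1L)

  bad <- withr::local_tempfile()
  writeLines(rep("garbage line without tabs", 5), bad)
  expect_error(
    suppressWarnings(read_tool_output(bad, "find_circ", "S1")),
    "wrong dialect"
  )
})

test_that("empty caller output yields an empty call set, not an error", {
  path <- withr::local_tempfile()
  file.create(path)
  got <- read_tool_output(path, "knife", "S1")
  expect_equal(nrow(got), 0)
})

test_that("SJ.out.tab parsing extracts intron coordinates and unique reads", {
  path <- withr::local_tempfile()
  writeLines(c(
    "chr1\t201\t300\t1\t1\t1\t12\t3\t40",
    "chr2\t50\t900\t2\t2\t0\t7\t0\t35"
  ), path)
  sj <- read_star_sj(path)
  expect_equal(sj$intron_start1, c(201, 50))
  expect_equal(sj$intron_end1, c(300, 900))
  expect_equal(sj$unique_reads, c(12, 7))

  bad <- withr::local_tempfile()
  writeLines("chr1\t1\t2\t3", bad)
  expect_error(read_star_sj(bad), "9 columns")

  empty <- withr::local_tempfile()
  file.create(empty)
  expect_equal(nrow(read_star_sj(empty)), 0)
})

test_that("sample table enforces unique ids and sums the JRPM denominator", {
  path <- withr::local_tempfile()
  tab <- tibble::tibble(
    sample_id = c("A_plasma", "A_urine"),
    participant_id = "A", biofluid = c("plasma", "urine"), visit = 1,
    canonical_junction_reads = c(100000, 50000),
    chimeric_junction_reads = c(500, 200)
  )
  readr::write_tsv(tab, path)
  got <- read_sample_table(path)
  expect_equal(got$total_junction_reads, c(100500, 50200))
  expect_equal(length(unique(got$participant_id)), 1)

  tab2 <- tab
  tab2$sample_id <- "dup"
  readr::write_tsv(tab2, path)
  expect_error(read_sample_table(path), "duplicate sample_id")
})

test_that("BED12 writer/reader round-trips exon structure and CDS", {
  tx <- tiny_transcripts()
  path <- withr::local_tempfile(fileext = ".bed")
  .emit_bed12(tx, path)
  got <- read_bed12(path)
  got <- got[match(tx$name, got$name), ]
  expect_equal(got$tx_start0, tx$tx_start0)
  expect_equal(got$tx_end0, tx$tx_end0)
  expect_equal(got$cds_start0, tx$cds_start0)
  expect_equal(got$cds_end0, tx$cds_end0)
  expect_equal(got$exon_start0, tx$exon_start0)
  expect_equal(got$exon_end0, tx$exon_end0)
  # last block must end at the transcript end
  for (i in seq_len(nrow(got))) {
    expect_equal(max(got$exon_end0[[i]]), got$tx_end0[i])
  }
})

test_that("junction BED6 and matrix writers round-trip", {
  recs <- .toy_calls()
  path <- withr::local_tempfile(fileext = ".bed")
  write_junction_bed(recs, path)
  got <- read_junction_bed(path)
  expect_equal(got$key, recs$key)
  expect_equal(got$count, recs$count)

  mat <- matrix(1:6, 2, 3,
                dimnames = list(c("chr1:1-50", "chr1:9-90"),
                                c("s1", "s2", "s3")))
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(mat, mpath)
  expect_equal(read_matrix(mpath), mat)
})

test_that("dialect readers recover the generator's planted calls exactly", {
  m <- noiseless_manifest()
  dir <- file.path(tempdir(), "io-roundtrip")
  emit_files(m, dir)
  fluid <- "plasma"
  samples <- m$samples[m$samples$biofluid == fluid, ]
  sid <- samples$sample_id[1]
  truth <- m$observed[[fluid]]
  for (tool in supported_tools()) {
    path <- .tool_file(dir, fluid, tool, sid)
    got <- read_tool_output(path, tool, sid)
    got <- got[got$count > 0, ]
    want <- truth[[tool]][truth[[tool]]$sample_id == sid, ]
    expect_equal(sort(got$key), sort(want$key), label = tool)
    expect_equal(got$count[match(want$key, got$key)], want$count,
                 label = tool)
  }
})
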