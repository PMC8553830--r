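test_that("simulation is deterministic given (config, seed)", {
  cfg <- generator_config(
    n_participants = 4, n_long_participants = 1,
    n_junctions = c(plasma = 60, urine = 60), n_transcripts = 60
  )
  m1 <- simulate_truth(cfg, seed = 9)
  m2 <- simulate_truth(cfg, seed = 9)
  expect_identical(m1, m2)
  m3 <- simulate_truth(cfg, seed = 10)
  expect_false(identical(m1$junctions, m3$junctions))
})

test_that("zero participant-effect sd gives identical expected counts", {
  cfg <- generator_config(
    n_participants = 4, n_long_participants = 1, participant_sd = 0,
    n_junctions = c(plasma = 50, urine = 50), n_transcripts = 60
  )
  m <- simulate_truth(cfg, seed = 2)
  expect_true(all(m$offsets == 1))
})

test_that("realized counts match the closed-form negative-binomial mean", {
  # pooled over ~50 junctions x 80 samples the mean of count/mu is 1
  # within Monte-Carlo error
  cfg <- generator_config(participant_sd = 0)
  m <- simulate_truth(cfg, seed = 5)
  cm <- m$counts$plasma
  lib <- m$samples$library_size[match(colnames(cm), m$samples$sample_id)]
  ab <- m$junctions$abundance_plasma[m$members$plasma]
  mu <- outer(ab, lib) / 1e6
  ratio <- mean(cm / mu)
  expect_equal(ratio, 1, tolerance = 0.02)
})

test_that("sample totals decompose into canonical plus chimeric reads", {
  m <- default_manifest()
  expect_equal(
    m$samples$canonical_junction_reads + m$samples$chimeric_junction_reads,
    m$samples$library_size
  )
  # chimeric reads equal the sample's summed back-splice counts
  for (fluid in c("plasma", "urine")) {
    fs <- m$samples[m$samples$biofluid == fluid, ]
    expect_equal(fs$chimeric_junction_reads,
                 unname(colSums(m$counts[[fluid]][, fs$sample_id])))
  }
})

test_that("one-based dialect files exceed the zero-based truth start by 1", {
  dir <- noiseless_run_dir()
  m <- noiseless_manifest()
  sid <- m$samples$sample_id[m$samples$biofluid == "plasma"][1]
  obs <- m$observed$plasma$ciri2
  want <- obs[obs$sample_id == sid, ]
  raw <- readr::read_lines(.tool_file(dir, "plasma", "ciri2", sid))[-1]
  f <- strsplit(raw, "\t", fixed = TRUE)
  starts1 <- as.numeric(vapply(f, `[[`, "", 3))
  ends1 <- as.numeric(vapply(f, `[[`, "", 4))
  mtch <- match(
    paste0(vapply(f, `[[`, "", 2), ":", starts1 - 1, "-", ends1),
    want$key
  )
  expect_false(anyNA(mtch))
  expect_equal(starts1, want$start0[mtch] + 1)
  expect_equal(ends1, want$end0[mtch])

  # a zero-based dialect writes the truth coordinates verbatim
  raw0 <- readr::read_lines(.tool_file(dir, "plasma", "find_circ", sid))
  f0 <- strsplit(raw0, "\t", fixed = TRUE)
  expect_true(all(
    paste0(vapply(f0, `[[`, "", 1), ":", vapply(f0, `[[`, "", 2), "-",
           vapply(f0, `[[`, "", 3)) %in% want$key
  ))
})

test_that("false-positive counts stay within binomial 99% bounds", {
  cfg <- generator_config(
    fp_rate = stats::setNames(rep(0.05, 6), supported_tools())
  )
  m <- simulate_truth(cfg, seed = 31)
  n_samples <- sum(m$samples$biofluid == "plasma")
  n_loci <- cfg$n_fp_loci
  n_trials <- n_samples * n_loci
  for (tool in c("ciri2", "find_circ")) {
    obs <- m$observed$plasma[[tool]]
    n_fp <- sum(obs$is_fp)
    expect_gte(n_fp, stats::qbinom(0.005, n_trials, 0.05))
    expect_lte(n_fp, stats::qbinom(0.995, n_trials, 0.05))
  }
})

test_that("per-tool false-positive pools are disjoint by default", {
  m <- default_manifest()
  keys <- lapply(m$fp_pools, function(p) p$key)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(length(intersect(keys[[i]], keys[[j]])), 0)
    }
  }
  truth <- m$junctions$key
  expect_false(any(unlist(keys) %in% truth))
})

test_that("planted abundances respect the floor and the catalog overlap", {
  m <- default_manifest()
  ab <- m$junctions$abundance_plasma[m$junctions$in_plasma]
  expect_true(all(ab >= m$config$abundance_floor_jrpm))
  expect_equal(sum(m$junctions$in_plasma), 300)
  expect_equal(sum(m$junctions$in_urine), 300)
  expect_equal(sum(m$junctions$in_plasma & m$junctions$in_urine),
               round(0.85 * 300))
})

test_that("emitted trees are byte-identical for identical invocations", {
  cfg <- generator_config(
    n_participants = 3, n_long_participants = 1,
    n_junctions = c(plasma = 40, urine = 40), n_transcripts = 50
  )
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  emit_files(simulate_truth(cfg, seed = 77), d1)
  emit_files(simulate_truth(cfg, seed = 77), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_equal(f1, f2)
  expect_equal(unname(tools::md5sum(file.path(d1, f1))),
               unname(tools::md5sum(file.path(d2, f2))))
})
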