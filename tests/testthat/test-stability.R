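test_that("coefficient of variation: closed forms and scale invariance", {
  expect_equal(cv(c(5, 5, 5)), 0)
  expect_equal(cv(c(1, 3)), sqrt(2) / 2)   # sd of two points = |x1-x2|/sqrt(2)
  expect_equal(cv(c(1, 3)), 0.7071068, tolerance = 1e-6)
  withr::with_seed(3, {
    x <- stats::rlnorm(20)
    for (c in c(0.1, 2, 1000)) expect_equal(cv(c * x), cv(x))
  })
  expect_true(is.na(cv(c(5))))
  expect_true(is.na(cv(c(0, 0, 0))))
})

test_that("within-participant CVs are lower than global under participant effects", {
  m <- default_manifest()
  jm <- jrpm_matrix(m$counts$plasma, m$samples)
  st <- participant_stability(jm, m$samples, min_visits = 5)
  expect_lt(st$test$median_within, st$test$median_global)
  expect_lt(st$test$p.value, 1e-4)
  # only the 4 long-visit participants qualify, plus the global scope
  expect_equal(nrow(st$summary), 5)
  expect_equal(nrow(st$per_participant_tests), 4)
  expect_true(all(st$cv_values$cv >= 0))
})

test_that("degenerate (constant) expression is reported, not an error", {
  jm <- matrix(5, 10, 12,
               dimnames = list(sprintf("j%d", 1:10), sprintf("s%d", 1:12)))
  meta <- tibble::tibble(
    sample_id = sprintf("s%d", 1:12),
    participant_id = rep(c("P1", "P2"), each = 6),
    biofluid = "plasma", visit = rep(1:6, 2),
    total_junction_reads = 1e5
  )
  st <- participant_stability(jm, meta, min_visits = 5)
  expect_true(all(st$cv_values$cv == 0))
  expect_true(st$test$degenerate)
})

test_that("no participant with enough visits is a hard error", {
  jm <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  meta <- tibble::tibble(
    sample_id = c("s1", "s2"), participant_id = c("P1", "P2"),
    biofluid = "plasma", visit = 1, total_junction_reads = 1e5
  )
  expect_error(participant_stability(jm, meta), ">= 5")
})

test_that("tool correlation: identical profiles give r = 1, unit diagonal", {
  m <- matrix(stats::rlnorm(50), 10, 5,
              dimnames = list(sprintf("j%d", 1:10), sprintf("s%d", 1:5)))
  cm <- tool_correlation(list(a = m, b = m, c = m))
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_equal(unname(cm["a", "b"]), 1)
  expect_true(isSymmetric(cm))
})

test_that("independent dropout degrades inter-tool correlation monotonically", {
  mean_offdiag <- function(level) {
    cfg <- generator_config(
      n_participants = 6, n_long_participants = 2,
      n_junctions = c(plasma = 120, urine = 120),
      n_transcripts = 90,
      dropout = stats::setNames(rep(level, 6), supported_tools()),
      fp_rate = stats::setNames(rep(0, 6), supported_tools())
    )
    m <- simulate_truth(cfg, seed = 400)
    cons <- manifest_consensus(m, "plasma")
    tj <- lapply(supported_tools(), function(t) {
      keys <- cons$sets[[t]]
      jrpm_matrix(cons$dms[[t]]$counts[keys, , drop = FALSE], m$samples)
    })
    names(tj) <- supported_tools()
    cm <- tool_correlation(tj)
    mean(cm[upper.tri(cm)])
  }
  r <- vapply(c(0.05, 0.25, 0.5), mean_offdiag, 1)
  expect_true(all(r < 1))
  expect_true(all(diff(r) < 0))
})

test_that("rank concordance: identical and reversed orderings", {
  rc <- rank_concordance(letters[1:5], ct = 1:5, jrpm_vals = 50:46)
  expect_equal(rc$spearman_rho, 1)
  expect_equal(rc$table$rank_ct, rc$table$rank_jrpm)
  rc2 <- rank_concordance(letters[1:5], ct = 1:5, jrpm_vals = 46:50)
  expect_equal(rc2$spearman_rho, -1)
  expect_error(rank_concordance(letters[1:2], 1:2, 2:1), "3 items")
  expect_error(rank_concordance(letters[1:3], rep(NA_real_, 3), 1:3),
               "missing")
})

test_that("spearman rho equals pearson on the rank vectors (oracle)", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      ct <- stats::runif(12, 25, 35)
      jv <- stats::rlnorm(12, 3)
      rc <- rank_concordance(sprintf("i%d", 1:12), ct, jv)
      oracle <- stats::cor(rank(ct), rank(-jv), method = "pearson")
      expect_equal(rc$spearman_rho, oracle, tolerance = 1e-12)
      expect_true(abs(rc$spearman_rho) <= 1)
      expect_equal(sort(rc$table$rank_ct), 1:12)
      expect_equal(sort(rc$table$rank_jrpm), 1:12)
    }
  })
})

test_that("published expression table ranks reproduce on both platforms", {
  for (fluid in c("plasma", "urine")) {
    tab <- qpcr_rank_table(fluid)
    rc <- rank_concordance(tab$circrna, tab$mean_ct, tab$mean_jrpm)
    expect_equal(rc$table$rank_jrpm, tab$rnaseq_rank)
    expect_equal(rc$table$rank_ct, tab$qpcr_rank)
  }
  # most abundant by sequencing: circMCU in plasma, circPHC3 in urine
  p <- qpcr_rank_table("plasma")
  expect_equal(p$circrna[which.max(p$mean_jrpm)], "circMCU")
  u <- qpcr_rank_table("urine")
  expect_equal(u$circrna[which.max(u$mean_jrpm)], "circPHC3")
})
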