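# Ground-truthed synthetic study generator.
#
# Emulates the study design the pipeline targets: two biofluids (plasma,
# urine) sampled longitudinally from a participant cohort, a shared truth
# catalog of back-splice junctions planted at known genomic features of
# synthetic BED12 transcripts, participant-specific expression profiles,
# negative-binomial back-splice counts, linear splice support at the
# flanking splice sites, and six caller "observations" of the truth with
# tool-specific coordinate basis, dropout, and false positives. Every
# emitted record is derivable from the returned truth manifest.

#' Generator configuration
#'
#' Defaults describe a small longitudinal cohort: 12 participants, 4 of
#' them sampled 6 times (the longitudinal subset), the rest twice, in both
#' biofluids; 300 truth junctions per biofluid with 85% of the urine
#' catalog shared with plasma; log-normal base abundance (JRPM scale) with
#' a floor that keeps every planted junction recoverable under the
#' detection filters; log-normal participant-by-junction expression
#' offsets; negative-binomial counts; per-tool dropout and false-positive
#' rates with disjoint per-tool false-positive locus pools.
#'
#' @param n_participants Cohort size.
#' @param n_long_participants Participants with `long_visits` visits.
#' @param long_visits,short_visits Visits for the longitudinal subset and
#'   the rest.
#' @param n_junctions Named vector: truth junctions per biofluid.
#' @param urine_shared_frac Fraction of the urine catalog shared with
#'   plasma.
#' @param class_props Named proportions of planted feature classes.
#' @param abundance_meanlog,abundance_sdlog Log-normal base abundance
#'   (JRPM units).
#' @param abundance_floor_jrpm Lower truncation of base abundance (JRPM).
#' @param participant_sd SD (log scale) of participant-specific
#'   multiplicative expression offsets; 0 removes participant structure.
#' @param nb_dispersion Negative-binomial size parameter for all counts.
#' @param library_size_range Range of per-sample total junction reads.
#' @param flank_prob Probability a junction has expressed linear flanks.
#' @param linear_meanlog,linear_sdlog Log-normal linear-flank abundance
#'   (JRPM units).
#' @param dropout Named per-tool probability of missing a true junction in
#'   a sample.
#' @param fp_rate Named per-tool per-sample per-locus false-positive
#'   probability.
#' @param n_fp_loci False-positive loci in each tool's pool.
#' @param shared_fp_pool Share one false-positive pool across tools
#'   (default FALSE: disjoint pools, so the strict intersection provably
#'   suppresses them)?
#' @param n_decoy_sj Decoy linear junctions per biofluid (linear splice
#'   noise unrelated to any circRNA flank).
#' @param n_transcripts Synthetic transcript models.
#' @param chromosomes Chromosome names used.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(
    n_participants = 12,
    n_long_participants = 4,
    long_visits = 6,
    short_visits = 2,
    n_junctions = c(plasma = 300, urine = 300),
    urine_shared_frac = 0.85,
    class_props = c(
      multi_exon_spanning_intron = 0.70,
      single_exon = 0.02,
      intronic = 0.10,
      boundary_outside_exon = 0.08,
      intergenic = 0.10
    ),
    abundance_meanlog = log(15),
    abundance_sdlog = 1,
    abundance_floor_jrpm = 8,
    participant_sd = 0.5,
    nb_dispersion = 8,
    library_size_range = c(2e5, 8e5),
    flank_prob = 0.85,
    linear_meanlog = log(45),
    linear_sdlog = 1,
    dropout = c(
      circexplorer = 0.04, ciri2 = 0.03, dcc = 0.03,
      find_circ = 0.08, knife = 0.02, mapsplice = 0.12
    ),
    fp_rate = c(
      circexplorer = 0.02, ciri2 = 0.02, dcc = 0.02,
      find_circ = 0.02, knife = 0.02, mapsplice = 0.02
    ),
    n_fp_loci = 60,
    shared_fp_pool = FALSE,
    n_decoy_sj = 150,
    n_transcripts = 160,
    chromosomes = paste0("chr", 1:4)) {
  cfg <- as.list(environment())
  stopifnot(
    n_participants >= 1,
    n_long_participants <= n_participants,
    all(n_junctions > 0),
    urine_shared_frac >= 0, urine_shared_frac <= 1,
    abs(sum(class_props) - 1) < 1e-8,
    all(dropout >= 0 & dropout <= 1),
    all(fp_rate >= 0 & fp_rate <= 1),
    participant_sd >= 0, nb_dispersion > 0,
    library_size_range[1] > 0, flank_prob >= 0, flank_prob <= 1
  )
  if (!all(supported_tools() %in% names(cfg$dropout))) {
    stop("dropout must name all six tools")
  }
  if (!all(supported_tools() %in% names(cfg$fp_rate))) {
    stop("fp_rate must name all six tools")
  }
  structure(cfg, class = "generator_config")
}

# ---- transcript synthesis ---------------------------------------------

.simulate_transcripts <- function(config) {
  per_chrom <- ceiling(config$n_transcripts / length(config$chromosomes))
  rows <- list()
  gaps <- list()
  chrom_sizes <- stats::setNames(
    numeric(length(config$chromosomes)), config$chromosomes
  )
  idx <- 0
  for (chrom in config$chromosomes) {
    cursor <- 10000
    for (k in seq_len(per_chrom)) {
      idx <- idx + 1
      if (idx > config$n_transcripts) break
      n_ex <- sample(4:8, 1)
      ex_sizes <- sample(100:300, n_ex, replace = TRUE)
      in_sizes <- sample(500:2000, n_ex - 1, replace = TRUE)
      es <- numeric(n_ex)
      ee <- numeric(n_ex)
      pos <- cursor
      for (e in seq_len(n_ex)) {
        es[e] <- pos
        ee[e] <- pos + ex_sizes[e]
        pos <- ee[e] + if (e < n_ex) in_sizes[e] else 0
      }
      tx_start0 <- es[1]
      tx_end0 <- ee[n_ex]
      rows[[idx]] <- list(
        chrom = chrom, tx_start0 = tx_start0, tx_end0 = tx_end0,
        name = sprintf("SYNGENE%04d", idx),
        strand = sample(c("+", "-"), 1),
        cds_start0 = es[2], cds_end0 = ee[n_ex - 1],
        exon_start0 = es, exon_end0 = ee
      )
      gap_len <- sample(5000:20000, 1)
      gaps[[length(gaps) + 1]] <- c(tx_end0 + 1000, tx_end0 + gap_len - 1000)
      names(gaps)[length(gaps)] <- chrom
      cursor <- tx_end0 + gap_len
    }
    chrom_sizes[chrom] <- cursor + 50000
  }
  transcripts <- tibble::tibble(
    chrom = vapply(rows, `[[`, "", "chrom"),
    tx_start0 = vapply(rows, `[[`, 1, "tx_start0"),
    tx_end0 = vapply(rows, `[[`, 1, "tx_end0"),
    name = vapply(rows, `[[`, "", "name"),
    strand = vapply(rows, `[[`, "", "strand"),
    cds_start0 = vapply(rows, `[[`, 1, "cds_start0"),
    cds_end0 = vapply(rows, `[[`, 1, "cds_end0"),
    exon_start0 = lapply(rows, `[[`, "exon_start0"),
    exon_end0 = lapply(rows, `[[`, "exon_end0")
  )
  list(
    transcripts = transcripts,
    gaps = tibble::tibble(
      chrom = names(gaps),
      lo = vapply(gaps, `[`, 1, 1),
      hi = vapply(gaps, `[`, 1, 2)
    ),
    chrom_sizes = chrom_sizes
  )
}

# ---- junction placement -----------------------------------------------

# Place `n` junctions with classes drawn from config$class_props at
# feature-true positions; acceptor (chrom:start0) and donor (chrom:end0)
# positions are kept globally unique so flanking linear junctions match
# exactly one circRNA.
.place_junctions <- function(n, genome, config) {
  tx <- genome$transcripts
  classes <- sample(
    names(config$class_props), n, replace = TRUE,
    prob = config$class_props
  )
  used_acceptor <- new.env(hash = TRUE)
  used_donor <- new.env(hash = TRUE)
  rows <- vector("list", n)
  max_tries <- 80 * n
  tries <- 0
  i <- 1
  # exon/intron geometry as plain lists for fast candidate draws
  txg <- list(
    chrom = tx$chrom, strand = tx$strand, name = tx$name,
    es = tx$exon_start0, ee = tx$exon_end0
  )
  while (i <= n) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop("infeasible generator config: cannot place ", n,
           " junctions on ", nrow(tx), " transcripts")
    }
    cls <- classes[i]
    cand <- .one_placement(cls, txg, genome$gaps)
    if (is.null(cand)) next
    ak <- paste(cand$chrom, cand$start0)
    dk <- paste(cand$chrom, cand$end0)
    if (!is.null(used_acceptor[[ak]]) || !is.null(used_donor[[dk]])) next
    used_acceptor[[ak]] <- TRUE
    used_donor[[dk]] <- TRUE
    cand$class <- cls
    rows[[i]] <- cand
    i <- i + 1
  }
  out <- tibble::tibble(
    chrom = vapply(rows, `[[`, "", "chrom"),
    start0 = vapply(rows, `[[`, 1, "start0"),
    end0 = vapply(rows, `[[`, 1, "end0"),
    strand = vapply(rows, `[[`, "", "strand"),
    host = vapply(rows, `[[`, "", "host"),
    class = vapply(rows, `[[`, "", "class")
  )
  out$key <- junction_key(out$chrom, out$start0, out$end0)
  out
}

.one_placement <- function(cls, txg, gaps) {
  if (cls == "intergenic") {
    gi <- sample(nrow(gaps), 1)
    lo <- gaps$lo[gi]
    hi <- gaps$hi[gi]
    if (hi - lo < 900) return(NULL)
    len <- sample(150:800, 1)
    s0 <- lo + sample.int(max(1, hi - lo - len), 1)
    return(list(
      chrom = gaps$chrom[gi], start0 = s0, end0 = s0 + len,
      strand = sample(c("+", "-"), 1), host = NA_character_
    ))
  }
  ti <- sample(length(txg$name), 1)
  es <- txg$es[[ti]]
  ee <- txg$ee[[ti]]
  n_ex <- length(es)
  base <- list(chrom = txg$chrom[ti], strand = txg$strand[ti],
               host = txg$name[ti])
  if (cls == "multi_exon_spanning_intron") {
    if (n_ex < 2) return(NULL)
    i <- sample(n_ex - 1, 1)
    j <- i + sample(n_ex - i, 1)
    return(c(base, start0 = es[i], end0 = ee[j]))
  }
  if (cls == "single_exon") {
    e <- sample(n_ex, 1)
    if (ee[e] - es[e] < 20) return(NULL)
    return(c(base, start0 = es[e] + 3, end0 = ee[e] - 3))
  }
  if (cls == "intronic") {
    if (n_ex < 2) return(NULL)
    k <- sample(n_ex - 1, 1)
    lo <- ee[k] + 10
    hi <- es[k + 1] - 10
    if (hi - lo < 50) return(NULL)
    return(c(base, start0 = lo, end0 = hi))
  }
  # boundary_outside_exon: start at an exon start, end inside the
  # following intron
  if (n_ex < 2) return(NULL)
  k <- sample(n_ex - 1, 1)
  mid <- floor((ee[k] + es[k + 1]) / 2)
  c(base, start0 = es[k], end0 = mid)
}

# false-positive locus pools: random loci whose acceptor/donor positions
# avoid the truth catalog
.fp_pools <- function(genome, truth, config) {
  tools <- supported_tools()
  n_pools <- if (config$shared_fp_pool) 1 else length(tools)
  total <- config$n_fp_loci * n_pools
  used_acceptor <- paste(truth$chrom, truth$start0)
  used_donor <- paste(truth$chrom, truth$end0)
  r_chrom <- character(total)
  r_s0 <- numeric(total)
  r_e0 <- numeric(total)
  r_strand <- character(total)
  i <- 1
  tries <- 0
  while (i <= total) {
    tries <- tries + 1
    if (tries > 200 * total) stop("cannot place false-positive loci")
    chrom <- sample(names(genome$chrom_sizes), 1)
    len <- sample(200:2000, 1)
    s0 <- sample.int(genome$chrom_sizes[[chrom]] - len - 1, 1)
    ak <- paste(chrom, s0)
    dk <- paste(chrom, s0 + len)
    if (ak %in% used_acceptor || dk %in% used_donor) next
    used_acceptor <- c(used_acceptor, ak)
    used_donor <- c(used_donor, dk)
    r_chrom[i] <- chrom
    r_s0[i] <- s0
    r_e0[i] <- s0 + len
    r_strand[i] <- sample(c("+", "-"), 1)
    i <- i + 1
  }
  pool <- tibble::tibble(
    chrom = r_chrom, start0 = r_s0, end0 = r_e0, strand = r_strand
  )
  pool$key <- junction_key(pool$chrom, pool$start0, pool$end0)
  if (config$shared_fp_pool) {
    stats::setNames(rep(list(pool), length(tools)), tools)
  } else {
    split(pool, rep(tools, each = config$n_fp_loci))
  }
}

# decoy linear splice junctions that match no circRNA flank
.decoy_sj <- function(genome, truth, config) {
  acceptors <- paste(truth$chrom, truth$start0)
  donors <- paste(truth$chrom, truth$end0)
  n <- config$n_decoy_sj
  r_chrom <- character(n)
  r_s1 <- numeric(n)
  r_e1 <- numeric(n)
  i <- 1
  tries <- 0
  while (i <= n) {
    tries <- tries + 1
    if (tries > 200 * n) stop("cannot place decoy introns")
    chrom <- sample(names(genome$chrom_sizes), 1)
    w <- sample(200:2000, 1)
    s1 <- sample.int(genome$chrom_sizes[[chrom]] - w - 2, 1) + 1
    e1 <- s1 + w - 1
    # must be a 5'-flank of nothing and a 3'-flank of nothing
    if (paste(chrom, e1) %in% acceptors) next
    if (paste(chrom, s1 - 1) %in% donors) next
    r_chrom[i] <- chrom
    r_s1[i] <- s1
    r_e1[i] <- e1
    i <- i + 1
  }
  tibble::tibble(chrom = r_chrom, intron_start1 = r_s1, intron_end1 = r_e1)
}

# ---- main simulation ---------------------------------------------------

#' Simulate a complete ground-truthed study
#'
#' Deterministic given `(config, seed)`. Generates synthetic transcript
#' models, plants the truth junction catalog at feature-true positions,
#' draws the longitudinal sample grid, participant offsets,
#' negative-binomial back-splice counts, linear flank counts, and each
#' tool's observed calls (dropout + false positives applied).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return List of class `truth_manifest`; see elements `transcripts`,
#'   `junctions`, `samples`, `counts` (per biofluid junction-by-sample
#'   true count matrices), `linear5`/`linear3` (flank count matrices),
#'   `observed` (per biofluid, per tool call tibbles), `fp_pools`,
#'   `decoy_sj`, `decoy_sj_counts`, `offsets`, `chrom_sizes`.
#' @export
simulate_truth <- function(config = generator_config(), seed = 1) {
  withr::with_seed(as.integer(seed), .simulate_truth_impl(config, seed))
}

.simulate_truth_impl <- function(config, seed) {
  genome <- .simulate_transcripts(config)
  fluids <- names(config$n_junctions)

  n_urine_shared <- round(config$urine_shared_frac * config$n_junctions[["urine"]])
  n_pool <- config$n_junctions[["plasma"]] +
    (config$n_junctions[["urine"]] - n_urine_shared)
  pool <- .place_junctions(n_pool, genome, config)

  plasma_idx <- seq_len(config$n_junctions[["plasma"]])
  urine_idx <- c(
    sort(sample(plasma_idx, n_urine_shared)),
    setdiff(seq_len(n_pool), plasma_idx)
  )
  members <- list(plasma = plasma_idx, urine = urine_idx)

  pool$in_plasma <- seq_len(n_pool) %in% plasma_idx
  pool$in_urine <- seq_len(n_pool) %in% urine_idx
  for (fl in fluids) {
    ab <- rep(NA_real_, n_pool)
    ab[members[[fl]]] <- pmax(
      stats::rlnorm(length(members[[fl]]), config$abundance_meanlog,
                    config$abundance_sdlog),
      config$abundance_floor_jrpm
    )
    pool[[paste0("abundance_", fl)]] <- ab
  }
  pool$has_flank <- stats::runif(n_pool) < config$flank_prob
  pool$flank5_abundance <- ifelse(
    pool$has_flank,
    stats::rlnorm(n_pool, config$linear_meanlog, config$linear_sdlog), 0
  )
  pool$flank3_abundance <- ifelse(
    pool$has_flank,
    stats::rlnorm(n_pool, config$linear_meanlog, config$linear_sdlog), 0
  )
  pool$flank5_width <- sample(200:2000, n_pool, replace = TRUE)
  pool$flank3_width <- sample(200:2000, n_pool, replace = TRUE)
  # keep flank introns off other junctions' splice sites and on-chromosome
  donors <- paste(pool$chrom, pool$end0)
  acceptors <- paste(pool$chrom, pool$start0)
  for (i in seq_len(n_pool)) {
    while (pool$start0[i] - pool$flank5_width[i] < 1 ||
           paste(pool$chrom[i], pool$start0[i] - pool$flank5_width[i]) %in% donors) {
      pool$flank5_width[i] <- sample(200:2000, 1)
    }
    while (paste(pool$chrom[i], pool$end0[i] + pool$flank3_width[i]) %in% acceptors) {
      pool$flank3_width[i] <- sample(200:2000, 1)
    }
  }

  participants <- sprintf("P%02d", seq_len(config$n_participants))
  visits <- ifelse(
    seq_len(config$n_participants) <= config$n_long_participants,
    config$long_visits, config$short_visits
  )
  grid <- expand.grid(
    visit = seq_len(max(visits)), biofluid = fluids,
    p = seq_len(config$n_participants),
    stringsAsFactors = FALSE
  )
  grid <- grid[grid$visit <= visits[grid$p], ]
  grid <- grid[order(grid$p, grid$biofluid, grid$visit), ]
  samples <- tibble::tibble(
    sample_id = sprintf("%s_%s_V%02d", participants[grid$p], grid$biofluid,
                        grid$visit),
    participant_id = participants[grid$p],
    biofluid = grid$biofluid,
    visit = grid$visit
  )
  samples$library_size <- round(stats::runif(
    nrow(samples), config$library_size_range[1], config$library_size_range[2]
  ))

  offsets <- matrix(
    exp(stats::rnorm(config$n_participants * n_pool, 0, config$participant_sd)),
    nrow = config$n_participants,
    dimnames = list(participants, pool$key)
  )

  counts <- list()
  linear5 <- list()
  linear3 <- list()
  for (fl in fluids) {
    fs <- samples[samples$biofluid == fl, ]
    jidx <- members[[fl]]
    keys <- pool$key[jidx]
    mu_base <- pool[[paste0("abundance_", fl)]][jidx]
    cmat <- matrix(0, length(jidx), nrow(fs),
                   dimnames = list(keys, fs$sample_id))
    l5 <- cmat
    l3 <- cmat
    for (s in seq_len(nrow(fs))) {
      off <- offsets[fs$participant_id[s], keys]
      mu <- mu_base * off * fs$library_size[s] / 1e6
      cmat[, s] <- stats::rnbinom(length(jidx), mu = mu,
                                  size = config$nb_dispersion)
      l5[, s] <- stats::rnbinom(
        length(jidx),
        mu = pool$flank5_abundance[jidx] * fs$library_size[s] / 1e6,
        size = config$nb_dispersion
      )
      l3[, s] <- stats::rnbinom(
        length(jidx),
        mu = pool$flank3_abundance[jidx] * fs$library_size[s] / 1e6,
        size = config$nb_dispersion
      )
    }
    counts[[fl]] <- cmat
    linear5[[fl]] <- l5
    linear3[[fl]] <- l3
  }

  # sample totals: chimeric = true back-splice reads, canonical the rest
  samples$chimeric_junction_reads <- vapply(seq_len(nrow(samples)), function(s) {
    fl <- samples$biofluid[s]
    sum(counts[[fl]][, samples$sample_id[s]])
  }, 1)
  samples$canonical_junction_reads <-
    samples$library_size - samples$chimeric_junction_reads
  if (any(samples$canonical_junction_reads <= 0)) {
    stop("infeasible config: chimeric reads exceed library size")
  }
  samples$total_junction_reads <- samples$library_size

  fp_pools <- .fp_pools(genome, pool, config)
  decoy_sj <- .decoy_sj(genome, pool, config)
  decoy_counts <- list()
  for (fl in fluids) {
    fs <- samples[samples$biofluid == fl, ]
    decoy_counts[[fl]] <- matrix(
      stats::rpois(nrow(decoy_sj) * nrow(fs), 20),
      nrow = nrow(decoy_sj), dimnames = list(NULL, fs$sample_id)
    )
  }

  observed <- list()
  for (fl in fluids) {
    fs <- samples[samples$biofluid == fl, ]
    cmat <- counts[[fl]]
    jinfo <- pool[members[[fl]], ]
    nz <- which(cmat > 0, arr.ind = TRUE)
    observed[[fl]] <- list()
    for (tool in supported_tools()) {
      d <- config$dropout[[tool]]
      fp <- config$fp_rate[[tool]]
      pool_fp <- fp_pools[[tool]]
      kept <- if (d > 0 && nrow(nz) > 0) {
        nz[stats::runif(nrow(nz)) >= d, , drop = FALSE]
      } else {
        nz
      }
      truth_calls <- tibble::tibble(
        sample_id = colnames(cmat)[kept[, 2]],
        chrom = jinfo$chrom[kept[, 1]],
        start0 = jinfo$start0[kept[, 1]],
        end0 = jinfo$end0[kept[, 1]],
        strand = jinfo$strand[kept[, 1]],
        key = jinfo$key[kept[, 1]],
        count = cmat[kept],
        is_fp = FALSE
      )
      fp_calls <- NULL
      if (fp > 0 && nrow(pool_fp) > 0) {
        # Bernoulli(fp) per (locus, sample)
        grid_loc <- rep(seq_len(nrow(pool_fp)), times = nrow(fs))
        grid_sam <- rep(fs$sample_id, each = nrow(pool_fp))
        hit <- stats::runif(length(grid_loc)) < fp
        if (any(hit)) {
          loc <- grid_loc[hit]
          fp_calls <- tibble::tibble(
            sample_id = grid_sam[hit],
            chrom = pool_fp$chrom[loc],
            start0 = pool_fp$start0[loc],
            end0 = pool_fp$end0[loc],
            strand = pool_fp$strand[loc],
            key = pool_fp$key[loc],
            count = 1 + stats::rpois(sum(hit), 1.5),
            is_fp = TRUE
          )
        }
      }
      obs <- dplyr::bind_rows(truth_calls, fp_calls)
      obs <- obs[order(obs$sample_id, obs$chrom, obs$start0), ]
      observed[[fl]][[tool]] <- obs
    }
  }

  structure(
    list(
      seed = seed, config = config,
      transcripts = genome$transcripts,
      chrom_sizes = genome$chrom_sizes,
      junctions = pool,
      members = members,
      samples = samples,
      offsets = offsets,
      counts = counts,
      linear5 = linear5,
      linear3 = linear3,
      fp_pools = fp_pools,
      decoy_sj = decoy_sj,
      decoy_sj_counts = decoy_counts,
      observed = observed
    ),
    class = "truth_manifest"
  )
}
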