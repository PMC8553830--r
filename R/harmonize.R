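# Per-tool detection filtering, six-tool consensus intersection, prevalence
# tiers, biofluid overlap, and the two expression-analysis pre-filters.

#' Detection filter configuration
#'
#' @param min_reads Minimum back-spliced read count for a junction to count
#'   as detected in a sample (default 2).
#' @param min_samples Minimum number of samples of a biofluid in which a
#'   junction must be detected to be retained for a tool (default 5).
#' @param junction_overlap_nt Minimum read overlap on each side of the
#'   junction used upstream when the callers were run; recorded as
#'   provenance only — it is not recomputable from caller outputs
#'   (default 18).
#' @param strand_aware Should junction matching distinguish strand?
#'   (default FALSE).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_reads = 2, min_samples = 5,
                          junction_overlap_nt = 18, strand_aware = FALSE) {
  stopifnot(min_reads >= 1, min_samples >= 1)
  structure(
    list(
      min_reads = min_reads, min_samples = min_samples,
      junction_overlap_nt = junction_overlap_nt,
      strand_aware = strand_aware
    ),
    class = "filter_config"
  )
}

#' Build a per-tool detection matrix for one biofluid
#'
#' Pivots one tool's calls into a junction-by-sample count matrix over all
#' samples of the biofluid and flags a junction as detected in a sample
#' when its count reaches `min_reads`. Duplicate reports of one junction in
#' one sample (e.g. per-mate calls later combined) are summed.
#'
#' @param calls Tibble of tool calls (one tool, one biofluid) with `key`,
#'   `sample_id`, `count`, and optionally `strand`, `chrom`, `start0`,
#'   `end0`.
#' @param samples Sample metadata tibble restricted to the biofluid
#'   (`sample_id` column used; all calls must reference these samples).
#' @param config A [filter_config()].
#' @param tool,biofluid Labels stored on the result (taken from `calls`
#'   when absent).
#' @return List of class `detection_matrix` with elements `tool`,
#'   `biofluid`, `counts` (junction x sample matrix), `detected` (logical
#'   matrix), `samples`, `config`.
#' @export
detect <- function(calls, samples, config = filter_config(),
                   tool = NULL, biofluid = NULL) {
  sample_ids <- samples$sample_id
  if (is.null(tool)) {
    tool <- if (nrow(calls) > 0) calls$tool[1] else NA_character_
  }
  if (is.null(biofluid) && "biofluid" %in% names(samples)) {
    biofluid <- samples$biofluid[1]
  }
  unknown <- setdiff(unique(calls$sample_id), sample_ids)
  if (length(unknown) > 0) {
    stop("calls reference sample(s) absent from the sample table: ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(calls) > 0) {
    key <- if (config$strand_aware) {
      junction_key(calls$chrom, calls$start0, calls$end0, calls$strand,
                   strand_aware = TRUE)
    } else if (all(c("chrom", "start0", "end0") %in% names(calls))) {
      junction_key(calls$chrom, calls$start0, calls$end0)
    } else {
      calls$key
    }
    agg <- stats::aggregate(
      calls$count, by = list(key = key, sample_id = calls$sample_id), FUN = sum
    )
    keys <- sort(unique(agg$key))
    counts <- matrix(
      0, nrow = length(keys), ncol = length(sample_ids),
      dimnames = list(keys, sample_ids)
    )
    counts[cbind(
      match(agg$key, keys), match(agg$sample_id, sample_ids)
    )] <- agg$x
  } else {
    counts <- matrix(
      0, nrow = 0, ncol = length(sample_ids),
      dimnames = list(character(), sample_ids)
    )
  }
  structure(
    list(
      tool = tool, biofluid = biofluid, counts = counts,
      detected = counts >= config$min_reads, samples = sample_ids,
      config = config
    ),
    class = "detection_matrix"
  )
}

#' Apply the sample-recurrence filter and summarize one tool
#'
#' A junction is retained for a tool when it is detected (per the
#' read-support rule of [detect()]) in at least `min_samples` samples of
#' the biofluid. The summary reports the retained total and the mean
#' number of retained junctions detected per sample.
#'
#' @param dm A `detection_matrix` from [detect()].
#' @param config A [filter_config()]; defaults to the one stored in `dm`.
#' @return List with `retained` (character vector of junction keys) and
#'   `summary` (tibble: `tool`, `biofluid`, `total_circrna`,
#'   `mean_circrna_per_sample`).
#' @export
retain_tool_junctions <- function(dm, config = dm$config) {
  n_det <- rowSums(dm$detected)
  retained <- rownames(dm$detected)[n_det >= config$min_samples]
  per_sample <- if (length(retained) > 0) {
    colSums(dm$detected[retained, , drop = FALSE])
  } else {
    rep(0, ncol(dm$detected))
  }
  list(
    retained = retained,
    summary = tibble::tibble(
      tool = dm$tool, biofluid = dm$biofluid,
      total_circrna = length(retained),
      mean_circrna_per_sample = mean(per_sample)
    )
  )
}

#' Intersect the per-tool retained junction sets
#'
#' The consensus catalog is the strict intersection: junctions retained by
#' every tool. The pattern table gives exclusive intersection sizes in
#' UpSet semantics — each junction of the union is counted once, under its
#' exact tool-membership pattern.
#'
#' @param sets Named list of character vectors (junction keys), one per
#'   tool; all six tools required unless `min_tools` is lowered.
#' @param min_tools Number of tools required for consensus membership
#'   (default: all supplied tools; the catalog definition is the strict
#'   six-tool intersection).
#' @return List with `consensus` (sorted keys), `patterns` (tibble:
#'   `tools` comma-joined pattern, `n_tools`, `n_junctions`), and `union`
#'   (all keys seen by any tool).
#' @export
intersect_tools <- function(sets, min_tools = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a named list (one element per tool)")
  }
  strict <- is.null(min_tools)
  if (strict) min_tools <- length(supported_tools())
  if (strict && length(sets) < length(supported_tools())) {
    stop("strict consensus requires all six tool sets; got ", length(sets))
  }
  all_keys <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) all_keys %in% s, logical(length(all_keys)))
  if (length(all_keys) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(all_keys, names(sets)))
  n_tools_per_key <- rowSums(member)
  consensus <- all_keys[n_tools_per_key >= min_tools]
  pattern <- apply(member, 1, function(m) paste(names(sets)[m], collapse = ","))
  pat_tab <- table(pattern)
  patterns <- tibble::tibble(
    tools = names(pat_tab),
    n_tools = vapply(strsplit(names(pat_tab), ",", fixed = TRUE), length, 1L),
    n_junctions = as.integer(pat_tab)
  )
  patterns <- patterns[order(-patterns$n_tools, patterns$tools), ]
  list(consensus = consensus, patterns = patterns, union = all_keys)
}

#' Combine per-tool detection matrices into one per-sample detection rule
#'
#' @param dms List of `detection_matrix` objects for one biofluid (same
#'   sample set).
#' @param keys Junction keys (rows of the result).
#' @param mode `"any"`: a junction is detected in a sample if at least one
#'   tool reports it with enough reads there; `"all"`: every tool must.
#' @return Logical junction-by-sample matrix.
#' @export
combined_detection <- function(dms, keys, mode = c("any", "all")) {
  mode <- match.arg(mode)
  samples <- dms[[1]]$samples
  out <- matrix(
    mode == "all", nrow = length(keys), ncol = length(samples),
    dimnames = list(keys, samples)
  )
  for (dm in dms) {
    if (!identical(dm$samples, samples)) {
      stop("detection matrices cover different sample sets")
    }
    hit <- matrix(FALSE, length(keys), length(samples))
    present <- keys %in% rownames(dm$detected)
    hit[present, ] <- dm$detected[keys[present], , drop = FALSE]
    out <- if (mode == "any") out | hit else out & hit
  }
  out
}

#' Prevalence tiers of the consensus catalog
#'
#' For thresholds 10%..100% in steps of 10%, counts consensus junctions
#' detected in at least that fraction of the biofluid's samples. The
#' boundary uses the ceiling: "detected in X% of samples" means at least
#' `ceiling(X * n)` samples.
#'
#' @param detection Logical junction-by-sample matrix (from
#'   [combined_detection()]) restricted to consensus junctions.
#' @param thresholds Fractions to evaluate (default `seq(0.1, 1, 0.1)`).
#' @return Tibble `threshold`, `min_samples`, `n_junctions`; counts are
#'   non-increasing in threshold.
#' @export
prevalence_table <- function(detection, thresholds = seq(0.1, 1, by = 0.1)) {
  n <- ncol(detection)
  n_det <- rowSums(detection)
  tibble::tibble(
    threshold = thresholds,
    min_samples = ceiling(thresholds * n),
    n_junctions = vapply(
      ceiling(thresholds * n), function(m) sum(n_det >= m), 1L
    )
  )
}

#' Overlap of the two biofluid consensus catalogs
#'
#' @param plasma,urine Character vectors of consensus junction keys.
#' @return List with `shared` (keys), `n_shared`, and `frac_of_urine`
#'   (share of the urine catalog also seen in plasma; `NA` when the urine
#'   catalog is empty).
#' @export
biofluid_overlap <- function(plasma, urine) {
  shared <- intersect(plasma, urine)
  list(
    shared = shared,
    n_shared = length(shared),
    frac_of_urine = if (length(urine) == 0) NA_real_ else {
      length(shared) / length(urine)
    }
  )
}

#' Expression-analysis pre-filters: sample QC then junction prevalence
#'
#' Before expression modelling, samples detecting fewer than `min_circ`
#' junctions are dropped, and then junctions detected in fewer than
#' `min_frac` of the remaining samples are dropped.
#'
#' @param detection Logical junction-by-sample matrix.
#' @param min_circ Minimum detected junctions for a sample to pass QC
#'   (default 300).
#' @return `sample_qc()`: character vector of kept sample ids.
#' @export
sample_qc <- function(detection, min_circ = 300) {
  kept <- colnames(detection)[colSums(detection) >= min_circ]
  if (length(kept) == 0) {
    stop("sample QC removed every sample (min_circ = ", min_circ, ")")
  }
  kept
}

#' @rdname sample_qc
#' @param min_frac Minimum fraction of kept samples in which a junction
#'   must be detected (default 0.5; a junction in exactly half the samples
#'   is kept).
#' @return `prevalence_filter()`: character vector of kept junction keys.
#' @export
prevalence_filter <- function(detection, min_frac = 0.5) {
  frac <- rowMeans(detection)
  rownames(detection)[frac >= min_frac]
}
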