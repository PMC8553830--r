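# End-to-end orchestration over an input tree laid out as emitted by
# emit_files(): per-tool harmonization and filtering, six-tool consensus,
# prevalence tiers, biofluid overlap, quantification, annotation, and
# longitudinal stability.

#' Read all six tools' calls for one biofluid
#'
#' @param input_dir Root of the input tree (see [emit_files()]).
#' @param fluid Biofluid subdirectory name.
#' @param samples Sample table rows for this biofluid.
#' @return Named list (per tool) of harmonized call tibbles.
#' @export
read_fluid_calls <- function(input_dir, fluid, samples) {
  out <- list()
  for (tool in supported_tools()) {
    calls <- list()
    for (sid in samples$sample_id) {
      path <- .tool_file(input_dir, fluid, tool, sid)
      if (!file.exists(path)) {
        stop("missing input file: ", path)
      }
      calls[[sid]] <- suppressWarnings(read_tool_output(path, tool, sid))
    }
    out[[tool]] <- dplyr::bind_rows(calls)
  }
  out
}

#' Read per-sample linear splice-junction tables for one biofluid
#' @inheritParams read_fluid_calls
#' @return Named list (per sample id) of linear-junction tibbles.
#' @export
read_fluid_sj <- function(input_dir, fluid, samples) {
  out <- list()
  for (sid in samples$sample_id) {
    path <- file.path(input_dir, fluid, "sj", paste0(sid, ".SJ.out.tab"))
    if (!file.exists(path)) stop("missing input file: ", path)
    out[[sid]] <- read_star_sj(path)
  }
  out
}

#' Consensus count matrix across tools
#'
#' One count per (junction, sample): the maximum across the tools
#' reporting the junction there. The maximum is robust to single-tool
#' dropout and equals the shared value whenever the tools agree.
#'
#' @param dms List of `detection_matrix` objects (one per tool).
#' @param keys Junction keys (rows of the result).
#' @return Numeric junction-by-sample matrix.
#' @export
consensus_counts <- function(dms, keys) {
  samples <- dms[[1]]$samples
  out <- matrix(0, length(keys), length(samples),
                dimnames = list(keys, samples))
  for (dm in dms) {
    present <- keys %in% rownames(dm$counts)
    if (!any(present)) next
    sub <- dm$counts[keys[present], , drop = FALSE]
    out[present, ] <- pmax(out[present, , drop = FALSE], sub)
  }
  out
}

#' Run the full harmonization-and-characterization pipeline
#'
#' Executes, per biofluid: per-tool detection filtering (read support then
#' sample recurrence), the strict six-tool consensus with the exclusive
#' intersection-pattern table, prevalence tiers, consensus quantification
#' (JRPM, flanking linear counts, CLR), genomic-feature annotation, the
#' expression pre-filters, inter-tool expression correlation, and the
#' longitudinal within-participant stability analysis; then the
#' cross-biofluid catalog overlap.
#'
#' @param input_dir Input tree (layout of [emit_files()]).
#' @param config A [filter_config()].
#' @param detection_mode Per-sample detection rule for prevalence tiers
#'   and pre-filters: `"any"` (default: any tool suffices) or `"all"`.
#' @param min_visits Minimum longitudinal samples per participant for the
#'   stability analysis (default 5).
#' @param qc_min_circ `min_circ` for [sample_qc()]; `NA` skips the
#'   expression pre-filter step.
#' @return List of class `pipeline_result`: per biofluid a list with
#'   `detection` (per-tool matrices), `retained`, `tool_summary`,
#'   `intersection` (consensus + patterns), `prevalence`, `counts`,
#'   `jrpm`, `expression`, `clr_summary`, `annotation`,
#'   `tool_correlation`, `stability`, `prefilter`; plus `overlap` and
#'   `samples`.
#' @export
run_pipeline <- function(input_dir, config = filter_config(),
                         detection_mode = c("any", "all"),
                         min_visits = 5, qc_min_circ = NA) {
  detection_mode <- match.arg(detection_mode)
  sample_tab <- read_sample_table(file.path(input_dir, "samples.tsv"))
  transcripts <- read_bed12(file.path(input_dir, "annotation.bed12"))
  fluids <- unique(sample_tab$biofluid)
  per_fluid <- list()

  for (fluid in fluids) {
    samples <- sample_tab[sample_tab$biofluid == fluid, ]
    calls <- read_fluid_calls(input_dir, fluid, samples)
    dms <- lapply(names(calls), function(tool) {
      detect(calls[[tool]], samples, config, tool = tool, biofluid = fluid)
    })
    names(dms) <- names(calls)
    ret <- lapply(dms, retain_tool_junctions, config = config)
    sets <- lapply(ret, `[[`, "retained")
    tool_summary <- dplyr::bind_rows(lapply(ret, `[[`, "summary"))
    inter <- intersect_tools(sets)
    consensus <- inter$consensus

    det_any <- combined_detection(dms, consensus, mode = detection_mode)
    prevalence <- prevalence_table(det_any)

    counts <- consensus_counts(dms, consensus)
    sj <- read_fluid_sj(input_dir, fluid, samples)
    junctions <- parse_junction_key(consensus)
    junctions$key <- consensus
    expression <- expression_records(counts, junctions, sample_tab, sj)
    clr_sum <- clr_summary(expression)
    jm <- jrpm_matrix(counts, sample_tab)

    annotation <- classify_junctions(junctions, transcripts)

    tool_jrpm <- lapply(names(dms), function(tool) {
      keys <- sets[[tool]]
      jrpm_matrix(dms[[tool]]$counts[keys, , drop = FALSE], sample_tab)
    })
    names(tool_jrpm) <- names(dms)
    tool_cor <- tool_correlation(tool_jrpm)

    stability <- tryCatch(
      participant_stability(jm, sample_tab, min_visits = min_visits),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "stability_result")
    )

    prefilter <- NULL
    if (!is.na(qc_min_circ)) {
      kept_samples <- sample_qc(det_any, min_circ = qc_min_circ)
      kept_junctions <- prevalence_filter(
        det_any[, kept_samples, drop = FALSE]
      )
      prefilter <- list(
        kept_samples = kept_samples, kept_junctions = kept_junctions
      )
    }

    per_fluid[[fluid]] <- list(
      samples = samples, detection = dms, retained = sets,
      tool_summary = tool_summary, intersection = inter,
      prevalence = prevalence, counts = counts, jrpm = jm,
      expression = expression, clr_summary = clr_sum,
      annotation = annotation, tool_correlation = tool_cor,
      stability = stability, prefilter = prefilter
    )
  }

  overlap <- if (all(c("plasma", "urine") %in% fluids)) {
    biofluid_overlap(
      per_fluid$plasma$intersection$consensus,
      per_fluid$urine$intersection$consensus
    )
  } else {
    NULL
  }

  structure(
    c(per_fluid, list(overlap = overlap, samples = sample_tab,
                      config = config)),
    class = "pipeline_result"
  )
}

#' Write the pipeline's standard output tables
#'
#' Per biofluid: consensus BED6, the exclusive intersection-pattern TSV,
#' prevalence tiers, per-tool summary, expression records, the JRPM
#' matrix, annotation, CV values and the tool-correlation matrix; plus a
#' JSON run report of record counts at each filter step.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fluids <- intersect(names(result), c("plasma", "urine"))
  report <- list()
  for (fluid in fluids) {
    r <- result[[fluid]]
    fd <- file.path(out_dir, fluid)
    dir.create(fd, showWarnings = FALSE)
    cj <- parse_junction_key(r$intersection$consensus)
    cj$key <- r$intersection$consensus
    cj$count <- rowSums(r$counts)[cj$key]
    write_junction_bed(cj, file.path(fd, "consensus.bed"))
    readr::write_tsv(r$intersection$patterns,
                     file.path(fd, "intersection_patterns.tsv"),
                     progress = FALSE)
    readr::write_tsv(r$prevalence, file.path(fd, "prevalence_tiers.tsv"),
                     progress = FALSE)
    readr::write_tsv(r$tool_summary, file.path(fd, "tool_summary.tsv"),
                     progress = FALSE)
    readr::write_tsv(r$expression, file.path(fd, "expression_records.tsv"),
                     progress = FALSE)
    write_matrix(r$jrpm, file.path(fd, "jrpm_matrix.tsv"))
    readr::write_tsv(r$annotation, file.path(fd, "annotation.tsv"),
                     progress = FALSE)
    if (!is.null(r$stability$cv_values)) {
      readr::write_tsv(r$stability$cv_values, file.path(fd, "cv_values.tsv"),
                       progress = FALSE)
    }
    cm <- as.data.frame(r$tool_correlation)
    cm <- cbind(tool = rownames(r$tool_correlation), cm)
    readr::write_tsv(cm, file.path(fd, "tool_correlation.tsv"),
                     progress = FALSE)
    report[[fluid]] <- list(
      n_samples = nrow(r$samples),
      retained_per_tool = lapply(r$retained, length),
      n_union = length(r$intersection$union),
      n_consensus = length(r$intersection$consensus),
      n_expression_records = nrow(r$expression)
    )
  }
  if (!is.null(result$overlap)) {
    report$overlap <- list(
      n_shared = result$overlap$n_shared,
      frac_of_urine = result$overlap$frac_of_urine
    )
  }
  jsonlite::write_json(
    report, file.path(out_dir, "run_report.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out_dir)
}
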