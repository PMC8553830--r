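# Longitudinal stability (coefficient of variation of JRPM), inter-tool
# expression correlation, and cross-platform rank concordance.

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' Undefined (NA) for fewer than two values or a non-positive mean; such
#' junctions are excluded upstream.
#'
#' @param x Numeric vector.
#' @return Scalar CV, or `NA` when undefined.
#' @export
#' @examples
#' cv(c(5, 5, 5))  # 0
#' cv(c(1, 3))     # sqrt(2)/2
cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  stats::sd(x) / m
}

# per-junction CVs over the columns `cols` of a jrpm matrix
.junction_cvs <- function(jrpm_mat, cols) {
  sub <- jrpm_mat[, cols, drop = FALSE]
  vals <- apply(sub, 1, cv)
  vals[!is.na(vals)]
}

#' Within-participant versus global expression variability
#'
#' For each participant with at least `min_visits` samples in the
#' biofluid, computes the per-junction CV of JRPM across that
#' participant's longitudinal samples; computes the same per-junction CV
#' across all samples of the biofluid ("global"); and compares the pooled
#' within-participant CV distribution against the global one with a
#' two-sided Mann-Whitney rank-sum test. Junctions with zero mean within
#' a scope are excluded from that scope.
#'
#' @param jrpm_mat Junction-by-sample JRPM matrix (consensus junctions).
#' @param sample_meta Sample table covering the matrix's samples.
#' @param min_visits Minimum samples per participant (default 5).
#' @return List of class `stability_result`: `cv_values` (tibble `scope`,
#'   `junction_key`, `cv`), `summary` (tibble `scope`, `n_samples`,
#'   `n_junctions`, `median_cv`), `test` (pooled comparison: statistic,
#'   p.value, n_within, n_global), `per_participant_tests` (tibble with
#'   one rank-sum test per participant vs global).
#' @export
participant_stability <- function(jrpm_mat, sample_meta, min_visits = 5) {
  meta <- sample_meta[match(colnames(jrpm_mat), sample_meta$sample_id), ]
  counts_per_p <- table(meta$participant_id)
  eligible <- names(counts_per_p)[counts_per_p >= min_visits]
  if (length(eligible) == 0) {
    stop("no participant has >= ", min_visits, " samples")
  }

  global_cv <- .junction_cvs(jrpm_mat, seq_len(ncol(jrpm_mat)))
  cv_rows <- list(tibble::tibble(
    scope = "all", junction_key = names(global_cv), cv = unname(global_cv)
  ))
  summary_rows <- list(tibble::tibble(
    scope = "all", n_samples = ncol(jrpm_mat),
    n_junctions = length(global_cv),
    median_cv = stats::median(global_cv)
  ))
  per_tests <- list()
  pooled <- numeric(0)

  for (p in eligible) {
    cols <- which(meta$participant_id == p)
    pcv <- .junction_cvs(jrpm_mat, cols)
    pooled <- c(pooled, pcv)
    cv_rows[[length(cv_rows) + 1]] <- tibble::tibble(
      scope = p, junction_key = names(pcv), cv = unname(pcv)
    )
    summary_rows[[length(summary_rows) + 1]] <- tibble::tibble(
      scope = p, n_samples = length(cols), n_junctions = length(pcv),
      median_cv = stats::median(pcv)
    )
    wt <- .safe_wilcox(pcv, global_cv)
    per_tests[[length(per_tests) + 1]] <- tibble::tibble(
      participant_id = p, n_cv = length(pcv),
      statistic = wt$statistic, p.value = wt$p.value,
      degenerate = wt$degenerate
    )
  }

  wt <- .safe_wilcox(pooled, global_cv)
  structure(
    list(
      cv_values = dplyr::bind_rows(cv_rows),
      summary = dplyr::bind_rows(summary_rows),
      test = list(
        method = "two-sided Mann-Whitney rank-sum",
        statistic = wt$statistic, p.value = wt$p.value,
        degenerate = wt$degenerate,
        n_within = length(pooled), n_global = length(global_cv),
        median_within = stats::median(pooled),
        median_global = stats::median(global_cv)
      ),
      per_participant_tests = dplyr::bind_rows(per_tests)
    ),
    class = "stability_result"
  )
}

# wilcox.test that reports rather than fails on degenerate input
.safe_wilcox <- function(x, y) {
  if (length(x) == 0 || length(y) == 0 ||
      (length(unique(c(x, y))) < 2)) {
    return(list(statistic = NA_real_, p.value = NA_real_, degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       degenerate = FALSE)
}

#' Pearson correlation of expression between tools
#'
#' Each tool contributes a per-junction mean JRPM profile over the union
#' of retained junctions, zero-filled where the tool did not report a
#' junction (the default basis), or a flattened junction-by-sample vector
#' (`basis = "flatten"`).
#'
#' @param tool_jrpm Named list (one element per tool) of junction-by-
#'   sample JRPM matrices.
#' @param basis `"mean"` or `"flatten"`.
#' @return Symmetric correlation matrix with unit diagonal; `NA` for
#'   pairs involving a zero-variance profile.
#' @export
tool_correlation <- function(tool_jrpm, basis = c("mean", "flatten")) {
  basis <- match.arg(basis)
  keys <- sort(unique(unlist(lapply(tool_jrpm, rownames))))
  profiles <- lapply(tool_jrpm, function(m) {
    if (basis == "mean") {
      v <- stats::setNames(rep(0, length(keys)), keys)
      v[rownames(m)] <- rowMeans(m)
      v
    } else {
      samples <- sort(unique(unlist(lapply(tool_jrpm, colnames))))
      full <- matrix(0, length(keys), length(samples),
                     dimnames = list(keys, samples))
      full[rownames(m), colnames(m)] <- m
      as.vector(full)
    }
  })
  x <- do.call(cbind, profiles)
  sds <- apply(x, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(x, method = "pearson"))
  cm[sds == 0, ] <- NA
  cm[, sds == 0] <- NA
  diag(cm) <- 1
  cm
}

#' Rank concordance between qRT-PCR and sequencing expression
#'
#' Ranks items on the qRT-PCR platform by ascending mean Ct (lowest Ct =
#' most abundant = rank 1) and on the sequencing platform by descending
#' mean JRPM (highest = rank 1). Missing Ct values are ranked last, in
#' their order of appearance. Spearman's rho is computed over complete
#' pairs and cross-checkable as the Pearson correlation of the rank
#' vectors.
#'
#' @param items Character vector of item names.
#' @param ct Mean Ct values (may contain NA).
#' @param jrpm_vals Mean JRPM values.
#' @return List with `table` (tibble `item`, `ct`, `jrpm`, `rank_ct`,
#'   `rank_jrpm`) and `spearman_rho` over complete pairs.
#' @export
rank_concordance <- function(items, ct, jrpm_vals) {
  n <- length(items)
  stopifnot(length(ct) == n, length(jrpm_vals) == n)
  if (n < 3) stop("need at least 3 items")
  if (all(is.na(ct)) || all(is.na(jrpm_vals))) {
    stop("all values missing on one platform")
  }
  rank_ct <- integer(n)
  present <- which(!is.na(ct))
  rank_ct[present] <- rank(ct[present], ties.method = "first")
  missing <- which(is.na(ct))
  rank_ct[missing] <- length(present) + seq_along(missing)
  rank_jrpm <- rank(-jrpm_vals, ties.method = "first")

  complete <- !is.na(ct) & !is.na(jrpm_vals)
  rho <- if (sum(complete) >= 3) {
    suppressWarnings(stats::cor(
      rank(ct[complete]), rank(-jrpm_vals[complete]), method = "pearson"
    ))
  } else {
    NA_real_
  }
  list(
    table = tibble::tibble(
      item = items, ct = ct, jrpm = jrpm_vals,
      rank_ct = rank_ct, rank_jrpm = as.integer(rank_jrpm)
    ),
    spearman_rho = rho
  )
}
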