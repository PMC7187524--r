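# Prioritization of expanded repeats across a cohort: a one-sided
# Wilcoxon rank-sum case-control test, or a bootstrap 95%-quantile
# outlier z-score for heterogeneous cohorts, applied either per merged
# anchored-IRR region ("locus" method, which localizes candidate
# expansions) or per motif's paired-IRR counts ("motif" method, which
# flags overall enrichment for long repeats of a motif).

#' One-sided Wilcoxon rank-sum test (cases greater)
#'
#' Tests whether case counts are stochastically greater than control
#' counts. The exact null distribution is used for small tie-free
#' inputs (`n + m <= 12`); otherwise the normal approximation with tie
#' and continuity correction.
#'
#' @param case_counts,control_counts Non-empty numeric vectors.
#' @return One-sided p-value.
#' @examples
#' wilcoxon_one_sided(c(10, 11), c(1, 2, 3))  # 0.1
#' @export
wilcoxon_one_sided <- function(case_counts, control_counts) {
  if (!length(case_counts) || !length(control_counts))
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(case_counts, control_counts)) > 0L
  n <- length(case_counts) + length(control_counts)
  suppressWarnings(
    stats::wilcox.test(case_counts, control_counts,
                       alternative = "greater",
                       exact = !ties && n <= 12L,
                       correct = TRUE)$p.value)
}

#' Outlier parameters
#'
#' @param quantile Quantile whose sampling distribution is
#'   bootstrapped (default 0.95).
#' @param bootstrap_reps Number of bootstrap resamples (>= 100).
#' @param seed Integer seed for the bootstrap.
#' @param controls_only Resample only control samples instead of the
#'   full cohort.
#' @return A list of class `outlier_params`.
#' @export
outlier_params <- function(quantile = 0.95, bootstrap_reps = 1000L,
                           seed = 1L, controls_only = FALSE) {
  if (!(quantile > 0 && quantile < 1))
    stop("quantile must be in (0, 1)", call. = FALSE)
  if (bootstrap_reps < 100L)
    stop("bootstrap_reps must be >= 100", call. = FALSE)
  structure(list(quantile = quantile,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed),
                 controls_only = isTRUE(controls_only)),
            class = "outlier_params")
}

#' Bootstrap outlier z-scores for case samples
#'
#' Bootstraps the sampling distribution of the cohort's 95% quantile
#' (B resamples with replacement of the full count vector, linear
#' interpolation quantile), giving mean `mu_q` and standard deviation
#' `sigma_q`. Every case whose count exceeds `mu_q` receives
#' `z = (count - mu_q) / sigma_q`; cases at or below `mu_q` are
#' omitted. A degenerate bootstrap (`sigma_q < 1e-9`) with a count
#' above `mu_q` yields `Inf`, which sorts first.
#'
#' @param counts Named numeric vector of per-sample counts (>= 3
#'   samples).
#' @param case_ids Names of the case samples.
#' @param params [outlier_params()].
#' @param control_ids Names of the controls (only used with
#'   `controls_only = TRUE`).
#' @return Named numeric vector of z-scores (possibly empty).
#' @export
outlier_zscores <- function(counts, case_ids, params = outlier_params(),
                            control_ids = NULL) {
  if (length(counts) < 3L)
    stop("outlier analysis needs at least 3 samples", call. = FALSE)
  pool <- if (params$controls_only) {
    if (is.null(control_ids))
      stop("controls_only requires control_ids", call. = FALSE)
    counts[names(counts) %in% control_ids]
  } else counts
  qs <- with_seed(params$seed, {
    vapply(seq_len(params$bootstrap_reps), function(b)
      stats::quantile(sample(pool, length(pool), replace = TRUE),
                      probs = params$quantile, names = FALSE, type = 7),
      numeric(1))
  })
  mu <- mean(qs)
  sdv <- stats::sd(qs)
  cc <- counts[names(counts) %in% case_ids]
  cc <- cc[cc > mu]
  if (!length(cc)) return(stats::setNames(numeric(0), character(0)))
  if (sdv < 1e-9) return(stats::setNames(rep(Inf, length(cc)), names(cc)))
  (cc - mu) / sdv
}

#' Rank prioritization results
#'
#' Orders a result table by ascending p-value or descending z-score.
#' Ties are broken by descending total case count, then by the target
#' id lexicographically, so ranks are a deterministic permutation of
#' `1..N`.
#'
#' @param results data.frame with columns `statistic_value`,
#'   `case_total`, `target_id` and a `statistic_name` of `p_value` or
#'   `z_score`.
#' @param by `"p_value"` (ascending) or `"z_score"` (descending).
#' @return The same data.frame with a `rank` column, sorted by rank.
#' @export
rank_targets <- function(results, by = c("p_value", "z_score")) {
  by <- match.arg(by)
  if (!nrow(results)) {
    results$rank <- integer(0)
    return(results)
  }
  key <- results$statistic_value
  key[is.na(key)] <- if (by == "p_value") Inf else -Inf
  ord <- order(if (by == "p_value") key else -key,
               -results$case_total, results$target_id)
  results <- results[ord, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  rownames(results) <- NULL
  results
}

#' Filter a cohort table before prioritization
#'
#' Composable filters reflecting the standard analysis restrictions:
#' keep targets whose motif length lies in `motif_len_range`; whose
#' region overlaps an interval of `bed` (each extended by `flank_bp` on
#' both sides; locus targets only); and which reach raw-count minima
#' (`min_anchored` for regions, `min_paired` for motifs) in at least
#' one sample.
#'
#' @param cohort An `irr_cohort` from [merge_cohort()].
#' @param motif_len_range Length-2 integer vector, e.g. `c(2, 6)`, or
#'   `NULL`.
#' @param bed Path to a BED file, or a `GRanges`, or `NULL`.
#' @param flank_bp Extension applied to each BED interval.
#' @param min_anchored,min_paired Raw-count minima (0 disables).
#' @return The filtered `irr_cohort`.
#' @export
filter_cohort <- function(cohort, motif_len_range = NULL, bed = NULL,
                          flank_bp = 5000L, min_anchored = 0L,
                          min_paired = 0L) {
  tg <- cohort$anchored$targets
  keep_a <- rep(TRUE, nrow(tg))
  keep_p <- rep(TRUE, length(cohort$paired$motifs))
  if (!is.null(motif_len_range)) {
    keep_a <- keep_a & nchar(tg$motif) >= motif_len_range[1] &
      nchar(tg$motif) <= motif_len_range[2]
    ml <- nchar(cohort$paired$motifs)
    keep_p <- keep_p & ml >= motif_len_range[1] & ml <= motif_len_range[2]
  }
  if (!is.null(bed) && nrow(tg)) {
    gr <- if (inherits(bed, "GRanges")) bed else read_bed_regions(bed)
    ext <- GenomicRanges::resize(gr,
                                 GenomicRanges::width(gr) + 2L * flank_bp,
                                 fix = "center")
    regions <- GenomicRanges::GRanges(
      tg$contig, IRanges::IRanges(start = tg$start + 1L, end = tg$end))
    # maxgap = 0: half-open intervals touching at a boundary count as
    # overlapping
    keep_a <- keep_a &
      IRanges::overlapsAny(regions, ext, maxgap = 0L,
                           ignore.strand = TRUE)
  }
  if (min_anchored > 0 && nrow(tg))
    keep_a <- keep_a &
      apply(cohort$anchored$raw, 1, max) >= min_anchored
  if (min_paired > 0 && length(cohort$paired$motifs))
    keep_p <- keep_p & apply(cohort$paired$raw, 1, max) >= min_paired
  cohort$anchored$targets <- tg[keep_a, , drop = FALSE]
  rownames(cohort$anchored$targets) <- NULL
  cohort$anchored$raw <- cohort$anchored$raw[keep_a, , drop = FALSE]
  cohort$anchored$norm <- cohort$anchored$norm[keep_a, , drop = FALSE]
  cohort$paired$motifs <- cohort$paired$motifs[keep_p]
  cohort$paired$raw <- cohort$paired$raw[keep_p, , drop = FALSE]
  cohort$paired$norm <- cohort$paired$norm[keep_p, , drop = FALSE]
  cohort
}

# Extract the target table and normalized count matrix for one method.
cohort_targets <- function(cohort, method) {
  if (method == "locus") {
    list(ids = cohort$anchored$targets$target_id,
         meta = cohort$anchored$targets,
         counts = cohort$anchored$norm)
  } else {
    m <- cohort$paired$motifs
    list(ids = m,
         meta = data.frame(motif = m, contig = NA_character_,
                           start = NA_integer_, end = NA_integer_,
                           target_id = m, stringsAsFactors = FALSE),
         counts = cohort$paired$norm)
  }
}

result_frame <- function(meta, method, statistic_name, statistic_value,
                         case_total, counts) {
  df <- data.frame(
    target_id = meta$target_id, motif = meta$motif,
    contig = meta$contig, start = meta$start, end = meta$end,
    method = method, statistic_name = statistic_name,
    statistic_value = statistic_value, case_total = case_total,
    stringsAsFactors = FALSE)
  df$counts <- lapply(seq_len(nrow(counts)), function(i) counts[i, ])
  df
}

#' Case-control prioritization of expanded repeats
#'
#' For each target (merged anchored-IRR region under the locus method,
#' or motif under the motif method), tests whether depth-normalized
#' counts in cases are stochastically greater than in controls with
#' [wilcoxon_one_sided()]. Emits raw p-values, Bonferroni-adjusted
#' p-values over the number of tested targets, and 1-based ranks.
#'
#' @param cohort An `irr_cohort` whose samples carry case/control
#'   statuses.
#' @param method `"locus"` or `"motif"`.
#' @return A data.frame of class `irr_results`, ranked by p-value, with
#'   per-sample normalized counts in the `counts` list column.
#' @export
case_control_analysis <- function(cohort, method = c("locus", "motif")) {
  method <- match.arg(method)
  st <- cohort$samples$status
  if (!any(st == "case", na.rm = TRUE) ||
      !any(st == "control", na.rm = TRUE))
    stop("case-control analysis needs both case and control samples",
         call. = FALSE)
  tg <- cohort_targets(cohort, method)
  is_case <- !is.na(st) & st == "case"
  is_ctrl <- !is.na(st) & st == "control"
  if (!length(tg$ids)) {
    out <- result_frame(tg$meta, method, "p_value", numeric(0),
                        numeric(0), tg$counts)
    out$adjusted_p <- numeric(0)
    return(structure(rank_targets(out, "p_value"),
                     class = c("irr_results", "data.frame")))
  }
  p <- vapply(seq_along(tg$ids), function(i)
    wilcoxon_one_sided(tg$counts[i, is_case], tg$counts[i, is_ctrl]),
    numeric(1))
  out <- result_frame(tg$meta, method, "p_value", p,
                      rowSums(tg$counts[, is_case, drop = FALSE]),
                      tg$counts)
  out$adjusted_p <- stats::p.adjust(p, method = "bonferroni")
  out <- rank_targets(out, "p_value")
  structure(out, class = c("irr_results", "data.frame"))
}

#' Outlier prioritization of expanded repeats
#'
#' For each target, computes bootstrap outlier z-scores for the case
#' samples with [outlier_zscores()]; the target's statistic is the
#' maximum z over its cases (targets where no case exceeds the
#' bootstrap quantile mean get `NA` and sort last). Suitable for
#' heterogeneous cohorts where no single shared expansion is expected.
#'
#' @param cohort An `irr_cohort` with statuses.
#' @param method `"locus"` or `"motif"`.
#' @param params [outlier_params()].
#' @return A data.frame of class `irr_results`, ranked by z-score.
#' @export
outlier_analysis <- function(cohort, method = c("locus", "motif"),
                             params = outlier_params()) {
  method <- match.arg(method)
  st <- cohort$samples$status
  case_ids <- cohort$samples$sample_id[!is.na(st) & st == "case"]
  ctrl_ids <- cohort$samples$sample_id[!is.na(st) & st == "control"]
  tg <- cohort_targets(cohort, method)
  if (!length(case_ids) || !length(tg$ids)) {
    out <- result_frame(tg$meta[0, , drop = FALSE], character(0),
                        character(0), numeric(0), numeric(0),
                        tg$counts[0, , drop = FALSE])
    return(structure(rank_targets(out, "z_score"),
                     class = c("irr_results", "data.frame")))
  }
  z <- vapply(seq_along(tg$ids), function(i) {
    zi <- outlier_zscores(tg$counts[i, ], case_ids, params, ctrl_ids)
    if (length(zi)) max(zi) else NA_real_
  }, numeric(1))
  out <- result_frame(tg$meta, method, "z_score", z,
                      rowSums(tg$counts[, cohort$samples$sample_id %in%
                                          case_ids, drop = FALSE]),
                      tg$counts)
  out <- rank_targets(out, "z_score")
  structure(out, class = c("irr_results", "data.frame"))
}

#' @export
print.irr_results <- function(x, n = 10L, ...) {
  cat(sprintf("Prioritized repeat targets (%d total); top %d:\n",
              nrow(x), min(n, nrow(x))))
  cols <- intersect(c("rank", "target_id", "method", "statistic_name",
                      "statistic_value", "adjusted_p"), names(x))
  print.data.frame(utils::head(x[, cols, drop = FALSE], n), digits = 4)
  invisible(x)
}

#' Write prioritization results as TSV
#'
#' Columns: contig, start, end, motif, method, statistic_name,
#' statistic_value, adjusted_p (empty for outlier runs), rank, and the
#' per-sample normalized counts as a trailing JSON object.
#'
#' @param results An `irr_results` data.frame.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  blob <- vapply(results$counts, function(cc)
    as.character(jsonlite::toJSON(as.list(cc), auto_unbox = TRUE,
                                  digits = NA)), "")
  df <- data.frame(
    contig = results$contig, start = results$start, end = results$end,
    motif = results$motif, method = results$method,
    statistic_name = results$statistic_name,
    statistic_value = results$statistic_value,
    adjusted_p = if ("adjusted_p" %in% names(results))
      results$adjusted_p else NA_real_,
    rank = results$rank, counts = blob, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
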