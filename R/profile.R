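# Per-sample STR profiles: classify candidate read pairs into anchored
# and paired IRRs, merge nearby anchors into regions, and combine
# profiles across a cohort into a depth-normalized count table.
#
# An anchored IRR localizes a repeat: the IRR itself aligns poorly, but
# its mate (the anchor) maps confidently in unique flanking sequence,
# so the event is recorded at the anchor's position. A paired IRR (both
# mates in-repeat, same motif) signals a repeat longer than the
# fragment length but cannot be localized, so only per-motif totals are
# kept.

empty_regions <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             count = integer(0), stringsAsFactors = FALSE)
}

new_str_profile <- function(sample_id, depth, read_length, params, motifs) {
  structure(
    list(sample_id = sample_id, depth = depth, read_length = read_length,
         params = params, motifs = motifs),
    class = "str_profile")
}

#' @export
print.str_profile <- function(x, ...) {
  cat(sprintf("STR profile for sample '%s' (depth %.1fx, read length %d)\n",
              x$sample_id, x$depth, x$read_length))
  if (length(x$motifs) == 0L) {
    cat("  no IRR-supported motifs\n")
    return(invisible(x))
  }
  for (m in names(x$motifs)) {
    mm <- x$motifs[[m]]
    cat(sprintf("  %-10s %d anchored region(s), %d anchored IRR(s), %d paired IRR(s)\n",
                m, nrow(mm$anchored_regions), sum(mm$anchored_regions$count),
                mm$paired_count))
  }
  invisible(x)
}

#' Classify one read pair as anchored IRR, paired IRR, or neither
#'
#' A mate is IRR-eligible only when unmapped or mapped with
#' `MAPQ < irr_mapq_max`; eligible mates are tested with [call_irr()].
#' Both mates IRR with the same canonical motif is a paired IRR.
#' Exactly one mate IRR whose mate is mapped with
#' `MAPQ >= anchor_mapq_min` is an anchored IRR, recorded at the
#' anchor's position. Everything else -- including two IRRs with
#' different motifs -- is classified as none.
#'
#' @param pair A one-row `irr_read_pairs` data.frame, or a list with
#'   the same fields.
#' @param params [detection_params()].
#' @param irr_mapq_max Maximum MAPQ of an IRR-eligible read (exclusive).
#' @param anchor_mapq_min Minimum MAPQ of an anchor read (inclusive).
#' @return A list with `type` in `"anchored"`, `"paired"`, `"none"`;
#'   anchored results carry `motif`, `contig`, `anchor_pos`; paired
#'   results carry `motif`.
#' @export
classify_pair <- function(pair, params = detection_params(),
                          irr_mapq_max = 40L, anchor_mapq_min = 50L) {
  classify_one(pair$seq1, pair$qual1, pair$mapped1, pair$mapq1,
               pair$contig1, pair$pos1,
               pair$seq2, pair$qual2, pair$mapped2, pair$mapq2,
               pair$contig2, pair$pos2,
               params, irr_mapq_max, anchor_mapq_min)
}

# Scalar classification shared by classify_pair() and the
# build_str_profile() fast path.
classify_one <- function(seq1, qual1, mapped1, mapq1, contig1, pos1,
                         seq2, qual2, mapped2, mapq2, contig2, pos2,
                         params, irr_mapq_max, anchor_mapq_min) {
  elig1 <- !mapped1 || mapq1 < irr_mapq_max
  elig2 <- !mapped2 || mapq2 < irr_mapq_max
  irr1 <- if (elig1) call_irr(seq1, qual1, params) else NULL
  irr2 <- if (elig2) call_irr(seq2, qual2, params) else NULL
  if (!is.null(irr1) && !is.null(irr2)) {
    if (irr1$canonical_motif == irr2$canonical_motif)
      return(list(type = "paired", motif = irr1$canonical_motif))
    return(list(type = "none"))
  }
  if (xor(is.null(irr1), is.null(irr2))) {
    irr <- if (is.null(irr1)) irr2 else irr1
    anchor_mapped <- if (is.null(irr1)) mapped1 else mapped2
    anchor_mapq <- if (is.null(irr1)) mapq1 else mapq2
    anchor_contig <- if (is.null(irr1)) contig1 else contig2
    anchor_pos <- if (is.null(irr1)) pos1 else pos2
    if (isTRUE(anchor_mapped) && anchor_mapq >= anchor_mapq_min)
      return(list(type = "anchored", motif = irr$canonical_motif,
                  contig = anchor_contig, anchor_pos = anchor_pos))
  }
  list(type = "none")
}

#' Merge anchored-IRR events into regions
#'
#' Single-linkage clustering of anchor positions per contig: successive
#' anchors (sorted by position) join one region while the distance
#' between them is at most `max_gap` (500 bp by default). A single
#' repeat scatters its anchors over roughly a fragment length around
#' the locus, so nearby anchors are evidence for the same repeat.
#'
#' @param events data.frame with columns `contig`, `anchor_pos`
#'   (0-based), all sharing one canonical motif.
#' @param max_gap Maximum distance between successive anchor positions
#'   within one region (inclusive).
#' @return data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open; `start` = leftmost anchor, `end` = rightmost anchor + 1)
#'   and `count` (number of anchors), sorted by contig then start.
#' @examples
#' merge_anchor_events(data.frame(contig = "chr1",
#'                                anchor_pos = c(1000, 1300, 2100)))
#' @export
merge_anchor_events <- function(events, max_gap = 500L) {
  if (nrow(events) == 0L) return(empty_regions())
  out <- lapply(split(events$anchor_pos, events$contig), function(pos) {
    ir <- IRanges::IRanges(start = pos + 1L, width = 1L)
    # two anchors p < q merge iff q - p <= max_gap, i.e. the 1-based gap
    # q - p - 1 is < max_gap
    red <- IRanges::reduce(ir, min.gapwidth = max_gap)
    data.frame(start = IRanges::start(red) - 1L,
               end = IRanges::end(red),
               count = IRanges::countOverlaps(red, ir),
               stringsAsFactors = FALSE)
  })
  contigs <- rep(names(out), vapply(out, nrow, integer(1)))
  res <- do.call(rbind, out)
  res <- data.frame(contig = contigs, res, stringsAsFactors = FALSE,
                    row.names = NULL)
  res[order(res$contig, res$start), , drop = FALSE]
}

#' Estimate mean sequencing depth of an alignment file
#'
#' Depth = (summed aligned read length of primary mapped non-duplicate
#' reads) / (total reference length from the header). Used to normalize
#' IRR counts across samples; an externally known depth can be supplied
#' downstream instead.
#'
#' @param path SAM/BAM/CRAM file.
#' @param reference Reference FASTA (CRAM only).
#' @param keep_dups Include duplicate-marked reads.
#' @return Estimated depth (x-fold coverage).
#' @export
estimate_depth <- function(path, reference = NULL, keep_dups = FALSE) {
  bf <- open_alignment(path, reference)
  hdr <- Rsamtools::scanBamHeader(bf)
  genome <- sum(as.numeric(hdr$targets))
  if (!length(hdr$targets) || genome <= 0)
    stop("alignment header has no contig lengths", call. = FALSE)
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (keep_dups) NA else FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = "qwidth")
  res <- Rsamtools::scanBam(bf, param = param)[[1]]
  sum(as.numeric(res$qwidth)) / genome
}

#' Depth-normalize an IRR count
#'
#' Scales a raw count to the nominal 40x depth used for cross-sample
#' comparison: `count * 40 / depth`.
#'
#' @param count Raw IRR count.
#' @param depth Sample depth (> 0).
#' @param target_depth Nominal depth (default 40).
#' @return Normalized count.
#' @examples
#' normalize_count(10, 20)  # 20
#' @export
normalize_count <- function(count, depth, target_depth = 40) {
  if (any(depth <= 0)) stop("depth must be positive", call. = FALSE)
  count * target_depth / depth
}

#' Build a genome-wide STR profile from candidate read pairs
#'
#' Applies [classify_pair()] to every pair, groups anchored events by
#' canonical motif, merges each motif's anchors into regions with
#' [merge_anchor_events()], and tallies paired-IRR counts per motif.
#' Raw integer counts are stored; normalization is deferred to
#' [merge_cohort()] so a profile remains reusable under a corrected
#' depth.
#'
#' @param pairs An `irr_read_pairs` data.frame
#'   (from [stream_candidate_pairs()] or the simulator).
#' @param sample_id Sample identifier recorded in the profile.
#' @param depth Mean sequencing depth of the sample
#'   (see [estimate_depth()]).
#' @param read_length Read length in bp.
#' @param params [detection_params()].
#' @param irr_mapq_max,anchor_mapq_min MAPQ thresholds
#'   (see [classify_pair()]).
#' @param max_gap Anchor merge distance in bp.
#' @return An `str_profile` object.
#' @export
build_str_profile <- function(pairs, sample_id, depth, read_length = 150L,
                              params = detection_params(),
                              irr_mapq_max = 40L, anchor_mapq_min = 50L,
                              max_gap = 500L) {
  cl <- as.list(pairs)  # column access is much cheaper than row slices
  n <- nrow(pairs)
  # only pairs with an IRR-eligible mate can contribute
  todo <- which((!cl$mapped1 | cl$mapq1 < irr_mapq_max) |
                  (!cl$mapped2 | cl$mapq2 < irr_mapq_max))
  ev_motif <- character(0); ev_contig <- character(0)
  ev_pos <- integer(0)
  paired <- integer(0)
  for (i in todo) {
    cls <- classify_one(cl$seq1[i], cl$qual1[i], cl$mapped1[i],
                        cl$mapq1[i], cl$contig1[i], cl$pos1[i],
                        cl$seq2[i], cl$qual2[i], cl$mapped2[i],
                        cl$mapq2[i], cl$contig2[i], cl$pos2[i],
                        params, irr_mapq_max, anchor_mapq_min)
    if (cls$type == "anchored") {
      ev_motif <- c(ev_motif, cls$motif)
      ev_contig <- c(ev_contig, cls$contig)
      ev_pos <- c(ev_pos, cls$anchor_pos)
    } else if (cls$type == "paired") {
      paired[cls$motif] <- (if (cls$motif %in% names(paired))
        paired[[cls$motif]] else 0L) + 1L
    }
  }
  events <- data.frame(motif = ev_motif, contig = ev_contig,
                       anchor_pos = ev_pos, stringsAsFactors = FALSE)
  motifs <- list()
  for (m in union(unique(events$motif), names(paired))) {
    ev <- events[events$motif == m, c("contig", "anchor_pos"), drop = FALSE]
    motifs[[m]] <- list(
      anchored_regions = merge_anchor_events(ev, max_gap),
      paired_count = if (m %in% names(paired)) paired[[m]] else 0L)
  }
  new_str_profile(sample_id, depth, as.integer(read_length), params, motifs)
}

#' Merge STR profiles across samples into a cohort table
#'
#' Per motif, anchored regions from all samples are pooled and
#' re-merged with the same gap rule (regions separated by at most
#' `max_gap` join), then each sample's anchored count in each merged
#' region is tabulated, both raw and normalized to `target_depth`
#' (absent sample/region combinations count 0). Paired-IRR counts are
#' tabulated per motif and sample the same way. Profiles must share
#' detection parameters; mixing parameterizations (or aligners) across
#' samples produces spurious differences.
#'
#' @param profiles List of `str_profile` objects (>= 2).
#' @param statuses Optional named character vector (`case`/`control`)
#'   keyed by sample id; required later for the comparison stage.
#' @param max_gap Cross-sample region merge distance in bp.
#' @param target_depth Depth that counts are normalized to.
#' @return An object of class `irr_cohort`: `samples` (data.frame with
#'   `sample_id`, `status`, `depth`), `anchored` (`targets` data.frame
#'   plus regions x samples `raw` and `norm` matrices), and `paired`
#'   (`motifs` plus motifs x samples matrices).
#' @export
merge_cohort <- function(profiles, statuses = NULL, max_gap = 500L,
                         target_depth = 40) {
  if (length(profiles) < 2L)
    stop("cohort merge needs at least two profiles", call. = FALSE)
  ids <- vapply(profiles, function(p) p$sample_id, "")
  if (anyDuplicated(ids))
    stop("duplicate sample ids across profiles", call. = FALSE)
  pars <- lapply(profiles, function(p) unclass(p$params))
  if (!all(vapply(pars, identical, logical(1), y = pars[[1]])))
    stop("profiles were built with different detection parameters",
         call. = FALSE)
  depths <- vapply(profiles, function(p) p$depth, 0)
  status <- if (is.null(statuses)) rep(NA_character_, length(ids)) else {
    miss <- setdiff(ids, names(statuses))
    if (length(miss))
      stop("no status for sample(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    tolower(unname(statuses[ids]))
  }

  all_motifs <- sort(unique(unlist(lapply(profiles,
                                          function(p) names(p$motifs)))))
  tgt_rows <- list(); raw_rows <- list()
  for (m in all_motifs) {
    per_sample <- lapply(profiles, function(p) {
      r <- p$motifs[[m]]$anchored_regions
      if (is.null(r)) empty_regions() else r
    })
    pooled <- do.call(rbind, per_sample)
    if (nrow(pooled) == 0L) next
    pooled$sample <- rep(seq_along(profiles), vapply(per_sample, nrow, 0L))
    for (ctg in unique(pooled$contig)) {
      pc <- pooled[pooled$contig == ctg, , drop = FALSE]
      ir <- IRanges::IRanges(start = pc$start + 1L, end = pc$end)
      # interval gap (bases between two regions) <= max_gap merges
      red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1L)
      hit <- IRanges::findOverlaps(ir, red, select = "first")
      for (j in seq_along(red)) {
        mem <- pc[hit == j, , drop = FALSE]
        raw <- vapply(seq_along(profiles), function(s)
          sum(mem$count[mem$sample == s]), 0)
        tgt_rows[[length(tgt_rows) + 1L]] <- data.frame(
          motif = m, contig = ctg,
          start = IRanges::start(red)[j] - 1L,
          end = IRanges::end(red)[j], stringsAsFactors = FALSE)
        raw_rows[[length(raw_rows) + 1L]] <- raw
      }
    }
  }
  targets <- if (length(tgt_rows)) do.call(rbind, tgt_rows) else
    data.frame(motif = character(0), contig = character(0),
               start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  raw_anch <- if (length(raw_rows))
    do.call(rbind, raw_rows) else matrix(0, 0, length(ids))
  colnames(raw_anch) <- ids
  ord <- order(targets$motif, targets$contig, targets$start)
  targets <- targets[ord, , drop = FALSE]
  raw_anch <- raw_anch[ord, , drop = FALSE]
  rownames(targets) <- NULL
  targets$target_id <- sprintf("%s@%s:%d-%d", targets$motif,
                               targets$contig, targets$start, targets$end)
  rownames(raw_anch) <- targets$target_id
  norm_anch <- sweep(raw_anch, 2, depths, "/") * target_depth

  raw_pair <- vapply(profiles, function(p)
    vapply(all_motifs, function(m)
      as.numeric(p$motifs[[m]]$paired_count %||% 0L), 0),
    numeric(length(all_motifs)))
  raw_pair <- matrix(raw_pair, nrow = length(all_motifs),
                     dimnames = list(all_motifs, ids))
  norm_pair <- sweep(raw_pair, 2, depths, "/") * target_depth

  structure(
    list(samples = data.frame(sample_id = ids, status = status,
                              depth = depths, stringsAsFactors = FALSE),
         anchored = list(targets = targets, raw = raw_anch,
                         norm = norm_anch),
         paired = list(motifs = all_motifs, raw = raw_pair,
                       norm = norm_pair),
         max_gap = as.integer(max_gap), target_depth = target_depth,
         params = profiles[[1]]$params),
    class = "irr_cohort")
}

#' @export
print.irr_cohort <- function(x, ...) {
  ncase <- sum(x$samples$status == "case", na.rm = TRUE)
  nctrl <- sum(x$samples$status == "control", na.rm = TRUE)
  cat(sprintf("IRR cohort: %d samples (%d case / %d control / %d unlabeled)\n",
              nrow(x$samples), ncase, nctrl,
              sum(is.na(x$samples$status))))
  cat(sprintf("  %d anchored-IRR regions across %d motifs; %d motifs with paired IRRs\n",
              nrow(x$anchored$targets),
              length(unique(x$anchored$targets$motif)),
              sum(rowSums(x$paired$raw) > 0)))
  invisible(x)
}
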