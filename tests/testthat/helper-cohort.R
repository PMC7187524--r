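# Cohort-scale simulation helpers shared across test files.
#
# Each locus lives on its own contig with fixed 1-kb flanks (cached per
# contig so all samples share a coordinate system). A sample profile is
# built by simulating every locus at 20x / 2x150 bp / 450-bp fragments
# (the package's baseline design), pooling the emulated alignments and
# running the profiling stage.

.flank_cache <- new.env(parent = emptyenv())

locus_flanks <- function(contig, flank_bp = 1000L) {
  key <- paste0(contig, "#", flank_bp)
  if (is.null(.flank_cache[[key]])) {
    h <- sum(utf8ToInt(contig)) %% 10000L
    .flank_cache[[key]] <- list(
      left = random_flank(flank_bp, seed = 100000L + h),
      right = random_flank(flank_bp, seed = 200000L + h))
  }
  .flank_cache[[key]]
}

# loci: data.frame(contig, motif, copies); one emulated-alignment
# read-pair table per locus, pooled into a single profile.
sim_sample_profile <- function(sample_id, loci, seed, coverage = 20,
                               detection = detection_params()) {
  all_pairs <- lapply(seq_len(nrow(loci)), function(i) {
    fl <- locus_flanks(loci$contig[i])
    hap <- build_haplotype(
      fl$left, list(list(motif = loci$motif[i],
                         copies = loci$copies[i])), fl$right)
    p <- sim_params(coverage = coverage, seed = seed + 977L * i)
    frags <- simulate_read_pairs(hap, p)
    out <- emulate_alignment(frags, hap, contig = loci$contig[i],
                             params = p)
    out$qname <- paste0(loci$contig[i], ":", out$qname)
    out
  })
  pairs <- do.call(rbind, all_pairs)
  build_str_profile(pairs, sample_id, depth = coverage,
                    params = detection)
}

# Background loci: distinct canonical motifs, per-sample repeat length
# drawn uniformly from 100-500 bp (spanning the no-IRR to
# anchored-plateau regimes), emulating natural polymorphism at long
# STRs.
background_motifs <- function(n) {
  pool <- c("AC", "AG", "AAC", "AAT", "ACC", "AAAT", "AATG", "ACTC",
            "AAGG", "AATC", "ACG", "ATC", "ACCC", "AAAG", "AGGC")
  pool[seq_len(n)]
}

# Build the full cohort design: per-sample locus tables plus statuses.
# `expansion` = list(contig, motif, case_copies, control_copies).
sim_cohort_profiles <- function(n_case, n_ctrl, expansion,
                                n_background, seed) {
  motifs <- background_motifs(n_background)
  ids <- c(sprintf("case%02d", seq_len(n_case)),
           sprintf("ctrl%02d", seq_len(n_ctrl)))
  status <- stats::setNames(rep(c("case", "control"), c(n_case, n_ctrl)),
                            ids)
  profiles <- with_seed(seed, {
    lapply(seq_along(ids), function(s) {
      bg_bp <- stats::runif(n_background, 100, 500)
      loci <- data.frame(
        contig = c(paste0("bg", seq_len(n_background)), expansion$contig),
        motif = c(motifs, expansion$motif),
        copies = c(round(bg_bp / nchar(motifs)),
                   if (status[s] == "case") expansion$case_copies
                   else expansion$control_copies),
        stringsAsFactors = FALSE)
      sim_sample_profile(ids[s], loci, seed = seed + 131L * s)
    })
  })
  list(profiles = profiles, statuses = status)
}

# irrscan is not exported from the package namespace but with_seed is
# internal; re-expose it for helpers above.
with_seed <- irrscan:::with_seed

# Directly assemble an irr_cohort from a counts matrix (regions x
# samples) -- used for statistical tests where simulating reads would
# add nothing.
make_cohort_table <- function(anchored_counts, statuses,
                              motif = "AAG", target_depth = 40) {
  n_reg <- nrow(anchored_counts)
  ids <- colnames(anchored_counts)
  targets <- data.frame(
    motif = motif, contig = sprintf("chr%d", seq_len(n_reg)),
    start = 0L, end = 100L, stringsAsFactors = FALSE)
  targets$target_id <- sprintf("%s@%s:%d-%d", targets$motif,
                               targets$contig, targets$start,
                               targets$end)
  rownames(anchored_counts) <- targets$target_id
  structure(
    list(samples = data.frame(sample_id = ids,
                              status = unname(statuses[ids]),
                              depth = target_depth,
                              stringsAsFactors = FALSE),
         anchored = list(targets = targets, raw = anchored_counts,
                         norm = anchored_counts),
         paired = list(motifs = character(0),
                       raw = matrix(0, 0, length(ids),
                                    dimnames = list(NULL, ids)),
                       norm = matrix(0, 0, length(ids),
                                     dimnames = list(NULL, ids))),
         max_gap = 500L, target_depth = target_depth,
         params = detection_params()),
    class = "irr_cohort")
}
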