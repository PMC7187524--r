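# Paired-end repeat-expansion read simulator with emulated alignment.
# A locus is a pair of unique flanks around an expanded repeat tract
# (possibly composed of several motif segments, to model complex loci
# whose expanded composition differs from the reference). Fragments are
# drawn uniformly along the haplotype, mates are extracted from the
# fragment ends, and a deterministic rule stands in for the aligner:
# reads with enough unique flank sequence map confidently at their true
# position, reads (nearly) contained in the repeat get MAPQ 0 at the
# repeat start (or are marked unmapped). Downstream IRR detection only
# consumes MAPQ, position and flags, so this emulation exercises the
# full pipeline.

#' Simulation parameters
#'
#' Defaults follow the package's baseline design: 2 x 150 bp reads at
#' 20x coverage with 450-bp mean fragment length (sd 50 bp, truncated
#' below at the read length) and a 0.1% uniform base-error rate on a
#' Phred 30 baseline.
#'
#' @param read_length Read length in bp.
#' @param coverage Haploid coverage of the locus.
#' @param fragment_mean,fragment_sd Fragment-length distribution
#'   (Normal, truncated at `read_length`).
#' @param base_error_rate Per-base substitution error probability.
#' @param error_quality Phred score assigned to error bases (low, so
#'   weighted purity down-weights them as a real base caller would).
#' @param seed Integer seed; every simulation is deterministic given it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(read_length = 150L, coverage = 20,
                       fragment_mean = 450, fragment_sd = 50,
                       base_error_rate = 0.001, error_quality = 10L,
                       seed = 1L) {
  if (fragment_mean <= read_length)
    stop("fragment_mean must exceed read_length", call. = FALSE)
  if (coverage <= 0) stop("coverage must be positive", call. = FALSE)
  structure(
    list(read_length = as.integer(read_length), coverage = coverage,
         fragment_mean = fragment_mean, fragment_sd = fragment_sd,
         base_error_rate = base_error_rate,
         error_quality = as.integer(error_quality),
         seed = as.integer(seed)),
    class = "sim_params")
}

#' Generate a non-repetitive flank sequence
#'
#' Uniform random A/C/G/T sequence, rejection-checked so that no
#' 150-bp window is periodic (no `k <= 20` reaches `S(k) >= 0.8`),
#' i.e. the flank cannot itself spawn in-repeat reads.
#'
#' @param length Flank length in bp (>= 1000 recommended).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Character scalar.
#' @export
random_flank <- function(length, seed = NULL) {
  with_seed(seed, {
    for (attempt in 1:25) {
      s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
      if (!has_periodic_window(s)) return(s)
    }
    stop("could not generate a non-repetitive flank", call. = FALSE)
  })
}

# TRUE if any 150-bp window of s has S(k) >= t for some k in 2..20.
has_periodic_window <- function(s, window = 150L, k_max = 20L, t = 0.8) {
  v <- seq_raw(s)
  L <- length(v)
  w <- min(window, L)
  for (k in 2:min(k_max, w - 1L)) {
    eq <- as.integer(v[seq_len(L - k)] == v[seq.int(k + 1L, L)])
    m <- w - k  # comparisons per window
    if (L - k <= m) {
      if (sum(eq) / (L - k) >= t) return(TRUE)
    } else {
      cs <- cumsum(eq)
      roll <- cs[m:(L - k)] - c(0, cs[seq_len(L - k - m)])
      if (max(roll) / m >= t) return(TRUE)
    }
  }
  FALSE
}

#' Build a repeat-locus haplotype
#'
#' Concatenates the left flank, the repeat tract (an ordered list of
#' `(motif, copies)` segments, so complex non-reference compositions
#' like an AAGGG tract replacing an AAAAG reference repeat are a single
#' segment list), and the right flank.
#'
#' @param left_flank,right_flank Unique flanking sequences.
#' @param segments List of `list(motif =, copies =)` entries, or a
#'   single `c(motif = ..., copies = ...)`-style list; `copies = 0`
#'   gives an empty tract.
#' @return A list of class `repeat_haplotype`: `sequence`,
#'   `repeat_start`, `repeat_end` (0-based half-open coordinates of the
#'   tract within the haplotype) and `segments`.
#' @examples
#' hap <- build_haplotype(random_flank(1000, seed = 1),
#'                        list(list(motif = "CAG", copies = 340)),
#'                        random_flank(1000, seed = 2))
#' hap$repeat_end - hap$repeat_start  # 1020
#' @export
build_haplotype <- function(left_flank, segments, right_flank) {
  if (!is.null(segments$motif)) segments <- list(segments)
  tract <- paste(vapply(segments, function(sg) {
    motif <- toupper(sg$motif)
    if (grepl("[^ACGT]", motif) || nchar(motif) == 0L)
      stop("segment motif must be a non-empty string over A/C/G/T",
           call. = FALSE)
    if (sg$copies < 0) stop("segment copies must be >= 0", call. = FALSE)
    strrep(motif, sg$copies)
  }, ""), collapse = "")
  lf <- toupper(left_flank); rf <- toupper(right_flank)
  structure(
    list(sequence = paste0(lf, tract, rf),
         repeat_start = nchar(lf),
         repeat_end = nchar(lf) + nchar(tract),
         segments = segments),
    class = "repeat_haplotype")
}

#' Simulate paired-end reads over a haplotype
#'
#' Fragment starts are uniform over the haplotype; fragment lengths are
#' Normal(`fragment_mean`, `fragment_sd`) truncated below at the read
#' length and above at the haplotype length. The forward mate is read
#' off the fragment's left end, the reverse mate is the reverse
#' complement of its right end. Sequencing errors are uniform random
#' substitutions at `base_error_rate`; error bases are assigned
#' `error_quality`, all other bases Phred 30. The number of pairs is
#' `round(L * coverage / (2 * read_length))`. Deterministic given
#' `params$seed`.
#'
#' @param haplotype A `repeat_haplotype` (or a bare sequence string).
#' @param params [sim_params()].
#' @return A data.frame of class `sim_fragments` with one row per pair:
#'   haplotype-coordinate starts of each mate, sequences and qualities.
#'   Feed through [emulate_alignment()] to obtain mapped read pairs.
#' @export
simulate_read_pairs <- function(haplotype, params = sim_params()) {
  seqc <- if (inherits(haplotype, "repeat_haplotype"))
    haplotype$sequence else as.character(haplotype)
  L <- nchar(seqc)
  rl <- params$read_length
  if (L < params$fragment_mean + 4 * params$fragment_sd)
    stop("haplotype shorter than fragment_mean + 4*fragment_sd",
         call. = FALSE)
  with_seed(params$seed, {
    n <- round(L * params$coverage / (2 * rl))
    frag <- round(stats::rnorm(n, params$fragment_mean, params$fragment_sd))
    frag <- pmin(pmax(frag, rl), L)
    start <- floor(stats::runif(n, 0, L - frag + 1))  # 0-based
    s1 <- start
    s2 <- start + frag - rl
    fwd <- substring(seqc, s1 + 1L, s1 + rl)
    rev_template <- substring(seqc, s2 + 1L, s2 + rl)
    rev <- revcomp_many(rev_template)
    inject <- function(reads) {
      qual <- rep(phred_encode(rep(30L, rl)), length(reads))
      if (params$base_error_rate > 0 && length(reads)) {
        nerr <- stats::rbinom(1, length(reads) * rl,
                              params$base_error_rate)
        if (nerr > 0) {
          at <- sample(length(reads) * rl, nerr)
          ri <- ((at - 1L) %/% rl) + 1L
          bi <- ((at - 1L) %% rl) + 1L
          for (e in seq_len(nerr)) {
            old <- substr(reads[ri[e]], bi[e], bi[e])
            new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
            substr(reads[ri[e]], bi[e], bi[e]) <- new
            substr(qual[ri[e]], bi[e], bi[e]) <-
              phred_encode(params$error_quality)
          }
        }
      }
      list(seq = reads, qual = qual)
    }
    m1 <- inject(fwd)
    m2 <- inject(rev)
    df <- data.frame(
      qname = sprintf("frag%06d", seq_len(n)),
      start1 = as.integer(s1), seq1 = m1$seq, qual1 = m1$qual,
      start2 = as.integer(s2), seq2 = m2$seq, qual2 = m2$qual,
      stringsAsFactors = FALSE)
    class(df) <- c("sim_fragments", "data.frame")
    df
  })
}

#' Emulate alignment of simulated reads
#'
#' Deterministic stand-in for a read aligner. A read with at least
#' `min_anchor_bases` (default 30) bases outside the repeat tract is
#' "mapped" at its true position with MAPQ 60; a read (nearly)
#' contained in the tract gets MAPQ 0 at the repeat start, or is marked
#' unmapped when `unmapped_irrs = TRUE`. Positions are projected onto
#' reference coordinates in which the tract has `ref_repeat_bp` bases,
#' so samples simulated with different expansion lengths share a
#' coordinate system (as reads aligned to a common reference would).
#'
#' @param frags A `sim_fragments` data.frame from
#'   [simulate_read_pairs()].
#' @param haplotype The `repeat_haplotype` the fragments came from.
#' @param contig Contig name used in the emulated alignment.
#' @param params [sim_params()] (for the read length).
#' @param min_anchor_bases Bases of unique sequence required to map
#'   confidently.
#' @param ref_repeat_bp Length of the repeat tract in the reference
#'   coordinate system (default 0: the expansion is a pure insertion).
#' @param unmapped_irrs Mark in-repeat reads unmapped instead of MAPQ 0.
#' @return An `irr_read_pairs` data.frame.
#' @export
emulate_alignment <- function(frags, haplotype, contig = "locus",
                              params = sim_params(),
                              min_anchor_bases = 30L,
                              ref_repeat_bp = 0L, unmapped_irrs = FALSE) {
  rl <- params$read_length
  rs <- haplotype$repeat_start
  re <- haplotype$repeat_end
  shift <- (re - rs) - ref_repeat_bp
  place <- function(start) {
    n <- length(start)
    end <- start + rl
    inside <- pmax(0L, pmin(end, re) - pmax(start, rs))
    anchor <- rl - inside
    confident <- anchor >= min_anchor_bases
    # project haplotype position to reference coordinates
    pos <- ifelse(start < rs, start,
                  ifelse(start >= re, start - shift, rs))
    pos <- as.integer(pmax(pos, 0L))
    pos[!confident] <- if (unmapped_irrs) NA_integer_ else as.integer(rs)
    is_mapped <- if (unmapped_irrs) confident else rep(TRUE, n)
    ctg <- rep(contig, n)
    ctg[!is_mapped] <- NA_character_
    list(mapped = is_mapped,
         mapq = ifelse(confident, 60L, 0L),
         pos = pos, ctg = ctg)
  }
  p1 <- place(frags$start1)
  p2 <- place(frags$start2)
  read_pairs(frags$qname,
             frags$seq1, frags$qual1, p1$mapped, p1$mapq, p1$ctg, p1$pos,
             frags$seq2, frags$qual2, p2$mapped, p2$mapq, p2$ctg, p2$pos)
}

#' Write read pairs to a coordinate-sorted SAM file
#'
#' Emits a valid SAM with `@HD SO:coordinate` and one `@SQ` line per
#' contig. Mate flags and mate-position fields are filled so the file
#' round-trips through [stream_candidate_pairs()]. Mate 2 is written as
#' reverse-strand (sequence reverse-complemented back to the reference
#' strand, as an aligner would store it is *not* done -- reads are
#' stored exactly as simulated, which is what the detector consumes).
#'
#' @param pairs An `irr_read_pairs` data.frame.
#' @param contigs Named integer vector of contig lengths for the header.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pairs, contigs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                   as.integer(contigs)))
  recs <- character(0)
  if (nrow(pairs)) {
    mk <- function(qname, seqx, qualx, mapped, mapq, ctg, pos,
                   o_mapped, o_ctg, o_pos, first, reverse) {
      flag <- 1L + 64L * first + 128L * (!first)
      flag <- flag + ifelse(mapped, 0L, 4L) + ifelse(o_mapped, 0L, 8L)
      flag <- flag + ifelse(reverse & mapped, 16L, 0L) +
        ifelse(o_mapped & !reverse, 32L, 0L)
      rname <- ifelse(mapped, ctg, "*")
      p <- ifelse(mapped, pos + 1L, 0L)
      cigar <- ifelse(mapped, paste0(nchar(seqx), "M"), "*")
      rnext <- ifelse(o_mapped, ifelse(o_ctg == rname & mapped, "=", o_ctg),
                      "*")
      pnext <- ifelse(o_mapped, o_pos + 1L, 0L)
      sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
              qname, flag, rname, p, mapq, cigar, rnext, pnext,
              seqx, qualx)
    }
    recs <- c(
      mk(pairs$qname, pairs$seq1, pairs$qual1, pairs$mapped1, pairs$mapq1,
         pairs$contig1, pairs$pos1, pairs$mapped2, pairs$contig2,
         pairs$pos2, first = TRUE, reverse = FALSE),
      mk(pairs$qname, pairs$seq2, pairs$qual2, pairs$mapped2, pairs$mapq2,
         pairs$contig2, pairs$pos2, pairs$mapped1, pairs$contig1,
         pairs$pos1, first = FALSE, reverse = TRUE))
    ctg <- c(pairs$contig1, pairs$contig2)
    pos <- c(pairs$pos1, pairs$pos2)
    mapped <- c(pairs$mapped1, pairs$mapped2)
    ord <- order(!mapped, match(ctg, names(contigs)), pos)
    recs <- recs[ord]
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write read pairs as a FASTQ pair for external alignment
#'
#' Escape hatch for users who prefer a real aligner over the emulated
#' alignment: exports mates to `<prefix>_1.fastq` / `<prefix>_2.fastq`.
#'
#' @param pairs An `irr_read_pairs` or `sim_fragments` data.frame.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq <- function(pairs, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    sq <- pairs[[paste0("seq", m)]]
    ql <- pairs[[paste0("qual", m)]]
    writeLines(as.vector(rbind(paste0("@", pairs$qname, "/", m),
                               sq, "+", ql)), paths[m])
  }
  invisible(paths)
}

#' Anchored/paired IRR counts across a sweep of repeat lengths
#'
#' For each copy number: build the haplotype, simulate reads, emulate
#' alignment, build an STR profile, and record the anchored and paired
#' IRR counts attributed to the motif's canonical form at the locus.
#' Reproduces the characteristic three-regime behavior: no IRRs while
#' the repeat is shorter than the read length, anchored IRRs growing
#' with repeat length up to the fragment length, then an anchored
#' plateau with paired IRRs growing beyond it.
#'
#' @param motif Repeat unit to expand.
#' @param copies Integer vector of copy numbers.
#' @param params [sim_params()]; each copy number uses a seed offset
#'   from `params$seed`.
#' @param flank_bp Flank length on each side.
#' @param detection [detection_params()].
#' @return data.frame with columns `copies`, `repeat_bp`,
#'   `anchored_count`, `paired_count`.
#' @export
length_sweep_experiment <- function(motif, copies, params = sim_params(),
                                    flank_bp = 1000L,
                                    detection = detection_params()) {
  canon <- canonical_motif(motif)
  lf <- random_flank(flank_bp, seed = params$seed)
  rf <- random_flank(flank_bp, seed = params$seed + 1L)
  res <- lapply(seq_along(copies), function(i) {
    hap <- build_haplotype(lf, list(list(motif = motif,
                                         copies = copies[i])), rf)
    p <- params
    p$seed <- params$seed + 1000L * i
    frags <- simulate_read_pairs(hap, p)
    pairs <- emulate_alignment(frags, hap, params = p)
    prof <- build_str_profile(pairs, sample_id = "sweep", depth = p$coverage,
                              read_length = p$read_length,
                              params = detection)
    entry <- prof$motifs[[canon]]
    data.frame(copies = copies[i],
               repeat_bp = copies[i] * nchar(motif),
               anchored_count = if (is.null(entry)) 0L else
                 sum(entry$anchored_regions$count),
               paired_count = if (is.null(entry)) 0L else
                 entry$paired_count)
  })
  do.call(rbind, res)
}
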