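# In-repeat read (IRR) detection: decide whether a single read lies
# entirely inside a short tandem repeat and, if so, for which canonical
# motif. A read qualifies when it is periodic with some period k
# (periodicity score S(k) >= t) and matches the tandem concatenation of
# its consensus repeat unit closely enough (weighted purity >= 0.9).

#' Detection parameters for in-repeat read calling
#'
#' Bundles the tunable thresholds of IRR detection. Defaults are the
#' values used throughout the package: repeat units of 2--20 bp
#' (homopolymers excluded), periodicity threshold `t = 0.8`, weighted
#' purity threshold 0.9, and Phred 20 as the low-quality cutoff.
#'
#' @param k_min Smallest repeat-unit length searched (>= 2 by default;
#'   set to 1 only for homopolymer exploration).
#' @param k_max Largest repeat-unit length searched.
#' @param t Periodicity threshold: the smallest `k` with `S(k) >= t` is
#'   taken as the read's period.
#' @param wp_threshold Minimum weighted-purity score for an IRR call.
#' @param low_quality_cutoff Phred score below which a base is treated
#'   as low quality in the weighted-purity score.
#' @return A list of class `irr_detection_params`.
#' @examples
#' detection_params()
#' detection_params(k_max = 6)
#' @export
detection_params <- function(k_min = 2L, k_max = 20L, t = 0.8,
                             wp_threshold = 0.9, low_quality_cutoff = 20L) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 1L) stop("k_min must be >= 1", call. = FALSE)
  if (k_min > k_max) stop("k_min must be <= k_max", call. = FALSE)
  if (!(t > 0 && t <= 1)) stop("t must be in (0, 1]", call. = FALSE)
  if (!(wp_threshold > 0 && wp_threshold <= 1))
    stop("wp_threshold must be in (0, 1]", call. = FALSE)
  structure(
    list(k_min = k_min, k_max = k_max, t = t,
         wp_threshold = wp_threshold,
         low_quality_cutoff = as.integer(low_quality_cutoff)),
    class = "irr_detection_params")
}

#' @export
print.irr_detection_params <- function(x, ...) {
  cat("IRR detection parameters\n")
  cat(sprintf("  repeat unit length: %d-%d bp\n", x$k_min, x$k_max))
  cat(sprintf("  periodicity threshold t: %g\n", x$t))
  cat(sprintf("  weighted purity threshold: %g\n", x$wp_threshold))
  cat(sprintf("  low-quality cutoff: Phred %d\n", x$low_quality_cutoff))
  invisible(x)
}

#' Periodicity score S(k) of a read
#'
#' Fraction of positions `i` (0-based, `0 <= i <= L - k - 1`) at which
#' base `i` equals base `i + k`:
#' `S(k) = sum I_k(i) / (L - k)`.
#' Comparison is case-insensitive; `N` matches nothing, including
#' another `N`. A perfect tandem stretch of a k-bp unit has `S(k) = 1`.
#'
#' @param sequence Read sequence (character scalar).
#' @param k Candidate period in bases; must satisfy `1 <= k < nchar(sequence)`.
#' @return The score in `[0, 1]`.
#' @examples
#' periodicity_score(strrep("CAG", 4), 3)    # 1
#' periodicity_score("AAAAAAAATTTTTTTT", 2)  # 12/14
#' @export
periodicity_score <- function(sequence, k) {
  v <- seq_raw(sequence)
  L <- length(v)
  k <- as.integer(k)
  if (k < 1L || k >= L)
    stop("k must satisfy 1 <= k < read length", call. = FALSE)
  a <- v[seq_len(L - k)]
  b <- v[seq.int(k + 1L, L)]
  ok <- (a == b) & (a != RAW_N) & (b != RAW_N)
  sum(ok) / (L - k)
}

# All S(k) for k in [k_min, k_max] at once; internal fast path.
periodicity_profile <- function(v, k_min, k_max) {
  L <- length(v)
  ks <- seq.int(k_min, min(k_max, L - 1L))
  notN <- v != RAW_N
  vapply(ks, function(k) {
    idx <- seq_len(L - k)
    sum((v[idx] == v[idx + k]) & notN[idx] & notN[idx + k]) / (L - k)
  }, numeric(1))
}

#' Smallest qualifying repeat period of a read
#'
#' Scans `k = k_min, ..., min(k_max, L - 1)` in increasing order and
#' returns the first `k` with `S(k) >= t`, or `NULL` when no period
#' qualifies (including reads too short to test).
#'
#' @param sequence Read sequence.
#' @param params A [detection_params()] object.
#' @return Integer period or `NULL`.
#' @examples
#' find_smallest_period(strrep("CA", 6))   # 2
#' find_smallest_period("ACGTACGGTCCA")    # NULL
#' @export
find_smallest_period <- function(sequence, params = detection_params()) {
  v <- seq_raw(sequence)
  L <- length(v)
  if (L <= params$k_min) return(NULL)
  notN <- v != RAW_N
  for (k in seq.int(params$k_min, min(params$k_max, L - 1L))) {
    idx <- seq_len(L - k)
    s <- sum((v[idx] == v[idx + k]) & notN[idx] & notN[idx + k]) / (L - k)
    if (s >= params$t) return(k)
  }
  NULL
}

#' Consensus repeat unit at a given period
#'
#' The k-mer whose base at offset `j` is the most frequent base among
#' read positions `p` with `p mod k == j`. `N` bases are excluded from
#' the frequency counts; ties are broken in `A < C < G < T` order (an
#' offset seeing only `N` yields `A`).
#'
#' @param sequence Read sequence.
#' @param k Period; `1 <= k < nchar(sequence)`.
#' @return A k-bp character scalar.
#' @examples
#' consensus_motif("CAGCAGCATCAG", 3)  # "CAG"
#' @export
consensus_motif <- function(sequence, k) {
  v <- seq_raw(sequence)
  L <- length(v)
  k <- as.integer(k)
  if (k < 1L || k >= L)
    stop("k must satisfy 1 <= k < read length", call. = FALSE)
  offs <- (seq_len(L) - 1L) %% k
  bases <- c(RAW_A, RAW_C, RAW_G, RAW_T)
  unit <- vapply(seq_len(k) - 1L, function(j) {
    col <- v[offs == j]
    counts <- vapply(bases, function(b) sum(col == b), integer(1))
    c("A", "C", "G", "T")[which.max(counts)]
  }, character(1))
  paste(unit, collapse = "")
}

#' Canonical form of a repeat motif
#'
#' The lexicographically smallest string (A < C < G < T) among all
#' circular rotations of the motif and of its reverse complement. The
#' canonical form removes the strand and phase ambiguity inherent in a
#' repeat unit extracted from a read.
#'
#' @param motif Non-empty character scalar over A/C/G/T.
#' @return Character scalar; idempotent
#'   (`canonical_motif(canonical_motif(m)) == canonical_motif(m)`).
#' @examples
#' canonical_motif("TTC")  # "AAG"
#' canonical_motif("CCG")  # "CCG"
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  if (nchar(motif) == 0L || grepl("[^ACGT]", motif))
    stop("motif must be a non-empty string over A/C/G/T", call. = FALSE)
  k <- nchar(motif)
  rc <- revcomp(motif)
  dbl <- c(paste0(motif, motif), paste0(rc, rc))
  starts <- seq_len(k)
  min(c(substring(dbl[1], starts, starts + k - 1L),
        substring(dbl[2], starts, starts + k - 1L)))
}

#' Quality-weighted purity of a read against a repeat unit
#'
#' Compares each read base to the tandem concatenation of `motif`
#' (offset by `phase`) and scores: high-quality match +1, high-quality
#' mismatch -1, low-quality base +0.5 whether it matches or not
#' (Phred < `low_quality_cutoff` is low quality). The per-read sum is
#' clamped below at 0 and divided by the read length. When
#' `phase = NULL` (the default) the score is maximized over all
#' `nchar(motif)` phases, which is the WP score used for IRR calling.
#' Down-weighting low-quality mismatches tolerates the elevated
#' base-call error rate typical of long repetitive tracts.
#'
#' @param sequence Read sequence.
#' @param qualities Phred scores: integer vector (recycled if length 1)
#'   or a Phred+33 string.
#' @param motif Repeat unit to compare against.
#' @param phase Fixed phase in `0 .. nchar(motif) - 1`, or `NULL` to
#'   maximize over phases.
#' @param params A [detection_params()] object (supplies the
#'   low-quality cutoff).
#' @return Score in `[0, 1]`.
#' @examples
#' weighted_purity(strrep("CAG", 50), 30L, "CAG")  # 1
#' @export
weighted_purity <- function(sequence, qualities, motif, phase = NULL,
                            params = detection_params()) {
  v <- seq_raw(sequence)
  L <- length(v)
  q <- as_phred(qualities, L)
  m <- seq_raw(motif)
  k <- length(m)
  if (k < 1L) stop("motif must be non-empty", call. = FALSE)
  lowq <- q < params$low_quality_cutoff
  phases <- if (is.null(phase)) seq_len(k) - 1L else as.integer(phase)
  if (any(phases < 0L | phases >= k))
    stop("phase must be in 0 .. nchar(motif) - 1", call. = FALSE)
  best <- 0
  idx0 <- seq_len(L) - 1L
  for (ph in phases) {
    expct <- m[((ph + idx0) %% k) + 1L]
    match <- v == expct  # N never equals A/C/G/T in the motif
    w <- ifelse(lowq, 0.5, ifelse(match, 1, -1))
    score <- max(sum(w), 0) / L
    if (score > best) best <- score
  }
  best
}

#' Call a read as an in-repeat read
#'
#' Full single-read IRR decision: find the smallest period `k` with
#' `S(k) >= t`, extract the consensus unit at that period, reduce it to
#' its canonical form, and accept the read iff its weighted purity
#' against the consensus unit reaches `wp_threshold`.
#'
#' @param sequence Read sequence.
#' @param qualities Phred scores (integer vector, length-1 integer, or
#'   Phred+33 string).
#' @param params A [detection_params()] object.
#' @return A list of class `motif_call` with elements `canonical_motif`,
#'   `period_k`, `periodicity_score`, `wp_score`, or `NULL` when the
#'   read is not an IRR.
#' @examples
#' call_irr(strrep("GAA", 50), 30L)  # canonical motif "AAG"
#' call_irr(paste(sample(c("A","C","G","T"), 150, TRUE), collapse = ""), 30L)
#' @export
call_irr <- function(sequence, qualities, params = detection_params()) {
  k <- find_smallest_period(sequence, params)
  if (is.null(k)) return(NULL)
  s <- periodicity_score(sequence, k)
  unit <- consensus_motif(sequence, k)
  wp <- weighted_purity(sequence, qualities, unit, phase = NULL, params)
  if (wp < params$wp_threshold) return(NULL)
  structure(
    list(canonical_motif = canonical_motif(unit), period_k = k,
         periodicity_score = s, wp_score = wp),
    class = "motif_call")
}

#' @export
print.motif_call <- function(x, ...) {
  cat(sprintf("IRR call: motif %s (k = %d), S(k) = %.3f, WP = %.3f\n",
              x$canonical_motif, x$period_k, x$periodicity_score,
              x$wp_score))
  invisible(x)
}
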