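# Alignment, manifest and profile I/O: stream candidate read pairs out
# of SAM/BAM/CRAM, and serialize STR profiles and cohort manifests.

#' Construct a read-pair table
#'
#' The in-memory representation of paired reads used throughout the
#' package: one row per fragment, both mates side by side. Positions
#' are 0-based leftmost aligned positions; unmapped mates carry
#' `mapped = FALSE`, MAPQ 0 and `NA` contig/position.
#'
#' @param qname Fragment (query) names.
#' @param seq1,seq2 Mate sequences (read 1 / read 2).
#' @param qual1,qual2 Phred+33 quality strings.
#' @param mapped1,mapped2 Logical mapping state.
#' @param mapq1,mapq2 Integer mapping qualities.
#' @param contig1,contig2 Contig names (`NA` when unmapped).
#' @param pos1,pos2 0-based leftmost positions (`NA` when unmapped).
#' @return A data.frame of class `irr_read_pairs`.
#' @export
read_pairs <- function(qname, seq1, qual1, mapped1, mapq1, contig1, pos1,
                       seq2, qual2, mapped2, mapq2, contig2, pos2) {
  df <- data.frame(
    qname = as.character(qname),
    seq1 = as.character(seq1), qual1 = as.character(qual1),
    mapped1 = as.logical(mapped1), mapq1 = as.integer(mapq1),
    contig1 = as.character(contig1), pos1 = as.integer(pos1),
    seq2 = as.character(seq2), qual2 = as.character(qual2),
    mapped2 = as.logical(mapped2), mapq2 = as.integer(mapq2),
    contig2 = as.character(contig2), pos2 = as.integer(pos2),
    stringsAsFactors = FALSE)
  df$mapq1[!df$mapped1] <- 0L
  df$mapq2[!df$mapped2] <- 0L
  class(df) <- c("irr_read_pairs", "data.frame")
  df
}

empty_read_pairs <- function() {
  read_pairs(character(0), character(0), character(0), logical(0),
             integer(0), character(0), integer(0), character(0),
             character(0), logical(0), integer(0), character(0),
             integer(0))
}

# Open an alignment file as a BamFile; plain-text SAM is converted to a
# temporary BAM first (CRAM needs `reference`).
open_alignment <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    bam <- tempfile(fileext = ".bam")
    Rsamtools::asBam(path, sub("\\.bam$", "", bam), overwrite = TRUE,
                     indexDestination = FALSE)
    path <- bam
  }
  if (ext == "cram" && is.null(reference))
    stop("CRAM input requires a reference FASTA", call. = FALSE)
  Rsamtools::BamFile(path)
}

scan_primary_reads <- function(path, reference = NULL, keep_dups = FALSE) {
  bf <- open_alignment(path, reference)
  flag <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (keep_dups) NA else FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "pos", "mapq", "seq", "qual"))
  res <- Rsamtools::scanBam(bf, param = param)[[1]]
  n <- length(res$qname)
  data.frame(
    qname = res$qname,
    first = bitwAnd(res$flag, 64L) > 0L,
    mapped = bitwAnd(res$flag, 4L) == 0L,
    mapq = ifelse(is.na(res$mapq), 0L, res$mapq),
    contig = as.character(res$rname),
    pos = ifelse(is.na(res$pos), NA_integer_, res$pos - 1L),
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
}

#' Stream candidate read pairs from an alignment file
#'
#' Reads primary, non-supplementary (and by default non-duplicate)
#' records from a SAM/BAM/CRAM file, pairs mates by query name, and
#' keeps every pair in which at least one mate is unmapped or has
#' MAPQ below `irr_mapq_max` -- the only pairs that can contain an
#' in-repeat read. Confidently mapped pairs are dropped immediately, so
#' downstream work scales with the repetitive fraction of the genome,
#' not its size.
#'
#' @param path SAM/BAM/CRAM file, coordinate-sorted.
#' @param reference Reference FASTA (required for CRAM).
#' @param irr_mapq_max A read is IRR-eligible when unmapped or
#'   `MAPQ < irr_mapq_max` (default 40).
#' @param keep_dups Keep duplicate-marked reads (default drops them).
#' @return An `irr_read_pairs` data.frame (see [read_pairs()]);
#'   mate 1 of each pair is the first-in-pair read.
#' @export
stream_candidate_pairs <- function(path, reference = NULL,
                                   irr_mapq_max = 40L, keep_dups = FALSE) {
  reads <- scan_primary_reads(path, reference, keep_dups)
  if (nrow(reads) == 0L) return(empty_read_pairs())
  r1 <- reads[reads$first, , drop = FALSE]
  r2 <- reads[!reads$first, , drop = FALSE]
  common <- intersect(r1$qname, r2$qname)
  r1 <- r1[match(common, r1$qname), , drop = FALSE]
  r2 <- r2[match(common, r2$qname), , drop = FALSE]
  cand <- (!r1$mapped | r1$mapq < irr_mapq_max) |
          (!r2$mapped | r2$mapq < irr_mapq_max)
  r1 <- r1[cand, , drop = FALSE]
  r2 <- r2[cand, , drop = FALSE]
  read_pairs(r1$qname,
             r1$seq, r1$qual, r1$mapped, r1$mapq, r1$contig, r1$pos,
             r2$seq, r2$qual, r2$mapped, r2$mapq, r2$contig, r2$pos)
}

#' Read a cohort manifest
#'
#' A manifest is a headerless three-column TSV: sample id, status
#' (`case` or `control`, case-insensitive), and the path to the
#' sample's STR profile JSON. Paths are resolved relative to the
#' manifest's directory.
#'
#' @param path Manifest TSV.
#' @param check_paths Validate that every profile file exists.
#' @return A data.frame of class `irr_manifest` with columns
#'   `sample_id`, `status`, `path`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("sample_id", "status", "path"),
                          colClasses = "character")
  df$status <- tolower(df$status)
  bad <- which(!df$status %in% c("case", "control"))
  if (length(bad))
    stop(sprintf("manifest row %d: unknown status '%s' (expected case/control)",
                 bad[1], df$status[bad[1]]), call. = FALSE)
  dup <- which(duplicated(df$sample_id))
  if (length(dup))
    stop(sprintf("manifest row %d: duplicate sample id '%s'",
                 dup[1], df$sample_id[dup[1]]), call. = FALSE)
  rel <- !grepl("^/", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  if (check_paths) {
    miss <- which(!file.exists(df$path))
    if (length(miss))
      stop(sprintf("manifest row %d: profile file not found: %s",
                   miss[1], df$path[miss[1]]), call. = FALSE)
  }
  class(df) <- c("irr_manifest", "data.frame")
  df
}

#' Write / read an STR profile as JSON
#'
#' Profiles are serialized with a fixed schema:
#' `{"meta": {"sample_id", "depth", "read_length", "params"},
#'   "motifs": {"<canonical motif>": {"anchored_regions":
#'   [{"contig", "start", "end", "count"}, ...], "paired_count"}}}`.
#' Coordinates are 0-based half-open; counts are raw integers (depth
#' normalization happens at cohort merge). `read_str_profile()`
#' validates the schema and rejects negative counts, so
#' `read_str_profile(write_str_profile(p)) == p`.
#'
#' @param profile An `str_profile` object (see [build_str_profile()]).
#' @param path Output / input JSON file.
#' @return `write_str_profile()` returns `path` invisibly;
#'   `read_str_profile()` returns the `str_profile`.
#' @export
write_str_profile <- function(profile, path) {
  stopifnot(inherits(profile, "str_profile"))
  motifs <- lapply(profile$motifs, function(m) {
    regs <- m$anchored_regions
    list(
      anchored_regions = lapply(seq_len(nrow(regs)), function(i) {
        list(contig = regs$contig[i], start = regs$start[i],
             end = regs$end[i], count = regs$count[i])
      }),
      paired_count = m$paired_count)
  })
  obj <- list(
    meta = list(sample_id = profile$sample_id,
                depth = profile$depth,
                read_length = profile$read_length,
                params = unclass(profile$params)),
    motifs = motifs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_str_profile
#' @export
read_str_profile <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$meta) || is.null(obj$meta$sample_id))
    stop("profile JSON missing /meta/sample_id", call. = FALSE)
  for (field in c("depth", "read_length"))
    if (is.null(obj$meta[[field]]))
      stop("profile JSON missing /meta/", field, call. = FALSE)
  motifs <- lapply(obj$motifs %||% list(), function(m) {
    regs <- m$anchored_regions %||% list()
    df <- if (length(regs)) {
      data.frame(
        contig = vapply(regs, function(r) as.character(r$contig), ""),
        start = vapply(regs, function(r) as.integer(r$start), 0L),
        end = vapply(regs, function(r) as.integer(r$end), 0L),
        count = vapply(regs, function(r) as.integer(r$count), 0L),
        stringsAsFactors = FALSE)
    } else empty_regions()
    if (any(df$count < 0) || (m$paired_count %||% 0L) < 0)
      stop("profile JSON /motifs: negative count", call. = FALSE)
    if (any(df$end < df$start))
      stop("profile JSON /motifs: region end < start", call. = FALSE)
    list(anchored_regions = df,
         paired_count = as.integer(m$paired_count %||% 0L))
  })
  p <- obj$meta$params
  params <- if (is.null(p)) detection_params() else
    detection_params(p$k_min %||% 2L, p$k_max %||% 20L, p$t %||% 0.8,
                     p$wp_threshold %||% 0.9,
                     p$low_quality_cutoff %||% 20L)
  new_str_profile(sample_id = obj$meta$sample_id,
                  depth = as.numeric(obj$meta$depth),
                  read_length = as.integer(obj$meta$read_length),
                  params = params, motifs = motifs)
}

# Parse a BED file into GRanges (0-based half-open on disk, 1-based
# closed in GRanges, as usual).
read_bed_regions <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop("malformed BED file '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  gr
}
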