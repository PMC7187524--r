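# Serialization of merged cohort tables. The JSON mirrors the
# irr_cohort structure: sample metadata, anchored targets with raw and
# depth-normalized count matrices, and per-motif paired counts.

#' Write / read a merged cohort table as JSON
#'
#' Round-trip serialization of an `irr_cohort`
#' (`read_cohort_json(write_cohort_json(x))` reproduces `x` up to an
#' optional provenance block).
#'
#' @param cohort An `irr_cohort` from [merge_cohort()].
#' @param path JSON file path.
#' @param provenance Optional named list recorded under `/provenance`.
#' @return `write_cohort_json()` returns `path` invisibly;
#'   `read_cohort_json()` the `irr_cohort`.
#' @export
write_cohort_json <- function(cohort, path, provenance = NULL) {
  tg <- cohort$anchored$targets
  obj <- list(
    samples = cohort$samples,
    anchored = list(
      targets = tg,
      raw = unname(as.matrix(cohort$anchored$raw)),
      norm = unname(as.matrix(cohort$anchored$norm))),
    paired = list(
      motifs = cohort$paired$motifs,
      raw = unname(as.matrix(cohort$paired$raw)),
      norm = unname(as.matrix(cohort$paired$norm))),
    max_gap = cohort$max_gap,
    target_depth = cohort$target_depth,
    params = unclass(cohort$params))
  if (!is.null(provenance)) obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor",
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_cohort_json
#' @export
read_cohort_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  samples <- as.data.frame(obj$samples, stringsAsFactors = FALSE)
  if (is.null(samples$status)) samples$status <- NA_character_
  tg <- as.data.frame(obj$anchored$targets, stringsAsFactors = FALSE)
  if (!nrow(tg))
    tg <- data.frame(motif = character(0), contig = character(0),
                     start = integer(0), end = integer(0),
                     target_id = character(0), stringsAsFactors = FALSE)
  shape <- function(m, rn) {
    m <- as.matrix(m)
    if (!length(m)) m <- matrix(0, length(rn), nrow(samples))
    if (nrow(m) != length(rn)) m <- matrix(as.numeric(m),
                                           nrow = length(rn))
    dimnames(m) <- list(rn, samples$sample_id)
    m
  }
  p <- obj$params
  params <- detection_params(p$k_min, p$k_max, p$t, p$wp_threshold,
                             p$low_quality_cutoff)
  structure(
    list(samples = samples,
         anchored = list(targets = tg,
                         raw = shape(obj$anchored$raw, tg$target_id),
                         norm = shape(obj$anchored$norm, tg$target_id)),
         paired = list(motifs = as.character(obj$paired$motifs %||%
                                               character(0)),
                       raw = shape(obj$paired$raw,
                                   as.character(obj$paired$motifs %||%
                                                  character(0))),
                       norm = shape(obj$paired$norm,
                                    as.character(obj$paired$motifs %||%
                                                   character(0)))),
         max_gap = as.integer(obj$max_gap),
         target_depth = as.numeric(obj$target_depth),
         params = params),
    class = "irr_cohort")
}
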