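# Internal helpers shared across modules.

RAW_A <- charToRaw("A")
RAW_C <- charToRaw("C")
RAW_G <- charToRaw("G")
RAW_T <- charToRaw("T")
RAW_N <- charToRaw("N")

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the A/C/G/T alphabet
#' (case-insensitive input, uppercase output).
#'
#' @param x Character scalar over A/C/G/T.
#' @return Character scalar.
#' @keywords internal
revcomp <- function(x) {
  r <- rev(charToRaw(chartr("acgtACGT", "TGCATGCA", x)))
  rawToChar(r)
}

# Vectorised reverse complement for equal-length read sets.
revcomp_many <- function(x) {
  if (length(x) == 0L) return(character(0))
  comp <- chartr("acgtACGT", "TGCATGCA", x)
  vapply(comp, function(s) rawToChar(rev(charToRaw(s))), character(1),
         USE.NAMES = FALSE)
}

# Decode a SAM-style Phred+33 quality string to integer scores.
phred_decode <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}

phred_encode <- function(q) {
  rawToChar(as.raw(as.integer(q) + 33L))
}

# Uppercase a read sequence as a raw vector (soft-masked lowercase is
# treated as its uppercase base).
seq_raw <- function(sequence) {
  charToRaw(toupper(sequence))
}

# Accept either an integer vector of Phred scores or a Phred+33 string.
as_phred <- function(qualities, L) {
  if (is.character(qualities)) qualities <- phred_decode(qualities)
  qualities <- as.integer(qualities)
  if (length(qualities) == 1L && L > 1L) qualities <- rep(qualities, L)
  if (length(qualities) != L)
    stop("qualities must have one value per base", call. = FALSE)
  if (any(qualities < 0L))
    stop("Phred qualities must be non-negative", call. = FALSE)
  qualities
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
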