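# Internal helpers shared across modules. Sequences are uppercase character
# strings over A/C/G/T/N; positions are 1-based inside R, 0-based in files.

DNA_BASES <- c("A", "C", "G", "T")

#' @keywords internal
seq_chars <- function(x) {
  strsplit(toupper(x), "", fixed = TRUE)[[1]]
}

#' @keywords internal
chars_seq <- function(x) {
  paste(x, collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stopf("%s must be a single character string", what)
  }
  if (grepl("[^ACGTNacgtn]", x)) {
    stopf("%s contains characters outside A/C/G/T/N", what)
  }
  invisible(TRUE)
}

#' Hamming distance between two equal-length sequences
#'
#' Number of mismatching positions between two nucleotide (or amino-acid)
#' strings of identical length, optionally restricted to a subset of
#' positions.
#'
#' @param a,b Character strings of equal length.
#' @param positions Optional integer vector of 1-based positions over which
#'   to count mismatches; defaults to all positions.
#' @return Integer mismatch count.
#' @examples
#' hamming("ACGT", "ACGA")
#' @export
hamming <- function(a, b, positions = NULL) {
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  if (length(ca) != length(cb)) {
    stopf("hamming: sequences differ in length (%d vs %d)", length(ca), length(cb))
  }
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) && (min(positions) < 1L || max(positions) > length(ca))) {
      stopf("hamming: positions out of bounds")
    }
    if (!length(positions)) return(0L)
    sum(ca[positions] != cb[positions])
  } else {
    sum(ca != cb)
  }
}

# mask (de)serialisation: integer vector (1-based) <-> "0,4,17" (0-based)
mask_to_string <- function(mask) {
  if (is.null(mask) || !length(mask)) return("")
  paste(sort(as.integer(mask)) - 1L, collapse = ",")
}

mask_from_string <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ",", fixed = TRUE)[[1]]) + 1L
}

# translate an in-frame nucleotide vector; '*' for stops, 'X' for ambiguous
translate_chars <- function(nt) {
  if (length(nt) %% 3L != 0L) {
    nt <- nt[seq_len(3L * (length(nt) %/% 3L))]
  }
  if (!length(nt)) return(character(0))
  seqinr::translate(tolower(nt), ambiguous = FALSE)
}

translate_seq <- function(x) {
  chars_seq(translate_chars(seq_chars(x)))
}

# run a block with its own RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# strip the allele suffix: "IGHV3-23*01" -> "IGHV3-23"
strip_allele <- function(x) sub("\\*.*$", "", x)

# gene family: "IGHV3-23" -> "IGHV3"
gene_family <- function(x) sub("-.*$", "", strip_allele(x))
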