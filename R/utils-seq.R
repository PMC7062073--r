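## Low-level nucleotide-string helpers shared across modules.
## Sequences are plain upper-case character scalars; anything outside
## ACGT is carried along and treated as "other" by the skew machinery.

#' Reverse complement of a nucleotide string
#'
#' Complements A/C/G/T (case preserved, IUPAC ambiguity codes for the
#' common cases) and reverses the string.  Characters without a defined
#' complement are passed through unchanged.
#'
#' @param seq Character scalar.
#' @return Character scalar, the reverse complement.
#' @export
#' @examples
#' revcomp("AACG")  # "CGTT"
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(seq)
  comp <- chartr("ACGTUacgtuRYKMrykmBDHVbdhv",
                 "TGCAAtgcaaYRMKyrmkVHDBvhdb", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

## split a sequence into a character vector of single bases
seq_chars <- function(seq) {
  if (nchar(seq) == 0L) return(character(0))
  strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
}

## circular 1-based slice: start..end on a genome of length n,
## wrapping through the origin when start > end
circular_slice <- function(seq, start, end) {
  n <- nchar(seq)
  if (start < 1L || end < 1L || start > n || end > n)
    stop("coordinates (", start, "..", end, ") exceed sequence length ", n)
  if (start <= end) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, n), substr(seq, 1L, end))
  }
}

## deterministic RNG scope: evaluate expr under a local seed without
## disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
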