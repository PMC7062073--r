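## Scan non-coding regions for residual tRNA anticodon hairpins.
##
## Incomplete tRNA sets are common in isopod mitogenomes; degenerate
## central segments of "missing" tRNAs (an anticodon arm that no longer
## folds into a full cloverleaf) can persist in the spacers where the
## genes sit in related species.  The detector here is the minimal
## canonical anticodon-arm model: a 7-nt loop with the anticodon at
## loop positions 3-5, closed by a contiguous stem of Watson-Crick or
## GU-wobble pairs.  The score is simply the stem length, which keeps
## every hit exactly explainable.

#' Default anticodon table
#'
#' The 22 standard metazoan mitochondrial tRNA anticodons (DNA
#' alphabet), named by canonical tRNA label.
#'
#' @return Named character vector.
#' @export
mt_trna_anticodons <- function() .mt_trna_anticodons

## Watson-Crick + GU wobble pairing on the DNA alphabet
.pairs_with <- function(x, y) {
  (x == "A" & y == "T") | (x == "T" & y == "A") |
  (x == "G" & y == "C") | (x == "C" & y == "G") |
  (x == "G" & y == "T") | (x == "T" & y == "G")
}

#' Candidate windows for the tRNA-fragment scan
#'
#' Each non-coding region longer than `min_ncr` bp (including the
#' control region), expanded by `flank` bp into the neighbouring genes
#' on both sides — degenerate tRNA fragments frequently overlap their
#' neighbours.  Windows wrap through the origin on circular genomes
#' and are clipped at the bounds of linear ones.
#'
#' @param g A [mito_annotation()] with sequence.
#' @param min_ncr Minimum NCR length (bp, exclusive) for a window.
#' @param flank Extension into each neighbouring gene (bp).
#' @return data.frame with columns `region`, `ncr_start`, `ncr_end`,
#'   `start`, `end`, `kind`, `sequence` (plus-strand orientation).
#' @export
candidate_windows <- function(g, min_ncr = 10L, flank = 20L) {
  if (is.null(g$sequence)) stop("annotation has no sequence")
  cat <- ncr_catalog(g)
  cat <- cat[cat$length > min_ncr, , drop = FALSE]
  n <- g$length
  out <- lapply(seq_len(nrow(cat)), function(i) {
    start <- cat$start[i] - flank
    end <- cat$end[i] + flank
    if (g$circular) {
      if (start < 1L) start <- start + n
      if (end > n) end <- end - n
    } else {
      start <- max(start, 1L)
      end <- min(end, n)
    }
    data.frame(
      region = paste0(cat$upstream[i], "/", cat$downstream[i]),
      ncr_start = cat$start[i], ncr_end = cat$end[i],
      start = start, end = end, kind = cat$kind[i],
      sequence = circular_slice(g$sequence, start, end),
      stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(region = character(0), ncr_start = integer(0),
                      ncr_end = integer(0), start = integer(0),
                      end = integer(0), kind = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## scan one strand; returns offsets in the supplied orientation
.scan_one_strand <- function(ch, anticodons, min_stem) {
  n <- length(ch)
  hits <- list()
  if (n < 7L + 2L * min_stem) return(hits)
  ## loop occupies i..i+6, anticodon at i+2..i+4
  for (i in seq_len(n - 6L)) {
    ac <- paste(ch[(i + 2L):(i + 4L)], collapse = "")
    match_idx <- which(anticodons == ac)
    if (!length(match_idx)) next
    ## count contiguous stem pairs closing the loop
    stem <- 0L
    repeat {
      left <- i - 1L - stem
      right <- i + 7L + stem
      if (left < 1L || right > n) break
      if (!.pairs_with(ch[left], ch[right])) break
      stem <- stem + 1L
    }
    if (stem >= min_stem)
      hits[[length(hits) + 1L]] <- data.frame(
        offset = i + 2L, anticodon = ac,
        trna = names(anticodons)[match_idx[1L]],
        stem_len = stem, score = stem, stringsAsFactors = FALSE)
  }
  hits
}

#' Scan a sequence for anticodon hairpins
#'
#' A hit at a position means a 7-nt loop whose positions 3-5 spell one
#' of the query anticodons, closed by at least `min_stem` contiguous
#' Watson-Crick or GU-wobble base pairs.  Both strands are scanned;
#' minus-strand hits report the plus-strand coordinate of the
#' anticodon's leftmost base, so a mirror-image sequence yields mirror
#' hits with strands swapped.  Hits are sorted by score (stem length)
#' then position.
#'
#' @param seq Nucleotide string (plus-strand orientation).
#' @param anticodons Named character vector, tRNA label -> anticodon;
#'   defaults to [mt_trna_anticodons()].
#' @param min_stem Minimum stem length in base pairs (default 3).
#' @return data.frame with columns `strand`, `offset` (1-based
#'   plus-strand position of the anticodon's leftmost base),
#'   `anticodon` (as read on the hit strand), `trna`, `stem_len`,
#'   `score`.
#' @export
scan_anticodon_hairpins <- function(seq, anticodons = mt_trna_anticodons(),
                                    min_stem = 3L) {
  stopifnot(length(anticodons) > 0L, !is.null(names(anticodons)))
  anticodons <- toupper(anticodons)
  seq <- toupper(seq)
  n <- nchar(seq)
  plus <- .scan_one_strand(seq_chars(seq), anticodons, min_stem)
  minus <- .scan_one_strand(seq_chars(revcomp(seq)), anticodons, min_stem)
  rows <- list()
  for (h in plus) { h$strand <- "+"; rows[[length(rows) + 1L]] <- h }
  for (h in minus) {
    ## revcomp offset j (anticodon j..j+2) maps to plus-strand
    ## positions (n-j-1)..(n-j+1); leftmost is n - j - 1
    h$offset <- n - h$offset - 1L
    h$strand <- "-"
    rows[[length(rows) + 1L]] <- h
  }
  if (!length(rows))
    return(data.frame(strand = character(0), offset = integer(0),
                      anticodon = character(0), trna = character(0),
                      stem_len = integer(0), score = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("strand", "offset", "anticodon", "trna", "stem_len", "score")]
}

#' Scan all candidate NCR windows of a genome
#'
#' @param g A [mito_annotation()] with sequence.
#' @param min_ncr,flank Passed to [candidate_windows()].
#' @param anticodons,min_stem Passed to [scan_anticodon_hairpins()].
#' @return data.frame of hits with a leading `region` column; offsets
#'   are genome coordinates (plus strand, leftmost anticodon base).
#' @export
scan_ncr_trna_fragments <- function(g, min_ncr = 10L, flank = 20L,
                                    anticodons = mt_trna_anticodons(),
                                    min_stem = 3L) {
  win <- candidate_windows(g, min_ncr = min_ncr, flank = flank)
  rows <- list()
  for (i in seq_len(nrow(win))) {
    hits <- scan_anticodon_hairpins(win$sequence[i], anticodons, min_stem)
    if (!nrow(hits)) next
    pos <- win$start[i] + hits$offset - 1L
    pos <- ifelse(pos > g$length, pos - g$length, pos)
    hits <- cbind(region = win$region[i], hits)
    hits$offset <- as.integer(pos)
    rows[[length(rows) + 1L]] <- hits
  }
  if (!length(rows))
    return(data.frame(region = character(0), strand = character(0),
                      offset = integer(0), anticodon = character(0),
                      trna = character(0), stem_len = integer(0),
                      score = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
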