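## AT/GC strand-asymmetry (skew) computation and classification.
##
## AT skew = (A - T) / (A + T); GC skew = (G - C) / (G + C).  Positive
## AT skew means more A than T on the strand being read; positive GC
## skew more G than C.  Crustacean mitogenomes conventionally show
## positive AT / negative GC skew on the majority strand (the strand
## encoding most genes); most isopods show the inverted pattern, and a
## second replication-origin inversion can restore the crustacean-type
## signs ("double-inverted" skews) — homoplastic with distant lineages.

#' Tally nucleotides
#'
#' Case-insensitive counts of A, C, G, T; anything else (ambiguity
#' codes, gaps) is counted as `other` and excluded from all skew
#' denominators.
#'
#' @param seq Nucleotide string.
#' @return Named integer vector `a`, `c`, `g`, `t`, `other`.
#' @export
base_counts <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- seq_chars(seq)
  m <- match(ch, c("A", "C", "G", "T"))
  counts <- tabulate(m, nbins = 4L)
  c(a = counts[1L], c = counts[2L], g = counts[3L], t = counts[4L],
    other = sum(is.na(m)))
}

#' AT and GC skew
#'
#' `(a - t)/(a + t)` and `(g - c)/(g + c)`; `NA` (undefined, not an
#' error) when the denominator is zero.
#'
#' @param counts Named vector as returned by [base_counts()], or a
#'   nucleotide string.
#' @return Numeric scalar in `[-1, 1]`, or `NA`.
#' @export
at_skew <- function(counts) {
  if (is.character(counts)) counts <- base_counts(counts)
  a <- counts[["a"]]; t <- counts[["t"]]
  if (a + t == 0) NA_real_ else (a - t) / (a + t)
}

#' @rdname at_skew
#' @export
gc_skew <- function(counts) {
  if (is.character(counts)) counts <- base_counts(counts)
  g <- counts[["g"]]; c <- counts[["c"]]
  if (g + c == 0) NA_real_ else (g - c) / (g + c)
}

skew_pair <- function(seq) {
  counts <- base_counts(seq)
  c(at_skew = at_skew(counts), gc_skew = gc_skew(counts))
}

#' Majority strand of an annotated mitogenome
#'
#' The strand carrying strictly more gene features (control region
#' excluded).  A tie is an error rather than a silent pick: a wrong
#' majority strand flips the sign of every downstream skew.
#'
#' @param g A [mito_annotation()].
#' @return `"+"` or `"-"`.
#' @export
majority_strand <- function(g) {
  f <- g$features[g$features$category != "CR", , drop = FALSE]
  f <- f[!is.na(f$strand), , drop = FALSE]
  if (nrow(f) == 0L) stop("no stranded features")
  n_plus <- sum(f$strand == "+")
  n_minus <- sum(f$strand == "-")
  if (n_plus == n_minus)
    stop("strand tie (", n_plus, " vs ", n_minus,
         "): designate the majority strand explicitly")
  if (n_plus > n_minus) "+" else "-"
}

#' Full skew profile of a mitogenome
#'
#' Computes AT/GC skews at every resolution used in comparative
#' mitogenomics:
#' \itemize{
#'   \item \code{whole_genome}: the full sequence read on the majority
#'     strand;
#'   \item \code{per_gene}: each gene in its own coding orientation;
#'   \item \code{per_strand_class}: concatenated protein-coding genes of
#'     the majority and of the minority strand class, each read in
#'     coding orientation (so the minority-class values are reported in
#'     minority-strand orientation);
#'   \item \code{per_codon_position}: positions 1/2/3 of the two
#'     concatenated protein-coding classes, complete codons only — a
#'     gene span not divisible by three (truncated stop codon) drops
#'     its trailing partial codon with a warning.
#' }
#'
#' @param g A [mito_annotation()] with sequence.
#' @param epsilon Dead-zone half-width passed to
#'   [classify_skew_pattern()] for the whole-genome pattern call.
#' @return Object of class `skew_profile`: list with elements
#'   `majority`, `whole_genome`, `per_strand_class`, `per_gene`,
#'   `per_codon_position`, `pattern`.
#' @export
skew_profile <- function(g, epsilon = 0.05) {
  if (is.null(g$sequence)) stop("annotation has no sequence")
  maj <- majority_strand(g)
  whole <- if (maj == "+") g$sequence else revcomp(g$sequence)

  f <- g$features
  genes <- f[f$category != "CR" & !is.na(f$strand), , drop = FALSE]
  per_gene <- data.frame(
    gene = genes$name, category = genes$category,
    strand_class = ifelse(genes$strand == maj, "majority", "minority"),
    at_skew = NA_real_, gc_skew = NA_real_, stringsAsFactors = FALSE)
  gene_seqs <- stats::setNames(
    lapply(seq_len(nrow(genes)),
           function(i) extract_feature_sequence(g, which(
             g$features$name == genes$name[i]))),
    genes$name)
  for (i in seq_len(nrow(genes))) {
    sk <- skew_pair(gene_seqs[[i]])
    per_gene$at_skew[i] <- sk[["at_skew"]]
    per_gene$gc_skew[i] <- sk[["gc_skew"]]
  }

  pcg <- genes[genes$category == "PCG", , drop = FALSE]
  classes <- list(majority = pcg$name[pcg$strand == maj],
                  minority = pcg$name[pcg$strand != maj])
  strand_class <- do.call(rbind, lapply(names(classes), function(cl) {
    seqs <- unlist(gene_seqs[classes[[cl]]], use.names = FALSE)
    cc <- paste(seqs, collapse = "")
    sk <- if (nzchar(cc)) skew_pair(cc) else
      c(at_skew = NA_real_, gc_skew = NA_real_)
    data.frame(strand_class = cl, n_genes = length(classes[[cl]]),
               length = nchar(cc), at_skew = sk[["at_skew"]],
               gc_skew = sk[["gc_skew"]], stringsAsFactors = FALSE)
  }))

  codon_rows <- list()
  for (cl in names(classes)) {
    pos_chars <- list(character(0), character(0), character(0))
    for (gene in classes[[cl]]) {
      ch <- seq_chars(gene_seqs[[gene]])
      extra <- length(ch) %% 3L
      if (extra != 0L) {
        warning("gene ", gene, " length not divisible by 3; dropping ",
                extra, " trailing base(s) (truncated stop codon)",
                call. = FALSE)
        ch <- ch[seq_len(length(ch) - extra)]
      }
      if (!length(ch)) next
      phase <- rep_len(1:3, length(ch))
      for (p in 1:3)
        pos_chars[[p]] <- c(pos_chars[[p]], ch[phase == p])
    }
    for (p in 1:3) {
      s <- paste(pos_chars[[p]], collapse = "")
      sk <- if (nzchar(s)) skew_pair(s) else
        c(at_skew = NA_real_, gc_skew = NA_real_)
      codon_rows[[length(codon_rows) + 1L]] <- data.frame(
        strand_class = cl, position = p, length = nchar(s),
        at_skew = sk[["at_skew"]], gc_skew = sk[["gc_skew"]],
        stringsAsFactors = FALSE)
    }
  }
  per_codon <- do.call(rbind, codon_rows)

  whole_pair <- skew_pair(whole)
  structure(
    list(majority = maj,
         whole_genome = whole_pair,
         per_strand_class = strand_class,
         per_gene = per_gene,
         per_codon_position = per_codon,
         pattern = classify_skew_pattern(whole_pair, epsilon = epsilon)),
    class = "skew_profile")
}

#' @export
print.skew_profile <- function(x, ...) {
  cat(sprintf("<skew_profile> majority strand %s\n", x$majority))
  cat(sprintf("  whole genome: AT %.3f  GC %.3f  -> %s\n",
              x$whole_genome[["at_skew"]], x$whole_genome[["gc_skew"]],
              x$pattern))
  print(x$per_strand_class, row.names = FALSE)
  invisible(x)
}

#' Classify a strand-asymmetry pattern
#'
#' `CRUSTACEAN_TYPE` when AT skew > epsilon and GC skew < -epsilon on
#' the majority strand (the ancestral crustacean state, and the state
#' restored by a double inversion of the replication origin);
#' `INVERTED_TYPE` for the opposite sign pair (the typical isopod
#' state); `INDETERMINATE` otherwise, including undefined skews.  The
#' dead zone `epsilon` prevents noise-driven calls on short sequences;
#' a pure sign rule is `epsilon = 0`.
#'
#' @param pair Numeric vector with elements `at_skew`, `gc_skew`, or a
#'   nucleotide string.
#' @param epsilon Dead-zone half-width (default 0.05).
#' @return `"CRUSTACEAN_TYPE"`, `"INVERTED_TYPE"` or `"INDETERMINATE"`.
#' @export
classify_skew_pattern <- function(pair, epsilon = 0.05) {
  if (is.character(pair)) pair <- skew_pair(pair)
  at <- pair[["at_skew"]]; gc <- pair[["gc_skew"]]
  if (is.na(at) || is.na(gc)) return("INDETERMINATE")
  if (at > epsilon && gc < -epsilon) return("CRUSTACEAN_TYPE")
  if (at < -epsilon && gc > epsilon) return("INVERTED_TYPE")
  "INDETERMINATE"
}
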