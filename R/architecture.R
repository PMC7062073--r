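## Mitogenome architecture statistics: intergenic spacers and overlaps,
## non-coding-region catalogs, and circular gene-order comparison.

#' Intergenic spacers and overlaps
#'
#' One record per adjacent feature pair in coordinate order, plus the
#' pair wrapping through the origin on circular genomes.  The signed
#' gap is `downstream.start - upstream.end - 1` on the circular
#' coordinate system; negative values are overlaps.  Overlap counting
#' is purely positional (strand-blind), matching the IGR-column
#' convention of comparative mitogenomics tables.  The control region
#' participates as an ordinary feature.
#'
#' @param g A [mito_annotation()] with at least two features.
#' @return data.frame with columns `upstream`, `downstream`, `spacer`.
#' @export
spacers <- function(g) {
  f <- g$features
  if (nrow(f) < 2L) stop("need at least two features")
  n <- nrow(f)
  nxt <- c(2:n, 1L)
  spacer <- integer(n)
  for (i in seq_len(n)) {
    j <- nxt[i]
    d <- f$start[j] - f$end[i] - 1L
    if (j == 1L && g$circular) d <- d + g$length   # wrap through origin
    spacer[i] <- d
  }
  if (!g$circular) spacer <- spacer[-n]
  ## three features sharing a base -> the pairwise records understate
  ## the true overlap; emit them anyway but warn
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      k <- i + 2L
      if (f$start[k] <= f$end[i]) {
        warning("features ", f$name[i], ", ", f$name[i + 1L], ", ",
                f$name[k], " share bases; spacer records are pairwise only",
                call. = FALSE)
        break
      }
    }
  }
  data.frame(upstream = f$name[seq_along(spacer)],
             downstream = f$name[nxt[seq_along(spacer)]],
             spacer = spacer, stringsAsFactors = FALSE)
}

#' Catalog of non-coding regions
#'
#' One region per positive intergenic spacer of at least `min_len` bp,
#' plus the annotated control region (kind `control_region`), sorted
#' by start.
#'
#' @param g A [mito_annotation()].
#' @param min_len Minimum length (bp) for an intergenic region.
#' @return data.frame with columns `start`, `end`, `length`, `kind`,
#'   `upstream`, `downstream`.
#' @export
ncr_catalog <- function(g, min_len = 1L) {
  sp <- spacers(g)
  f <- g$features
  pos <- sp[sp$spacer >= min_len & sp$spacer > 0L, , drop = FALSE]
  regions <- list()
  for (i in seq_len(nrow(pos))) {
    up <- f[f$name == pos$upstream[i], ][1L, ]
    down <- f[f$name == pos$downstream[i], ][1L, ]
    start <- up$end + 1L
    end <- down$start - 1L
    if (start > g$length) start <- start - g$length
    if (end < 1L) end <- end + g$length
    regions[[length(regions) + 1L]] <- data.frame(
      start = start, end = end, length = pos$spacer[i],
      kind = "intergenic", upstream = pos$upstream[i],
      downstream = pos$downstream[i], stringsAsFactors = FALSE)
  }
  cr <- f[f$category == "CR", , drop = FALSE]
  for (i in seq_len(nrow(cr))) {
    idx <- which(f$name == cr$name[i])
    nxt <- if (idx == nrow(f)) 1L else idx + 1L
    prv <- if (idx == 1L) nrow(f) else idx - 1L
    regions[[length(regions) + 1L]] <- data.frame(
      start = cr$start[i], end = cr$end[i],
      length = feature_span(cr[i, ], g$length),
      kind = "control_region", upstream = f$name[prv],
      downstream = f$name[nxt], stringsAsFactors = FALSE)
  }
  if (!length(regions))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), kind = character(0),
                      upstream = character(0), downstream = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, regions)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------
## circular gene orders
## ---------------------------------------------------------------------

#' Extract the circular gene order
#'
#' Signed circular permutation of gene labels in coordinate order
#' (sign = strand).  Labels are stored in genome coordinate order;
#' equality and adjacency computations are rotation-invariant.
#' Reflections are *not* identified: a strand flip is biologically
#' meaningful.
#'
#' @param g A [mito_annotation()].
#' @param include_cr Include the control region as a label?  Gene-order
#'   comparisons conventionally cover genes only.
#' @param id Genome identifier carried in the result.
#' @return Object of class `gene_order` with elements `labels`
#'   (character), `strand` ("+"/"-") and `id`.
#' @export
gene_order <- function(g, include_cr = FALSE, id = NULL) {
  f <- g$features
  if (!include_cr) f <- f[f$category != "CR", , drop = FALSE]
  if (nrow(f) == 0L) stop("no features to order")
  dup <- unique(f$name[duplicated(f$name)])
  if (length(dup))
    stop("duplicate gene labels: ", paste(dup, collapse = ", "))
  if (is.null(id))
    id <- if (nzchar(g$accession)) g$accession else g$organism
  strand <- f$strand
  strand[is.na(strand)] <- "+"
  structure(list(labels = f$name, strand = strand, id = id),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s (%d genes)\n", x$id, length(x$labels)))
  cat(" ", paste0(ifelse(x$strand == "-", "-", ""), x$labels,
                  collapse = " "), "\n")
  invisible(x)
}

#' @export
format.gene_order <- function(x, ...) {
  paste0(ifelse(x$strand == "-", "-", ""), x$labels, collapse = " ")
}

## canonical rotation: lexicographically smallest label first
canonical_rotation <- function(o) {
  k <- which(o$labels == min(o$labels))[1L]
  n <- length(o$labels)
  idx <- c(k:n, if (k > 1L) 1:(k - 1L))
  o$labels <- o$labels[idx]
  o$strand <- o$strand[idx]
  o
}

#' Rotation-invariant gene-order equality
#'
#' @param o1,o2 [gene_order()] objects.
#' @return TRUE iff one order is a rotation of the other (labels and
#'   strands both matching).
#' @export
gene_order_equal <- function(o1, o2) {
  a <- canonical_rotation(o1); b <- canonical_rotation(o2)
  identical(a$labels, b$labels) && identical(a$strand, b$strand)
}

#' Signed adjacency set of a circular gene order
#'
#' Every circular order over n labels has n signed adjacencies.  An
#' adjacency (a, b) is equivalent to (-b, -a) (reading the molecule
#' from the other strand does not create new adjacencies); each pair
#' is normalized to a canonical string representation.
#'
#' @param o A [gene_order()].
#' @return Character vector (a set) of normalized adjacencies.
#' @export
adjacency_set <- function(o) {
  n <- length(o$labels)
  signed <- paste0(ifelse(o$strand == "-", "-", "+"), o$labels)
  flip <- function(s)
    ifelse(startsWith(s, "-"), paste0("+", substring(s, 2L)),
           paste0("-", substring(s, 2L)))
  nxt <- c(2:n, 1L)[seq_len(if (n > 1L) n else 0L)]
  if (n == 1L) return(character(0))
  out <- character(n)
  for (i in seq_len(n)) {
    a <- signed[i]; b <- signed[nxt[i]]
    alt_a <- flip(b); alt_b <- flip(a)       # (a,b) == (-b,-a)
    fwd <- paste0(a, "|", b); rev <- paste0(alt_a, "|", alt_b)
    out[i] <- if (fwd <= rev) fwd else rev
  }
  unique(out)
}

## restrict a circular order to a label subset, preserving circular
## adjacency of the survivors
restrict_order <- function(o, labels) {
  keep <- o$labels %in% labels
  o$labels <- o$labels[keep]
  o$strand <- o$strand[keep]
  o
}

#' Breakpoint distance between two circular gene orders
#'
#' Number of signed adjacencies of `o1` absent from `o2`, after
#' restricting both orders to their shared (unsigned) label set;
#' missing labels (e.g. tRNAs lost in some lineages) are dropped with
#' a warning.  Zero iff the orders match up to rotation.
#'
#' @param o1,o2 [gene_order()] objects.
#' @return Non-negative integer.
#' @export
breakpoint_distance <- function(o1, o2) {
  shared <- intersect(o1$labels, o2$labels)
  if (length(shared) == 0L) stop("no shared gene labels")
  dropped <- length(setdiff(o1$labels, shared)) +
    length(setdiff(o2$labels, shared))
  if (dropped > 0L)
    warning(dropped, " label(s) absent from one order dropped before ",
            "comparison", call. = FALSE)
  a <- adjacency_set(restrict_order(o1, shared))
  b <- adjacency_set(restrict_order(o2, shared))
  sum(!(a %in% b))
}

#' Is a gene order unique among comparators?
#'
#' @param o A [gene_order()].
#' @param others List of [gene_order()] comparators.
#' @return List with `unique` (TRUE iff breakpoint distance > 0 against
#'   every comparator), `min_distance`, `nearest` (id of the closest
#'   comparator) and the full `distances` vector.
#' @export
is_unique_order <- function(o, others) {
  if (length(others) == 0L) stop("need at least one comparator")
  d <- vapply(others, function(x) breakpoint_distance(o, x), numeric(1))
  ids <- vapply(others, function(x) as.character(x$id), character(1))
  k <- which.min(d)
  list(unique = all(d > 0), min_distance = unname(d[k]),
       nearest = unname(ids[k]),
       distances = stats::setNames(d, ids))
}
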