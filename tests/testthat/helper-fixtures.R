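## Shared fixtures, built in code.

## the printed isopod feature table shipped with the package; the two
## known printed-size discrepancies (nad1, CR) warn by design
asotana <- function() {
  suppressWarnings(parse_feature_table(
    system.file("extdata", "asotana_magnifica_mito.tsv",
                package = "mitoskew"),
    organism = "Asotana magnifica"))
}

## tiny annotation from a compact spec: list(name, start, end, strand)
toy_annotation <- function(..., length = NULL, sequence = NULL,
                           circular = TRUE) {
  rows <- list(...)
  f <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), strand = r[[4]],
               stringsAsFactors = FALSE)))
  mito_annotation(f, length = length, sequence = sequence,
                  circular = circular)
}

## independent test-side GenBank formatter (deliberately not the
## package's writer: the parser is tested against text the package
## never produced)
genbank_text <- function(g, name = "TESTREC") {
  lines <- c(sprintf("LOCUS       %s %d bp    DNA     %s   INV",
                     name, g$length,
                     if (g$circular) "circular" else "linear"),
             "DEFINITION  synthetic test record.",
             "ACCESSION   SYN00001",
             "  ORGANISM  Synthetica testii",
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", g$length))
  for (i in seq_len(nrow(g$features))) {
    f <- g$features[i, ]
    loc <- if (f$wraps_origin)
      sprintf("join(%d..%d,1..%d)", f$start, g$length, f$end)
    else sprintf("%d..%d", f$start, f$end)
    if (identical(f$strand, "-")) loc <- sprintf("complement(%s)", loc)
    key <- switch(f$category, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  CR = "D-loop", "misc_feature")
    lines <- c(lines,
               sprintf("     %-15s %s", key, loc),
               if (f$category != "CR")
                 sprintf("                     /gene=\"%s\"", f$name))
  }
  if (!is.null(g$sequence)) {
    lines <- c(lines, "ORIGIN")
    s <- tolower(g$sequence)
    starts <- seq(1L, nchar(s), by = 60L)
    lines <- c(lines, vapply(starts, function(st)
      sprintf("%9d %s", st, substr(s, st, min(st + 59L, nchar(s)))),
      character(1)))
  }
  c(lines, "//")
}

## random nucleotide string
random_seq <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

## random signed circular gene order over n labels
random_order <- function(n, id = "x") {
  labs <- sample(sprintf("g%02d", seq_len(n)))
  structure(list(labels = labs,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 id = id),
            class = "gene_order")
}
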