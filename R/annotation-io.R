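## Reading/writing annotated mitogenomes.
##
## The central container is the S3 class "mito_annotation": one circular
## (usually) mitochondrial genome with an ordered feature table and an
## optional nucleotide sequence.  Coordinates are 1-based inclusive at
## every interface; a feature spanning the origin of the circular
## molecule carries wraps_origin = TRUE and has start > end.

## ---------------------------------------------------------------------
## gene-name canonicalization
## ---------------------------------------------------------------------

## GenBank dialects are wildly inconsistent; this table maps the common
## spellings to the canonical lower-case labels used throughout
## (cox1..3, nad1..6, nad4l, atp6/8, cytb, rrnS/rrnL, trnX, CR).
.canonical_gene_table <- c(
  "coi" = "cox1", "coii" = "cox2", "coiii" = "cox3",
  "co1" = "cox1", "co2" = "cox2", "co3" = "cox3",
  "cox1" = "cox1", "cox2" = "cox2", "cox3" = "cox3",
  "nd1" = "nad1", "nd2" = "nad2", "nd3" = "nad3", "nd4" = "nad4",
  "nd4l" = "nad4l", "nd5" = "nad5", "nd6" = "nad6",
  "nad1" = "nad1", "nad2" = "nad2", "nad3" = "nad3", "nad4" = "nad4",
  "nad4l" = "nad4l", "nad4 l" = "nad4l", "nad5" = "nad5", "nad6" = "nad6",
  "atp6" = "atp6", "atp8" = "atp8", "atpase6" = "atp6", "atpase8" = "atp8",
  "cob" = "cytb", "cytb" = "cytb", "cyt b" = "cytb",
  "12s" = "rrnS", "s-rrna" = "rrnS", "rrns" = "rrnS", "12s rrna" = "rrnS",
  "16s" = "rrnL", "l-rrna" = "rrnL", "rrnl" = "rrnL", "16s rrna" = "rrnL",
  "d-loop" = "CR", "control region" = "CR", "cr" = "CR",
  "putative control region" = "CR"
)

## standard metazoan mitochondrial tRNA anticodons, used both to name
## tRNAs parsed from GenBank products and as the default search table
## for the NCR hairpin scan
.mt_trna_anticodons <- c(
  trnA = "TGC", trnR = "TCG", trnN = "GTT", trnD = "GTC", trnC = "GCA",
  trnQ = "TTG", trnE = "TTC", trnG = "TCC", trnH = "GTG", trnI = "GAT",
  trnL1 = "TAG", trnL2 = "TAA", trnK = "TTT", trnM = "CAT", trnF = "GAA",
  trnP = "TGG", trnS1 = "TCT", trnS2 = "TGA", trnT = "TGT", trnW = "TCA",
  trnY = "GTA", trnV = "TAC"
)

## one-letter amino-acid code -> trn label stem (L and S need the
## anticodon to disambiguate L1/L2, S1/S2)
.aa_to_trn <- c(
  Ala = "trnA", Arg = "trnR", Asn = "trnN", Asp = "trnD", Cys = "trnC",
  Gln = "trnQ", Glu = "trnE", Gly = "trnG", His = "trnH", Ile = "trnI",
  Leu = "trnL", Lys = "trnK", Met = "trnM", Phe = "trnF", Pro = "trnP",
  Ser = "trnS", Thr = "trnT", Trp = "trnW", Tyr = "trnY", Val = "trnV"
)

#' Canonicalize a gene label
#'
#' Maps the common GenBank spellings of mitochondrial gene names
#' ("COI", "ND5", "s-rRNA", "D-loop", "tRNA-Leu", ...) onto the
#' canonical labels used throughout the package (`cox1`, `nad5`,
#' `rrnS`, `CR`, `trnL1`, ...).  Unrecognized names are returned
#' lower-cased with internal whitespace removed.
#'
#' @param name Character vector of raw gene labels.
#' @param anticodon Optional character vector of anticodons, used to
#'   disambiguate the two leucine and serine tRNAs.
#' @return Character vector of canonical labels.
#' @export
canonical_gene_name <- function(name, anticodon = NA_character_) {
  anticodon <- rep_len(anticodon, length(name))
  out <- character(length(name))
  for (i in seq_along(name)) {
    raw <- trimws(name[i])
    key <- tolower(raw)
    if (!is.na(.canonical_gene_table[key])) {
      out[i] <- .canonical_gene_table[[key]]
      next
    }
    ## compact tRNA spellings: trnX, trnX1/2
    if (grepl("^trn[a-z][0-9]?$", key)) {
      out[i] <- paste0("trn", toupper(substr(raw, 4L, 4L)),
                       substr(key, 5L, nchar(key)))
      next
    }
    ## product-style spellings: tRNA-Xyz
    m <- regmatches(raw, regexec("^t-?RNA-([A-Za-z]{3})", raw,
                                 ignore.case = TRUE))[[1L]]
    if (length(m) == 2L) {
      stem <- .aa_to_trn[m[2L]]
      if (!is.na(stem)) {
        if (stem %in% c("trnL", "trnS") && !is.na(anticodon[i])) {
          ac <- toupper(chartr("U", "T", anticodon[i]))
          hit <- names(.mt_trna_anticodons)[.mt_trna_anticodons == ac]
          hit <- hit[startsWith(hit, stem)]
          if (length(hit) == 1L) { out[i] <- hit; next }
        }
        out[i] <- stem
        next
      }
    }
    out[i] <- gsub("\\s+", "", key)
  }
  out
}

## infer the feature category from a canonical name
feature_category <- function(name) {
  ifelse(startsWith(name, "trn"), "tRNA",
         ifelse(startsWith(name, "rrn"), "rRNA",
                ifelse(name == "CR", "CR", "PCG")))
}

## ---------------------------------------------------------------------
## constructor / validator
## ---------------------------------------------------------------------

#' Construct a mitogenome annotation
#'
#' @param features data.frame with columns `name`, `start`, `end`,
#'   `strand` ("+", "-" or NA for the control region), and optionally
#'   `category`, `wraps_origin`, `start_codon`, `stop_codon`,
#'   `anticodon`, `size_printed`, `igr_printed`.  Coordinates are
#'   1-based inclusive.
#' @param length Genome length in bp; defaults to the maximum feature
#'   end.
#' @param organism,accession Identification strings.
#' @param circular Logical; compact mitogenomes are circular.
#' @param sequence Optional nucleotide string of length `length`.
#' @return An object of class `mito_annotation`.
#' @export
mito_annotation <- function(features, length = NULL, organism = "",
                            accession = "", circular = TRUE,
                            sequence = NULL) {
  stopifnot(is.data.frame(features),
            all(c("name", "start", "end", "strand") %in% names(features)))
  f <- features
  f$start <- as.integer(f$start)
  f$end <- as.integer(f$end)
  f$strand <- as.character(f$strand)
  f$strand[!(f$strand %in% c("+", "-"))] <- NA_character_
  if (is.null(f$category)) f$category <- feature_category(f$name)
  if (is.null(f$wraps_origin)) f$wraps_origin <- f$start > f$end
  for (col in c("start_codon", "stop_codon", "anticodon"))
    if (is.null(f[[col]])) f[[col]] <- NA_character_
  for (col in c("size_printed", "igr_printed"))
    if (is.null(f[[col]])) f[[col]] <- NA_integer_
  if (is.null(length))
    length <- max(f$end, f$start)
  length <- as.integer(length)
  if (any(f$start < 1L | f$end < 1L | f$start > length | f$end > length))
    stop("feature coordinates outside 1..", length)
  bad <- !f$wraps_origin & f$start > f$end
  if (any(bad))
    stop("start > end without wraps_origin for: ",
         paste(f$name[bad], collapse = ", "))
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != length)
      stop("sequence length (", nchar(sequence),
           ") does not match genome length (", length, ")")
  }
  f <- f[order(f$start), , drop = FALSE]
  rownames(f) <- NULL
  structure(
    list(organism = organism, accession = accession, length = length,
         circular = circular, sequence = sequence, features = f),
    class = "mito_annotation")
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat(sprintf("<mito_annotation> %s %s\n",
              if (nzchar(x$organism)) x$organism else "(unnamed)",
              if (nzchar(x$accession)) paste0("[", x$accession, "]") else ""))
  cat(sprintf("  %d bp, %s, sequence %s\n", x$length,
              if (x$circular) "circular" else "linear",
              if (is.null(x$sequence)) "absent" else "present"))
  tab <- table(x$features$category)
  cat("  features:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

feature_span <- function(f, genome_length) {
  ifelse(f$wraps_origin,
         genome_length - f$start + 1L + f$end,
         f$end - f$start + 1L)
}

## ---------------------------------------------------------------------
## feature-table (TSV) dialect
## ---------------------------------------------------------------------

#' Parse a tab-separated mitogenome feature table
#'
#' Reads the compact dialect used in comparative mitogenomics tables:
#' columns `gene`, `from`, `to`, `size`, `igr` (intergenic region,
#' negative = overlap with the preceding gene), `start_codon`,
#' `stop_codon`, `anticodon`, `strand`.  Only `gene`, `from`, `to` and
#' `strand` are required.  The printed `size`/`igr` columns are
#' retained (as `size_printed`/`igr_printed`) for cross-validation but
#' recomputed values take precedence everywhere; rows whose printed
#' size disagrees with `to - from + 1` are reported in a warning.
#'
#' @param path Path to the TSV file, or a character vector of lines.
#' @param organism,accession Passed to [mito_annotation()].
#' @param genome_length Genome length; defaults to the maximum `to`.
#' @param sequence Optional genome sequence.
#' @return A [mito_annotation()].
#' @export
parse_feature_table <- function(path, organism = "", accession = "",
                                genome_length = NULL, sequence = NULL) {
  if (length(path) == 1L && file.exists(path)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  } else {
    tab <- utils::read.delim(text = paste(path, collapse = "\n"),
                             stringsAsFactors = FALSE, check.names = FALSE)
  }
  names(tab) <- tolower(names(tab))
  required <- c("gene", "from", "to", "strand")
  if (!all(required %in% names(tab)))
    stop("feature table must have columns: ",
         paste(required, collapse = ", "))
  grab <- function(col) if (col %in% names(tab)) tab[[col]] else NA
  ac <- as.character(grab("anticodon"))
  ac[!is.na(ac) & !nzchar(ac)] <- NA_character_
  feats <- data.frame(
    name = canonical_gene_name(tab$gene, ac),
    start = as.integer(tab$from),
    end = as.integer(tab$to),
    strand = as.character(tab$strand),
    start_codon = as.character(grab("start_codon")),
    stop_codon = as.character(grab("stop_codon")),
    anticodon = ac,
    size_printed = suppressWarnings(as.integer(grab("size"))),
    igr_printed = suppressWarnings(as.integer(grab("igr"))),
    stringsAsFactors = FALSE)
  for (col in c("start_codon", "stop_codon"))
    feats[[col]][!is.na(feats[[col]]) & !nzchar(feats[[col]])] <- NA_character_
  ann <- mito_annotation(feats, length = genome_length, organism = organism,
                         accession = accession, sequence = sequence)
  span <- feature_span(ann$features, ann$length)
  bad <- !is.na(ann$features$size_printed) & ann$features$size_printed != span
  if (any(bad))
    warning("printed size differs from coordinate span for: ",
            paste(sprintf("%s (printed %d, span %d)",
                          ann$features$name[bad],
                          ann$features$size_printed[bad], span[bad]),
                  collapse = "; "), call. = FALSE)
  ann
}

#' Write a mitogenome annotation as a feature table
#'
#' Inverse of [parse_feature_table()]: `gene`, `from`, `to` and
#' `strand` round-trip exactly; `size` and `igr` are the *recomputed*
#' values.
#'
#' @param g A [mito_annotation()].
#' @param path Output file, or NULL to return lines invisibly.
#' @return The data.frame written, invisibly.
#' @export
write_feature_table <- function(g, path = NULL) {
  f <- g$features
  sp <- spacers(g)
  igr <- sp$spacer[match(f$name, sp$downstream)]
  out <- data.frame(
    gene = f$name, from = f$start, to = f$end,
    size = feature_span(f, g$length), igr = igr,
    start_codon = ifelse(is.na(f$start_codon), "", f$start_codon),
    stop_codon = ifelse(is.na(f$stop_codon), "", f$stop_codon),
    anticodon = ifelse(is.na(f$anticodon), "", f$anticodon),
    strand = ifelse(is.na(f$strand), "", f$strand),
    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(out)
}

## ---------------------------------------------------------------------
## GenBank flat files
## ---------------------------------------------------------------------

## parse one GenBank location string into (start, end, strand, wraps)
.parse_location <- function(loc, feature_key, genome_length = NA) {
  raw <- loc
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
    rng <- lapply(parts, function(p) {
      m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", trimws(p)))[[1L]]
      if (length(m) != 3L)
        stop("malformed location for feature ", feature_key, ": ", raw)
      as.integer(m[2:3])
    })
    if (length(rng) != 2L || rng[[1L]][2L] < rng[[1L]][1L] ||
        rng[[2L]][1L] != 1L)
      stop("unsupported join location for feature ", feature_key, ": ", raw,
           " (only two-segment origin-spanning joins are handled)")
    return(list(start = rng[[1L]][1L], end = rng[[2L]][2L],
                strand = strand, wraps = TRUE))
  }
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1L]]
  if (length(m) != 3L) {
    m1 <- regmatches(loc, regexec("^(\\d+)$", loc))[[1L]]
    if (length(m1) == 2L)
      return(list(start = as.integer(m1[2L]), end = as.integer(m1[2L]),
                  strand = strand, wraps = FALSE))
    stop("malformed location for feature ", feature_key, ": ", raw)
  }
  list(start = as.integer(m[2L]), end = as.integer(m[3L]),
       strand = strand, wraps = wraps)
}

#' Parse a GenBank flat file into a mitogenome annotation
#'
#' A deliberately small reader for single-record GenBank flat files:
#' LOCUS/ORGANISM metadata, the FEATURES table (keys `gene`, `CDS`,
#' `tRNA`, `rRNA`, `D-loop`, `misc_feature`) and the ORIGIN sequence
#' block.  `complement(a..b)` sets strand "-";
#' `join(a..N,1..b)` marks an origin-spanning feature.  Where a `gene`
#' feature and a `CDS`/`tRNA`/`rRNA` feature describe the same locus
#' the more specific key wins.  Offline by design: nothing is fetched.
#'
#' @param text Path to a file, or the flat-file content as a character
#'   vector of lines (or one string with embedded newlines).
#' @return A [mito_annotation()].
#' @export
parse_genbank <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  else if (length(text) == 1L)
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  locus <- grep("^LOCUS", text)
  if (length(locus) == 0L) stop("no LOCUS record found")
  if (length(locus) > 1L)
    stop("multiple LOCUS records: one genome per call")
  lfields <- strsplit(trimws(text[locus]), "\\s+")[[1L]]
  len_idx <- which(lfields == "bp")[1L]
  glen <- if (!is.na(len_idx)) as.integer(lfields[len_idx - 1L]) else NA
  circular <- any(grepl("circular", lfields, ignore.case = TRUE))
  accession <- ""
  acc_line <- grep("^ACCESSION", text, value = TRUE)
  if (length(acc_line))
    accession <- strsplit(trimws(acc_line[1L]), "\\s+")[[1L]][2L]
  if (is.na(accession)) accession <- ""
  organism <- ""
  org_line <- grep("^\\s+ORGANISM", text, value = TRUE)
  if (length(org_line))
    organism <- trimws(sub("^\\s+ORGANISM\\s+", "", org_line[1L]))

  feat_start <- grep("^FEATURES", text)
  origin <- grep("^ORIGIN", text)
  feat_end <- if (length(origin)) origin[1L] - 1L else {
    slash <- grep("^//", text)
    if (length(slash)) slash[1L] - 1L else length(text)
  }
  sequence <- NULL
  if (length(origin)) {
    stop_line <- grep("^//", text)
    stop_line <- if (length(stop_line)) stop_line[1L] - 1L else length(text)
    seq_lines <- text[(origin[1L] + 1L):stop_line]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (!nzchar(sequence)) sequence <- NULL
  }

  feats <- list()
  if (length(feat_start)) {
    lines <- text[(feat_start[1L] + 1L):feat_end]
    ## a new feature starts at column 6 with a non-blank key
    is_key <- grepl("^ {1,10}\\S", lines) & !grepl("^ {12,}", lines)
    idx <- which(is_key)
    keep_keys <- c("gene", "CDS", "tRNA", "rRNA", "D-loop", "misc_feature")
    for (k in seq_along(idx)) {
      first <- lines[idx[k]]
      block_end <- if (k < length(idx)) idx[k + 1L] - 1L else length(lines)
      block <- lines[idx[k]:block_end]
      parts <- strsplit(trimws(first), "\\s+")[[1L]]
      key <- parts[1L]
      if (key == "source" || !(key %in% keep_keys)) next
      loc <- paste(parts[-1L], collapse = "")
      ## location may continue on the next line(s) before qualifiers
      qual_start <- grep("^\\s+/", block)
      loc_extra <- setdiff(seq_along(block)[-1L],
                           if (length(qual_start))
                             qual_start[1L]:length(block) else integer(0))
      if (length(loc_extra))
        loc <- paste0(loc, gsub("\\s", "", paste(block[loc_extra],
                                                 collapse = "")))
      quals <- paste(block[grepl("^\\s+/", block)], collapse = " ")
      get_q <- function(q) {
        m <- regmatches(quals,
                        regexec(paste0("/", q, "=\"([^\"]*)\""), quals))[[1L]]
        if (length(m) == 2L) m[2L] else NA_character_
      }
      gene_q <- get_q("gene")
      prod_q <- get_q("product")
      note_q <- get_q("note")
      raw_name <- if (key == "D-loop") "CR"
                  else if (!is.na(gene_q)) gene_q
                  else if (!is.na(prod_q)) prod_q
                  else if (!is.na(note_q)) note_q
                  else key
      ac <- NA_character_
      acm <- regmatches(quals, regexec("anticodon[^A-Za-z]*seq:([a-zA-Z]{3})",
                                       quals))[[1L]]
      if (length(acm) == 2L) ac <- toupper(chartr("Uu", "Tt", acm[2L]))
      pl <- .parse_location(loc, raw_name, glen)
      feats[[length(feats) + 1L]] <- data.frame(
        key = key, name = canonical_gene_name(raw_name, ac),
        start = pl$start, end = pl$end, strand = pl$strand,
        wraps_origin = pl$wraps, anticodon = ac, stringsAsFactors = FALSE)
    }
  }
  if (!length(feats)) stop("no features found in GenBank record")
  f <- do.call(rbind, feats)
  ## prefer the specific key over the bare "gene" duplicate at one locus
  specific <- f[f$key != "gene", , drop = FALSE]
  generic <- f[f$key == "gene", , drop = FALSE]
  dup <- generic$name %in% specific$name |
    paste(generic$start, generic$end) %in%
      paste(specific$start, specific$end)
  f <- rbind(specific, generic[!dup, , drop = FALSE])
  f$key <- NULL
  f$category <- feature_category(f$name)
  mito_annotation(f, length = glen, organism = organism,
                  accession = accession, circular = circular,
                  sequence = sequence)
}

## ---------------------------------------------------------------------
## sequence extraction
## ---------------------------------------------------------------------

#' Extract a feature's sequence in coding orientation
#'
#' Plus-strand features return the genomic slice `start..end`;
#' minus-strand features its reverse complement; origin-spanning
#' features concatenate the tail and head of the circular molecule
#' before orienting.
#'
#' @param g A [mito_annotation()] with sequence.
#' @param feature A feature name, or a row index into `g$features`.
#' @return Nucleotide string in coding orientation.
#' @export
extract_feature_sequence <- function(g, feature) {
  if (is.null(g$sequence))
    stop("annotation has no sequence; cannot extract features")
  f <- g$features
  if (is.character(feature)) {
    i <- which(f$name == feature)
    if (length(i) != 1L)
      stop("feature ", feature, " not found (or duplicated)")
  } else i <- as.integer(feature)
  row <- f[i, ]
  s <- if (row$wraps_origin)
    circular_slice(g$sequence, row$start, row$end)
  else
    substr(g$sequence, row$start, row$end)
  if (identical(row$strand, "-")) revcomp(s) else s
}

#' Read a single-sequence FASTA file
#'
#' @param path FASTA file.
#' @return Upper-case nucleotide string (first record).
#' @export
read_fasta_sequence <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(dna) < 1L) stop("no sequences in ", path)
  toupper(paste(as.character(dna)[[1L]], collapse = ""))
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of nucleotide strings.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, max(nchar(s), 1L), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}
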