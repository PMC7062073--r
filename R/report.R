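## Report assembly and the command-line entry point.
##
## Every number in a report is recomputed by calling the underlying
## module function with the same configuration; nothing is computed
## "report-only".  Reports are written as TSV + JSON so they diff
## cleanly and are byte-stable for fixed inputs, config and seeds.

#' Per-genome architecture + skew report
#'
#' For each annotation: feature-table echo, spacer/overlap table, NCR
#' catalog, gene-order string, summary counts, and — when a sequence
#' is present — the skew profile with its pattern call and the NCR
#' tRNA-fragment scan.  A missing sequence downgrades that genome to
#' an architecture-only report with a warning.  With more than one
#' genome a cross-genome section reports pairwise breakpoint distances
#' and order-uniqueness flags.
#'
#' @param annotations A [mito_annotation()] or list of them.
#' @param out_dir Optional directory; when given, TSV/JSON files are
#'   written there.
#' @param epsilon,min_ncr,flank,min_stem Analysis knobs (see
#'   [classify_skew_pattern()], [candidate_windows()],
#'   [scan_anticodon_hairpins()]).
#' @return List (class `genome_report`) with one entry per genome plus
#'   `cross_genome`.
#' @export
run_genome_report <- function(annotations, out_dir = NULL,
                              epsilon = 0.05, min_ncr = 10L,
                              flank = 20L, min_stem = 3L) {
  if (inherits(annotations, "mito_annotation"))
    annotations <- list(annotations)
  ids <- vapply(seq_along(annotations), function(i) {
    g <- annotations[[i]]
    if (nzchar(g$accession)) g$accession
    else if (nzchar(g$organism)) g$organism
    else paste0("genome", i)
  }, character(1))
  per_genome <- vector("list", length(annotations))
  names(per_genome) <- ids
  orders <- vector("list", length(annotations))
  for (i in seq_along(annotations)) {
    g <- annotations[[i]]
    sp <- spacers(g)
    cat_all <- ncr_catalog(g)
    ord <- gene_order(g, id = ids[i])
    orders[[i]] <- ord
    f <- g$features
    counts <- list(
      features = nrow(f),
      genes = sum(f$category != "CR"),
      pcg = sum(f$category == "PCG"),
      trna = sum(f$category == "tRNA"),
      rrna = sum(f$category == "rRNA"),
      minus_strand_genes = sum(f$strand == "-" &
                                 f$category != "CR", na.rm = TRUE),
      overlaps = sum(sp$spacer < 0),
      max_overlap = if (any(sp$spacer < 0)) -min(sp$spacer) else 0L,
      ncr = nrow(cat_all),
      ncr_over_10bp = sum(cat_all$length > 10L),
      genome_length = g$length)
    entry <- list(id = ids[i], counts = counts,
                  feature_table = write_feature_table(g),
                  spacers = sp, ncr = cat_all,
                  gene_order = format(ord))
    if (is.null(g$sequence)) {
      warning("genome ", ids[i],
              " has no sequence: architecture-only report", call. = FALSE)
    } else {
      entry$skew_profile <- skew_profile(g, epsilon = epsilon)
      entry$pattern <- entry$skew_profile$pattern
      entry$ncr_hits <- scan_ncr_trna_fragments(
        g, min_ncr = min_ncr, flank = flank, min_stem = min_stem)
    }
    per_genome[[i]] <- entry
  }
  cross <- NULL
  if (length(annotations) > 1L) {
    n <- length(orders)
    bd <- matrix(0L, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      bd[i, j] <- bd[j, i] <- breakpoint_distance(orders[[i]], orders[[j]])
    uniq <- vapply(seq_len(n), function(i)
      is_unique_order(orders[[i]], orders[-i])$unique, logical(1))
    cross <- list(breakpoint_distances = bd,
                  unique_order = stats::setNames(uniq, ids))
  }
  report <- structure(list(genomes = per_genome, cross_genome = cross),
                      class = "genome_report")
  if (!is.null(out_dir)) write_genome_report(report, out_dir)
  report
}

write_genome_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(report$genomes)) {
    e <- report$genomes[[id]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", id)
    utils::write.table(e$spacers,
                       file.path(out_dir, paste0(safe, "_spacers.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(e$ncr,
                       file.path(out_dir, paste0(safe, "_ncr.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- c(e$counts, list(gene_order = e$gene_order))
    if (!is.null(e$pattern)) {
      p <- e$skew_profile
      summary$pattern <- e$pattern
      summary$whole_genome_at_skew <- unname(p$whole_genome[["at_skew"]])
      summary$whole_genome_gc_skew <- unname(p$whole_genome[["gc_skew"]])
      utils::write.table(
        p$per_gene, file.path(out_dir, paste0(safe, "_skew_genes.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        rbind(p$per_strand_class[, c("strand_class", "length",
                                     "at_skew", "gc_skew")],
              data.frame(strand_class = paste0(
                           p$per_codon_position$strand_class, "_pos",
                           p$per_codon_position$position),
                         length = p$per_codon_position$length,
                         at_skew = p$per_codon_position$at_skew,
                         gc_skew = p$per_codon_position$gc_skew)),
        file.path(out_dir, paste0(safe, "_skew_classes.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      if (nrow(e$ncr_hits))
        utils::write.table(
          e$ncr_hits, file.path(out_dir, paste0(safe, "_ncr_hits.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary,
                         file.path(out_dir, paste0(safe, "_summary.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  if (!is.null(report$cross_genome)) {
    bd <- report$cross_genome$breakpoint_distances
    utils::write.table(data.frame(id = rownames(bd), bd,
                                  check.names = FALSE),
                       file.path(out_dir, "breakpoint_distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(report$cross_genome$unique_order),
                         file.path(out_dir, "unique_order.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out_dir)
}

#' @export
print.genome_report <- function(x, ...) {
  for (id in names(x$genomes)) {
    e <- x$genomes[[id]]
    cat(sprintf("== %s ==\n", id))
    cat("  ", paste(names(e$counts), unlist(e$counts), sep = "=",
                    collapse = " "), "\n")
    if (!is.null(e$pattern)) cat("  pattern:", e$pattern, "\n")
  }
  if (!is.null(x$cross_genome)) {
    cat("unique orders:\n")
    print(x$cross_genome$unique_order)
  }
  invisible(x)
}

## ---------------------------------------------------------------------
## command-line entry point
## ---------------------------------------------------------------------

.cli_usage <- "usage: mitoskew <command> [options]

commands:
  report   <annotation.tsv|.gb> [more...] [--fasta seq.fa] [--out DIR]
           architecture + skew + NCR-scan report per genome
  arch     <annotation.tsv|.gb> [more...] [--out DIR]
           spacer/NCR/gene-order statistics only
  skew     <annotation.tsv|.gb> --fasta seq.fa [--out DIR]
           skew profile and pattern call
  ncr      <annotation.tsv|.gb> --fasta seq.fa [--out DIR]
           scan NCRs for residual tRNA anticodon hairpins
  simulate --seed N [--out DIR]
           simulate a skewed mitogenome from the default template
  lba      --seed N [--replicates N] [--length N] [--out DIR]
           run the outgroup-strategy LBA experiment

options: --out DIR (default '.'), --epsilon X, --min-ncr N, --flank N,
         --min-stem N, --version, --help
exit codes: 0 ok, 1 runtime error, 2 usage error"

.cli_parse <- function(args) {
  opts <- list(out = ".", fasta = NULL, seed = NULL, replicates = 200L,
               length = 2000L, epsilon = 0.05, min_ncr = 10L,
               flank = 20L, min_stem = 3L)
  pos <- character(0)
  i <- 1L
  flagmap <- c("--out" = "out", "--fasta" = "fasta", "--seed" = "seed",
               "--replicates" = "replicates", "--length" = "length",
               "--epsilon" = "epsilon", "--min-ncr" = "min_ncr",
               "--flank" = "flank", "--min-stem" = "min_stem")
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% names(flagmap)) {
      if (i == length(args)) stop("flag ", a, " needs a value")
      val <- args[i + 1L]
      key <- flagmap[[a]]
      opts[[key]] <- if (key %in% c("out", "fasta")) val else
        as.numeric(val)
      i <- i + 2L
    } else if (startsWith(a, "--")) {
      stop("unknown flag: ", a)
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

.read_annotation_arg <- function(path, fasta = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  seq <- if (!is.null(fasta)) {
    if (!file.exists(fasta)) stop("input file not found: ", fasta)
    read_fasta_sequence(fasta)
  } else NULL
  g <- if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE)) {
    gb <- parse_genbank(path)
    if (!is.null(seq)) gb$sequence <- seq
    gb
  } else {
    parse_feature_table(path, sequence = seq)
  }
  ## fall back to the file name as the report id
  if (!nzchar(g$organism) && !nzchar(g$accession))
    g$organism <- sub("\\.[^.]*$", "", basename(path))
  g
}

#' Command-line entry point
#'
#' Subcommands: `report`, `arch`, `skew`, `ncr`, `simulate`, `lba`.
#' Intended to be driven by the `inst/cli/mitoskew` Rscript wrapper;
#' callable directly for testing.
#'
#' @param argv Character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (0 ok, 1 runtime error,
#'   2 usage error).
#' @export
main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L || argv[1L] %in% c("--help", "-h", "help")) {
    cat(.cli_usage, "\n")
    return(invisible(0L))
  }
  if (argv[1L] == "--version") {
    cat("mitoskew", as.character(utils::packageVersion("mitoskew")), "\n")
    return(invisible(0L))
  }
  cmd <- argv[1L]
  known <- c("report", "arch", "skew", "ncr", "simulate", "lba")
  if (!(cmd %in% known)) {
    message("unknown command: ", cmd, "\n", .cli_usage)
    return(invisible(2L))
  }
  parsed <- tryCatch(.cli_parse(argv[-1L]), error = function(e) e)
  if (inherits(parsed, "error")) {
    message("error: ", conditionMessage(parsed))
    return(invisible(2L))
  }
  o <- parsed$opts
  status <- tryCatch({
    switch(cmd,
      report = , arch = {
        if (!length(parsed$pos)) stop("no input annotations given")
        anns <- lapply(parsed$pos, .read_annotation_arg,
                       fasta = if (cmd == "report") o$fasta else NULL)
        rep <- run_genome_report(anns, out_dir = o$out,
                                 epsilon = o$epsilon,
                                 min_ncr = as.integer(o$min_ncr),
                                 flank = as.integer(o$flank),
                                 min_stem = as.integer(o$min_stem))
        print(rep)
      },
      skew = {
        if (!length(parsed$pos)) stop("no input annotation given")
        g <- .read_annotation_arg(parsed$pos[1L], fasta = o$fasta)
        if (is.null(g$sequence)) stop("skew needs a sequence (--fasta)")
        p <- skew_profile(g, epsilon = o$epsilon)
        print(p)
        jsonlite::write_json(
          list(pattern = p$pattern,
               at_skew = unname(p$whole_genome[["at_skew"]]),
               gc_skew = unname(p$whole_genome[["gc_skew"]])),
          file.path(o$out, "skew_summary.json"), auto_unbox = TRUE,
          digits = NA)
      },
      ncr = {
        if (!length(parsed$pos)) stop("no input annotation given")
        g <- .read_annotation_arg(parsed$pos[1L], fasta = o$fasta)
        if (is.null(g$sequence)) stop("ncr scan needs a sequence (--fasta)")
        hits <- scan_ncr_trna_fragments(g, min_ncr = as.integer(o$min_ncr),
                                        flank = as.integer(o$flank),
                                        min_stem = as.integer(o$min_stem))
        utils::write.table(hits, file.path(o$out, "ncr_hits.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        cat(nrow(hits), "hit(s) written\n")
      },
      simulate = {
        if (is.null(o$seed)) stop("simulate needs --seed")
        g <- simulate_mitogenome(genome_sim_config(seed = o$seed))
        dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
        write_feature_table(g, file.path(o$out, "simulated_genome.tsv"))
        write_fasta(stats::setNames(g$sequence, "simulated_genome"),
                    file.path(o$out, "simulated_genome.fa"))
        cat("simulated", g$length, "bp genome written to", o$out, "\n")
      },
      lba = {
        if (is.null(o$seed)) stop("lba needs --seed")
        res <- run_outgroup_experiment(
          lba_default_config(seq_len = as.integer(o$length)),
          replicates = as.integer(o$replicates),
          seed = as.integer(o$seed))
        print(res)
        dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(as.data.frame(res),
                           file.path(o$out, "lba_result.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(as.data.frame(res),
                             file.path(o$out, "lba_result.json"),
                             digits = NA)
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
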