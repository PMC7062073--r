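test_that("feature table parsing recovers the printed isopod genome", {
  g <- asotana()
  expect_s3_class(g, "mito_annotation")
  expect_equal(g$length, 14435L)            # max end = CR end
  expect_equal(nrow(g$features), 35L)       # 34 genes + CR
  tab <- table(g$features$category)
  expect_equal(unname(tab[["tRNA"]]), 19L)
  expect_equal(unname(tab[["PCG"]]), 13L)
  expect_equal(unname(tab[["rRNA"]]), 2L)
  ## recomputed sizes take precedence: nad5 printed size is consistent
  nad5 <- g$features[g$features$name == "nad5", ]
  expect_equal(nad5$end - nad5$start + 1L, 1692L)
  expect_equal(nad5$size_printed, 1692L)
  ## the two known printed discrepancies surface as a warning
  expect_warning(
    parse_feature_table(system.file("extdata", "asotana_magnifica_mito.tsv",
                                    package = "mitoskew")),
    "nad1.*printed 948, span 921")
  ## CR span vs printed size: both numbers are reported, not reconciled
  cr <- g$features[g$features$category == "CR", ]
  expect_equal(cr$end - cr$start + 1L, 476L)
  expect_equal(cr$size_printed, 475L)
})

test_that("feature table round-trips gene/from/to/strand exactly", {
  g <- asotana()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(g, path)
  g2 <- suppressWarnings(parse_feature_table(path))
  for (col in c("name", "start", "end", "strand"))
    expect_equal(g2$features[[col]], g$features[[col]])
  ## size inconsistency in input triggers a row-naming warning
  expect_warning(
    parse_feature_table(c("gene\tfrom\tto\tsize\tstrand",
                          "cox1\t1\t90\t91\t+",
                          "trnA\t95\t160\t66\t+")),
    "cox1")
})

test_that("GenBank parsing handles strands, joins and real layouts", {
  simple <- toy_annotation(list("cox1", 1, 30, "+"), list("cox2", 41, 70, "+"),
                           length = 80)
  g <- parse_genbank(genbank_text(simple))
  expect_equal(nrow(g$features), 2L)
  expect_equal(g$organism, "Synthetica testii")
  expect_equal(g$accession, "SYN00001")
  expect_true(g$circular)
  expect_equal(spacers(g)$spacer[1L], 10L)

  ## complement location -> minus strand, coordinates untouched
  txt <- c("LOCUS       X 200 bp DNA circular",
           "FEATURES             Location/Qualifiers",
           "     gene            complement(100..160)",
           "                     /gene=\"nad5\"",
           "//")
  g2 <- parse_genbank(txt)
  expect_equal(g2$features$strand, "-")
  expect_equal(g2$features$start, 100L)
  expect_equal(g2$features$end, 160L)

  ## origin-spanning join
  txt3 <- c("LOCUS       X 100 bp DNA circular",
            "FEATURES             Location/Qualifiers",
            "     gene            join(90..100,1..20)",
            "                     /gene=\"rrnS\"",
            "//")
  g3 <- parse_genbank(txt3)
  expect_true(g3$features$wraps_origin)
  expect_equal(c(g3$features$start, g3$features$end), c(90L, 20L))

  ## a record reproducing the full printed table -> 34 genes + CR
  full <- parse_genbank(genbank_text(asotana()))
  expect_equal(nrow(full$features), 35L)
  expect_equal(sum(full$features$category == "CR"), 1L)
  expect_equal(full$features$name[order(full$features$start)],
               asotana()$features$name)

  ## malformed location names the feature; multiple records refused
  bad <- c("LOCUS       X 100 bp DNA circular",
           "FEATURES             Location/Qualifiers",
           "     gene            12..x9",
           "                     /gene=\"cox3\"", "//")
  expect_error(parse_genbank(bad), "cox3")
  expect_error(parse_genbank(c(genbank_text(simple),
                               genbank_text(simple))),
               "multiple LOCUS")
})

test_that("gene-name canonicalization covers the common dialects", {
  expect_equal(canonical_gene_name(c("COI", "ND5", "s-rRNA", "D-loop",
                                     "nad4 L", "CYTB", "atp6")),
               c("cox1", "nad5", "rrnS", "CR", "nad4l", "cytb", "atp6"))
  ## leucine/serine tRNAs disambiguated by anticodon
  expect_equal(canonical_gene_name("tRNA-Leu", "TAG"), "trnL1")
  expect_equal(canonical_gene_name("tRNA-Leu", "UAA"), "trnL2")
  expect_equal(canonical_gene_name("tRNA-Ser", "TGA"), "trnS2")
  expect_equal(canonical_gene_name("tRNA-Trp"), "trnW")
})

test_that("feature sequence extraction orients and wraps correctly", {
  g <- toy_annotation(list("a", 1, 3, "+"), list("b", 4, 6, "-"),
                      sequence = "AAACCC")
  expect_equal(extract_feature_sequence(g, "a"), "AAA")
  expect_equal(extract_feature_sequence(g, "b"), "GGG")
  gw <- mito_annotation(
    data.frame(name = "x", start = 5, end = 2, strand = "+",
               wraps_origin = TRUE),
    length = 6, sequence = "AATTGG")
  expect_equal(extract_feature_sequence(gw, "x"), "GGAA")
  expect_error(extract_feature_sequence(asotana(), "cox1"), "no sequence")
})

test_that("extraction properties: length and reverse-complement involution", {
  set.seed(101)
  g <- simulate_mitogenome(genome_sim_config(seed = 11))
  f <- g$features
  mirror <- mito_annotation(
    data.frame(name = f$name,
               start = g$length - f$end + 1L,
               end = g$length - f$start + 1L,
               strand = ifelse(is.na(f$strand), NA,
                               ifelse(f$strand == "+", "-", "+")),
               stringsAsFactors = FALSE)[!f$wraps_origin, ],
    length = g$length, sequence = revcomp(g$sequence))
  for (i in sample(nrow(f), 10L)) {
    s <- extract_feature_sequence(g, i)
    span <- if (f$wraps_origin[i])
      g$length - f$start[i] + 1L + f$end[i] else f$end[i] - f$start[i] + 1L
    expect_equal(nchar(s), span)
    if (!f$wraps_origin[i] && !is.na(f$strand[i]))
      expect_equal(extract_feature_sequence(mirror, f$name[i]), s)
  }
})
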