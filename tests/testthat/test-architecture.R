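test_that("spacer arithmetic matches the printed IGR column", {
  g <- asotana()
  sp <- spacers(g)
  expect_equal(nrow(sp), 35L)               # one record per adjacency
  expect_equal(sum(sp$spacer < 0), 14L)     # the 14 gene overlaps
  expect_equal(sp$spacer[sp$upstream == "trnK"], 7L)   # trnK -> trnD
  ## every recomputed spacer equals the printed IGR of the downstream row
  f <- g$features
  printed <- f$igr_printed[match(sp$downstream, f$name)]
  comparable <- !is.na(printed)
  expect_true(all(sp$spacer[comparable] == printed[comparable]))
  ## global vs PCG-restricted maxima: the 9-bp tRNA overlaps coexist
  ## with the 7-bp largest PCG-PCG overlaps
  expect_equal(min(sp$spacer), -9L)
  pcg <- f$name[f$category == "PCG"]
  pcg_pairs <- sp$upstream %in% pcg & sp$downstream %in% pcg
  expect_equal(min(sp$spacer[pcg_pairs]), -7L)

  expect_equal(spacers(toy_annotation(list("a", 1, 10, "+"),
                                      list("b", 11, 20, "+"),
                                      length = 30))$spacer[1L], 0L)
})

test_that("NCR catalog reproduces the printed counts and is monotone", {
  g <- asotana()
  cat1 <- ncr_catalog(g)
  expect_equal(nrow(cat1), 12L)
  expect_equal(sum(cat1$kind == "control_region"), 1L)
  big <- cat1[cat1$length > 10L, ]
  expect_equal(nrow(big), 4L)
  expect_setequal(big$length[big$kind == "intergenic"], c(41L, 34L, 69L))
  ## monotone non-increasing in min_len
  counts <- vapply(c(1L, 5L, 10L, 35L, 80L),
                   function(L) nrow(ncr_catalog(g, min_len = L)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  ## all features abutting, no CR -> empty catalog
  abut <- toy_annotation(list("a", 1, 10, "+"), list("b", 11, 20, "-"),
                         list("c", 21, 30, "+"), length = 30)
  expect_equal(nrow(ncr_catalog(abut)), 0L)
})

test_that("genome length partitions into features plus spacers", {
  check_partition <- function(g) {
    sp <- spacers(g)
    spans <- ifelse(g$features$wraps_origin,
                    g$length - g$features$start + 1L + g$features$end,
                    g$features$end - g$features$start + 1L)
    expect_equal(sum(spans) + sum(sp$spacer), g$length)
  }
  check_partition(asotana())
  check_partition(simulate_mitogenome(genome_sim_config(seed = 5)))
})

test_that("gene orders are rotation-invariant with signed labels", {
  g <- asotana()
  o <- gene_order(g)
  expect_length(o$labels, 34L)              # CR excluded by default
  expect_equal(head(paste0(ifelse(o$strand == "-", "-", ""), o$labels), 3),
               c("-trnL1", "-trnL2", "-trnS1"))
  expect_length(gene_order(g, include_cr = TRUE)$labels, 35L)
  ## rotation: start the same annotation at cox1
  f <- g$features[g$features$category != "CR", ]
  shift <- function(v, k) c(v[k:length(v)], v[seq_len(k - 1L)])
  k <- which(f$name == "cox1")
  rot <- structure(list(labels = shift(f$name, k),
                        strand = shift(f$strand, k), id = "rot"),
                   class = "gene_order")
  expect_true(gene_order_equal(o, rot))
  expect_equal(breakpoint_distance(o, rot), 0L)
  ## single gene
  expect_length(gene_order(toy_annotation(list("cox1", 1, 9, "+")))$labels, 1L)
  dup <- toy_annotation(list("cox1", 1, 9, "+"), list("cox1", 20, 29, "+"),
                        length = 40)
  expect_error(gene_order(dup), "duplicate")
})

test_that("adjacency sets normalize (a,b) == (-b,-a)", {
  o <- structure(list(labels = c("a", "b", "c"),
                      strand = c("+", "+", "+"), id = "t"),
                 class = "gene_order")
  expect_setequal(adjacency_set(o), c("+a|+b", "+b|+c", "+c|+a"))
  o2 <- structure(list(labels = c("a", "b", "c"),
                       strand = c("+", "-", "+"), id = "t"),
                  class = "gene_order")
  ## (a,-b) is equivalent to (b,-a); one canonical form must appear
  s <- adjacency_set(o2)
  expect_true(("+a|-b" %in% s) != ("+b|-a" %in% s))
  ## rotations give identical sets
  o3 <- structure(list(labels = c("c", "a", "b"),
                       strand = c("+", "+", "+"), id = "t"),
                  class = "gene_order")
  expect_setequal(adjacency_set(o), adjacency_set(o3))
})

test_that("breakpoint distance: worked example, symmetry, pseudometric", {
  mk <- function(labels, strand, id = "x")
    structure(list(labels = labels, strand = strand, id = id),
              class = "gene_order")
  o1 <- mk(letters[1:4], rep("+", 4))
  o2 <- mk(letters[1:4], c("+", "-", "+", "+"))
  ## hand enumeration: o1 = {ab, bc, cd, da}; o2 = {a(-b), (-b)c, cd, da}
  ## -> exactly ab and bc are missing from o2
  expect_equal(breakpoint_distance(o1, o2), 2L)
  expect_equal(breakpoint_distance(o1, o1), 0L)
  ## symmetry and triangle inequality over random 10-label orders
  set.seed(42)
  for (rep in 1:20) {
    x <- random_order(10); y <- random_order(10); z <- random_order(10)
    y$labels <- sample(x$labels); z$labels <- sample(x$labels)
    dxy <- breakpoint_distance(x, y)
    expect_equal(dxy, breakpoint_distance(y, x))
    expect_lte(dxy, breakpoint_distance(x, z) + breakpoint_distance(z, y))
  }
  ## shared-label restriction drops missing tRNAs with a warning
  o4 <- mk(c("a", "b", "c", "e"), rep("+", 4))
  expect_warning(d <- breakpoint_distance(o1, o4), "dropped")
  expect_equal(d, breakpoint_distance(mk(letters[1:3], rep("+", 3)),
                                      mk(letters[1:3], rep("+", 3))))
  expect_error(breakpoint_distance(o1, mk(c("x", "y"), c("+", "+"))),
               "no shared")
})

test_that("order uniqueness against comparator sets", {
  g <- asotana()
  o <- gene_order(g, id = "self")
  expect_false(is_unique_order(o, list(o))$unique)
  ## rotated copy is equal, hence not unique
  rot <- o
  rot$labels <- c(o$labels[5:34], o$labels[1:4])
  rot$strand <- c(o$strand[5:34], o$strand[1:4])
  expect_false(is_unique_order(o, list(rot))$unique)
  ## shuffled variants each differing by at least one inversion
  set.seed(7)
  variants <- lapply(1:5, function(i) {
    v <- o
    k <- sort(sample(34, 2))
    idx <- k[1]:k[2]
    v$labels[idx] <- rev(v$labels[idx])
    v$strand[idx] <- chartr("+-", "-+", rev(v$strand[idx]))
    v$id <- paste0("var", i)
    v
  })
  res <- is_unique_order(o, variants)
  expect_true(res$unique)
  expect_gt(res$min_distance, 0)
  expect_true(res$nearest %in% paste0("var", 1:5))
})
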