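## Independent oracles used by the property and acceptance tests.
## These deliberately avoid the package's own code paths.

## edge-indicator least-squares fit of branch lengths for a fixed
## topology; returns the residual sum of squares
ls_rss <- function(topology, d) {
  tips <- rownames(d)
  nt <- length(tips)
  edges <- topology$edge
  ## tip set below each edge, by recursion over ape's edge table
  below <- function(node) {
    if (node <= nt) return(topology$tip.label[node])
    unlist(lapply(edges[edges[, 1] == node, 2], below))
  }
  pairs <- t(combn(seq_len(nt), 2))
  A <- matrix(0, nrow(pairs), nrow(edges))
  y <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- tips[pairs[p, 1]]; j <- tips[pairs[p, 2]]
    for (e in seq_len(nrow(edges))) {
      side <- below(edges[e, 2])
      A[p, e] <- (i %in% side) != (j %in% side)
    }
    y[p] <- d[i, j]
  }
  fit <- stats::lm.fit(A, y)
  sum(fit$residuals^2)
}

## brute-force least-squares topology search over all unrooted
## topologies (4-5 taxa); returns the best phylo
ls_best_topology <- function(d) {
  tips <- rownames(d)
  all_t <- phangorn::allTrees(length(tips), rooted = FALSE,
                              tip.label = tips)
  rss <- vapply(all_t, ls_rss, numeric(1), d = d)
  all_t[[which.min(rss)]]
}

## brute-force bipartition enumeration: all split sides of an unrooted
## tree via ape::prop.part (independent of the package's postorder
## code), returned as sorted label vectors
oracle_splits <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sides <- lapply(pp, function(idx) sort(labs[idx]))
  c(sides, lapply(sides, function(s) sort(setdiff(labs, s))))
}

## oracle clade test: taxa form a clade iff taxa (or their complement)
## is one of the enumerated split sides
oracle_is_clade <- function(tree, taxa) {
  target <- sort(taxa)
  any(vapply(oracle_splits(tree), identical, logical(1), y = target))
}

## oracle RF via phangorn
oracle_rf <- function(t1, t2) phangorn::RF.dist(t1, t2)
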