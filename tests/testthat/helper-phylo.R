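# Independent oracles for the phylogeny module.

# random unrooted binary tree with positive branch lengths
random_additive_tree <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   tip.label = paste0("t", seq_len(n_taxa)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  tr
}

tree_distances <- function(tr) {
  D <- ape::cophenetic.phylo(tr)
  D[order(rownames(D)), order(colnames(D))]
}

# exhaustive least-squares topology search: fit branch lengths to every
# unrooted topology by unconstrained LS on the path-indicator design matrix,
# return the minimum-RSS topology
ls_best_topology <- function(D) {
  taxa <- rownames(D)
  cand <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  pairs <- t(utils::combn(length(taxa), 2))
  d_vec <- D[pairs]
  best <- NULL; best_rss <- Inf
  # NB: index with [[ so the multiPhylo container re-attaches tip labels
  for (k_tr in seq_along(cand)) {
    tr <- cand[[k_tr]]
    ne <- nrow(tr$edge)
    X <- matrix(0, nrow(pairs), ne)
    for (r in seq_len(nrow(pairs))) {
      i <- match(taxa[pairs[r, 1]], tr$tip.label)
      j <- match(taxa[pairs[r, 2]], tr$tip.label)
      path_nodes <- ape::nodepath(tr, i, j)
      for (s in seq_len(length(path_nodes) - 1)) {
        e <- which((tr$edge[, 1] == path_nodes[s] & tr$edge[, 2] == path_nodes[s + 1]) |
                     (tr$edge[, 2] == path_nodes[s] & tr$edge[, 1] == path_nodes[s + 1]))
        X[r, e] <- 1
      }
    }
    fit <- stats::lm.fit(X, d_vec)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- tr }
  }
  list(tree = best, rss = best_rss)
}

same_topology <- function(a, b) {
  isTRUE(all.equal(ape::dist.topo(a, b)[[1]], 0))
}
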