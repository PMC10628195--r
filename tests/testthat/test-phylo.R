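test_that("jc_distance matches the closed form and flags saturation", {
  set.seed(80)
  # identical rows are at distance zero
  aln <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  expect_equal(jc_distance(aln)["a", "b"], 0)
  # random pairs agree with an independent recomputation to 1e-12
  for (i in 1:20) {
    s1 <- random_dna(2000)
    s2 <- mutate_branch(s1, runif(1, 0.01, 0.4), seed = 800 + i)
    D <- jc_distance(c(x = s1, y = s2))
    p <- mean(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
    expect_equal(D["x", "y"], -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)
  }
  # gapped/ambiguous columns are excluded from p
  g <- c(a = "ACGT-NACGT", b = "ACGAAAACGT")
  p <- 1 / 8
  expect_equal(jc_distance(g)["a", "b"], -0.75 * log(1 - 4 * p / 3))
  # saturation errors
  s1 <- random_dna(1000)
  s2 <- mutate_branch(s1, 0.95, seed = 3)
  expect_error(jc_distance(c(x = s1, y = s2)), "saturated")
})

test_that("NJ reproduces additive distances exactly", {
  for (s in 1:5) {
    tr <- random_additive_tree(4, seed = 90 + s)
    D <- tree_distances(tr)
    nj <- nj_tree(D)
    expect_true(same_topology(nj, tr))
    Dhat <- ape::cophenetic.phylo(nj)[rownames(D), colnames(D)]
    expect_equal(Dhat, D, tolerance = 1e-9)
  }
})

test_that("three taxa are resolved by the closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  bl <- stats::setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(bl[["a"]], 1)   # (3+4-5)/2
  expect_equal(bl[["b"]], 2)
  expect_equal(bl[["c"]], 3)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ agrees with exhaustive least-squares topology search", {
  skip_if_not_installed("phangorn")
  for (n in c(4, 5)) {
    for (s in 1:8) {
      tr <- random_additive_tree(n, seed = 100 * n + s)
      D <- tree_distances(tr)
      nj <- nj_tree(D)
      ls <- ls_best_topology(D)
      expect_true(same_topology(nj, ls$tree),
                  label = sprintf("n=%d seed=%d", n, s))
      expect_lt(ls$rss, 1e-12)
    }
  }
})

test_that("degenerate equal distances resolve deterministically", {
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  t1 <- nj_tree(D); t2 <- nj_tree(D)
  expect_s3_class(t1, "phylo")
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("bootstrap is deterministic, optional, and saturates on signal", {
  set.seed(81)
  anc0 <- random_dna(3000)                     # hierarchical, clean signal
  anc1 <- mutate_branch(anc0, 0.05, seed = 3)
  proto <- mutate_branch(anc1, 0.04, seed = 4)
  aln <- c(X = mutate_branch(anc0, 0.08, seed = 1),
           Y = mutate_branch(anc1, 0.01, seed = 2),
           Z = mutate_branch(proto, 0.01, seed = 5),
           W = mutate_branch(proto, 0.01, seed = 6),
           OUT = mutate_branch(anc0, 0.20, seed = 7))
  t0 <- bootstrap_support(aln, B = 0)
  expect_null(t0$node.label)
  ta <- bootstrap_support(aln, B = 100, seed = 42)
  tb <- bootstrap_support(aln, B = 100, seed = 42)
  expect_identical(ta$node.label, tb$node.label)
  sup <- suppressWarnings(as.numeric(ta$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))   # divergence >> noise
})

test_that("monophyly is read correctly from informative topologies", {
  yes <- ape::read.tree(text = "((Y:1,(Z:1,W:1):1):1,(X:1,O:1):1);")
  no <- ape::read.tree(text = "((X:1,(Z:1,W:1):1):1,(Y:1,O:1):1);")
  m1 <- test_monophyly(yes, c("Y", "Z", "W"), "O")
  expect_true(m1$monophyletic)
  m2 <- test_monophyly(no, c("Y", "Z", "W"), "O")
  expect_false(m2$monophyletic)
  m3 <- test_monophyly(no, c("X", "Z", "W"), "O")
  expect_true(m3$monophyletic)
  # complement of size 1 is vacuously monophyletic with support NA
  q <- ape::read.tree(text = "((Y,Z),(W,X));")
  m4 <- test_monophyly(q, c("Y", "Z", "W"), "X")
  expect_true(m4$monophyletic)
  expect_true(is.na(m4$support))
  expect_error(test_monophyly(yes, c("Y", "Q"), "O"), "absent")
})

test_that("the verdict combines counts and monophyly as specified", {
  tree_y <- ape::read.tree(text = "((Y:1,(Z:1,W:1):1):1,(X:1,OUT:1):1);")
  tree_y$node.label <- c("", "95", "99", "88")
  mk_trace <- function(nY, nX) {
    list(totals = data.frame(target = "W", n_loci = nY + nX + 2,
                             n_placed = nY + nX, n_Y_match = nY,
                             n_X_match = nX, n_neither = 0, n_unplaced = 2))
  }
  # the headline regime: 28 Y-matches, 0 X-matches, monophyly supported
  v <- w_origin_verdict(mk_trace(28, 0), tree_y)
  expect_equal(v$verdict, "W_from_Y")
  expect_lt(v$evidence$binomial_p, 1e-6)
  # symmetric counts are undetermined regardless of the tree
  expect_equal(w_origin_verdict(mk_trace(10, 10), tree_y)$verdict,
               "undetermined")
  # zero informative loci
  expect_equal(w_origin_verdict(mk_trace(0, 0), tree_y)$verdict,
               "undetermined")
  # mirrored evidence gives the mirrored verdict
  tree_x <- ape::read.tree(text = "((X:1,(Z:1,W:1):1):1,(Y:1,OUT:1):1);")
  tree_x$node.label <- c("", "95", "99", "88")
  expect_equal(w_origin_verdict(mk_trace(0, 28), tree_x)$verdict, "W_from_X")
  # counts without tree support stay undetermined
  # (node.label order follows ape node numbering: root, {Y,Z,W}, {Z,W}, {X,OUT})
  weak <- tree_y; weak$node.label <- c("", "40", "95", "88")
  expect_equal(w_origin_verdict(mk_trace(28, 0), weak)$verdict, "undetermined")
})

test_that("each planted duplicate has a single origin on the Y/Z clade", {
  sim <- simulate_transition(transition_scenario(seed = 9))
  q <- sim$query_gene[[1]]
  td <- sim$truth$duplicates
  for (i in seq_len(nrow(td))) {
    ycopy <- substring(sim$haplotypes[["Y"]], td$y_start[i] + 1, td$y_end[i])
    zcopy <- substring(sim$haplotypes[["Z"]], td$z_start[i] + 1, td$z_end[i])
    if (td$strand[i] == "-") {
      ycopy <- heterotrace:::revcomp(ycopy)
      zcopy <- heterotrace:::revcomp(zcopy)
    }
    gene_frag <- substring(q, td$q_start[i], td$q_end[i] - 1)
    out_frag <- mutate_branch(gene_frag, 0.02, seed = 900 + i)
    aln <- c(Ycopy = ycopy, Zcopy = zcopy,
             W_gene = gene_frag, OUT_gene = out_frag)
    tr <- nj_tree(jc_distance(aln))
    m <- test_monophyly(tr, c("Ycopy", "Zcopy"), "OUT_gene")
    expect_true(m$monophyletic, label = sprintf("duplicate %d", i))
  }
})
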