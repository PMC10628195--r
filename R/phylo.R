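# Jukes-Cantor distances, neighbor-joining, column bootstrap, monophyly
# testing, and the W-origin verdict.

#' Coerce sequences to an aligned character matrix
#' @param x named character vector of equal-length sequences, or a character
#'   matrix with taxon rownames.
#' @return character matrix (rows = taxa).
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    stopifnot(!is.null(rownames(x)))
    return(x)
  }
  stopifnot(!is.null(names(x)), length(unique(nchar(x))) == 1)
  mat <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
  rownames(mat) <- names(x)
  mat
}

#' Jukes-Cantor pairwise distances
#'
#' For each pair, `p` is the mismatch fraction over columns where both rows
#' carry a plain base (no `-`/`N`), and `d = -(3/4) log(1 - (4/3) p)`.
#' Saturated pairs (`p >= 0.75`) raise an error naming the pair.
#'
#' @param x alignment acceptable to [as_alignment()].
#' @return symmetric numeric distance matrix.
#' @export
jc_distance <- function(x) {
  mat <- as_alignment(x)
  n <- nrow(mat)
  if (n < 2) stop("need >= 2 taxa", call. = FALSE)
  plain <- mat %in% DNA_BASES
  dim(plain) <- dim(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- plain[i, ] & plain[j, ]
    if (!any(ok)) stop("no comparable columns for pair", call. = FALSE)
    p <- mean(mat[i, ok] != mat[j, ok])
    if (p >= 0.75) {
      stop(sprintf("saturated pair %s/%s (p = %.3f >= 0.75)",
                   rownames(mat)[i], rownames(mat)[j], p), call. = FALSE)
    }
    D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  D
}

#' Neighbor-joining tree
#'
#' Classic NJ on a symmetric distance matrix; on additive distances the
#' returned tree reproduces the input path lengths exactly. Ties in the
#' Q-criterion are broken by taxon order as given (first minimal pair in
#' row-major order), which makes the degenerate equal-distance case
#' deterministic.
#'
#' @param D symmetric numeric distance matrix with taxon dimnames (>= 3
#'   taxa).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(D)
  if (n < 3) stop("need >= 3 taxa", call. = FALSE)
  labs <- rownames(D)
  frags <- labs                  # newick fragment per active node
  d <- D
  while (length(frags) > 3) {
    r <- length(frags)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    sel <- which(ij[, 1] < ij[, 2])[1]
    i <- ij[sel, 1]; j <- ij[sel, 2]
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frags[i], bi, frags[j], bj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frags <- c(frags[keep], newfrag)
    d <- d2
  }
  if (length(frags) == 3) {
    b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                   frags[1], b1, frags[2], b2, frags[3], b3)
  } else {
    nwk <- sprintf("(%s:%.10g,%s:%.10g);", frags[1], d[1, 2] / 2,
                   frags[2], d[1, 2] / 2)
  }
  ape::read.tree(text = nwk)
}

# canonical keys of the non-trivial bipartitions of an unrooted tree:
# each internal edge splits the tips; the side not containing the first
# taxon (alphabetically) is sorted and collapsed with "|"
bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  pp <- ape::prop.part(tree)
  keys <- character(0); nodes <- integer(0)
  for (k in seq_along(pp)) {
    clade <- tree$tip.label[pp[[k]]]
    if (length(clade) <= 1 || length(clade) >= length(tips) - 1) next
    side <- if (anchor %in% clade) setdiff(tips, clade) else clade
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, length(tree$tip.label) + k)
  }
  list(keys = keys, nodes = nodes)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the NJ
#' tree per replicate, and reports, for each internal bipartition of the
#' original tree, the percentage of replicates containing it. Supports are
#' stored in `tree$node.label` (empty for the basal node) and rounded to
#' integers. `B = 0` returns the point tree with supports unset. Within
#' bootstrap replicates a saturated mismatch fraction is capped just below
#' 0.75 rather than erroring.
#'
#' @param x alignment acceptable to [as_alignment()].
#' @param B number of bootstrap replicates (default 100).
#' @param seed optional RNG seed (stream-local).
#' @return `ape::phylo` with integer `node.label` supports.
#' @export
bootstrap_support <- function(x, B = 100, seed = NULL) {
  mat <- as_alignment(x)
  base <- nj_tree(jc_distance(mat))
  if (B == 0) return(base)
  n <- nrow(mat)
  plain <- mat %in% DNA_BASES
  dim(plain) <- dim(mat)
  pairs <- utils::combn(n, 2)
  # per-column usable/mismatch indicators per pair, for fast resampling
  ok_l <- list(); mm_l <- list()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ok_l[[k]] <- plain[i, ] & plain[j, ]
    mm_l[[k]] <- ok_l[[k]] & (mat[i, ] != mat[j, ])
  }
  bp0 <- bipartitions(base)
  counts <- stats::setNames(rep(0L, length(bp0$keys)), bp0$keys)
  run <- function() {
    nc <- ncol(mat)
    for (b in seq_len(B)) {
      idx <- sample.int(nc, nc, replace = TRUE)
      D <- matrix(0, n, n, dimnames = dimnames(mat)[c(1, 1)])
      rownames(D) <- colnames(D) <- rownames(mat)
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1, k]; j <- pairs[2, k]
        no <- sum(ok_l[[k]][idx])
        p <- if (no == 0) 0 else sum(mm_l[[k]][idx]) / no
        p <- min(p, 0.7499)
        D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
      }
      bt <- nj_tree(D)
      kb <- bipartitions(bt)$keys
      hit <- bp0$keys %in% kb
      counts[hit] <<- counts[hit] + 1L
    }
  }
  if (is.null(seed)) run() else with_seed(seed, run())
  supp <- round(100 * counts / B)
  lab <- rep("", base$Nnode)
  lab[bp0$nodes - length(base$tip.label)] <- as.character(supp)
  base$node.label <- lab
  base
}

#' Test monophyly of an ingroup with respect to an outgroup
#'
#' The ingroup is monophyletic iff rooting on the outgroup yields a clade
#' containing exactly the ingroup, i.e. iff the unrooted tree contains the
#' bipartition ingroup | complement. When the complement has at most one
#' taxon the bipartition is trivial: monophyly is vacuously `TRUE` and the
#' support is `NA` (use a matrix with an outgroup plus at least one further
#' taxon outside the ingroup for an informative test).
#'
#' @param tree `ape::phylo`, optionally with bootstrap `node.label`s.
#' @param ingroup character vector of ingroup taxa.
#' @param outgroup single outgroup taxon (must not be in `ingroup`).
#' @return list with `monophyletic`, `support` (numeric or `NA`) and
#'   `bipartition` (canonical key).
#' @export
test_monophyly <- function(tree, ingroup, outgroup) {
  taxa <- tree$tip.label
  missing <- setdiff(c(ingroup, outgroup), taxa)
  if (length(missing)) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (outgroup %in% ingroup) stop("outgroup inside ingroup", call. = FALSE)
  comp <- setdiff(taxa, ingroup)
  key <- {
    tips <- sort(taxa); anchor <- tips[1]
    side <- if (anchor %in% ingroup) sort(comp) else sort(ingroup)
    paste(side, collapse = "|")
  }
  if (length(comp) <= 1) {
    return(list(monophyletic = TRUE, support = NA_real_, bipartition = key))
  }
  bp <- bipartitions(tree)
  hit <- match(key, bp$keys)
  if (is.na(hit)) {
    return(list(monophyletic = FALSE, support = NA_real_, bipartition = key))
  }
  supp <- NA_real_
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label[bp$nodes[hit] - length(tree$tip.label)]
    if (nzchar(lab)) supp <- as.numeric(lab)
  }
  list(monophyletic = TRUE, support = supp, bipartition = key)
}

#' Verdict on the origin of the W (and Z) haplotypes
#'
#' Combines two evidence lines: (i) an exact two-sided binomial test of the
#' Y-match vs X-match counts among loci placed on the W target (loci scored
#' `neither` are excluded), and (ii) monophyly of {Y, Z, W} (resp.
#' {X, Z, W}) with respect to the outgroup-rooted tree at bootstrap support
#' of at least `min_support`. The verdict is `W_from_Y` iff the binomial
#' test rejects 0.5 toward Y at `alpha` AND the {Y,Z,W} clade holds with
#' support; mirrored for `W_from_X`; otherwise `undetermined`.
#'
#' @param trace `trace_result` from [count_matches()] (must include a `W`
#'   target row; a `Z` row is reported when present).
#' @param tree bootstrap-annotated tree from [bootstrap_support()]
#'   containing taxa X, Y, Z, W and the outgroup.
#' @param taxa named character vector mapping roles `x`, `y`, `z`, `w`,
#'   `outgroup` to tip labels.
#' @param w_target name of the W row in `trace$totals`.
#' @param alpha binomial significance level (default 0.05).
#' @param min_support minimum bootstrap support (default 70).
#' @return list of class `w_origin_verdict` with `verdict` and an `evidence`
#'   report (JSON-serialisable).
#' @export
w_origin_verdict <- function(trace, tree,
                             taxa = c(x = "X", y = "Y", z = "Z", w = "W",
                                      outgroup = "OUT"),
                             w_target = "W", alpha = 0.05, min_support = 70) {
  tot <- trace$totals[trace$totals$target == w_target, , drop = FALSE]
  if (nrow(tot) != 1) stop("no W target in trace result", call. = FALSE)
  n_y <- tot$n_Y_match; n_x <- tot$n_X_match
  n <- n_y + n_x
  mono_y <- test_monophyly(tree, taxa[c("y", "z", "w")], taxa[["outgroup"]])
  mono_x <- test_monophyly(tree, taxa[c("x", "z", "w")], taxa[["outgroup"]])
  if (n == 0) {
    verdict <- "undetermined"; p <- NA_real_; reason <- "zero informative placed loci"
  } else {
    bt <- stats::binom.test(n_y, n, 0.5)
    p <- bt$p.value
    toward_y <- n_y > n_x && p <= alpha
    toward_x <- n_x > n_y && p <= alpha
    sup_ok <- function(m) isTRUE(m$monophyletic) && !is.na(m$support) &&
      m$support >= min_support
    verdict <- if (toward_y && sup_ok(mono_y)) "W_from_Y"
      else if (toward_x && sup_ok(mono_x)) "W_from_X"
      else "undetermined"
    reason <- if (verdict == "undetermined") {
      if (!toward_y && !toward_x) "allele counts do not reject symmetry"
      else "monophyly unsupported"
    } else "ok"
  }
  res <- list(
    verdict = verdict,
    evidence = list(
      n_Y_match_W = n_y, n_X_match_W = n_x,
      n_informative = n, binomial_p = p,
      monophyly_YZW = mono_y, monophyly_XZW = mono_x,
      alpha = alpha, min_support = min_support, reason = reason))
  class(res) <- "w_origin_verdict"
  res
}

#' @export
print.w_origin_verdict <- function(x, ...) {
  e <- x$evidence
  cat(sprintf("W-origin verdict: %s\n", x$verdict))
  cat(sprintf("  W target: %d Y-matches vs %d X-matches (binomial p = %.3g)\n",
              e$n_Y_match_W, e$n_X_match_W, e$binomial_p))
  cat(sprintf("  monophyly {Y,Z,W}: %s (support %s); {X,Z,W}: %s (support %s)\n",
              e$monophyly_YZW$monophyletic, e$monophyly_YZW$support,
              e$monophyly_XZW$monophyletic, e$monophyly_XZW$support))
  invisible(x)
}
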