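# Seed-and-extend detection of partial duplicates of a query gene, and
# pairing of homologous duplicates across chromosomes.

# rolling k-mer integer keys (base 4); NA where the window contains non-ACGT
kmer_keys <- function(v, w) {
  n <- length(v)
  if (n < w) return(integer(0))
  keys <- numeric(n - w + 1L)
  for (j in 0:(w - 1L)) {
    keys <- keys + v[(1L + j):(n - w + 1L + j)] * 4^(w - 1L - j)
  }
  keys
}

# best-scoring segment (Kadane via prefix sums, vectorised) of a +1/-2
# match/mismatch vector; among equal-score optima the longest (then
# leftmost) segment is chosen so trimming is symmetric under sequence
# reversal; returns c(start, end, matches) or NULL
best_segment <- function(mv) {
  sc <- ifelse(mv, 1, -2)
  S <- cumsum(sc)
  pref <- c(0, S[-length(S)])
  M <- cummin(pref)                 # best (lowest) prefix before each end
  gain <- S - M
  maxg <- max(gain)
  if (maxg <= 0) return(NULL)
  best <- NULL
  for (hi in which(gain == maxg)) {
    lo <- match(M[hi], pref[seq_len(hi)])
    len <- hi - lo + 1L
    if (is.null(best) || len > best[3]) best <- c(lo, hi, len)
  }
  c(best[1], best[2], sum(mv[best[1]:best[2]]))
}

# Karlin-Altschul ungapped significance for +1/-2 scoring on uniform base
# composition: lambda solves 0.25 e^l + 0.75 e^{-2l} = 1, giving
# e^lambda = (3 + sqrt(21))/2; K is approximated by the conventional
# blastn-scale constant.
KA_LAMBDA <- log((3 + sqrt(21)) / 2)
KA_K <- 0.62

min_hit_score <- function(nq, nt, evalue) {
  ceiling(log(KA_K * as.double(nq) * as.double(nt) / evalue) / KA_LAMBDA)
}

#' Scan a target sequence for (partial) duplicates of a query gene
#'
#' BLASTN-like seed-and-extend local search: exact `word`-mers seed
#' diagonals; each seeded diagonal is scored ungapped at +1/-2 and trimmed to
#' its maximal-scoring segment; hits shorter than `min_len`, below
#' `min_identity` percent identity, or below the Karlin-Altschul minimum
#' score implied by `evalue` (BLAST-style chance-hit control for the search
#' space) are dropped. Both strands are scanned.
#' Hits covering at least 90% of the query are labelled intact copies,
#' others partial duplicates. Overlapping hits from nearby diagonals are
#' deduplicated keeping the higher-scoring one.
#'
#' @param query query gene sequence (character scalar).
#' @param target target chromosome sequence (character scalar).
#' @param word seed length (default 8; short words trade speed for
#'   sensitivity to small diverged duplicates).
#' @param min_len minimum hit length (default 30).
#' @param min_identity minimum percent identity (default 70).
#' @param evalue expected number of chance hits tolerated for the search
#'   space (default 1e-6); converted to a minimum segment score.
#' @param target_name label recorded in the hit table.
#' @return data.frame of class `duplicate_hits`: `target`, `t_start`,
#'   `t_end` (0-based half-open), `strand`, `q_start`, `q_end` (query
#'   coordinates, 0-based half-open, forward orientation), `length`,
#'   `identity` (percent), `intact`, `seq` (hit sequence in query
#'   orientation).
#' @export
scan_duplicates <- function(query, target, word = 8, min_len = 30,
                            min_identity = 70, evalue = 1e-6,
                            target_name = "target") {
  nq <- nchar(query); nt <- nchar(target)
  if (nq < word) stop("query shorter than seed word", call. = FALSE)
  score_min <- min_hit_score(nq, nt, evalue)
  tv <- seq_to_int(target)
  tkeys <- kmer_keys(tv, word)
  hits <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") query else revcomp(query)
    qv <- seq_to_int(qs)
    qkeys <- kmer_keys(qv, word)
    dq <- data.table::data.table(kmer = qkeys, qpos = seq_along(qkeys))
    dt <- data.table::data.table(kmer = tkeys, tpos = seq_along(tkeys))
    dq <- dq[!is.na(dq$kmer), ]; dt <- dt[!is.na(dt$kmer), ]
    seeds <- merge(dq, dt, by = "kmer", allow.cartesian = TRUE)
    if (nrow(seeds) == 0) next
    for (dg in unique(seeds$tpos - seeds$qpos)) {
      qlo <- max(1L, 1L - dg); qhi <- min(nq, nt - dg)
      if (qhi - qlo + 1L < word) next
      qr <- qlo:qhi
      mv <- qv[qr] == tv[qr + dg]
      mv[is.na(mv)] <- FALSE
      seg <- best_segment(mv)
      if (is.null(seg)) next
      q1 <- qlo + seg[1] - 1L; q2 <- qlo + seg[2] - 1L
      len <- q2 - q1 + 1L
      ident <- 100 * seg[3] / len
      score <- seg[3] - 2L * (len - seg[3])
      if (len < min_len || ident < min_identity || score < score_min) next
      t1 <- q1 + dg; t2 <- q2 + dg
      # map minus-strand query coordinates back to forward orientation
      if (strand == "+") { qa <- q1; qb <- q2 } else {
        qa <- nq - q2 + 1L; qb <- nq - q1 + 1L
      }
      hits[[length(hits) + 1L]] <- data.frame(
        target = target_name,
        t_start = t1 - 1L, t_end = t2, strand = strand,
        q_start = qa - 1L, q_end = qb, length = len,
        identity = ident, score = seg[3] - 2L * (len - seg[3]),
        seq = if (strand == "+") substr(target, t1, t2)
              else revcomp(substr(target, t1, t2)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    res <- data.frame(target = character(), t_start = integer(),
                      t_end = integer(), strand = character(),
                      q_start = integer(), q_end = integer(),
                      length = integer(), identity = numeric(),
                      score = numeric(), seq = character(), intact = logical())
    class(res) <- c("duplicate_hits", "data.frame")
    return(res)
  }
  res <- do.call(rbind, hits)
  # dedupe: keep the best-scoring hit among target-overlapping ones
  res <- res[order(-res$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      ov <- min(res$t_end[i], res$t_end[j]) - max(res$t_start[i], res$t_start[j])
      if (ov > 0.5 * res$length[i]) { keep[i] <- FALSE; break }
    }
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$t_start), , drop = FALSE]
  res$intact <- (res$q_end - res$q_start) >= 0.9 * nq
  rownames(res) <- NULL
  class(res) <- c("duplicate_hits", "data.frame")
  res
}

#' Flag palindromic duplicate pairs on one chromosome
#'
#' Two intact copies on the same target whose strands oppose and whose
#' spacing is below `max_spacing` are flagged palindromic.
#'
#' @param hits `duplicate_hits` from [scan_duplicates()].
#' @param max_spacing maximum gap between the two copies (bp).
#' @return `hits` with a logical `palindromic` column.
#' @export
annotate_palindromes <- function(hits, max_spacing = 5000) {
  pal <- rep(FALSE, nrow(hits))
  idx <- which(hits$intact)
  if (length(idx) >= 2) {
    for (a in idx) for (b in idx) {
      if (a < b && hits$strand[a] != hits$strand[b]) {
        gap <- hits$t_start[b] - hits$t_end[a]
        if (gap >= 0 && gap < max_spacing) pal[c(a, b)] <- TRUE
      }
    }
  }
  hits$palindromic <- pal
  hits
}

#' Pair homologous duplicates across two chromosomes
#'
#' Greedy pairing by best inter-hit percent identity (global alignment of the
#' hit sequences, both taken in query orientation so strand is factored out).
#' Pairs below `min_identity` are not formed; each hit is used at most once.
#' A pair is flagged `same_length` when the two spans are equal; the overall
#' `order_orientation_preserved` flag is `TRUE` iff, with pairs sorted by
#' position on chromosome A, the positions on B are strictly increasing and
#' every pair's strands agree.
#'
#' @param hits_a,hits_b `duplicate_hits` for the two chromosomes.
#' @param min_identity minimum inter-hit percent identity (default 70).
#' @return list of class `duplicate_pairing` with `pairs` (data.frame) and
#'   `order_orientation_preserved`.
#' @export
pair_duplicates <- function(hits_a, hits_b, min_identity = 70) {
  empty <- data.frame(a = integer(), b = integer(), identity = numeric(),
                      same_length = logical(), strands_agree = logical())
  if (nrow(hits_a) == 0 || nrow(hits_b) == 0) {
    res <- list(pairs = empty, order_orientation_preserved = NA)
    class(res) <- "duplicate_pairing"
    return(res)
  }
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  idm <- matrix(NA_real_, nrow(hits_a), nrow(hits_b))
  for (i in seq_len(nrow(hits_a))) for (j in seq_len(nrow(hits_b))) {
    pa <- Biostrings::pairwiseAlignment(hits_a$seq[i], hits_b$seq[j],
                                        type = "global",
                                        substitutionMatrix = sub,
                                        gapOpening = 5, gapExtension = 2)
    idm[i, j] <- Biostrings::pid(pa)
  }
  pairs <- empty
  while (TRUE) {
    best <- which(idm == max(idm, na.rm = TRUE), arr.ind = TRUE)
    if (!nrow(best) || max(idm, na.rm = TRUE) < min_identity) break
    i <- best[1, 1]; j <- best[1, 2]
    pairs <- rbind(pairs, data.frame(
      a = i, b = j, identity = idm[i, j],
      same_length = hits_a$length[i] == hits_b$length[j],
      strands_agree = hits_a$strand[i] == hits_b$strand[j]))
    idm[i, ] <- NA; idm[, j] <- NA
    if (all(is.na(idm))) break
  }
  preserved <- NA
  if (nrow(pairs) >= 1) {
    o <- order(hits_a$t_start[pairs$a])
    bpos <- hits_b$t_start[pairs$b][o]
    preserved <- all(diff(bpos) > 0) && all(pairs$strands_agree)
  }
  res <- list(pairs = pairs, order_orientation_preserved = preserved)
  class(res) <- "duplicate_pairing"
  res
}
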