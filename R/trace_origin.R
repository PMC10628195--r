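# Placement of phased X/Y alleles onto a second species' Z and W haplotypes
# via flanking sequence, and allele-identity counting.

#' Extract flanking sequence around phased SDR alleles
#'
#' Returns up to `flank` bases on each side of every phased position, drawn
#' from the source reference; the focal base itself is excluded. Flanks are
#' truncated at sequence ends and the truncation recorded.
#'
#' @param reference named character vector of reference sequences (names are
#'   chromosome ids).
#' @param phased `phased_sdr_alleles` from [phase_sdr()].
#' @param flank flank length in bp (default 150).
#' @return data.frame of class `flanked_loci` with `chrom`, `pos`,
#'   `y_allele`, `x_allele`, `left_flank`, `right_flank`, `truncated`.
#' @export
extract_flanks <- function(reference, phased, flank = 150) {
  if (any(!phased$chrom %in% names(reference))) {
    stop("phased chromosome absent from reference", call. = FALSE)
  }
  len <- nchar(reference)[match(phased$chrom, names(reference))]
  if (any(phased$pos < 1 | phased$pos > len)) {
    stop("phased position outside reference sequence", call. = FALSE)
  }
  lo <- pmax(1L, phased$pos - flank)
  hi <- pmin(len, phased$pos + flank)
  seqs <- reference[match(phased$chrom, names(reference))]
  res <- data.frame(
    chrom = phased$chrom, pos = phased$pos,
    y_allele = phased$y_allele, x_allele = phased$x_allele,
    left_flank = substr(seqs, lo, phased$pos - 1L),
    right_flank = substr(seqs, phased$pos + 1L, hi),
    truncated = (phased$pos - lo < flank) | (hi - phased$pos < flank),
    stringsAsFactors = FALSE)
  class(res) <- c("flanked_loci", "data.frame")
  res
}

# precompute a target for repeated placements
prepare_target <- function(seq) {
  rc <- revcomp(seq)
  list(fwd = Biostrings::DNAString(seq), rc = Biostrings::DNAString(rc),
       fwd_int = utf8ToInt(seq), rc_int = utf8ToInt(rc), len = nchar(seq))
}

#' Place one flanked locus on a target haplotype
#'
#' The query `left_flank + N + right_flank` is located by exact k-mer seed
#' matching followed by ungapped comparison over the full query, on both
#' strands. The unique best placement with identity at least `min_identity`
#' is accepted; ties between distinct placements, or no placement above
#' threshold, yield `unplaced`. On the minus strand the focal target base is
#' complemented before being reported, so alleles are always compared in the
#' source orientation.
#'
#' @param locus one row of [extract_flanks()] output (or an equivalent list).
#' @param target target sequence (character scalar) or a prepared target.
#' @param min_identity minimum flank identity (default 0.9).
#' @param seed_len exact seed length (default 31).
#' @param seed_step spacing between attempted seed positions (default 8),
#'   giving high seed sensitivity under a few percent flank divergence.
#' @return list with `placed`, `target_pos` (1-based, forward coordinates of
#'   the focal base), `strand`, `identity`, `target_allele`, `reason`.
#' @export
place_locus <- function(locus, target, min_identity = 0.9, seed_len = 31,
                        seed_step = 8) {
  tg <- if (is.list(target) && !is.null(target$fwd_int)) target
        else prepare_target(target)
  query <- paste0(locus$left_flank, "N", locus$right_flank)
  starts <- seed_starts(nchar(query), seed_len, seed_step)
  offs <- list()
  for (strand in c("+", "-")) {
    tdna <- if (strand == "+") tg$fwd else tg$rc
    so <- integer()
    for (s in starts) {
      seed <- substr(query, s, s + seed_len - 1L)
      if (grepl("N", seed, fixed = TRUE)) next
      hits <- Biostrings::start(Biostrings::matchPattern(seed, tdna))
      if (length(hits)) so <- c(so, hits - (s - 1L))
    }
    offs[[strand]] <- unique(so)
  }
  place_from_offsets(utf8ToInt(query), nchar(locus$left_flank) + 1L, tg,
                     offs, min_identity)
}

# attempted seed start positions along the query
seed_starts <- function(nq, seed_len, seed_step) {
  seq(1L, max(1L, nq - seed_len + 1L), by = seed_step)
}

# shared candidate scoring: ungapped comparison of the full query at each
# implied offset, per strand; unique best above threshold wins
place_from_offsets <- function(qv, focal, tg, offs_by_strand, min_identity) {
  n_code <- utf8ToInt("N")
  nq <- length(qv)
  cands <- list()
  for (strand in names(offs_by_strand)) {
    tv <- if (strand == "+") tg$fwd_int else tg$rc_int
    for (off in offs_by_strand[[strand]]) {
      ti <- off + seq_len(nq) - 1L
      keep <- ti >= 1L & ti <= tg$len & qv != n_code
      if (sum(keep) < nq * 0.5) next      # demand most of the query aligned
      ident <- sum(qv[keep] == tv[ti[keep]]) / sum(keep)
      t_focal <- off + focal - 1L
      if (t_focal < 1L || t_focal > tg$len) next
      cands[[length(cands) + 1L]] <- list(strand = strand, off = off,
                                          identity = ident, t_focal = t_focal)
    }
  }
  fail <- function(reason) list(placed = FALSE, target_pos = NA_integer_,
                                strand = NA_character_, identity = NA_real_,
                                target_allele = NA_character_, reason = reason)
  if (!length(cands)) return(fail("no_seed_hit"))
  ids <- vapply(cands, `[[`, 0, "identity")
  best <- max(ids)
  if (best < min_identity) return(fail("below_identity"))
  top <- which(ids >= best - 1e-12)
  if (length(top) > 1) return(fail("ambiguous"))
  b <- cands[[top]]
  if (b$strand == "+") {
    t_pos <- b$t_focal
    allele <- intToUtf8(tg$fwd_int[t_pos])
  } else {
    # focal position in reverse-complement coordinates -> forward coordinates
    t_pos <- tg$len - b$t_focal + 1L
    allele <- intToUtf8(tg$rc_int[b$t_focal])
  }
  list(placed = TRUE, target_pos = t_pos, strand = b$strand,
       identity = b$identity, target_allele = allele, reason = "ok")
}

#' Place all flanked loci on a set of target haplotypes
#'
#' @param flanked `flanked_loci` from [extract_flanks()].
#' @param targets named character vector (or list) of target sequences, e.g.
#'   `c(Z = ..., W = ...)`.
#' @inheritParams place_locus
#' @return data.frame with one row per locus x target: placement fields plus
#'   the locus' `pos`, `y_allele`, `x_allele`.
#' @export
trace_loci <- function(flanked, targets, min_identity = 0.9, seed_len = 31,
                       seed_step = 8) {
  prepped <- lapply(targets, prepare_target)
  n <- nrow(flanked)
  queries <- paste0(flanked$left_flank, "N", flanked$right_flank)
  focals <- nchar(flanked$left_flank) + 1L
  qvs <- lapply(queries, utf8ToInt)
  # batch all valid seeds across loci into one dictionary per strand
  seed_tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    st <- seed_starts(nchar(queries[i]), seed_len, seed_step)
    seeds <- substring(queries[i], st, st + seed_len - 1L)
    ok <- !grepl("N", seeds, fixed = TRUE) & nchar(seeds) == seed_len
    if (!any(ok)) return(NULL)
    data.frame(locus = i, start = st[ok], seed = seeds[ok],
               stringsAsFactors = FALSE)
  }))
  rows <- list()
  pdict <- Biostrings::PDict(Biostrings::DNAStringSet(seed_tab$seed))
  for (tn in names(prepped)) {
    tg <- prepped[[tn]]
    offs_all <- list()
    for (strand in c("+", "-")) {
      tdna <- if (strand == "+") tg$fwd else tg$rc
      si <- Biostrings::startIndex(Biostrings::matchPDict(pdict, tdna))
      offs_all[[strand]] <- si
    }
    for (i in seq_len(n)) {
      rows_i <- which(seed_tab$locus == i)
      offs <- list()
      for (strand in c("+", "-")) {
        so <- integer()
        for (k in rows_i) {
          hits <- offs_all[[strand]][[k]]
          if (length(hits)) so <- c(so, hits - (seed_tab$start[k] - 1L))
        }
        offs[[strand]] <- unique(so)
      }
      pl <- place_from_offsets(qvs[[i]], focals[i], tg, offs, min_identity)
      rows[[length(rows) + 1L]] <- data.frame(
        target = tn, pos = flanked$pos[i],
        y_allele = flanked$y_allele[i], x_allele = flanked$x_allele[i],
        placed = pl$placed, target_pos = pl$target_pos, strand = pl$strand,
        identity = pl$identity, target_allele = pl$target_allele,
        reason = pl$reason, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Count Y/X allele identity among placed loci
#'
#' Per placed locus, `match` is `Y` iff the target allele equals the phased
#' Y allele, `X` iff it equals the X allele, otherwise `neither`; unplaced
#' loci are excluded from totals and reported as `unplaced`. A link table of
#' (source position, target position) pairs supports rearrangement
#' diagnostics (crossing count).
#'
#' @param placements data.frame from [trace_loci()].
#' @return list of class `trace_result` with `placements` (with a `match`
#'   column), `totals` (per-target counts) and `links`.
#' @export
count_matches <- function(placements) {
  pl <- placements
  pl$match <- ifelse(!pl$placed, "unplaced",
               ifelse(pl$target_allele == pl$y_allele, "Y",
               ifelse(pl$target_allele == pl$x_allele, "X", "neither")))
  totals <- do.call(rbind, lapply(split(pl, pl$target), function(d) {
    data.frame(target = d$target[1],
               n_loci = nrow(d),
               n_placed = sum(d$placed),
               n_Y_match = sum(d$match == "Y"),
               n_X_match = sum(d$match == "X"),
               n_neither = sum(d$match == "neither"),
               n_unplaced = sum(!d$placed),
               stringsAsFactors = FALSE)
  }))
  rownames(totals) <- NULL
  links <- pl[pl$placed, c("target", "pos", "target_pos", "strand")]
  rownames(links) <- NULL
  res <- list(placements = pl, totals = totals, links = links)
  class(res) <- "trace_result"
  res
}

#' @export
print.trace_result <- function(x, ...) {
  cat("trace_result:\n")
  print(x$totals, row.names = FALSE)
  invisible(x)
}

#' Count crossings in a link table (rearrangement diagnostic)
#'
#' Zero crossings means the placed loci are collinear between source and
#' target; inversions and transpositions introduce crossings.
#' @param links link table from [count_matches()] (single target).
#' @export
link_crossings <- function(links) {
  o <- order(links$pos)
  tp <- links$target_pos[o]
  n <- length(tp)
  if (n < 2) return(0L)
  cr <- 0L
  for (i in seq_len(n - 1)) {
    cr <- cr + sum(tp[(i + 1):n] < tp[i])
  }
  cr
}

#' Consensus haplotype from homogametic genotypes
#'
#' Builds a haplotype sequence by substituting, at each variant site, the
#' strict-majority allele among the called genotypes of the given samples
#' into the reference; ties become `N`. Used to survey a Z haplotype from
#' Z/Z males when no Z assembly is available.
#'
#' @param vt a [variant_table()].
#' @param samples sample ids to take the consensus over.
#' @param reference named character vector containing the table's chromosome.
#' @return named character vector (consensus sequence per chromosome).
#' @export
consensus_haplotype <- function(vt, samples, reference) {
  out <- reference
  for (ch in unique(vt$chrom)) {
    sel <- vt$chrom == ch
    g <- vt$gt[sel, samples, drop = FALSE]
    ref_n <- rowSums(2L - g, na.rm = TRUE)
    alt_n <- rowSums(g, na.rm = TRUE)
    allele <- ifelse(alt_n > ref_n, vt$alt[sel],
              ifelse(ref_n > alt_n, vt$ref[sel], "N"))
    chv <- strsplit(out[[ch]], "", fixed = TRUE)[[1]]
    chv[vt$pos[sel]] <- allele
    out[[ch]] <- paste(chv, collapse = "")
  }
  out
}

#' Build a concatenated locus alignment across X, Y and target haplotypes
#'
#' For each annotated window containing exactly one placed representative
#' locus on every target, the X and Y rows are the reference window with the
#' phased X (resp. Y) alleles substituted at every phased site inside the
#' window, and each target row is the corresponding window of the target
#' sequence read off the placement (reverse-complemented for minus-strand
#' placements). Windows whose representative locus failed to place on any
#' target, or whose target window would run off the sequence end, are
#' dropped. Rows are concatenated across windows into an equal-length matrix.
#'
#' @param reference named character vector (source reference).
#' @param phased `phased_sdr_alleles` (all confirmed sites, not only the
#'   representatives).
#' @param windows interval data.frame of locus windows (e.g. exon
#'   annotation).
#' @param targets named character vector of target sequences.
#' @param placements data.frame from [trace_loci()] for the representative
#'   loci.
#' @return character matrix with rows `X`, `Y` and one per target; attribute
#'   `windows_used` lists the retained windows.
#' @export
build_locus_alignment <- function(reference, phased, windows, targets,
                                  placements) {
  tnames <- names(targets)
  rc_cache <- lapply(targets, revcomp)
  rows <- stats::setNames(rep(list(character()), 2 + length(tnames)),
                          c("X", "Y", tnames))
  used <- integer()
  for (w in seq_len(nrow(windows))) {
    ch <- windows$chrom[w]; ws <- windows$start[w]; we <- windows$end[w]
    in_w <- placements$pos - 1L >= ws & placements$pos - 1L < we
    rep_pos <- unique(placements$pos[in_w])
    if (length(rep_pos) != 1) next
    pls <- placements[placements$pos == rep_pos, , drop = FALSE]
    if (!all(tnames %in% pls$target) || !all(pls$placed)) next
    refseq <- reference[[ch]]
    base <- strsplit(substr(refseq, ws + 1L, we), "", fixed = TRUE)[[1]]
    ph_w <- phased[phased$chrom == ch & phased$pos - 1L >= ws &
                     phased$pos - 1L < we, , drop = FALSE]
    xrow <- base; yrow <- base
    if (nrow(ph_w)) {
      rel <- ph_w$pos - ws
      xrow[rel] <- ph_w$x_allele
      yrow[rel] <- ph_w$y_allele
    }
    trows <- list(); ok <- TRUE
    for (tn in tnames) {
      pl <- pls[pls$target == tn, ]
      tl <- nchar(targets[[tn]])
      d_left <- rep_pos - 1L - ws          # bases left of focal in window
      d_right <- we - rep_pos              # bases right of focal
      if (pl$strand == "+") {
        lo <- pl$target_pos - d_left; hi <- pl$target_pos + d_right
        if (lo < 1 || hi > tl) { ok <- FALSE; break }
        trows[[tn]] <- strsplit(substr(targets[[tn]], lo, hi), "")[[1]]
      } else {
        p_rc <- tl - pl$target_pos + 1L
        lo <- p_rc - d_left; hi <- p_rc + d_right
        if (lo < 1 || hi > tl) { ok <- FALSE; break }
        trows[[tn]] <- strsplit(substr(rc_cache[[tn]], lo, hi), "")[[1]]
      }
    }
    if (!ok) next
    rows$X <- c(rows$X, xrow)
    rows$Y <- c(rows$Y, yrow)
    for (tn in tnames) rows[[tn]] <- c(rows[[tn]], trows[[tn]])
    used <- c(used, w)
  }
  if (!length(used)) stop("no usable windows for alignment", call. = FALSE)
  mat <- do.call(rbind, rows)
  attr(mat, "windows_used") <- used
  mat
}
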