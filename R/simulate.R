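# Forward simulator of a homologous XY -> ZW sex-system transition.
#
# History modelled: an ancestral chromosome pair diverges into X and Y inside
# a non-recombining SDR; the Y acquires a hemizygous Y-specific segment
# carrying planted partial duplicates of a query gene; a second species then
# inherits either the Y (scenario W_from_Y) or the X (W_from_X) as the seed of
# both its Z and W chromosomes; Z and W diverge on their own branches, the W
# loses the partial duplicates (W_from_Y) and gains two palindromic blocks of
# full-length query-gene copies. The simulator emits every input the analysis
# pipeline consumes plus a ground-truth record.

#' Define a transition scenario
#'
#' Defaults describe the desk-scale stated world: a 200 kb chromosome with an
#' SDR at [60 kb, 190 kb) containing a Y-specific segment at [60 kb, 130 kb)
#' (1/10 of the real system's 0.6-1.9 Mb SDR and 0.6-1.3 Mb Y-specific
#' region), 30 exon-anchored tracer loci in the X/Y-homologous part of the
#' SDR, 24 males + 24 females per species, 48 sexed half-sib progeny, mean
#' sequencing depth 30, genotyping error 0.01 and missingness 0.02.
#'
#' @param scenario `"W_from_Y"` or `"W_from_X"`: which ancestral haplotype
#'   seeds the derived species' Z and W.
#' @param L chromosome length in bp.
#' @param sdr,y_specific 0-based half-open `c(start, end)` intervals;
#'   `y_specific` must nest inside `sdr`.
#' @param n_tracer number of exon-anchored tracer loci inside the SDR.
#' @param d_xy ancestral per-site X/Y divergence inside the SDR (symmetric:
#'   the derived state lands on X or Y with probability 1/2).
#' @param rate_x,rate_y per-site substitution rates on the species-1 X and Y
#'   branches after the species split (SDR only; tracer loci and previously
#'   divergent sites exempt).
#' @param rate_split per-site rate on the stem leading to the derived species.
#' @param rate_z,rate_w per-site rates on the Z and W branches (SDR only).
#' @param rate_outgroup per-site rate on the outgroup branch.
#' @param n_duplicates number of partial duplicates planted on the Y.
#' @param dup_len_range length range (bp) of planted partial duplicates.
#' @param dup_divergence per-site divergence of each planted duplicate from
#'   the intact query gene at planting time (the duplicates are older than
#'   the species split, so this exceeds the split-branch rate).
#' @param query_gene_len length of the intact query gene.
#' @param epsilon per-genotype error rate; `missing` per-genotype missingness.
#' @param n_males,n_females,n_progeny,n_fathers cohort sizes.
#' @param depth_lambda mean depth for a diploid (copy-number 2) window.
#' @param window depth-track window size in bp.
#' @param n_background autosomal-style population SNPs outside the SDR.
#' @param capture_fraction fraction of non-tracer sex-divergent sites that
#'   are genotyped (sequence-capture analogue); tracer loci always genotyped.
#' @param qc_fail_frac per-criterion fraction of sites drawn from the failing
#'   component of the QC annotation mixture (scalar or named per-key vector).
#' @param seed master seed; all outputs derive named substreams from it.
#' @return a `transition_scenario` list.
#' @export
transition_scenario <- function(scenario = c("W_from_Y", "W_from_X"),
                                L = 200000,
                                sdr = c(60000, 190000),
                                y_specific = c(60000, 130000),
                                n_tracer = 30,
                                d_xy = 0.02,
                                rate_x = 0.002, rate_y = 0.002,
                                rate_split = 0.04,
                                rate_z = 0.015, rate_w = 0.015,
                                rate_outgroup = 0.06,
                                n_duplicates = 5,
                                dup_len_range = c(60, 300),
                                dup_divergence = 0.08,
                                query_gene_len = 1200,
                                epsilon = 0.01, missing = 0.02,
                                n_males = 24, n_females = 24,
                                n_progeny = 48, n_fathers = 1,
                                depth_lambda = 30, window = 5000,
                                n_background = 800,
                                capture_fraction = 1.0,
                                qc_fail_frac = 0.02,
                                seed = 1) {
  scenario <- match.arg(scenario)
  rates <- c(d_xy, rate_x, rate_y, rate_split, rate_z, rate_w, rate_outgroup)
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0,1)", call. = FALSE)
  if (epsilon + missing >= 1) stop("epsilon + missing must be < 1", call. = FALSE)
  if (!(y_specific[1] >= sdr[1] && y_specific[2] <= sdr[2])) {
    stop("y_specific must nest inside sdr", call. = FALSE)
  }
  if (!(sdr[1] >= 0 && sdr[2] <= L && sdr[1] < sdr[2] &&
        y_specific[1] < y_specific[2])) {
    stop("invalid sdr/y_specific geometry", call. = FALSE)
  }
  out <- as.list(environment())
  class(out) <- "transition_scenario"
  out
}

#' Substitute sites along a branch (Jukes-Cantor style)
#'
#' Each site is independently replaced by a uniformly chosen *different* base
#' with probability `rate`; expected substitutions = `rate * nchar(seq)`.
#'
#' @param seq character scalar over A/C/G/T/N.
#' @param rate per-site substitution probability in `[0,1)`.
#' @param seed optional seed (uses and restores its own stream); `NULL` draws
#'   from the current stream.
#' @param exempt_pos 1-based positions never mutated.
#' @param region optional 0-based half-open `c(start, end)`: mutations are
#'   confined to this window.
#' @return mutated sequence (character scalar).
#' @export
mutate_branch <- function(seq, rate, seed = NULL, exempt_pos = NULL,
                          region = NULL) {
  stopifnot(rate >= 0, rate < 1)
  run <- function() {
    n <- nchar(seq)
    lo <- 1L; hi <- n
    if (!is.null(region)) { lo <- region[1] + 1L; hi <- region[2] }
    span <- hi - lo + 1L
    if (span <= 0 || rate == 0) return(seq)
    hit <- lo - 1L + which(stats::runif(span) < rate)
    if (!is.null(exempt_pos)) hit <- setdiff(hit, exempt_pos)
    if (!length(hit)) return(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    old <- ch[hit]
    # uniform over the three other bases
    shift <- sample.int(3L, length(hit), replace = TRUE)
    idx <- match(old, DNA_BASES)
    ok <- !is.na(idx)
    ch[hit[ok]] <- DNA_BASES[((idx[ok] - 1L + shift[ok]) %% 4L) + 1L]
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# ---- segment maps: derived chromosomes as edits of the ancestral frame ----

# segments: list of list(kind = "ref", a_start, a_end)  [0-based half-open]
#        or list(kind = "ins", seq = <string>, label = <chr>)
segmap_seq <- function(segs, A) {
  paste(vapply(segs, function(s) {
    if (s$kind == "ref") substr(A, s$a_start + 1L, s$a_end) else s$seq
  }, ""), collapse = "")
}

# map 1-based ancestral positions to 1-based derived positions (NA if absent)
segmap_map <- function(segs, pos) {
  out <- rep(NA_real_, length(pos))
  off <- 0
  for (s in segs) {
    len <- if (s$kind == "ref") s$a_end - s$a_start else nchar(s$seq)
    if (s$kind == "ref") {
      sel <- pos > s$a_start & pos <= s$a_end
      out[sel] <- off + (pos[sel] - s$a_start)
    }
    off <- off + len
  }
  out
}

# 0-based half-open intervals of insertion segments in derived coordinates
segmap_ins_intervals <- function(segs) {
  off <- 0; out <- list()
  for (s in segs) {
    len <- if (s$kind == "ref") s$a_end - s$a_start else nchar(s$seq)
    if (s$kind == "ins") {
      out[[length(out) + 1L]] <- data.frame(start = off, end = off + len,
                                            label = s$label %||% "ins")
    }
    off <- off + len
  }
  if (!length(out)) data.frame(start = numeric(), end = numeric(),
                               label = character())
  else do.call(rbind, out)
}

# ---- QC annotation mixture --------------------------------------------------

# Two-component draw per annotation: a passing component and, with probability
# fail_frac[key], a component that violates the corresponding hard filter.
sim_qc_matrix <- function(n, fail_frac = 0.02, seed = NULL) {
  if (length(fail_frac) == 1) {
    fail_frac <- stats::setNames(rep(fail_frac, length(QC_KEYS)), QC_KEYS)
  }
  run <- function() {
    bad <- function(k) stats::runif(n) < fail_frac[[k]]
    qc <- matrix(NA_real_, n, length(QC_KEYS), dimnames = list(NULL, QC_KEYS))
    b <- bad("MQ")
    qc[, "MQ"] <- ifelse(b, stats::runif(n, 2, 12), stats::rnorm(n, 50, 5))
    b <- bad("SOR")
    qc[, "SOR"] <- ifelse(b, stats::runif(n, 4.5, 8), abs(stats::rnorm(n, 1, 0.5)))
    b <- bad("QD")
    qc[, "QD"] <- ifelse(b, stats::runif(n, 5, 18), stats::rnorm(n, 30, 3))
    b <- bad("FS")
    qc[, "FS"] <- ifelse(b, stats::runif(n, 65, 120), abs(stats::rnorm(n, 5, 4)))
    b <- bad("MQRankSum")
    qc[, "MQRankSum"] <- ifelse(b, stats::runif(n, -20, -11), stats::rnorm(n, 0, 1))
    b <- bad("ReadPosRankSum")
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    qc[, "ReadPosRankSum"] <- ifelse(b, sgn * stats::runif(n, 2.2, 4),
                                     stats::rnorm(n, 0, 0.7))
    b <- bad("DP")
    qc[, "DP"] <- ifelse(b,
                         sample(c(2:5, 101:160), n, replace = TRUE),
                         round(stats::rnorm(n, 40, 12)))
    qc
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# corrupt genotype matrix: error eps (uniform different value among 0:2) on
# called entries, then missingness m on all entries
corrupt_gt <- function(gt, eps, m, seed = NULL) {
  run <- function() {
    if (eps > 0) {
      err <- !is.na(gt) & matrix(stats::runif(length(gt)) < eps, nrow(gt))
      if (any(err)) {
        gt[err] <- (gt[err] + sample.int(2L, sum(err), replace = TRUE)) %% 3L
      }
    }
    if (m > 0) {
      gt[matrix(stats::runif(length(gt)) < m, nrow(gt))] <- NA_integer_
    }
    gt
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# fraction of a window [ws,we) covered by intervals iv (0-based half-open)
overlap_frac <- function(ws, we, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(rep(0, length(ws)))
  tot <- rep(0, length(ws))
  for (i in seq_len(nrow(iv))) {
    tot <- tot + pmax(0, pmin(we, iv$end[i]) - pmax(ws, iv$start[i]))
  }
  tot / (we - ws)
}

#' Simulate a homologous XY -> ZW transition
#'
#' Generates species-1 (XY) and species-2 (ZW) population variant tables,
#' a half-sib family variant table, sexed depth tracks for both species,
#' haplotype sequences (X, Y, Z, W, outgroup), the species-1 reference
#' (hybrid X/Y assembly), a query gene with planted partial duplicates, an
#' exon-window annotation for the tracer loci, sample sheets, a pedigree and
#' a ground-truth record. With `out_dir` set, everything is also written to
#' standard text formats (VCF, FASTA, BED, TSV, JSON).
#'
#' @param scenario a [transition_scenario()].
#' @param out_dir optional directory to write all artifacts into.
#' @return a `transition_sim` list; see the methods vignette for the schema.
#' @export
simulate_transition <- function(scenario = transition_scenario(),
                                out_dir = NULL) {
  sc <- scenario
  L <- sc$L
  ys <- sc$y_specific; sd_iv <- sc$sdr
  hom <- c(ys[2], sd_iv[2])              # X/Y-homologous part of the SDR

  A <- with_seed(sub_seed(sc$seed, "ancestral"), random_seq(L))

  # tracer loci: evenly spaced 1-based positions in the homologous SDR,
  # kept >= 200 bp from its edges so 150 bp flanks never truncate
  tracer_pos <- round(seq(hom[1] + 200, hom[2] - 200,
                          length.out = sc$n_tracer))

  # ancestral X/Y divergence: derived allele on X or Y with prob 1/2
  div <- with_seed(sub_seed(sc$seed, "divergence"), {
    p <- (hom[1] + 1):hom[2]
    bg <- p[stats::runif(length(p)) < sc$d_xy]
    pos <- sort(unique(c(bg, tracer_pos)))
    anc <- substring(A, pos, pos)
    shift <- sample.int(3L, length(pos), replace = TRUE)
    derived <- DNA_BASES[((match(anc, DNA_BASES) - 1L + shift) %% 4L) + 1L]
    on_x <- stats::runif(length(pos)) < 0.5
    data.frame(pos = pos,
               x = ifelse(on_x, derived, anc),
               y = ifelse(on_x, anc, derived),
               stringsAsFactors = FALSE)
  })

  subst_at <- function(seq, pos, alleles) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    ch[pos] <- alleles
    paste(ch, collapse = "")
  }

  X0 <- subst_at(A, div$pos, div$x)
  Y0 <- subst_at(A, div$pos, div$y)

  # query gene and planted partial duplicates on the Y-specific segment
  query <- with_seed(sub_seed(sc$seed, "query"), random_seq(sc$query_gene_len))
  dups <- with_seed(sub_seed(sc$seed, "duplicates"), {
    nd <- sc$n_duplicates
    if (nd == 0) {
      data.frame(y_start = integer(), y_end = integer(), strand = character(),
                 q_start = integer(), q_end = integer())
    } else {
      len <- sample(sc$dup_len_range[1]:sc$dup_len_range[2], nd, replace = TRUE)
      qs <- vapply(len, function(l) sample.int(sc$query_gene_len - l + 1L, 1L), 1L)
      slot <- floor(seq(ys[1] + 1000, ys[2] - 1000 - max(len),
                        length.out = nd))
      strand <- sample(c("+", "-"), nd, replace = TRUE)
      data.frame(y_start = as.integer(slot), y_end = as.integer(slot + len),
                 strand = strand, q_start = as.integer(qs),
                 q_end = as.integer(qs + len))
    }
  })
  if (nrow(dups)) {
    ch <- strsplit(Y0, "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(dups))) {
      frag <- substr(query, dups$q_start[i], dups$q_end[i] - 1L)
      frag <- mutate_branch(frag, sc$dup_divergence,
                            sub_seed(sc$seed, paste0("dup_div", i)))
      if (dups$strand[i] == "-") frag <- revcomp(frag)
      ch[(dups$y_start[i] + 1L):dups$y_end[i]] <- strsplit(frag, "")[[1]]
    }
    Y0 <- paste(ch, collapse = "")
  }
  dup_iv <- data.frame(chrom = "chr15", start = dups$y_start, end = dups$y_end)

  # species-1 branches: SDR-confined, previously divergent sites exempt
  X1 <- mutate_branch(X0, sc$rate_x, sub_seed(sc$seed, "branch_x"),
                      exempt_pos = div$pos, region = sd_iv)
  Y1 <- mutate_branch(Y0, sc$rate_y, sub_seed(sc$seed, "branch_y"),
                      exempt_pos = div$pos, region = sd_iv)

  # derived species: stem genome-wide, Z/W branches SDR-confined
  source0 <- if (sc$scenario == "W_from_Y") Y0 else X0
  proto <- mutate_branch(source0, sc$rate_split, sub_seed(sc$seed, "branch_split"))
  Zseq_a <- mutate_branch(proto, sc$rate_z, sub_seed(sc$seed, "branch_z"),
                          region = sd_iv)
  Wseq_a <- mutate_branch(proto, sc$rate_w, sub_seed(sc$seed, "branch_w"),
                          region = sd_iv)
  OUT <- mutate_branch(A, sc$rate_outgroup, sub_seed(sc$seed, "branch_out"))

  # assemble Z and W frames as segment maps over the ancestral frame
  ref_segs <- function(breaks) {
    # contiguous ref segments covering [0,L) minus nothing; breaks define cuts
    segs <- list(); lo <- 0
    for (b in breaks) {
      if (b$start > lo) segs[[length(segs) + 1L]] <-
          list(kind = "ref", a_start = lo, a_end = b$start)
      if (!is.null(b$ins)) segs[[length(segs) + 1L]] <-
          list(kind = "ins", seq = b$ins, label = b$label)
      lo <- b$end
    }
    if (lo < nchar(A)) segs[[length(segs) + 1L]] <-
        list(kind = "ref", a_start = lo, a_end = nchar(A))
    segs
  }

  has_ys <- sc$scenario == "W_from_Y"   # Z/W inherit the Y-specific segment?
  # each W insertion = a palindrome (two inverted full-length gene copies,
  # short spacer) plus W-specific filler long enough that the depth scan can
  # resolve the insertion at the configured window size
  blocks <- with_seed(sub_seed(sc$seed, "w_blocks"), {
    lapply(1:2, function(i) {
      paste0(query, random_seq(50), revcomp(query), random_seq(2 * sc$window))
    })
  })
  ins_at <- round(hom[1] + c(0.15, 0.45) * (hom[2] - hom[1]))

  z_breaks <- list()
  w_breaks <- list()
  if (!has_ys) {
    z_breaks <- c(z_breaks, list(list(start = ys[1], end = ys[2])))
    w_breaks <- c(w_breaks, list(list(start = ys[1], end = ys[2])))
  } else if (nrow(dups)) {
    # partial duplicates deleted from the W
    for (i in seq_len(nrow(dups))) {
      w_breaks <- c(w_breaks, list(list(start = dups$y_start[i],
                                        end = dups$y_end[i])))
    }
  }
  for (i in 1:2) {
    w_breaks <- c(w_breaks, list(list(start = ins_at[i], end = ins_at[i],
                                      ins = blocks[[i]],
                                      label = "palindrome")))
  }
  ord <- function(br) br[order(vapply(br, function(b) b$start, 0))]
  z_segs <- ref_segs(ord(z_breaks))
  w_segs <- ref_segs(ord(w_breaks))
  Zseq <- segmap_seq(z_segs, Zseq_a)
  Wseq <- segmap_seq(w_segs, Wseq_a)
  w_ins <- segmap_ins_intervals(w_segs)

  # species-1 reference: hybrid assembly = ancestral frame with the
  # Y-specific segment taken from the (duplicate-bearing) Y
  ref_seq <- paste0(substr(A, 1, ys[1]),
                    substr(Y0, ys[1] + 1, ys[2]),
                    substr(A, ys[2] + 1, L))

  # X haplotype as assembled from a female: Y-specific segment absent
  x_segs <- list(list(kind = "ref", a_start = 0, a_end = ys[1]),
                 list(kind = "ref", a_start = ys[2], a_end = L))
  Xseq <- segmap_seq(x_segs, X1)

  # ---- species-1 population VCF --------------------------------------------
  chx <- strsplit(X1, "", fixed = TRUE)[[1]]
  chy <- strsplit(Y1, "", fixed = TRUE)[[1]]
  cha <- strsplit(A, "", fixed = TRUE)[[1]]

  hom_pos <- (hom[1] + 1):hom[2]
  d_eff <- hom_pos[chx[hom_pos] != chy[hom_pos]]
  cap <- with_seed(sub_seed(sc$seed, "capture"), {
    keep <- d_eff %in% tracer_pos |
      stats::runif(length(d_eff)) < sc$capture_fraction
    d_eff[keep]
  })
  a_ref <- cha[cap]
  a_x <- chx[cap]; a_y <- chy[cap]
  a_alt <- ifelse(a_x == a_ref, a_y, a_x)

  # Y-specific male-only sites (post-split Y mutations, outside planted dups)
  ys_pos <- (ys[1] + 1):ys[2]
  in_dup <- rep(FALSE, length(ys_pos))
  if (nrow(dups)) {
    for (i in seq_len(nrow(dups))) {
      in_dup <- in_dup | (ys_pos > dups$y_start[i] & ys_pos <= dups$y_end[i])
    }
  }
  chref <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  b_pos <- ys_pos[!in_dup & chy[ys_pos] != chref[ys_pos]]
  b_ref <- chref[b_pos]; b_alt <- chy[b_pos]

  # background population SNPs outside the SDR
  bg <- with_seed(sub_seed(sc$seed, "background"), {
    cand <- setdiff(seq_len(L), (sd_iv[1] + 1):sd_iv[2])
    pos <- sort(sample(cand, sc$n_background))
    anc <- chref[pos]
    shift <- sample.int(3L, length(pos), replace = TRUE)
    alt <- DNA_BASES[((match(anc, DNA_BASES) - 1L + shift) %% 4L) + 1L]
    maf <- stats::runif(length(pos), 0.05, 0.95)
    list(pos = pos, ref = anc, alt = alt, maf = maf)
  })

  nm <- sc$n_males; nf <- sc$n_females
  sp1_samples <- c(sprintf("M%02d", seq_len(nm)), sprintf("F%02d", seq_len(nf)))
  sp1_sexes <- stats::setNames(rep(c("male", "female"), c(nm, nf)), sp1_samples)

  gt_sp1 <- with_seed(sub_seed(sc$seed, "sp1_gt"), {
    na <- length(cap); nb <- length(b_pos); nc <- length(bg$pos)
    gt <- matrix(NA_integer_, na + nb + nc, nm + nf)
    # divergent sites: males X/Y het; females X/X hom
    g_f <- ifelse(a_x == a_ref, 0L, 2L)
    gt[seq_len(na), seq_len(nm)] <- 1L
    gt[seq_len(na), nm + seq_len(nf)] <- matrix(rep(g_f, nf), ncol = nf)
    # Y-specific sites: males hemizygous alt (called hom); females no call
    if (nb) gt[na + seq_len(nb), seq_len(nm)] <- 2L
    # background: HWE, sex-independent
    if (nc) {
      gt[na + nb + seq_len(nc), ] <-
        matrix(stats::rbinom(nc * (nm + nf), 2, rep(bg$maf, nm + nf)), nc)
    }
    gt
  })
  pos1 <- c(cap, b_pos, bg$pos)
  o1 <- order(pos1)
  sp1 <- variant_table(
    chrom = "chr15", pos = pos1[o1],
    ref = c(a_ref, b_ref, bg$ref)[o1], alt = c(a_alt, b_alt, bg$alt)[o1],
    gt = corrupt_gt(gt_sp1[o1, , drop = FALSE], sc$epsilon, sc$missing,
                    sub_seed(sc$seed, "sp1_noise")),
    qc = sim_qc_matrix(length(pos1), sc$qc_fail_frac, sub_seed(sc$seed, "sp1_qc")),
    samples = sp1_samples)

  # ---- species-2 population VCF (reference = W chromosome) -----------------
  chza <- strsplit(Zseq_a, "", fixed = TRUE)[[1]]
  chwa <- strsplit(Wseq_a, "", fixed = TRUE)[[1]]
  zw_cand <- (sd_iv[1] + 1):sd_iv[2]
  if (!has_ys) zw_cand <- setdiff(zw_cand, ys_pos)
  zw_pos_a <- zw_cand[chza[zw_cand] != chwa[zw_cand]]
  zw_pos_a <- with_seed(sub_seed(sc$seed, "capture2"),
    zw_pos_a[stats::runif(length(zw_pos_a)) < sc$capture_fraction])
  zw_pos_w <- segmap_map(w_segs, zw_pos_a)
  present <- !is.na(zw_pos_w)        # drop sites inside W deletions
  zw_pos_a <- zw_pos_a[present]; zw_pos_w <- zw_pos_w[present]
  zw_z_allele <- chza[zw_pos_a]; zw_w_allele <- chwa[zw_pos_a]

  bg2 <- with_seed(sub_seed(sc$seed, "background2"), {
    cand <- seq_len(sd_iv[1])           # pre-SDR region maps 1:1 onto the W
    pos <- sort(sample(cand, min(sc$n_background, length(cand))))
    anc <- chwa[pos]
    shift <- sample.int(3L, length(pos), replace = TRUE)
    alt <- DNA_BASES[((match(anc, DNA_BASES) - 1L + shift) %% 4L) + 1L]
    maf <- stats::runif(length(pos), 0.05, 0.95)
    list(pos = pos, ref = anc, alt = alt, maf = maf)
  })

  sp2_samples <- c(sprintf("S2M%02d", seq_len(nm)), sprintf("S2F%02d", seq_len(nf)))
  sp2_sexes <- stats::setNames(rep(c("male", "female"), c(nm, nf)), sp2_samples)
  gt_sp2 <- with_seed(sub_seed(sc$seed, "sp2_gt"), {
    na <- length(zw_pos_a); nc <- length(bg2$pos)
    gt <- matrix(NA_integer_, na + nc, nm + nf)
    # Z/W divergent: ref = W allele; males Z/Z hom-alt, females Z/W het
    gt[seq_len(na), seq_len(nm)] <- 2L
    gt[seq_len(na), nm + seq_len(nf)] <- 1L
    if (nc) {
      gt[na + seq_len(nc), ] <-
        matrix(stats::rbinom(nc * (nm + nf), 2, rep(bg2$maf, nm + nf)), nc)
    }
    gt
  })
  pos2 <- c(zw_pos_w, bg2$pos)
  o2 <- order(pos2)
  sp2 <- variant_table(
    chrom = "chr15W", pos = pos2[o2],
    ref = c(zw_w_allele, bg2$ref)[o2], alt = c(zw_z_allele, bg2$alt)[o2],
    gt = corrupt_gt(gt_sp2[o2, , drop = FALSE], sc$epsilon, sc$missing,
                    sub_seed(sc$seed, "sp2_noise")),
    qc = sim_qc_matrix(length(pos2), sc$qc_fail_frac, sub_seed(sc$seed, "sp2_qc")),
    samples = sp2_samples)

  # ---- half-sib family VCF -------------------------------------------------
  npm <- sc$n_progeny %/% 2; npf <- sc$n_progeny - npm
  prog <- c(sprintf("P%02d", seq_len(npm)), sprintf("P%02d", npm + seq_len(npf)))
  prog_sex <- stats::setNames(rep(c("male", "female"), c(npm, npf)), prog)
  fam_samples <- c("MOTHER", prog)

  gt_fam <- with_seed(sub_seed(sc$seed, "fam_gt"), {
    na <- length(cap); nb <- length(b_pos); nc <- length(bg$pos)
    ns <- 1L + length(prog)
    gt <- matrix(NA_integer_, na + nb + nc, ns)
    g_x <- ifelse(a_x == a_ref, 0L, 1L)  # one X allele's alt dosage
    gt[seq_len(na), 1L] <- 2L * g_x                       # mother X/X
    gt[seq_len(na), 1L + seq_len(npm)] <- 1L              # sons X/Y het
    gt[seq_len(na), 1L + npm + seq_len(npf)] <- 2L * g_x  # daughters X/X
    if (nb) gt[na + seq_len(nb), 1L + seq_len(npm)] <- 2L # sons hemizygous
    if (nc) {
      g_m <- stats::rbinom(nc, 2, bg$maf)                 # mother HWE
      gt[na + nb + seq_len(nc), 1L] <- g_m
      for (j in seq_along(prog)) {
        mat <- stats::rbinom(nc, 1, g_m / 2)
        pat <- stats::rbinom(nc, 1, bg$maf)
        gt[na + nb + seq_len(nc), 1L + j] <- mat + pat
      }
    }
    gt
  })
  fam <- variant_table(
    chrom = "chr15", pos = pos1[o1],
    ref = c(a_ref, b_ref, bg$ref)[o1], alt = c(a_alt, b_alt, bg$alt)[o1],
    gt = corrupt_gt(gt_fam[o1, , drop = FALSE], sc$epsilon, sc$missing,
                    sub_seed(sc$seed, "fam_noise")),
    qc = sim_qc_matrix(length(pos1), sc$qc_fail_frac, sub_seed(sc$seed, "fam_qc")),
    samples = fam_samples)
  pedigree <- as_pedigree("MOTHER", prog_sex)

  # ---- depth tracks --------------------------------------------------------
  win_of <- function(len) {
    ws <- seq(0, len - 1, by = sc$window)
    data.frame(chrom = NA_character_, start = ws, end = pmin(ws + sc$window, len))
  }
  ys_iv <- data.frame(start = ys[1], end = ys[2])
  depth1 <- with_seed(sub_seed(sc$seed, "depth1"), {
    w <- win_of(L); w$chrom <- "chr15"
    f_ys <- overlap_frac(w$start, w$end, ys_iv)
    cn_m <- 2 * (1 - f_ys) + 1 * f_ys
    cn_f <- 2 * (1 - f_ys) + 0 * f_ys
    cn <- cbind(matrix(rep(cn_m, nm), ncol = nm),
                matrix(rep(cn_f, nf), ncol = nf))
    d <- matrix(stats::rpois(length(cn), sc$depth_lambda * cn / 2), nrow(w))
    colnames(d) <- sp1_samples
    list(windows = w, depth = d)
  })
  depth2 <- with_seed(sub_seed(sc$seed, "depth2"), {
    lw <- nchar(Wseq)
    w <- win_of(lw); w$chrom <- "chr15W"
    f_ins <- overlap_frac(w$start, w$end, w_ins)
    cn_m <- 2 * (1 - f_ins) + 0 * f_ins   # Z/Z males lack W insertions
    cn_f <- 2 * (1 - f_ins) + 1 * f_ins   # Z/W females hemizygous there
    cn <- cbind(matrix(rep(cn_m, nm), ncol = nm),
                matrix(rep(cn_f, nf), ncol = nf))
    d <- matrix(stats::rpois(length(cn), sc$depth_lambda * cn / 2), nrow(w))
    colnames(d) <- sp2_samples
    list(windows = w, depth = d)
  })

  # ---- exon annotation and truth -------------------------------------------
  exons <- data.frame(chrom = "chr15",
                      start = tracer_pos - 151L, end = tracer_pos + 150L,
                      label = sprintf("exon%02d", seq_along(tracer_pos)))

  tr_i <- match(tracer_pos, div$pos)
  tracer <- data.frame(
    pos = tracer_pos,
    x_allele = div$x[tr_i], y_allele = div$y[tr_i],
    z_allele = chza[tracer_pos], w_allele = chwa[tracer_pos],
    z_pos = segmap_map(z_segs, tracer_pos),
    w_pos = segmap_map(w_segs, tracer_pos),
    ancestry = if (sc$scenario == "W_from_Y") "from-Y" else "from-X",
    stringsAsFactors = FALSE)

  dup_truth <- dups
  if (nrow(dup_truth)) {
    dup_truth$z_start <- segmap_map(z_segs, dups$y_start + 1L) - 1L
    dup_truth$z_end <- dup_truth$z_start + (dups$y_end - dups$y_start)
    dup_truth$on_w <- FALSE
  }

  truth <- list(
    scenario = sc$scenario,
    sex_system = c(species1 = "XY", species2 = "ZW"),
    sdr = data.frame(chrom = "chr15", start = sd_iv[1], end = sd_iv[2]),
    y_specific = data.frame(chrom = "chr15", start = ys[1], end = ys[2]),
    tracer = tracer,
    duplicates = dup_truth,
    w_insertions = if (nrow(w_ins)) {
      data.frame(chrom = "chr15W", start = w_ins$start, end = w_ins$end,
                 label = w_ins$label)
    } else data.frame(chrom = character(), start = numeric(), end = numeric()),
    n_divergent_sites = length(d_eff))

  sim <- list(
    scenario = sc,
    reference = c(chr15 = ref_seq),
    haplotypes = c(X = Xseq, Y = Y1, Z = Zseq, W = Wseq, OUT = OUT),
    query_gene = c(query_gene = query),
    sp1 = sp1, sp2 = sp2, family = fam,
    sp1_sexes = sp1_sexes, sp2_sexes = sp2_sexes,
    pedigree = pedigree,
    depth_sp1 = depth1, depth_sp2 = depth2,
    exons = exons,
    truth = truth)
  class(sim) <- "transition_sim"

  if (!is.null(out_dir)) write_transition_sim(sim, out_dir)
  sim
}

#' @export
print.transition_sim <- function(x, ...) {
  cat(sprintf("transition_sim (%s): L=%d bp, %d tracer loci\n",
              x$scenario$scenario, x$scenario$L, nrow(x$truth$tracer)))
  cat(sprintf("  sp1: %d sites, sp2: %d sites, family: %d sites\n",
              n_sites(x$sp1), n_sites(x$sp2), n_sites(x$family)))
  invisible(x)
}

#' Write all simulator artifacts to a directory
#' @param sim a `transition_sim`.
#' @param out_dir output directory (created if needed).
#' @export
write_transition_sim <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_fasta(sim$reference, p("reference.fasta"))
  write_fasta(sim$haplotypes, p("haplotypes.fasta"))
  write_fasta(sim$query_gene, p("query_gene.fasta"))
  write_vcf(sim$sp1, p("species1.vcf"))
  write_vcf(sim$sp2, p("species2.vcf"))
  write_vcf(sim$family, p("family.vcf"))
  write_sample_sheet(sim$sp1_sexes, p("samples_species1.tsv"))
  write_sample_sheet(sim$sp2_sexes, p("samples_species2.tsv"))
  write_pedigree(sim$pedigree, p("pedigree.tsv"))
  write_depth_bed(sim$depth_sp1, p("depth_species1.bed"))
  write_depth_bed(sim$depth_sp2, p("depth_species2.bed"))
  write_bed(sim$exons, p("exons.bed"))
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(out_dir)
}
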