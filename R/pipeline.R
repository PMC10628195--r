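# End-to-end analysis chain: QC -> GWAS -> heterogamety -> hemizygosity ->
# phasing -> tracing -> phylogeny -> verdict.

#' Pick one representative phased locus per annotated window
#'
#' The locus-tracing and per-window alignment steps operate on one tracer SNP
#' per annotated (exon) window; the confirmed phased site closest to the
#' window centre is chosen.
#'
#' @param phased `phased_sdr_alleles` (with `confirmed` column if available).
#' @param windows interval data.frame of annotated windows.
#' @return subset of `phased`, one row per window with any eligible site.
#' @export
representative_loci <- function(phased, windows) {
  if ("confirmed" %in% names(phased)) {
    phased <- phased[phased$confirmed, , drop = FALSE]
  }
  picks <- integer()
  for (w in seq_len(nrow(windows))) {
    sel <- which(phased$chrom == windows$chrom[w] &
                   phased$pos - 1L >= windows$start[w] &
                   phased$pos - 1L < windows$end[w])
    if (!length(sel)) next
    centre <- (windows$start[w] + windows$end[w]) / 2
    picks <- c(picks, sel[which.min(abs(phased$pos[sel] - centre))])
  }
  phased[picks, , drop = FALSE]
}

#' Run the full transition analysis on simulator output
#'
#' Applies the hard filters and the 75% call-rate rule, runs the sex GWAS
#' with Bonferroni control, summarises the SDR interval, classifies
#' heterogamety in both species, scans depth and SNP presence for the
#' hemizygous Y-specific region, phases X/Y alleles from the half-sib family
#' inside the inferred SDR, confirms them against the GWAS, places one
#' representative locus per exon window onto the Z, W and outgroup
#' haplotypes, builds the concatenated locus alignment, bootstraps a
#' neighbor-joining tree and renders the W-origin verdict.
#'
#' @param sim a `transition_sim` from [simulate_transition()].
#' @param policy a [filter_policy()].
#' @param alpha GWAS family-wise level (default 0.05).
#' @param gap SDR cluster merge distance in bp.
#' @param tol phasing discordance tolerance.
#' @param B bootstrap replicates (default 100).
#' @param seed seed for the bootstrap resampling.
#' @return list with every intermediate (`assoc`, `sdr`, `heterogamety_sp1`,
#'   `heterogamety_sp2`, `hemizygous`, `snp_presence`, `phased`, `trace`,
#'   `tree`, `verdict`).
#' @export
run_transition_analysis <- function(sim, policy = filter_policy(),
                                    alpha = 0.05, gap = 500000, tol = 0,
                                    B = 100, seed = 1) {
  hf1 <- hard_filter(sim$sp1, policy)
  sp1_cr <- call_rate_filter(hf1$kept)
  assoc <- sex_gwas(sp1_cr, sim$sp1_sexes, alpha = alpha)
  sdr <- sdr_interval(assoc, gap = gap)
  het1 <- classify_heterogamety(subset_significant(sp1_cr, assoc),
                                sim$sp1_sexes)
  hf2 <- hard_filter(sim$sp2, policy)
  sp2_cr <- call_rate_filter(hf2$kept)
  assoc2 <- sex_gwas(sp2_cr, sim$sp2_sexes, alpha = alpha)
  het2 <- classify_heterogamety(subset_significant(sp2_cr, assoc2),
                                sim$sp2_sexes)

  hemi <- depth_scan(sim$depth_sp1, sim$sp1_sexes)
  presence <- snp_presence_scan(hf1$kept, sim$sp1_sexes,
                                window = sim$scenario$window)

  famf <- call_rate_filter(hard_filter(sim$family, policy)$kept)
  phased <- phase_sdr(famf, sim$pedigree, sdr, tol = tol)
  phased <- confirm_sex_linkage(phased, assoc)

  reps <- representative_loci(phased, sim$exons)
  flanked <- extract_flanks(sim$reference, reps)
  targets <- sim$haplotypes[c("Z", "W", "OUT")]
  placements <- trace_loci(flanked, targets)
  trace <- count_matches(placements)

  aln <- build_locus_alignment(sim$reference, phased[phased$confirmed, ],
                               sim$exons, targets, placements)
  tree <- bootstrap_support(aln, B = B, seed = seed)
  verdict <- w_origin_verdict(trace, tree)

  list(assoc = assoc, sdr = sdr,
       heterogamety_sp1 = het1, heterogamety_sp2 = het2,
       hemizygous = hemi, snp_presence = presence,
       phased = phased, flanked = flanked, trace = trace,
       alignment = aln, tree = tree, verdict = verdict,
       qc = list(sp1 = hf1$tally, sp2 = hf2$tally))
}
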