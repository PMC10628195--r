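---
title: "Tracing sex-chromosome turnover: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing sex-chromosome turnover: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In dioecious plants and many animals, sex is controlled by a small
non-recombining sex-determination region (SDR). Sex systems turn over:
a male-heterogametic XY system can be replaced by a female-heterogametic ZW
system on the same linkage group (a *homologous* transition). When that
happens, the new Z and W chromosomes must each descend from one of the old
haplotypes — the X or the Y — and which one they descend from constrains the
genetic mechanism of the turnover.

`heterotrace` implements the full inference chain needed to answer that
question from short-read genotyping data of two related species (the "old"
XY species and the "new" ZW species) plus a maternal half-sib family:

1. **variant QC** — hard site filters and a genotype call-rate rule;
2. **sex GWAS** — per-SNP sex association with Bonferroni control, and
   summarisation of significant SNPs into SDR interval(s);
3. **heterogamety classification** — XY vs ZW from sex-conditional
   heterozygosity at the associated SNPs;
4. **hemizygosity detection** — Y-specific (one-sex-only) sequence from
   sexed read-depth tracks and SNP-call presence;
5. **half-sib phasing** — X- and Y-specific alleles by maternal exclusion;
6. **allele tracing** — placement of each phased locus onto the second
   species' Z and W via 150-bp flanks, counting Y- vs X-allele identity;
7. **duplicate scanning** — seed-and-extend detection of partial duplicates
   of a candidate sex-determining gene, cross-chromosome pairing, palindrome
   annotation;
8. **phylogenetic verdict** — a Jukes–Cantor neighbor-joining bootstrap
   tree over the concatenated tracer loci, a monophyly test, and a combined
   verdict (`W_from_Y` / `W_from_X` / `undetermined`).

A forward simulator (`simulate_transition()`) generates every input the
chain consumes together with ground truth, so each stage and the end-to-end
chain are testable without any external data.

# The simulator: the stated world

The simulator encodes one explicit history:

* An ancestral chromosome of length `L` (default 200 kb) carries an SDR at
  `[60 kb, 190 kb)` — a 1/10-scale model of a real system whose SDR spans
  0.6–1.9 Mb with a Y-specific (hemizygous) segment at 0.6–1.3 Mb; the
  simulated Y-specific segment is `[60 kb, 130 kb)` accordingly.
* Inside the X/Y-homologous part of the SDR, X and Y diverge at `d_xy`
  (default 0.02 per site, derived states split evenly between X and Y), and
  30 evenly spaced **tracer loci** are forced divergent. These model the
  exon-anchored SNPs a sequence-capture panel would interrogate; the exon
  windows (301 bp around each tracer) are emitted as a public annotation.
* Five partial duplicates of a query gene (lengths 60–300 bp) are planted
  on the Y-specific segment, each carrying `dup_divergence = 0.08` per-site
  divergence from the intact gene: the duplicates are *older than the
  species split*, so each duplicate's phylogeny groups its Y and Z copies
  together — "a single origin per duplicate".
* A second species inherits either the Y (`W_from_Y`) or the X
  (`W_from_X`) as the seed of both its Z and W. Branch rates:
  species-split stem 0.04, Z and W branches 0.015 each, species-1 X/Y
  post-split branches 0.002, outgroup 0.06. The stem+W survival
  probability per tracer site is (1-0.04)(1-0.015) ≈ 0.945, so of 30
  tracer alleles about 28 survive identical on the W — the regime the
  method is designed to resolve. The species-1 post-split rates are kept
  short relative to `d_xy` because post-split Y mutations are genuinely
  phaseable Y alleles whose Z/W state equals the ancestral (X) allele;
  real tracer panels are dominated by old X/Y divergence, and a 10:1
  old:young ratio reflects that.
* Under `W_from_Y` the W deletes the partial duplicates; in both scenarios
  the W gains two insertions, each a palindrome of two inverted full-length
  gene copies (50 bp apart) plus W-specific filler two depth-windows long,
  so the insertions are resolvable by the mirrored depth scan.
* Genotypes: species-1 males are X/Y (heterozygous at every divergent
  site), females X/X; species-2 males Z/Z, females Z/W; the half-sib family
  is a genotyped mother plus 48 sexed progeny sired by X/Y father(s)
  (default one father; more fathers only add X-allele diversity, which the
  maternal-exclusion logic is insensitive to). Calls are corrupted at rate
  `epsilon` (default 0.01, uniform over the two other genotypes) and masked
  at rate `missing` (default 0.02). Sites in the Y-specific segment are
  structurally missing in females and appear homozygous in males, as a
  diploid caller would report hemizygous sequence.
* Depth: per window (5 kb) per sample, a Poisson draw with mean
  `depth_lambda x copy_number / 2` (default `depth_lambda = 30`).
* QC annotations (`MQ, SOR, QD, FS, MQRankSum, ReadPosRankSum, DP`) are
  drawn from a two-component mixture: a passing component and, with
  probability `qc_fail_frac = 0.02` per criterion, a component violating
  the corresponding hard filter.

All randomness derives from one master seed through named substreams
(`sub_seed`), so any single output is reproducible in isolation and a fixed
seed yields byte-identical files.

**What the simulator does not emulate:** reads (depth is drawn, not
computed), recombination inside the SDR (treated as fully non-recombining),
indels outside the explicitly planted insertions/deletions, linked selection
and population structure. A green end-to-end test therefore establishes the
*inference logic* under the stated noise model, not robustness to mapping
artefacts or structural misassembly.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| hard filters | `MQ<15, SOR>4, QD<20, FS>60, MQRankSum<-10, |RPRS|>2, DP outside [6,100]` | — | the workflow's removal criteria, applied verbatim; `QD<20` is far stricter than GATK practice (likely intended `QD<2`) and is overridable (`filter_policy(qd_min=)`) |
| call rate | 0.75 | fraction | at least 75% of genotypes called, boundary inclusive |
| GWAS alpha | 0.05 | — | Bonferroni over SNPs actually tested (monomorphic sites excluded from test and denominator) |
| heterogamety threshold `t` | 0.8 | fraction | accepts a strongly sex-linked pattern (male het ≈ 0.92, female hom ≈ 0.97) with margin while rejecting autosomal noise |
| depth scan `f_low`/`m_min` | 0.2 / 0.35 | median-normalised depth | separate copy number 0 from 1 from 2 under Poisson noise at mean depth ≥ 20 |
| SNP-presence depletion | 0.1 | ratio | female/male called-site ratio for a flag; windows with < 5 carrier sites are unflaggable |
| X-contig rule | length > 300 kb, density > 1e-4 genes/bp | — | applied per contig ("total length" is ambiguous; cumulative length also reported) |
| phasing `tol` | 0 | progeny | the maternal-exclusion set logic has no intrinsic error allowance; `tol` exposes one |
| flank length | 150 | bp | long enough to place uniquely at desk scale, short enough to stay within one exon |
| placement `min_identity` / `seed_len` | 0.9 / 31 | — | unstated in the source; 0.9 tolerates the expected ≈6.5% reference-to-target divergence, 31-mer seeds stepped every 8 bp give high seed sensitivity at 5% flank divergence |
| duplicate scan | word 8, min length 30, min identity 70%, E ≤ 1e-6 | — | short word for sensitivity to small diverged duplicates; scoring +1/−2 ungapped with Karlin–Altschul chance-hit control (BLASTN-like, approximated) |
| bootstrap `B` | 100 | replicates | standard resampling depth for topology support |
| verdict | binomial α = 0.05, support ≥ 70 | — | two-sided exact binomial on Y- vs X-matches on the W; monophyly of {Y,Z,W} (or {X,Z,W}) against the outgroup at the conventional support-70 reporting threshold |

# Numerical and design choices

* **Fisher exact test**: the default sex-association p-value is computed by
  explicit hypergeometric enumeration on the 2×2 allele-count table with
  the conventional `1 + 1e-7` relative tie rule, matching
  `stats::fisher.test` to ~1e-12 while being vectorisable across thousands
  of sites and permutations. The 1-df allelic chi-square is available
  (`test = "chisq"`) for comparability with standard GWAS tooling; which
  test the original analysis used is not documented, so the robust exact
  test is the default at n = 48.
* **Missing QC annotations** pass the corresponding filter by default (a
  criterion that cannot be evaluated is not evidence of low quality); a
  strict mode fails them instead.
* **Placement** is an in-house seed-and-extend ungapped mapper rather than
  an external BLASTN dependency; ambiguous placements (two equal best hits)
  are dropped and counted, never guessed. On the minus strand the focal
  base is complemented before allele comparison.
* **Tree inference** is Jukes–Cantor neighbor-joining with column
  bootstrap, not maximum likelihood: at these divergences the acceptance
  surface is the *topology* (monophyly), and NJ on near-additive distances
  recovers it; this substitution is deliberate and tested against an
  exhaustive least-squares topology search on 4- and 5-taxon problems.
  NJ ties break by taxon order as given; bootstrap replicates cap the
  mismatch fraction just below the Jukes–Cantor saturation point instead
  of erroring; supports are integer percentages on internal bipartitions.
* **Monophyly** of an ingroup is read as "the unrooted tree contains the
  bipartition ingroup | complement" (equivalently: rooting on the outgroup
  yields a clade of exactly the ingroup). When the complement has at most
  one taxon the question is degenerate — vacuously true, support `NA` — so
  the verdict path always works on a 5-taxon matrix (X, Y, Z, W, outgroup),
  where the question is informative. The verdict requires both evidence
  lines: the allele-count binomial *and* supported monophyly; either one
  alone leaves it `undetermined`.
* **One representative locus per exon window** enters the tracing step
  (the phased site nearest the window centre), mirroring the one-SNP-per-
  exon-region structure of the real analysis; the concatenated alignment
  substitutes *all* confirmed phased alleles within the retained windows.
* **Duplicate hits** are trimmed to the maximal-scoring segment of their
  seeded diagonal (+1 match / −2 mismatch); among equal-scoring optima the
  longest (then leftmost) segment is chosen so trimming is symmetric under
  strand reversal. Hits below the Karlin–Altschul score implied by
  `evalue = 1e-6` for the search space are discarded — without this,
  word-8 seeding admits occasional ≥30 bp chance segments at ≥70%
  identity, which BLASTN would likewise suppress by E-value.
* **SNP-presence scanning** runs on hard-filtered but *not*
  call-rate-filtered records: the 75% rule would delete exactly the
  female-missing hemizygous sites the scan exists to find.

# Degenerate inputs and edge behaviour

Zero significant SNPs yield an empty SDR with a warning, not an error.
Monomorphic sites are never tested. Phasing requires at least one genotyped
progeny of each sex and a genotyped mother at each called site; sites where
she is missing give no call. Flanks truncate at contig ends and the
truncation is recorded. A saturated sequence pair (p ≥ 0.75) is a hard
error in `jc_distance` — concatenating more loci, not silently clamping, is
the remedy (the clamp exists only inside bootstrap resampling). Zero placed
informative loci give an `undetermined` verdict with a reason string.

# Known limitations

The simulator's clonal haplotype populations (one X, one Y per species by
default) overstate linkage homogeneity relative to real populations; the
maternal-exclusion phasing logic is insensitive to this, but GWAS effect
sizes are idealised. The duplicate scanner is ungapped: diverged duplicates
containing indels fragment into multiple hits that the 10-bp merge rule
only partially rejoins. The verdict's binomial test treats loci as
independent, which non-recombining linkage strictly violates — the paired
monophyly requirement is the guard against over-reading the count evidence.
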