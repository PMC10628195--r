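# heterotrace

Tracing sex-chromosome turnover from XY to ZW systems.

## The problem

Sex-determination systems turn over. In a *homologous* transition, a new
female-heterogametic ZW pair replaces an old male-heterogametic XY pair on
the same chromosome — and the new Z and W must each descend from one of the
old haplotypes. Which one they descend from (the Y or the X) is the central
historical question: it decides whether the old male-determining haplotype
was repurposed or lost.

`heterotrace` is for population geneticists with short-read genotyping data
from two related dioecious species (one XY, one ZW), a maternal half-sib
family, and assemblies of the relevant chromosomes. It implements the whole
inference chain:

* **SDR mapping** — per-SNP sex association (Fisher exact test on the 2×2
  sex × allele table, Bonferroni control over the SNPs actually tested)
  after hard site filters (`MQ < 15`, `SOR > 4`, `QD < 20`, `FS > 60`,
  `MQRankSum < −10`, `|ReadPosRankSum| > 2`, `DP` outside `[6, 100]`) and a
  ≥ 75% call-rate rule; significant SNPs are merged into SDR interval(s).
* **Heterogamety** — XY iff mean male heterozygosity and mean female
  homozygosity at the associated SNPs both reach 0.8; ZW for the mirrored
  pattern.
* **Hemizygosity** — Y-specific sequence from sexed, median-normalised
  depth tracks (female < 0.2, male ≥ 0.35) and from windowed SNP-call
  presence (female calls ≤ 10% of male calls); plus the X-contig selection
  rule (length > 300 kb, gene density > 1e-4 genes/bp).
* **Phasing** — at each SDR site, the Y allele is the allele carried
  heterozygously by (all but ≤ tol) male half-sib progeny, absent from the
  mother, and absent from (all but ≤ tol) female progeny; the X allele is
  the site's other allele.
* **Tracing** — each phased locus, with 150-bp flanks, is placed on the
  second species' Z and W by exact-seed + ungapped-extension mapping; the
  target allele is scored as a Y-match or X-match.
* **Duplicates** — BLAST-like word-size-8 seed-and-extend scan for partial
  duplicates of a query gene, greedy cross-chromosome pairing with
  order/orientation flags, palindrome annotation.
* **Verdict** — a Jukes–Cantor neighbor-joining tree with column bootstrap
  over the concatenated tracer loci; `W_from_Y` iff an exact binomial test
  rejects symmetry of Y- vs X-matches on the W toward Y (α = 0.05) *and*
  {Y, Z, W} is monophyletic against the outgroup with support ≥ 70.

A forward simulator of the whole history (`simulate_transition()`) emits
every input the pipeline consumes — population VCFs for both species, a
half-sib family VCF, sexed depth BEDs, haplotype FASTAs, sample sheets, a
pedigree, an exon annotation and a ground-truth JSON — so everything is
testable offline. See `vignettes/heterotrace-methods.Rmd` for the model,
parameter rationale, and limitations.

## Worked example

Simulate one full XY→ZW transition at default (desk-scale) parameters and
run the complete analysis:

```r
library(heterotrace)
sim <- simulate_transition(transition_scenario(seed = 42))
res <- run_transition_analysis(sim, seed = 42)
res$sdr
#>   chrom  start    end n_snps
#> 1 chr15 130035 189947   1227
res$heterogamety_sp1
#> heterogamety: XY (male het 0.990, female hom 0.995, female het 0.005, male hom 0.010)
res$hemizygous$intervals[, c("chrom","start","end","carrier_mean","depleted_mean")]
#>   chrom start    end carrier_mean depleted_mean
#> 1 chr15 60000 130000    0.5781136             0
res$trace
#> trace_result:
#>  target n_loci n_placed n_Y_match n_X_match n_neither n_unplaced
#>     OUT     29       27        12        15         0          2
#>       W     29       24        21         2         1          5
#>       Z     29       27        25         2         0          2
res$verdict
#> W-origin verdict: W_from_Y
#>   W target: 21 Y-matches vs 2 X-matches (binomial p = 6.6e-05)
#>   monophyly {Y,Z,W}: TRUE (support 100); {X,Z,W}: FALSE (support NA)
```

Reading the output: the GWAS localises the SDR to the X/Y-homologous
segment (the simulated truth is [60 kb, 190 kb), whose homologous part
starts at 130 kb — the Y-specific part is invisible to an association test
because females have no calls there); males are heterozygous and females
homozygous at the associated SNPs, so the first species is XY; the depth
scan recovers the Y-specific interval [60 kb, 130 kb) exactly (female
normalised depth 0, male ≈ 0.58 ≈ one copy); of the phased tracer loci
placed on the W, 21 carry the Y allele and 2 the X allele, and the
bootstrap tree puts Y, Z and W in one clade at support 100 — together:
the W (and Z) descend from the ancestral Y. The outgroup row is the
control: it predates the X/Y split, so its alleles split roughly evenly.

Individual stages are exposed both as functions (`hard_filter()`,
`sex_gwas()`, `classify_heterogamety()`, `depth_scan()`, `phase_sdr()`,
`trace_loci()`, `scan_duplicates()`, `nj_tree()`, `w_origin_verdict()`, …)
and as subcommands of a small CLI (`exec/heterotrace`; `simulate`,
`filter`, `assoc`, `classify`, `hemiscan`, `xcontigs`, `phase`, `dupscan`,
`all`). `simulate_transition(..., out_dir = )` writes all artifacts as
plain VCF/FASTA/BED/TSV/JSON; `truth.json` holds the scenario, true
intervals, tracer-locus alleles and ancestry, and planted duplicate
coordinates.

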