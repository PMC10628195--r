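mk_sexes <- function(n_m, n_f) {
  stats::setNames(rep(c("male", "female"), c(n_m, n_f)),
                  sprintf("S%02d", seq_len(n_m + n_f)))
}

mk_vt <- function(gt_rows) {
  gt <- do.call(rbind, gt_rows)
  colnames(gt) <- sprintf("S%02d", seq_len(ncol(gt)))
  n <- nrow(gt)
  variant_table("chr1", seq_len(n) * 10L, rep("A", n), rep("T", n), gt)
}

test_that("identical genotype distributions give p = 1", {
  g <- c(rep(1L, 12), rep(0L, 12), rep(1L, 12), rep(0L, 12))
  vt <- mk_vt(list(g))
  res <- sex_gwas(vt, mk_sexes(24, 24))
  expect_equal(res$p, 1)
  expect_false(res$significant)
})

test_that("the fully sex-linked table matches the enumeration oracle", {
  # 24 males all het, 24 females all hom-ref:
  # allele table males (24 ref, 24 alt) / females (48 ref, 0 alt)
  g <- c(rep(1L, 24), rep(0L, 24))
  res <- sex_gwas(mk_vt(list(g)), mk_sexes(24, 24))
  oracle <- stats::fisher.test(matrix(c(24, 24, 48, 0), 2, byrow = TRUE))
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  expect_true(res$significant)
  expect_equal(res$m_het, 24)
  expect_equal(res$f_homref, 24)
})

test_that("fisher_allelic_p equals stats::fisher.test on random tables", {
  set.seed(99)
  for (i in 1:200) {
    n1 <- 2L * sample(2:24, 1); n2 <- 2L * sample(2:24, 1)
    a <- sample(0:n1, 1); c_ <- sample(0:n2, 1)
    K <- a + c_
    if (K == 0 || K == n1 + n2) next
    mine <- fisher_allelic_p(a, K, n1, n1 + n2)
    ref <- stats::fisher.test(matrix(c(a, n1 - a, c_, n2 - c_), 2,
                                     byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("monomorphic SNPs are excluded from test and denominator", {
  rows <- list(c(rep(1L, 24), rep(0L, 24)),   # sex-linked
               rep(0L, 48),                   # monomorphic
               rep(2L, 48))                   # monomorphic
  res <- sex_gwas(mk_vt(rows), mk_sexes(24, 24))
  expect_equal(attr(res, "n_tests"), 1)
  expect_false(res$tested[2])
  expect_true(is.na(res$p[2]))
})

test_that("single-sex input errors; chisq route agrees directionally", {
  vt <- mk_vt(list(c(rep(1L, 10), rep(0L, 10))))
  expect_error(sex_gwas(vt, stats::setNames(rep("male", 20), vt$samples)),
               "both sexes")
  res <- sex_gwas(mk_vt(list(c(rep(1L, 24), rep(0L, 24)))), mk_sexes(24, 24),
                  test = "chisq")
  expect_lt(res$p, 1e-6)
})

test_that("sdr_interval merges, splits and degenerates as specified", {
  assoc <- data.frame(chrom = "Chr15",
                      pos = c(1800000L, 1850000L, 1900000L),
                      significant = TRUE)
  iv <- sdr_interval(assoc, gap = 500000)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 1800000 - 1)
  expect_equal(iv$end, 1900000)

  one <- sdr_interval(data.frame(chrom = "c", pos = 500L, significant = TRUE))
  expect_equal(one$end - one$start, 1)   # degenerate 1-bp span

  two <- sdr_interval(data.frame(chrom = "c", pos = c(1e6, 3e6),
                                 significant = TRUE), gap = 500000)
  expect_equal(nrow(two), 2)

  expect_warning(
    empty <- sdr_interval(data.frame(chrom = "c", pos = 1L,
                                     significant = FALSE)),
    "no significant")
  expect_equal(nrow(empty), 0)
})

test_that("heterogamety classification and its mirror", {
  # perfect XY linkage
  rows <- replicate(5, c(rep(1L, 24), rep(0L, 24)), simplify = FALSE)
  vt <- mk_vt(rows)
  sx <- mk_sexes(24, 24)
  call <- classify_heterogamety(vt, sx)
  expect_equal(call$system, "XY")
  expect_equal(call$male_het, 1)
  expect_equal(call$female_hom, 1)
  expect_equal(call$male_het + call$male_hom, 1)
  # sex-swapped labels give the mirrored system
  swapped <- stats::setNames(ifelse(sx == "male", "female", "male"), names(sx))
  expect_equal(classify_heterogamety(vt, swapped)$system, "ZW")
  # weak linkage is ambiguous
  weak <- mk_vt(replicate(5, c(rep(1L, 12), rep(0L, 36)), simplify = FALSE))
  expect_equal(classify_heterogamety(weak, sx)$system, "ambiguous")
})

test_that("simulated XY data: SDR SNPs significant, autosomal ones not", {
  sim <- simulate_transition(small_scenario(seed = 12, epsilon = 0,
                                            missing = 0))
  vt <- call_rate_filter(hard_filter(sim$sp1)$kept)
  assoc <- sex_gwas(vt, sim$sp1_sexes)
  sdr <- sim$truth$sdr
  in_sdr <- assoc$pos - 1 >= sdr$start & assoc$pos - 1 < sdr$end
  # every tracer SNP present post-QC is significant
  tr <- assoc$pos %in% sim$truth$tracer$pos
  expect_true(all(assoc$significant[tr]))
  # no background SNP outside the SDR reaches Bonferroni significance
  expect_equal(sum(assoc$significant[!in_sdr]), 0)
  # heterogamety from the significant set
  het <- classify_heterogamety(subset_significant(vt, assoc), sim$sp1_sexes)
  expect_equal(het$system, "XY")
  # species 2 mirrors to ZW with fractions ~ 1 - 2*eps
  vt2 <- call_rate_filter(hard_filter(sim$sp2)$kept)
  a2 <- sex_gwas(vt2, sim$sp2_sexes)
  het2 <- classify_heterogamety(subset_significant(vt2, a2), sim$sp2_sexes)
  expect_equal(het2$system, "ZW")
  expect_gte(het2$female_het, 0.98)
})
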