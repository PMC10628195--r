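mk_phased <- function(pos, reference, y = NULL, x = NULL) {
  base <- substring(reference, pos, pos)
  rot <- function(b, k) c(A = "C", C = "G", G = "T", T = "A")[b]
  data.frame(chrom = "src", pos = pos,
             ref = base, alt = unname(rot(base)),
             y_allele = y %||% unname(rot(base)), x_allele = x %||% base,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("extract_flanks returns and truncates flanks correctly", {
  ref <- c(src = random_dna(10000, seed = 50))
  ph <- mk_phased(c(200L, 50L, 9990L), ref[[1]])
  fl <- extract_flanks(ref, ph, flank = 150)
  expect_equal(nchar(fl$left_flank), c(150, 49, 150))
  expect_equal(nchar(fl$right_flank), c(150, 150, 10))
  expect_equal(fl$truncated, c(FALSE, TRUE, TRUE))
  # flanks exclude the focal base and re-locate to the source position
  expect_equal(paste0(fl$left_flank[1], substring(ref[[1]], 200, 200),
                      fl$right_flank[1]),
               substring(ref[[1]], 50, 350))
  expect_error(extract_flanks(ref, mk_phased(10001L, ref[[1]])), "outside")
})

test_that("place_locus finds identity placements on both strands", {
  ref <- c(src = random_dna(8000, seed = 51))
  ph <- mk_phased(4000L, ref[[1]])
  fl <- extract_flanks(ref, ph)
  pl <- place_locus(fl[1, ], ref[[1]])
  expect_true(pl$placed)
  expect_equal(pl$target_pos, 4000L)
  expect_equal(pl$strand, "+")
  expect_equal(pl$identity, 1)
  expect_equal(pl$target_allele, substring(ref[[1]], 4000, 4000))
  # reverse-complement target: minus strand, allele complemented back
  rc <- heterotrace:::revcomp(ref[[1]])
  pl2 <- place_locus(fl[1, ], rc)
  expect_true(pl2$placed)
  expect_equal(pl2$strand, "-")
  expect_equal(pl2$target_allele, substring(ref[[1]], 4000, 4000))
  expect_equal(pl2$target_pos, 8000L - 4000L + 1L)
})

test_that("placement tolerates 5% flank divergence at truth coordinates", {
  set.seed(7)
  ref <- c(src = random_dna(60000))
  pos <- sort(sample(500:59500, 50))
  ph <- mk_phased(pos, ref[[1]])
  fl <- extract_flanks(ref, ph)
  target <- mutate_branch(ref[[1]], 0.05, seed = 7)
  pls <- trace_loci(fl, c(T1 = target))
  expect_gte(mean(pls$placed), 0.9)
  ok <- pls$placed
  expect_true(all(pls$target_pos[ok] == pls$pos[ok]))
  expect_true(all(pls$strand[ok] == "+"))
})

test_that("match totals are strand-consistent and bookkeeping is exact", {
  set.seed(8)
  ref <- c(src = random_dna(30000))
  pos <- sort(sample(500:29500, 20))
  ph <- mk_phased(pos, ref[[1]])
  fl <- extract_flanks(ref, ph)
  target <- mutate_branch(ref[[1]], 0.03, seed = 9)
  fwd <- count_matches(trace_loci(fl, c(T1 = target)))
  rev <- count_matches(trace_loci(fl, c(T1 = heterotrace:::revcomp(target))))
  expect_equal(fwd$totals[, c("n_Y_match", "n_X_match", "n_neither")],
               rev$totals[, c("n_Y_match", "n_X_match", "n_neither")])
  tot <- fwd$totals
  expect_equal(tot$n_Y_match + tot$n_X_match + tot$n_neither, tot$n_placed)
  expect_equal(tot$n_placed + tot$n_unplaced, tot$n_loci)
})

test_that("ambiguous placements are dropped, not guessed", {
  set.seed(9)
  core <- random_dna(2000)
  target <- paste0(core, random_dna(500), core)   # exact tandem repeat
  ref <- c(src = core)
  ph <- mk_phased(1000L, core)
  fl <- extract_flanks(ref, ph)
  pl <- place_locus(fl[1, ], target)
  expect_false(pl$placed)
  expect_equal(pl$reason, "ambiguous")
})

test_that("simulated scenarios give the expected match structure", {
  sim <- simulate_transition(small_scenario(seed = 60, epsilon = 0,
                                            missing = 0))
  ph <- phase_sdr(sim$family, sim$pedigree, sim$truth$sdr)
  reps <- representative_loci(ph, sim$exons)
  fl <- extract_flanks(sim$reference, reps)
  tr <- count_matches(trace_loci(fl, sim$haplotypes[c("Z", "W")]))
  tw <- tr$totals[tr$totals$target == "W", ]
  expect_gt(tw$n_Y_match, tw$n_X_match)   # W inherited the Y alleles
  simx <- simulate_transition(small_scenario(seed = 60, epsilon = 0,
                                             missing = 0,
                                             scenario = "W_from_X"))
  phx <- phase_sdr(simx$family, simx$pedigree, simx$truth$sdr)
  repx <- representative_loci(phx, simx$exons)
  flx <- extract_flanks(simx$reference, repx)
  trx <- count_matches(trace_loci(flx, simx$haplotypes[c("Z", "W")]))
  twx <- trx$totals[trx$totals$target == "W", ]
  tzx <- trx$totals[trx$totals$target == "Z", ]
  expect_gt(twx$n_X_match, twx$n_Y_match)
  expect_gt(tzx$n_X_match, tzx$n_Y_match)
})

test_that("link crossings detect a planted inversion", {
  links <- data.frame(target = "T1", pos = c(100, 200, 300, 400),
                      target_pos = c(100, 200, 300, 400), strand = "+")
  expect_equal(link_crossings(links), 0L)
  inv <- links
  inv$target_pos <- c(100, 400, 300, 450)   # middle block inverted
  expect_gt(link_crossings(inv), 0L)
})

test_that("consensus_haplotype takes strict majorities and ties to N", {
  gt <- matrix(c(2L, 2L, 2L,    # all alt
                 0L, 0L, 2L,    # ref majority
                 1L, 1L, NA),   # 2 ref vs 2 alt among called -> tie
               nrow = 3, byrow = TRUE)
  colnames(gt) <- c("z1", "z2", "z3")
  ref <- c(chrZ = "AAAAAAAAAA")
  vt <- variant_table("chrZ", c(2L, 5L, 8L), rep("A", 3), rep("G", 3), gt)
  cons <- consensus_haplotype(vt, c("z1", "z2", "z3"), ref)
  expect_equal(substring(cons[[1]], 2, 2), "G")
  expect_equal(substring(cons[[1]], 5, 5), "A")
  expect_equal(substring(cons[[1]], 8, 8), "N")
})
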