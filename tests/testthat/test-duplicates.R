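test_that("a planted exact reverse-complement segment is found once", {
  set.seed(70)
  query <- random_dna(1200)
  frag <- substring(query, 301, 400)                 # 100 bp of the query
  target <- paste0(random_dna(5000), heterotrace:::revcomp(frag),
                   random_dna(4900))
  hits <- scan_duplicates(query, target)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "-")
  expect_equal(hits$length, 100L)
  expect_equal(hits$identity, 100)
  expect_equal(hits$t_start, 5000)
  expect_equal(hits$t_end, 5100)
  expect_equal(hits$q_start, 300)
  expect_equal(hits$q_end, 400)
  expect_false(hits$intact)
  expect_error(scan_duplicates("ACGT", target, word = 8), "shorter")
})

test_that("random targets yield no hits (empirical null, 100 seeds)", {
  set.seed(71)
  query <- random_dna(1200)
  n_hits <- 0
  for (i in 1:100) {
    target <- random_dna(10000)
    n_hits <- n_hits + nrow(scan_duplicates(query, target))
  }
  expect_equal(n_hits, 0)
})

test_that("diverged planted segments are recovered near the oracle identity", {
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  set.seed(72)
  for (i in 1:10) {
    query <- random_dna(1200)
    frag <- mutate_branch(substring(query, 201, 500), 0.10, seed = 720 + i)
    target <- paste0(random_dna(4000), frag, random_dna(4000))
    hits <- scan_duplicates(query, target)
    expect_gte(nrow(hits), 1)
    h <- hits[which.max(hits$length), ]
    # oracle: dynamic-programming local alignment of hit vs query
    pa <- Biostrings::pairwiseAlignment(
      h$seq, substring(query, h$q_start + 1, h$q_end),
      type = "local", substitutionMatrix = sub,
      gapOpening = 5, gapExtension = 2)
    expect_lt(abs(h$identity - Biostrings::pid(pa)), 3)
  }
})

test_that("scanning is symmetric under reverse-complementing the target", {
  set.seed(73)
  query <- random_dna(1200)
  frag <- mutate_branch(substring(query, 101, 350), 0.05, seed = 73)
  target <- paste0(random_dna(3000), frag, random_dna(2000))
  a <- scan_duplicates(query, target)
  b <- scan_duplicates(query, heterotrace:::revcomp(target))
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(a$length), sort(b$length))
  nt <- nchar(target)
  expect_setequal(paste(nt - a$t_end, nt - a$t_start), paste(b$t_start, b$t_end))
  expect_true(all(a$strand != b$strand[match(nt - a$t_end, b$t_start)]))
})

test_that("intact copies and palindromes are annotated", {
  set.seed(74)
  query <- random_dna(1000)
  target <- paste0(random_dna(2000), query, random_dna(300),
                   heterotrace:::revcomp(query), random_dna(2000))
  hits <- annotate_palindromes(scan_duplicates(query, target))
  intact <- hits[hits$intact, ]
  expect_equal(nrow(intact), 2)
  expect_setequal(intact$strand, c("+", "-"))
  expect_true(all(intact$palindromic))
})

test_that("pairing recovers shared duplicates and their arrangement", {
  set.seed(75)
  query <- random_dna(1200)
  frags <- lapply(1:5, function(i) {
    len <- sample(80:250, 1)
    qs <- sample(seq_len(1200 - len), 1)
    mutate_branch(substring(query, qs, qs + len - 1), 0.08, seed = 750 + i)
  })
  strands <- c("+", "-", "+", "+", "-")
  mk_chrom <- function(extra_rate, seed) {
    parts <- character(0)
    for (i in 1:5) {
      f <- mutate_branch(frags[[i]], extra_rate, seed = seed * 10 + i)
      if (strands[i] == "-") f <- heterotrace:::revcomp(f)
      parts <- c(parts, random_dna(1500), f)
    }
    paste0(paste(parts, collapse = ""), random_dna(1500))
  }
  chrA <- mk_chrom(0.03, seed = 81)
  chrB <- mk_chrom(0.03, seed = 82)
  ha <- scan_duplicates(query, chrA)
  hb <- scan_duplicates(query, chrB)
  pr <- pair_duplicates(ha, hb)
  expect_equal(nrow(pr$pairs), 5)
  expect_true(pr$order_orientation_preserved)
  expect_true(all(pr$pairs$identity >= 70))
  # planted whole-chromosome inversion: pairs survive, the flag does not
  prx <- pair_duplicates(ha, scan_duplicates(query, heterotrace:::revcomp(chrB)))
  expect_equal(nrow(prx$pairs), 5)
  expect_false(prx$order_orientation_preserved)
  # no hits -> empty pairing
  pe <- pair_duplicates(ha, scan_duplicates(query, random_dna(5000)))
  expect_equal(nrow(pe$pairs), 0)
})

test_that("simulator-planted duplicates are recovered on Y and paired with Z", {
  sim <- simulate_transition(transition_scenario(seed = 5))
  q <- sim$query_gene[[1]]
  hy <- scan_duplicates(q, sim$haplotypes[["Y"]], target_name = "Y")
  expect_equal(nrow(hy), nrow(sim$truth$duplicates))
  # positions agree with truth within Kadane end-trimming slack
  expect_true(all(abs(hy$t_start - sim$truth$duplicates$y_start) <= 10))
  hz <- scan_duplicates(q, sim$haplotypes[["Z"]], target_name = "Z")
  pr <- pair_duplicates(hy, hz)
  expect_equal(nrow(pr$pairs), nrow(sim$truth$duplicates))
  expect_true(pr$order_orientation_preserved)
  # the W lost the partial duplicates but carries intact palindromic copies
  hw <- annotate_palindromes(scan_duplicates(q, sim$haplotypes[["W"]]),
                             max_spacing = 500)
  expect_equal(sum(hw$intact), 4)
  expect_true(all(hw$palindromic[hw$intact]))
  expect_equal(sum(!hw$intact & hw$length > 250), 0)
})
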