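# Shared fixtures, built in code.

# small, fast scenario for unit tests (defaults are exercised in
# test-acceptance.R); geometry keeps the same proportions
small_scenario <- function(seed = 1, ...) {
  transition_scenario(
    L = 60000, sdr = c(20000, 57000), y_specific = c(20000, 40000),
    n_tracer = 16, n_background = 200, n_progeny = 24,
    seed = seed, ...)
}

# variant table with a single site and explicit genotypes/qc
one_site_vt <- function(gt, ref = "A", alt = "T", qc = NULL, pos = 100) {
  gt <- matrix(as.integer(gt), nrow = 1)
  colnames(gt) <- sprintf("S%02d", seq_len(ncol(gt)))
  if (!is.null(qc)) qc <- matrix(qc, nrow = 1, dimnames = list(NULL, names(qc)))
  variant_table("chr1", pos, ref, alt, gt, qc)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
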