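# Maternal-exclusion phasing of X- and Y-specific alleles from a half-sib
# family (mother + sexed progeny).

#' Phase X/Y alleles in the SDR from a half-sib family
#'
#' At each biallelic SDR site, an allele `a` is called the Y allele iff
#' (i) every non-missing male progeny except at most `tol` carries `a`
#' heterozygously, (ii) the mother is called and does not carry `a`, and
#' (iii) every non-missing female progeny except at most `tol` lacks `a`.
#' The X allele is then the site's other allele, as carried by the female
#' progeny. Missing genotypes are excluded from both the "present" and
#' "absent" tallies. Sites failing any clause yield no call. With `tol = 0`
#' and error-free genotypes the mother-exclusion clause guarantees zero false
#' Y alleles for any number of fathers.
#'
#' @param vt a [variant_table()] containing the mother and all progeny.
#' @param pedigree list from [as_pedigree()] (mother id + named progeny sex
#'   vector).
#' @param sdr interval data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) restricting the scan; `NULL` scans all sites.
#' @param tol allowed discordant progeny per clause (default 0).
#' @return data.frame of class `phased_sdr_alleles` with `chrom`, `pos`,
#'   `ref`, `alt`, `y_allele`, `x_allele`, `n_male_support`,
#'   `n_female_support`.
#' @export
phase_sdr <- function(vt, pedigree, sdr = NULL, tol = 0) {
  if (!pedigree$mother %in% vt$samples) {
    stop("mother absent from variant table", call. = FALSE)
  }
  prog <- pedigree$progeny[names(pedigree$progeny) %in% vt$samples]
  if (!any(prog == "male") || !any(prog == "female")) {
    stop("pedigree needs >= 1 genotyped progeny of each sex", call. = FALSE)
  }
  if (!is.null(sdr)) {
    check_intervals(sdr)
    keep <- rep(FALSE, n_sites(vt))
    for (i in seq_len(nrow(sdr))) {
      keep <- keep | (vt$chrom == sdr$chrom[i] &
                        vt$pos - 1L >= sdr$start[i] & vt$pos - 1L < sdr$end[i])
    }
    vt <- vt[keep]
  }
  g0 <- vt$gt[, pedigree$mother]
  M <- vt$gt[, names(prog)[prog == "male"], drop = FALSE]
  F_ <- vt$gt[, names(prog)[prog == "female"], drop = FALSE]

  call_for <- function(alt_is_y) {
    # dosage views: carrying allele a; het for a; lacking a
    if (alt_is_y) {
      m_het <- M == 1L
      mother_lacks <- !is.na(g0) & g0 == 0L
      f_lacks <- F_ == 0L
    } else {
      m_het <- M == 1L
      mother_lacks <- !is.na(g0) & g0 == 2L
      f_lacks <- F_ == 2L
    }
    m_nm <- rowSums(!is.na(M)); f_nm <- rowSums(!is.na(F_))
    m_ok <- rowSums(m_het, na.rm = TRUE)
    f_ok <- rowSums(f_lacks, na.rm = TRUE)
    ok <- m_nm > 0 & f_nm > 0 &
      (m_nm - m_ok) <= tol & mother_lacks & (f_nm - f_ok) <= tol
    list(ok = ok, m_support = m_ok, f_support = f_ok)
  }
  y_alt <- call_for(TRUE)
  y_ref <- call_for(FALSE)
  any_call <- y_alt$ok | y_ref$ok
  idx <- which(any_call)
  use_alt <- y_alt$ok[idx]
  res <- data.frame(
    chrom = vt$chrom[idx], pos = vt$pos[idx],
    ref = vt$ref[idx], alt = vt$alt[idx],
    y_allele = ifelse(use_alt, vt$alt[idx], vt$ref[idx]),
    x_allele = ifelse(use_alt, vt$ref[idx], vt$alt[idx]),
    n_male_support = ifelse(use_alt, y_alt$m_support[idx], y_ref$m_support[idx]),
    n_female_support = ifelse(use_alt, y_alt$f_support[idx], y_ref$f_support[idx]),
    stringsAsFactors = FALSE)
  class(res) <- c("phased_sdr_alleles", "data.frame")
  res
}

#' Confirm phased alleles against an independent sex GWAS
#'
#' Flags a phased site as sex-linkage-confirmed iff a Bonferroni-significant
#' association SNP lies at the same position (or within `radius` bp).
#' Unconfirmed sites are retained with `confirmed = FALSE`.
#'
#' @param phased `phased_sdr_alleles` from [phase_sdr()].
#' @param assoc `association_records` from [sex_gwas()] on an independent
#'   population sample.
#' @param radius match radius in bp (default 0 = exact position).
#' @return `phased` with a logical `confirmed` column.
#' @export
confirm_sex_linkage <- function(phased, assoc, radius = 0) {
  sig <- assoc[assoc$significant, , drop = FALSE]
  conf <- vapply(seq_len(nrow(phased)), function(i) {
    any(sig$chrom == phased$chrom[i] & abs(sig$pos - phased$pos[i]) <= radius)
  }, TRUE)
  phased$confirmed <- conf
  phased
}
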