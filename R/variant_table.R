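QC_KEYS <- c("MQ", "SOR", "QD", "FS", "MQRankSum", "ReadPosRankSum", "DP")

#' Construct a variant table
#'
#' The package's in-memory container for biallelic SNP calls: parallel vectors
#' of site fields, a sites x samples genotype matrix coded as alt-allele
#' dosage (0, 1, 2, `NA` = missing), and a sites x 7 matrix of site QC
#' annotations (`MQ`, `SOR`, `QD`, `FS`, `MQRankSum`, `ReadPosRankSum`, `DP`;
#' `NA` = annotation absent).
#'
#' @param chrom character vector of sequence names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-base reference and alternate alleles (`ref != alt`).
#' @param gt integer matrix (sites x samples) of alt dosages in 0:2 or `NA`.
#' @param qc numeric matrix (sites x 7) with columns `MQ, SOR, QD, FS,
#'   MQRankSum, ReadPosRankSum, DP`; missing annotations are `NA`.
#' @param samples character vector of sample ids (unique).
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, gt, qc = NULL, samples = colnames(gt)) {
  n <- length(pos)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  gt <- as.matrix(gt)
  if (is.null(qc)) {
    qc <- matrix(NA_real_, n, length(QC_KEYS), dimnames = list(NULL, QC_KEYS))
  }
  qc <- as.matrix(qc)
  missing_cols <- setdiff(QC_KEYS, colnames(qc))
  if (length(missing_cols)) {
    qc <- cbind(qc, matrix(NA_real_, n, length(missing_cols),
                           dimnames = list(NULL, missing_cols)))
  }
  qc <- qc[, QC_KEYS, drop = FALSE]
  stopifnot(
    length(chrom) == n, length(ref) == n, length(alt) == n,
    nrow(gt) == n, nrow(qc) == n, !any(ref == alt),
    all(pos >= 1), !anyDuplicated(samples)
  )
  if (length(samples) == 0) stop("zero samples in variant table", call. = FALSE)
  colnames(gt) <- samples
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         gt = gt, qc = qc, samples = as.character(samples)),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d biallelic SNPs x %d samples\n",
              length(x$pos), length(x$samples)))
  cat(sprintf("  chrom(s): %s\n", paste(unique(x$chrom), collapse = ", ")))
  miss <- mean(is.na(x$gt))
  cat(sprintf("  missing genotype fraction: %.3f\n", miss))
  invisible(x)
}

#' Number of sites in a variant table
#' @param vt a `variant_table`.
#' @export
n_sites <- function(vt) length(vt$pos)

#' Subset a variant table by site index
#' @param x a `variant_table`.
#' @param i site index (logical or integer).
#' @param ... unused.
#' @export
`[.variant_table` <- function(x, i, ...) {
  variant_table(x$chrom[i], x$pos[i], x$ref[i], x$alt[i],
                x$gt[i, , drop = FALSE], x$qc[i, , drop = FALSE], x$samples)
}

#' Read a sample sheet (sample id, sex) from a two-column TSV
#'
#' @param path TSV with columns `sample` and `sex` (values `male`/`female`).
#' @return named character vector sample -> sex.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  as_sample_sheet(stats::setNames(df$sex, df$sample))
}

#' @rdname read_sample_sheet
#' @param sexes named character vector to validate.
#' @export
as_sample_sheet <- function(sexes) {
  sexes <- unlist(sexes)
  if (anyDuplicated(names(sexes))) stop("duplicate sample ids", call. = FALSE)
  if (!all(sexes %in% c("male", "female"))) {
    stop("sex labels must be 'male' or 'female'", call. = FALSE)
  }
  sexes
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sexes, path) {
  utils::write.table(
    data.frame(sample = names(sexes), sex = unname(sexes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a half-sib pedigree (mother plus sexed progeny)
#'
#' TSV with columns `sample`, `role` (`mother`/`progeny`), `sex`.
#' @param path file path.
#' @return list with `mother` (id) and `progeny` (named sex vector).
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  as_pedigree(df$sample[df$role == "mother"][1],
              stats::setNames(df$sex[df$role == "progeny"],
                              df$sample[df$role == "progeny"]))
}

#' @rdname read_pedigree
#' @param mother mother sample id.
#' @param progeny named character vector progeny id -> sex.
#' @export
as_pedigree <- function(mother, progeny) {
  progeny <- as_sample_sheet(progeny)
  if (mother %in% names(progeny)) stop("mother listed among progeny", call. = FALSE)
  list(mother = mother, progeny = progeny)
}

#' @rdname read_pedigree
#' @param ped pedigree list as returned by [as_pedigree()].
#' @export
write_pedigree <- function(ped, path) {
  df <- data.frame(
    sample = c(ped$mother, names(ped$progeny)),
    role = c("mother", rep("progeny", length(ped$progeny))),
    sex = c("female", unname(ped$progeny)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
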