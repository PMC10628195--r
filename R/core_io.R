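# Readers/writers for the standard formats every stage touches.
# Conventions: VCF positions are 1-based; BED intervals are 0-based half-open;
# a VCF position p corresponds to interval [p-1, p).

#' Read a VCF into a variant table
#'
#' Parses a VCF 4.x file (plain or bgzipped) via `VariantAnnotation`, keeping
#' biallelic SNPs only. Multiallelic records and indels are dropped with a
#' message reporting the count. The seven site QC annotations
#' (`MQ, SOR, QD, FS, MQRankSum, ReadPosRankSum, DP`) are read from INFO when
#' present; absent keys surface as `NA`, not zero.
#'
#' @param path path to a VCF file.
#' @return a [variant_table()].
#' @export
read_vcf <- function(path) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("malformed VCF: ", conditionMessage(e), call. = FALSE))
  if (ncol(vcf) == 0) stop("VCF contains zero samples", call. = FALSE)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  keep <- n_alt == 1 & nchar(ref) == 1 & !is.na(alt1) & nchar(alt1) == 1 &
    ref %in% DNA_BASES & alt1 %in% DNA_BASES
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("read_vcf: dropped %d multiallelic/indel record(s)", dropped))
  }
  vcf <- vcf[keep]
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt_chr <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt_chr)) stop("VCF lacks GT genotype field", call. = FALSE)
  gt <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr))
  gt[gt_chr %in% c("0/0", "0|0")] <- 0L
  gt[gt_chr %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  gt[gt_chr %in% c("1/1", "1|1")] <- 2L
  info <- VariantAnnotation::info(vcf)
  qc <- matrix(NA_real_, nrow(gt), length(QC_KEYS),
               dimnames = list(NULL, QC_KEYS))
  for (k in QC_KEYS) {
    if (k %in% colnames(info)) {
      v <- info[[k]]
      if (is.list(v)) v <- vapply(v, function(x) if (length(x)) as.numeric(x[1]) else NA_real_, 0)
      qc[, k] <- as.numeric(v)
    }
  }
  variant_table(as.character(GenomicRanges::seqnames(rr)),
                GenomicRanges::start(rr),
                ref[keep], alt1[keep], gt, qc,
                samples = colnames(gt_chr))
}

#' Write a variant table as VCF 4.2
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @export
write_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=heterotrace",
    sprintf("##contig=<ID=%s>", unique(vt$chrom)),
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=SOR,Number=1,Type=Float,Description="Strand odds ratio">',
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="MQ rank sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Combined depth">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples), collapse = "\t"))
  writeLines(hdr, con)
  n <- n_sites(vt)
  if (n > 0) {
    info <- vapply(seq_len(n), function(i) {
      v <- vt$qc[i, ]
      v <- v[!is.na(v)]
      if (!length(v)) return(".")
      paste(sprintf("%s=%s", names(v), format(v, trim = TRUE, digits = 6)),
            collapse = ";")
    }, "")
    gts <- matrix(c("0/0", "0/1", "1/1")[vt$gt + 1L], nrow = n)
    gts[is.na(vt$gt)] <- "./."
    gt_str <- apply(gts, 1, paste, collapse = "\t")
    writeLines(paste(vt$chrom, vt$pos, ".", vt$ref, vt$alt, ".", "PASS",
                     info, "GT", gt_str, sep = "\t"), con)
  }
  invisible(path)
}

#' Read/write FASTA as named uppercase character vectors
#'
#' Thin wrappers over `Biostrings`; sequences are returned as plain character
#' scalars over `{A,C,G,T,N}` for downstream string algorithms.
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  s <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", s)
  if (any(bad)) stop("inconsistent sequence alphabet in FASTA", call. = FALSE)
  stats::setNames(s, sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  if (any(nchar(seqs) == 0)) stop("empty sequence", call. = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80)
  invisible(path)
}

#' Read/write BED (0-based half-open)
#'
#' @param path file path. Lines starting with `#` are treated as header.
#' @return data.frame with `chrom`, `start`, `end` and optionally `label`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  df <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          data.table = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "label"
  check_intervals(df)
  df
}

#' @rdname read_bed
#' @param iv interval data.frame (`chrom`, `start`, `end`, optional `label`).
#' @export
write_bed <- function(iv, path) {
  check_intervals(iv)
  cols <- intersect(c("chrom", "start", "end", "label"), names(iv))
  data.table::fwrite(iv[, cols, drop = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Write a generic TSV with header
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read/write Newick trees (ape `phylo` objects)
#' @param path file path.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree an ape `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Convert a VCF position to interval space
#'
#' A 1-based VCF position `p` maps to the 0-based half-open interval
#' `[p-1, p)`.
#' @param pos 1-based position vector.
#' @param chrom chromosome name(s).
#' @export
pos_to_interval <- function(pos, chrom = "chr") {
  data.frame(chrom = chrom, start = pos - 1, end = pos,
             stringsAsFactors = FALSE)
}

#' Read/write per-window per-sample depth tracks
#'
#' BED-like TSV: a `#`-prefixed header line naming `chrom start end` plus one
#' column per sample; body rows give mean depth per window per sample.
#' @param path file path.
#' @return list with `windows` (interval data.frame) and `depth`
#'   (windows x samples matrix).
#' @export
read_depth_bed <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) stop("depth BED lacks '#' header", call. = FALSE)
  samples <- strsplit(sub("^#", "", first), "\t")[[1]][-(1:3)]
  df <- data.table::fread(path, header = FALSE, sep = "\t", skip = 1,
                          data.table = FALSE)
  windows <- stats::setNames(df[, 1:3], c("chrom", "start", "end"))
  depth <- as.matrix(df[, -(1:3), drop = FALSE])
  colnames(depth) <- samples
  check_intervals(windows)
  list(windows = windows, depth = depth)
}

#' @rdname read_depth_bed
#' @param track list with `windows` and `depth` as returned by
#'   [read_depth_bed()].
#' @export
write_depth_bed <- function(track, path) {
  writeLines(paste(c("#chrom", "start", "end", colnames(track$depth)),
                   collapse = "\t"), path)
  body <- cbind(track$windows[, c("chrom", "start", "end")],
                as.data.frame(track$depth))
  data.table::fwrite(body, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}
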