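# Internal helpers shared across modules.

#' Run code with a temporary RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's `.Random.seed`
#' so package functions never clobber the session RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a named RNG substream seed from a master seed
#'
#' Deterministic hash of (seed, label) kept below 2^31 so every simulator
#' output draws from its own reproducible stream.
#' @noRd
sub_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483629
  as.integer(h %% 2147483647)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Alphabet used throughout; sequences are plain uppercase character scalars.
DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequence of length n (uses current RNG stream)
#' @noRd
random_seq <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a character sequence
#' @noRd
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Complement single bases (vectorised)
#' @noRd
comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

#' Sequence to integer codes A,C,G,T -> 0..3 (other -> NA)
#' @noRd
seq_to_int <- function(s) {
  v <- utf8ToInt(s)
  code <- rep(NA_integer_, 128)
  code[utf8ToInt("A")] <- 0L; code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L; code[utf8ToInt("T")] <- 3L
  code[v]
}

#' Jaccard index of two interval sets (same chrom assumed), 0-based half-open
#' @noRd
interval_jaccard <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(1)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  cover <- function(iv, pos) {
    hit <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(iv))) hit <- hit | (pos >= iv$start[i] & pos < iv$end[i])
    hit
  }
  lo <- min(a$start, b$start); hi <- max(a$end, b$end)
  # evaluate on unit grid only at breakpoints for efficiency
  brk <- sort(unique(c(a$start, a$end, b$start, b$end)))
  mids <- (brk[-length(brk)] + brk[-1]) / 2
  w <- diff(brk)
  ina <- cover(a, mids); inb <- cover(b, mids)
  inter <- sum(w[ina & inb]); un <- sum(w[ina | inb])
  if (un == 0) 1 else inter / un
}

#' Merge adjacent/overlapping flagged windows into intervals
#' @param df data.frame with chrom,start,end sorted; rows are windows to merge
#' @noRd
merge_windows <- function(df, gap = 0) {
  if (nrow(df) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  out <- list()
  cur <- df[1, c("chrom", "start", "end")]
  for (i in seq_len(nrow(df))[-1]) {
    if (df$chrom[i] == cur$chrom && df$start[i] <= cur$end + gap) {
      cur$end <- max(cur$end, df$end[i])
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- df[i, c("chrom", "start", "end")]
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Validate a 0-based half-open genomic interval data.frame
#' @noRd
check_intervals <- function(iv) {
  stopifnot(all(c("chrom", "start", "end") %in% names(iv)))
  if (any(iv$start < 0) || any(iv$end <= iv$start)) {
    stop("invalid interval: need 0 <= start < end", call. = FALSE)
  }
  invisible(iv)
}
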