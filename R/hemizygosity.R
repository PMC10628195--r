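# Detection of sex-specific (hemizygous) regions from grouped read depth and
# SNP-call density, and the X-contig selection rule.

#' Scan a depth track for hemizygous (sex-specific) intervals
#'
#' Each sample's window depths are first normalised by that sample's
#' genome-wide median (library-size robustness), then a window is flagged iff
#' the mean normalised depth of the `depleted` sex falls below `f_low` while
#' the mean of the other sex stays at or above `m_min`. Adjacent flagged
#' windows are merged. Defaults separate copy number 0 from 1 from 2 under
#' Poisson noise at mean depth >= 20: a hemizygous window sits near 0.5 in
#' the carrying sex and near 0 in the other.
#'
#' @param track list with `windows` (interval data.frame) and `depth`
#'   (windows x samples matrix), as from [read_depth_bed()].
#' @param sexes sample sheet covering the track's samples.
#' @param f_low normalised-depth ceiling for the depleted sex (default 0.2).
#' @param m_min normalised-depth floor for the carrying sex (default 0.35).
#' @param depleted which sex is expected to lack the region: `"female"`
#'   (Y-specific scan, default) or `"male"` (W-specific scan).
#' @return list with `intervals` (merged flagged intervals) and `windows`
#'   (per-window means and flags).
#' @export
depth_scan <- function(track, sexes, f_low = 0.2, m_min = 0.35,
                       depleted = c("female", "male")) {
  depleted <- match.arg(depleted)
  sexes <- as_sample_sheet(sexes[colnames(track$depth)])
  if (length(unique(sexes)) < 2) {
    stop("depth track must include both sexes", call. = FALSE)
  }
  med <- apply(track$depth, 2, stats::median)
  if (any(med == 0)) stop("sample with zero median depth", call. = FALSE)
  norm <- sweep(track$depth, 2, med, "/")
  dep_sex <- depleted
  car_sex <- if (depleted == "female") "male" else "female"
  dep_mean <- rowMeans(norm[, sexes == dep_sex, drop = FALSE])
  car_mean <- rowMeans(norm[, sexes == car_sex, drop = FALSE])
  flagged <- dep_mean < f_low & car_mean >= m_min
  win <- cbind(track$windows,
               data.frame(depleted_mean = dep_mean, carrier_mean = car_mean,
                          flagged = flagged))
  iv <- merge_windows(track$windows[flagged, , drop = FALSE])
  if (nrow(iv)) {
    iv$depleted_mean <- vapply(seq_len(nrow(iv)), function(i) {
      sel <- track$windows$chrom == iv$chrom[i] &
        track$windows$start >= iv$start[i] & track$windows$end <= iv$end[i]
      mean(dep_mean[sel])
    }, 0)
    iv$carrier_mean <- vapply(seq_len(nrow(iv)), function(i) {
      sel <- track$windows$chrom == iv$chrom[i] &
        track$windows$start >= iv$start[i] & track$windows$end <= iv$end[i]
      mean(car_mean[sel])
    }, 0)
  }
  list(intervals = iv, windows = win)
}

#' Windowed SNP-presence scan by sex
#'
#' Counts, per window and sex, the sites with at least one called genotype,
#' and flags windows where the depleted sex's count is at most
#' `depletion_frac` of the other sex's count. Windows where the carrying sex
#' has fewer than `min_carrier_sites` called sites are unflaggable (a 0/0
#' window carries no evidence).
#'
#' @param vt a [variant_table()] (post hard-filter, pre call-rate filter:
#'   the call-rate rule would remove exactly the hemizygous sites this scan
#'   looks for).
#' @param sexes sample sheet covering the table's samples.
#' @param window window size in bp.
#' @param depletion_frac flag threshold (default 0.1).
#' @param min_carrier_sites minimum called sites in the carrying sex
#'   (default 5).
#' @param depleted `"female"` (default) or `"male"`.
#' @return list with `intervals` (merged flagged windows) and `windows`
#'   (per-window per-sex counts).
#' @export
snp_presence_scan <- function(vt, sexes, window = 5000, depletion_frac = 0.1,
                              min_carrier_sites = 5,
                              depleted = c("female", "male")) {
  depleted <- match.arg(depleted)
  sexes <- as_sample_sheet(sexes[vt$samples])
  m_called <- rowSums(!is.na(vt$gt[, sexes == "male", drop = FALSE])) > 0
  f_called <- rowSums(!is.na(vt$gt[, sexes == "female", drop = FALSE])) > 0
  out <- list(); winflag <- list()
  for (ch in unique(vt$chrom)) {
    sel <- vt$chrom == ch
    pos <- vt$pos[sel]
    hi <- max(pos)
    ws <- seq(0, hi, by = window)
    bin <- findInterval(pos - 1L, ws)
    cm <- tapply(m_called[sel], bin, sum)
    cf <- tapply(f_called[sel], bin, sum)
    n_m <- n_f <- rep(0L, length(ws))
    n_m[as.integer(names(cm))] <- as.integer(cm)
    n_f[as.integer(names(cf))] <- as.integer(cf)
    dep <- if (depleted == "female") n_f else n_m
    car <- if (depleted == "female") n_m else n_f
    flagged <- car >= min_carrier_sites & dep <= depletion_frac * car
    winflag[[ch]] <- data.frame(chrom = ch, start = ws, end = ws + window,
                                male_sites = n_m, female_sites = n_f,
                                flagged = flagged)
  }
  win <- do.call(rbind, winflag)
  rownames(win) <- NULL
  iv <- merge_windows(win[win$flagged, c("chrom", "start", "end"), drop = FALSE])
  list(intervals = iv, windows = win)
}

#' Select putative X contigs by length and gene density
#'
#' A contig is selected iff its length exceeds `min_len` and its gene density
#' (genes annotated to the target chromosome homologs per bp) exceeds
#' `min_density`. The length rule is applied per contig (whether a cumulative
#' reading was intended is ambiguous; see the methods vignette), and the
#' cumulative selected length is also reported.
#'
#' @param annotations data.frame with columns `contig`, `length`, `genes`.
#' @param min_len minimum contig length (default 300000).
#' @param min_density minimum gene density in genes/bp (default 1e-4).
#' @return list with `selected` (contig ids), `table` (annotated input) and
#'   `cumulative_length` of selected contigs.
#' @export
select_x_contigs <- function(annotations, min_len = 300000, min_density = 1e-4) {
  stopifnot(all(c("contig", "length", "genes") %in% names(annotations)),
            all(annotations$length > 0), all(annotations$genes >= 0))
  density <- annotations$genes / annotations$length
  sel <- annotations$length > min_len & density > min_density
  tab <- cbind(annotations, density = density, selected = sel)
  list(selected = annotations$contig[sel], table = tab,
       cumulative_length = sum(annotations$length[sel]))
}
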