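# Hard filtering of variant records and the genotype call-rate rule.

#' Hard-filter policy
#'
#' Default thresholds: a site is removed if
#' `MQ < 15`, `SOR > 4`, `QD < 20`, `FS > 60`, `MQRankSum < -10`,
#' `ReadPosRankSum` outside `[-2, 2]`, or `DP` outside `[6, 100]`
#' ("between 6 and 100" read as inclusive). Note `QD < 20` is far stricter
#' than common GATK practice (usually `QD < 2`); it is applied verbatim and
#' can be overridden here.
#'
#' @param mq_min,sor_max,qd_min,fs_max,mqrs_min,rprs_abs_max,dp_min,dp_max
#'   numeric thresholds; set any to `NA` to disable that criterion.
#' @param min_call_rate minimum fraction of called genotypes per site
#'   (boundary inclusive: "at least").
#' @param strict_missing if `TRUE`, a site whose annotation is absent fails
#'   that criterion; default `FALSE` (absent annotation cannot be evaluated,
#'   so the criterion passes).
#' @return a `filter_policy` list.
#' @export
filter_policy <- function(mq_min = 15, sor_max = 4, qd_min = 20, fs_max = 60,
                          mqrs_min = -10, rprs_abs_max = 2,
                          dp_min = 6, dp_max = 100,
                          min_call_rate = 0.75, strict_missing = FALSE) {
  stopifnot(is.na(dp_min) || is.na(dp_max) || dp_min < dp_max,
            min_call_rate > 0, min_call_rate <= 1)
  structure(as.list(environment()), class = "filter_policy")
}

#' Apply hard filters to a variant table
#'
#' A record is removed iff any enabled criterion fires. The per-criterion
#' tally counts every firing, so its sum can exceed the number of removed
#' records (a record may fail several criteria).
#'
#' @param vt a [variant_table()].
#' @param policy a [filter_policy()].
#' @return list with `kept` (filtered `variant_table`), `removed` (count) and
#'   `tally` (named integer vector of per-criterion firings).
#' @export
hard_filter <- function(vt, policy = filter_policy()) {
  qc <- vt$qc
  crit <- function(v, fails) {
    out <- !is.na(v) & fails
    if (isTRUE(policy$strict_missing)) out <- out | is.na(v)
    out
  }
  off <- function(x) rep(FALSE, n_sites(vt))
  fires <- cbind(
    MQ = if (is.na(policy$mq_min)) off() else crit(qc[, "MQ"], qc[, "MQ"] < policy$mq_min),
    SOR = if (is.na(policy$sor_max)) off() else crit(qc[, "SOR"], qc[, "SOR"] > policy$sor_max),
    QD = if (is.na(policy$qd_min)) off() else crit(qc[, "QD"], qc[, "QD"] < policy$qd_min),
    FS = if (is.na(policy$fs_max)) off() else crit(qc[, "FS"], qc[, "FS"] > policy$fs_max),
    MQRankSum = if (is.na(policy$mqrs_min)) off() else
      crit(qc[, "MQRankSum"], qc[, "MQRankSum"] < policy$mqrs_min),
    ReadPosRankSum = if (is.na(policy$rprs_abs_max)) off() else
      crit(qc[, "ReadPosRankSum"], abs(qc[, "ReadPosRankSum"]) > policy$rprs_abs_max),
    DP = if (is.na(policy$dp_min)) off() else
      crit(qc[, "DP"], qc[, "DP"] < policy$dp_min | qc[, "DP"] > policy$dp_max))
  bad <- rowSums(fires) > 0
  list(kept = vt[!bad], removed = sum(bad), tally = colSums(fires))
}

#' Filter sites on genotype call rate
#'
#' Keeps a site iff the fraction of non-missing genotypes is at least
#' `min_rate` (the at-least-75%-of-genotypes rule; boundary inclusive).
#'
#' @param vt a [variant_table()].
#' @param min_rate minimum call-rate fraction (default 0.75).
#' @return filtered `variant_table`.
#' @export
call_rate_filter <- function(vt, min_rate = 0.75) {
  rate <- rowMeans(!is.na(vt$gt))
  vt[rate >= min_rate]
}
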