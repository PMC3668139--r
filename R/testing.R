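## Weighted multiple-testing procedures.
##
## With mean-one weights W (sum W = m) and Q_i = P_i / W_i:
##   Bonferroni: reject H_j iff Q_j <= alpha / m
##   Holm: no rejection if Q_(1) >= alpha/m; otherwise reject the j smallest
##     Q's for the largest j with Q_(i) <= alpha / sum_{k>=i} W_(k) for all
##     i <= j
##   BH: step-up, largest j with Q_(j) <= alpha * j / m
## When an effective number of tests m_eff = m * ratio is configured, it
## replaces m in the Bonferroni and BH thresholds; in Holm the weight-sum
## denominators are rescaled by (m_eff / m) so the first step reproduces
## alpha / m_eff.

#' Weighted p-values Q = P / W
#'
#' @param assoc an [AssocResults-class] object.
#' @param w a normalized (mean-one) [WeightVector-class] aligned with
#'   `assoc` by SNP id.
#' @return A [WeightedPValues-class] object.  Q can exceed 1; it is not a
#'   p-value and is never clipped.
#' @examples
#' a <- AssocResults("rs1877031", 4.32e-6)
#' w <- new("WeightVector", snp = "rs1877031", w = 3.70,
#'          normalized = FALSE, scheme = "binary")
#' qValues(weightedPValues(a, w, requireNormalized = FALSE))  # 1.17e-6
#' @param requireNormalized insist on mean-one weights (default TRUE).
#' @export
weightedPValues <- function(assoc, w, requireNormalized = TRUE) {
  stopifnot(is(assoc, "AssocResults"), is(w, "WeightVector"))
  if (!identical(assoc@snp, w@snp)) {
    bad <- which(assoc@snp != rep_len(w@snp, length(assoc@snp)))[1L]
    stop("association table and weights are misaligned; first mismatch: '",
         assoc@snp[bad], "' vs '", rep_len(w@snp, length(assoc@snp))[bad],
         "'")
  }
  if (requireNormalized && !w@normalized)
    stop("weights must be mean-one normalized (see normalizeWeights)")
  new("WeightedPValues", snp = assoc@snp, p = assoc@p, w = w@w,
      q = assoc@p / w@w)
}

#' Effective number of independent tests
#'
#' `m * ratio`, not rounded; used as the divisor in thresholds to account
#' for LD-induced correlation between SNP tests.  The ratio itself is a
#' supplied parameter (e.g. 0.791 for a 300k genotyping array, 0.30 for
#' HapMap-imputed data).
#'
#' @param m integer number of tests.
#' @param ratio effective ratio in (0, 1].
#' @return numeric effective test count.
#' @export
effectiveTestCount <- function(m, ratio) {
  stopifnot(m >= 1)
  if (ratio > 1 || ratio <= 0) stop("effective ratio must lie in (0, 1]")
  m * ratio
}

.sorted_q <- function(q) {
  # stable sort by (q, snp_id); NA q (failed fits) sort last and never reject
  ord <- order(q@q, q@snp, na.last = TRUE)
  list(ord = ord, q = q@q[ord], snp = q@snp[ord], w = q@w[ord])
}

.report <- function(procedure, alpha, count, q, reject, threshold) {
  ord <- order(q@q, q@snp, na.last = TRUE)
  new("RejectionReport", procedure = procedure, alpha = alpha,
      count = count, snp = q@snp, q = q@q, reject = reject,
      threshold = threshold, rejected = q@snp[ord][reject[ord]])
}

#' Weighted Bonferroni procedure (FWER)
#'
#' Rejects every hypothesis with `Q_j <= alpha / count`.  With mean-one
#' weights this controls the FWER at level alpha.
#'
#' @param q a [WeightedPValues-class] object.
#' @param alpha nominal FWER level.
#' @param count test count used in the threshold; defaults to m, pass an
#'   [effectiveTestCount()] to adjust for LD.
#' @return A [RejectionReport-class] object.
#' @export
weightedBonferroni <- function(q, alpha = 0.05, count = length(q)) {
  stopifnot(is(q, "WeightedPValues"), count > 0)
  thr <- alpha / count
  reject <- !is.na(q@q) & q@q <= thr
  .report("bonferroni", alpha, count, q, reject,
          rep(thr, length(q@snp)))
}

#' Weighted Holm step-down procedure (FWER)
#'
#' Sort Q ascending; stop immediately if `Q_(1) >= alpha / count`;
#' otherwise reject the j smallest Q's for the largest j such that
#' `Q_(i) <= alpha / (S_i * count/m)` for all `i <= j`, where
#' `S_i = sum_{k >= i} W_(k)` is the tail sum of the sorted weights.  With
#' `count = m` (default) this is the quoted weighted Holm procedure; with
#' an effective count the denominators are rescaled so that step one
#' reproduces the Bonferroni threshold `alpha / count`.
#'
#' @param assoc an [AssocResults-class] object.
#' @param w a normalized [WeightVector-class].
#' @param alpha nominal FWER level.
#' @param count effective test count (default m).
#' @return A [RejectionReport-class] object.
#' @export
weightedHolm <- function(assoc, w, alpha = 0.05, count = length(assoc)) {
  q <- weightedPValues(assoc, w)
  m <- length(q)
  s <- .sorted_q(q)
  tailW <- rev(cumsum(rev(s$w)))          # S_i = sum_{k>=i} W_(k)
  thr <- alpha / (tailW * (count / m))
  nrej <- 0L
  if (!is.na(s$q[1L]) && s$q[1L] < alpha / count) {
    ok <- !is.na(s$q) & s$q <= thr
    fail <- which(!ok)
    nrej <- if (length(fail)) fail[1L] - 1L else m
  }
  reject <- logical(m)
  reject[s$ord[seq_len(nrej)]] <- TRUE
  threshold <- numeric(m)
  threshold[s$ord] <- thr
  .report("holm", alpha, count, q, reject, threshold)
}

#' Weighted Benjamini-Hochberg step-up procedure (FDR)
#'
#' Sort Q ascending and find the largest j with
#' `Q_(j) <= alpha * j / count`; reject the j smallest Q's.
#'
#' @inheritParams weightedBonferroni
#' @param alpha nominal FDR level.
#' @return A [RejectionReport-class] object.
#' @export
weightedBH <- function(q, alpha = 0.05, count = length(q)) {
  stopifnot(is(q, "WeightedPValues"), count > 0)
  m <- length(q)
  s <- .sorted_q(q)
  thr <- alpha * seq_len(m) / count
  ok <- which(!is.na(s$q) & s$q <= thr)
  nrej <- if (length(ok)) max(ok) else 0L
  reject <- logical(m)
  reject[s$ord[seq_len(nrej)]] <- TRUE
  threshold <- numeric(m)
  threshold[s$ord] <- thr
  .report("bh", alpha, count, q, reject, threshold)
}

#' Rank shifts induced by weighting
#'
#' 1-based ranks of each SNP by the original p-value and by the weighted
#' p-value (ascending; ties broken by SNP id), plus the eQTL flag --
#' plot-ready for rank-shift and Q-Q displays.
#'
#' @param assoc an [AssocResults-class] object.
#' @param q a [WeightedPValues-class] object aligned with `assoc`.
#' @param eqtlFlags logical per-SNP eQTL indicator (or an
#'   [EqtlCatalog-class]).
#' @return data.frame with columns snp_id, is_eqtl, rank_by_p, rank_by_q.
#' @export
rankShiftTable <- function(assoc, q, eqtlFlags = FALSE) {
  stopifnot(is(assoc, "AssocResults"), is(q, "WeightedPValues"),
            identical(assoc@snp, q@snp))
  if (is(eqtlFlags, "EqtlCatalog")) eqtlFlags <- assoc@snp %in% eqtlFlags@snp
  rank_of <- function(v) {
    ord <- order(v, assoc@snp, na.last = TRUE)
    r <- integer(length(v)); r[ord] <- seq_along(v); r
  }
  data.frame(snp_id = assoc@snp,
             is_eqtl = rep_len(eqtlFlags, length(assoc)),
             rank_by_p = rank_of(assoc@p),
             rank_by_q = rank_of(q@q),
             stringsAsFactors = FALSE)
}

#' Q-Q table of observed versus expected -log10 p
#'
#' Expected quantiles are `-log10(j / (m + 1))` for the j-th smallest
#' value; plot-ready for quantile-quantile displays of original or weighted
#' p-values.
#'
#' @param p numeric vector of p-values (or weighted p-values).
#' @return data.frame with columns expected, observed (both -log10 scale),
#'   sorted by the observed statistic.
#' @export
qqTable <- function(p) {
  p <- sort(p[!is.na(p)])
  m <- length(p)
  data.frame(expected = -log10(seq_len(m) / (m + 1)),
             observed = -log10(p))
}
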