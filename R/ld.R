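## Pairwise linkage disequilibrium from unphased genotypes.
##
## Two-locus haplotype frequencies are estimated by maximum-likelihood EM:
## every genotype pair determines its two haplotypes except the double
## heterozygote, whose mass is split between the (AB, ab) and (Ab, aB)
## phases in the E-step according to the current frequencies.  r2 =
## D^2 / (pA pa pB pb); D' = |D| / Dmax with the standard Dmax by the sign
## of D.  Individuals with a missing genotype at either SNP are dropped
## pairwise.

.EM_TOL <- 1e-8
.EM_MAXIT <- 1000L

#' Pairwise LD between two SNPs (EM on unphased genotypes)
#'
#' @param g1,g2 numeric alt-dosage vectors in {0,1,2,NA}, same length.
#' @param trace return the per-iteration observed-data log-likelihood in
#'   attribute `"loglik"` (default FALSE).
#' @return An [LdEstimate-class] with haplotype frequencies (AB, Ab, aB,
#'   ab; capital = alt allele), D, r2 and D'.
#' @examples
#' g <- c(0, 1, 2, 1, 0, 2)
#' pairwiseLd(g, g)  # perfect LD: r2 = 1, D' = 1
#' @export
pairwiseLd <- function(g1, g2, trace = FALSE) {
  stopifnot(length(g1) == length(g2))
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  if (n < 2) stop("need >= 2 individuals with complete data for the pair")
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2)
    stop("monomorphic SNP in the complete-data subsample: r2 undefined")
  # 3x3 genotype table, cells indexed by (alt count at 1, alt count at 2)
  tab <- matrix(0L, 3, 3)
  for (i in seq_len(n)) tab[g1[i] + 1L, g2[i] + 1L] <-
      tab[g1[i] + 1L, g2[i] + 1L] + 1L
  est <- .ld_em(tab, trace = trace)
  est@nUsed <- n
  est
}

## EM on a 3x3 genotype count table; haplotypes ordered (AB, Ab, aB, ab)
.ld_em <- function(tab, trace = FALSE) {
  n <- sum(tab)
  # known haplotype contributions from unambiguous cells: cell (i,j) with
  # alt counts (a1, a2) contributes min/max split; only (1,1) is ambiguous
  base <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (a1 in 0:2) for (a2 in 0:2) {
    cnt <- tab[a1 + 1L, a2 + 1L]
    if (!cnt || (a1 == 1 && a2 == 1)) next
    # alleles at each locus split deterministically across the 2 haplotypes
    h1 <- c(min(a1, 1), a1 - min(a1, 1))      # alt indicator per haplotype
    # for a1 in {0,2} both haplotypes identical; for a1==1 one alt one ref,
    # and since a2 != 1 the pairing is forced
    hapcount <- matrix(0, 2, 2)  # rows: hap 1/2; cols: locus
    hapcount[, 1] <- if (a1 == 2) c(1, 1) else if (a1 == 0) c(0, 0) else c(1, 0)
    hapcount[, 2] <- if (a2 == 2) c(1, 1) else if (a2 == 0) c(0, 0) else {
      # a2 == 1 with a1 != 1: both haplotypes agree at locus 1, phase
      # irrelevant; put the alt-2 allele on haplotype 1
      c(1, 0)
    }
    for (h in 1:2) {
      key <- 1L + (1L - hapcount[h, 1]) * 2L + (1L - hapcount[h, 2])
      # key: AB=1, Ab=2, aB=3, ab=4
      base[key] <- base[key] + cnt
    }
  }
  ndh <- tab[2, 2]                       # double heterozygotes
  p <- {
    # linkage-equilibrium initialization from allele frequencies
    pA <- (sum(tab * matrix(0:2, 3, 3)) ) / (2 * n)
    pB <- (sum(tab * matrix(0:2, 3, 3, byrow = TRUE))) / (2 * n)
    c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  }
  ll <- numeric(0)
  for (it in seq_len(.EM_MAXIT)) {
    # E-step: split double-het mass between cis (AB,ab) and trans (Ab,aB)
    cis <- p[1] * p[4]
    trans <- p[2] * p[3]
    wcis <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    hap <- base
    hap[c(1, 4)] <- hap[c(1, 4)] + ndh * wcis
    hap[c(2, 3)] <- hap[c(2, 3)] + ndh * (1 - wcis)
    pNew <- hap / (2 * n)
    if (trace) ll <- c(ll, .ld_loglik(tab, pNew))
    if (max(abs(pNew - p)) < .EM_TOL) { p <- pNew; break }
    p <- pNew
  }
  pA <- p[1] + p[2]; pB <- p[1] + p[3]
  D <- p[1] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom > 0) D^2 / denom else NA_real_
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax > 0) abs(D) / dmax else 0
  out <- new("LdEstimate", r2 = min(r2, 1), dprime = min(dprime, 1), D = D,
             hapFreq = setNames(p, c("AB", "Ab", "aB", "ab")),
             nUsed = as.integer(sum(tab)))
  if (trace) attr(out, "loglik") <- ll
  out
}

## observed-data log-likelihood of a genotype table under haplotype freqs
.ld_loglik <- function(tab, p) {
  # genotype pair probability = sum over compatible ordered haplotype pairs
  hapAllele <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  ll <- 0
  for (a1 in 0:2) for (a2 in 0:2) {
    cnt <- tab[a1 + 1L, a2 + 1L]
    if (!cnt) next
    pr <- 0
    for (h1 in 1:4) for (h2 in 1:4)
      if (hapAllele[h1, 1] + hapAllele[h2, 1] == a1 &&
          hapAllele[h1, 2] + hapAllele[h2, 2] == a2)
        pr <- pr + p[h1] * p[h2]
    ll <- ll + cnt * log(max(pr, 1e-300))
  }
  ll
}

#' Window-based LD pruning
#'
#' Slides a window of `window` SNPs advancing by `step` along each
#' chromosome (SNPs must be ordered by chromosome and position); within
#' every window placement, while any retained pair has `r2 > r2max`, the
#' pair member with the lower minor-allele frequency is dropped (ties: the
#' one at the larger position).  Removed SNPs are never reconsidered.
#' Defaults mirror the common PLINK setting `--indep-pairwise 50 5 0.8`.
#'
#' @param G a [GenotypeData-class] object.
#' @param window window width in SNPs.
#' @param step step size in SNPs.
#' @param r2max prune threshold (drop when r2 strictly exceeds it).
#' @return character vector of kept SNP ids, input order preserved.
#' @export
ldPrune <- function(G, window = 50L, step = 5L, r2max = 0.8) {
  stopifnot(is(G, "GenotypeData"), window >= 2, step >= 1)
  rd <- SummarizedExperiment::rowData(G)
  g <- dosages(G)
  m <- nrow(rd)
  if (!all(is.na(rd$pos))) {
    ord <- order(rd$chrom, rd$pos)
    if (!identical(ord, seq_len(m)))
      stop("SNPs must be ordered by (chrom, pos) before pruning")
  }
  maf <- apply(g, 2, function(col) {
    f <- mean(col, na.rm = TRUE) / 2
    min(f, 1 - f)
  })
  keep <- rep(TRUE, m)
  chromF <- factor(rd$chrom, levels = unique(rd$chrom))
  for (idx in split(seq_len(m), chromF)) {
    mm <- length(idx)
    starts <- unique(c(seq(1L, max(1L, mm - window + 1L), by = step)))
    for (s in starts) {
      win <- idx[s:min(mm, s + window - 1L)]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2) break
        dropped <- FALSE
        for (ii in seq_len(length(act) - 1L)) {
          if (dropped) break
          for (jj in seq(ii + 1L, length(act))) {
            a <- act[ii]; b <- act[jj]
            r2 <- tryCatch(pairwiseLd(g[, a], g[, b])@r2,
                           error = function(e) NA_real_)
            if (!is.na(r2) && r2 > r2max) {
              # drop the lower-MAF member; tie -> larger position (later col)
              drop <- if (maf[a] < maf[b]) a
                      else if (maf[b] < maf[a]) b
                      else b
              keep[drop] <- FALSE
              dropped <- TRUE
              break
            }
          }
        }
        if (!dropped) break
      }
    }
  }
  rd$snp[keep]
}

#' Extend a SNP set with LD proxies
#'
#' Adds every SNP in strong LD (`r2 >= r2min`) with a member of the input
#' set -- one LD hop only, no transitive closure.  When positions are
#' supplied, pairs farther apart than `maxDist` are not used (500 kb
#' default, the usual proxy-search distance limit).
#'
#' @param snps character SNP ids.
#' @param ld an [LdTable-class] object.
#' @param r2min inclusion threshold (inclusive).
#' @param maxDist distance cap in bp, applied when the LD table carries
#'   distances.
#' @return character vector: the input set plus its proxies (unique).
#' @export
extendWithProxies <- function(snps, ld, r2min = 0.8, maxDist = 5e5) {
  stopifnot(is(ld, "LdTable"))
  snps <- unique(as.character(snps))
  ok <- ld@r2 >= r2min & (is.na(ld@dist) | abs(ld@dist) <= maxDist)
  prox <- c(ld@snpB[ok & ld@snpA %in% snps],
            ld@snpA[ok & ld@snpB %in% snps])
  unique(c(snps, prox))
}

#' LD-aware novelty filter for weighted hit lists
#'
#' Returns the SNPs found only by the weighted analysis that are not in LD
#' (`r2 < r2max`, default 0.4) with any SNP found by the unweighted
#' analysis.  Pairs absent from the LD table are treated as not in LD and
#' flagged `ld_known = FALSE` so that no-LD-data novelty claims are
#' distinguishable.
#'
#' @param weightedHits,unweightedHits character SNP id sets.
#' @param ld an [LdTable-class] object.
#' @param r2max novelty threshold (a hit is novel when all its r2 against
#'   unweighted hits are strictly below it).
#' @return data.frame with columns snp_id, max_r2 (NA when no pair was in
#'   the table) and ld_known.
#' @export
novelHits <- function(weightedHits, unweightedHits, ld, r2max = 0.4) {
  stopifnot(is(ld, "LdTable"))
  extra <- setdiff(weightedHits, unweightedHits)
  if (!length(extra) || !length(unweightedHits))
    return(data.frame(snp_id = extra,
                      max_r2 = rep(NA_real_, length(extra)),
                      ld_known = rep(FALSE, length(extra)),
                      stringsAsFactors = FALSE))
  res <- vapply(extra, function(s) {
    r2 <- ldR2(ld, s, unweightedHits)
    c(max_r2 = if (all(is.na(r2))) NA_real_ else max(r2, na.rm = TRUE),
      ld_known = as.numeric(any(!is.na(r2))))
  }, numeric(2))
  novel <- is.na(res["max_r2", ]) | res["max_r2", ] < r2max
  data.frame(snp_id = extra[novel],
             max_r2 = unname(res["max_r2", novel]),
             ld_known = unname(res["ld_known", novel] > 0),
             stringsAsFactors = FALSE)
}
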