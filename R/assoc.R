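## Genotype QC and the per-SNP logistic association scan.

#' QC thresholds for genotype filtering
#'
#' Defaults follow common GWAS practice: drop SNPs with missing rate
#' >= 5%, minor-allele frequency < 5%, or Hardy-Weinberg 1-df chi-square
#' p-value < 1e-5.
#'
#' @param maxMissing missing-rate cutoff (SNPs at or above are removed).
#' @param minMaf MAF cutoff (SNPs strictly below are removed).
#' @param hweMinP HWE p-value cutoff (SNPs strictly below are removed).
#' @return list of thresholds, validated.
#' @export
qcThresholds <- function(maxMissing = 0.05, minMaf = 0.05, hweMinP = 1e-5) {
  stopifnot(maxMissing > 0, maxMissing < 1, minMaf > 0, minMaf < 1,
            hweMinP > 0, hweMinP < 1)
  list(maxMissing = maxMissing, minMaf = minMaf, hweMinP = hweMinP)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' 1-df chi-square comparing observed genotype counts (n0, n1, n2 copies of
#' the alt allele) with Hardy-Weinberg expectations at the sample allele
#' frequency.
#'
#' @param g numeric dosage vector in {0,1,2,NA}.
#' @return HWE p-value (1 for monomorphic SNPs, where the test is vacuous).
#' @export
hweTest <- function(g) {
  g <- g[!is.na(g)]
  n <- length(g)
  if (n == 0) return(NA_real_)
  cnt <- tabulate(g + 1L, nbins = 3L)
  p <- (cnt[2] + 2 * cnt[3]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  exp <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((cnt - exp)^2 / exp)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Filter SNPs by missingness, MAF and HWE
#'
#' @param G a [GenotypeData-class] object.
#' @param thresholds a [qcThresholds()] list.
#' @return list with elements `genotypes` (the filtered
#'   [GenotypeData-class]) and `removed` (data.frame snp_id, rule; every
#'   rule a SNP violates is listed, comma-separated).
#' @export
qcFilter <- function(G, thresholds = qcThresholds()) {
  stopifnot(is(G, "GenotypeData"))
  g <- dosages(G)
  miss <- colMeans(is.na(g))
  maf <- apply(g, 2, function(col) {
    f <- mean(col, na.rm = TRUE) / 2
    if (is.nan(f)) 0 else min(f, 1 - f)
  })
  hwe <- apply(g, 2, hweTest)
  rules <- cbind(
    missing = miss >= thresholds$maxMissing,
    maf = maf < thresholds$minMaf,
    hwe = !is.na(hwe) & hwe < thresholds$hweMinP)
  bad <- rowSums(rules) > 0
  labels <- c(missing = sprintf("missing >= %g", thresholds$maxMissing),
              maf = sprintf("MAF < %g", thresholds$minMaf),
              hwe = sprintf("HWE p < %g", thresholds$hweMinP))
  removed <- data.frame(
    snp_id = snpIds(G)[bad],
    rule = apply(rules[bad, , drop = FALSE], 1, function(r)
      paste(labels[r], collapse = ", ")),
    stringsAsFactors = FALSE)
  rownames(removed) <- NULL
  list(genotypes = G[!bad, ], removed = removed)
}

#' Per-SNP logistic association scan
#'
#' Fits, for each SNP, an additive-dosage logistic regression of the binary
#' phenotype on the genotype plus optional covariates (iteratively
#' reweighted least squares) and reports the two-sided Wald p-value of the
#' genotype coefficient.  Individuals missing a genotype are dropped for
#' that SNP only.  Non-convergence or separation at a SNP yields a missing
#' p-value with an explanatory note, never a silent 0 or 1; a genotype
#' coefficient aliased with the covariates (rank deficiency) is an error.
#'
#' A closed-form vectorized IRLS path handles the covariate-free scan (the
#' hot loop of permutation studies); the covariate path goes through
#' [stats::glm.fit] per SNP.  The two agree to numerical precision.
#'
#' @param G a [GenotypeData-class] object.
#' @param y binary phenotype (defaults to `phenotype(G)`).
#' @param covar numeric covariate matrix (defaults to `covariates(G)`),
#'   or NULL.
#' @param maxit,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return An [AssocResults-class] object in SNP order; failed fits carry
#'   `NA` p with a note.
#' @export
logisticScan <- function(G, y = phenotype(G), covar = covariates(G),
                         maxit = 50L, tol = 1e-8) {
  stopifnot(is(G, "GenotypeData"))
  if (is.null(y)) stop("no phenotype available")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("phenotype must be binary 0/1")
  if (length(unique(y)) < 2) stop("phenotype must have both classes")
  g <- dosages(G)
  rd <- SummarizedExperiment::rowData(G)
  if (is.null(covar)) {
    res <- .scan_fast(g, y, maxit = maxit, tol = tol)
  } else {
    covar <- as.matrix(covar)
    if (qr(cbind(1, covar))$rank < ncol(covar) + 1)
      stop("covariate matrix is rank deficient")
    res <- .scan_glm(g, y, covar, snp = rd$snp, maxit = maxit, tol = tol)
  }
  AssocResults(rd$snp, res$p, chrom = rd$chrom, pos = rd$pos,
               note = res$note)
}

## per-SNP IRLS for the intercept + dosage model, compiled hot loop;
## missing dosages drop the individual for that SNP only
.scan_fast <- function(g, y, maxit = 50L, tol = 1e-8) {
  res <- .scan_logistic_cpp(g, y, maxit = maxit, tol = tol)
  note <- c("", "monomorphic", "separation", "non-convergence")[res$flag + 1L]
  list(p = res$p, note = note)
}

.scan_glm <- function(g, y, covar, snp, maxit = 50L, tol = 1e-8) {
  m <- ncol(g)
  p <- rep(NA_real_, m)
  note <- rep("", m)
  for (j in seq_len(m)) {
    keep <- !is.na(g[, j])
    X <- cbind(`(Intercept)` = 1, dosage = g[keep, j], covar[keep, , drop = FALSE])
    yy <- y[keep]
    if (length(unique(g[keep, j])) < 2) { note[j] <- "monomorphic"; next }
    if (qr(X)$rank < ncol(X))
      stop("rank-deficient design at SNP ", snp[j],
           " (genotype aliased with covariates)")
    fit <- suppressWarnings(
      glm.fit(X, yy, family = binomial(),
              control = list(maxit = maxit, epsilon = tol)))
    if (!fit$converged) { note[j] <- "non-convergence"; next }
    cf <- fit$coefficients["dosage"]
    if (abs(cf) > 15) { note[j] <- "separation"; next }
    cov <- chol2inv(chol(crossprod(X * fit$weights, X)))
    se <- sqrt(cov[2, 2])
    p[j] <- 2 * pnorm(-abs(cf) / se)
    p[j] <- min(max(p[j], .Machine$double.xmin), 1)
  }
  list(p = p, note = note)
}
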