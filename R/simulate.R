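## Synthetic GWAS study generation and the permutation-based FWER size
## study.
##
## Genotypes are drawn by latent-Gaussian thresholding: each haplotype
## allele is the indicator that an equicorrelated normal exceeds the
## quantile matching its allele frequency, and a genotype is the sum of two
## independent haplotypes -- so Hardy-Weinberg holds marginally and LD is
## confined to blocks.  The latent correlation is calibrated per block so
## the *allelic* correlation, not the latent one, matches the requested
## rho.

#' Synthetic study configuration
#'
#' @param nIndividuals,nSnps study dimensions.
#' @param blockSize LD-block size range in SNPs (scalar or length-2).
#' @param rho target within-block pairwise allelic correlation.
#' @param mafRange minor-allele-frequency range, drawn uniformly per SNP.
#' @param eqtlFraction marginal fraction of SNPs flagged as eQTLs (default
#'   0.106, the cis-eQTL fraction of a 300k asthma GWAS array).
#' @param eqtlLogPRange range of -log10 eQTL p-values, drawn uniformly.
#' @param nCausal number of causal SNPs (0 = complete null).
#' @param effectLogOdds per-allele log-odds of each causal SNP.
#' @param causalEqtlEnrichment odds multiplier for causal SNPs to be
#'   eQTL-flagged (5 = strongly informative prior, 1 = uninformative).
#' @param seed integer RNG seed (mandatory).
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(nIndividuals = 500L, nSnps = 2000L,
                      blockSize = c(10L, 25L), rho = 0.5,
                      mafRange = c(0.05, 0.45), eqtlFraction = 0.106,
                      eqtlLogPRange = c(4, 16), nCausal = 0L,
                      effectLogOdds = 0, causalEqtlEnrichment = 1,
                      seed) {
  if (missing(seed)) stop("seed is mandatory for any stochastic run")
  if (length(blockSize) == 1) blockSize <- rep(blockSize, 2)
  new("SimConfig", nIndividuals = as.integer(nIndividuals),
      nSnps = as.integer(nSnps), blockSize = as.integer(blockSize),
      rho = rho, mafRange = as.numeric(mafRange),
      eqtlFraction = eqtlFraction, eqtlLogPRange = as.numeric(eqtlLogPRange),
      nCausal = as.integer(nCausal), effectLogOdds = effectLogOdds,
      causalEqtlEnrichment = causalEqtlEnrichment, seed = as.integer(seed))
}

## latent correlation giving allelic correlation rho_target for thresholded
## standard normals at threshold t (equal MAF approximation per block)
.latent_rho_cache <- new.env(parent = emptyenv())

.latent_rho <- function(rho_target, maf) {
  if (rho_target <= 0) return(0)
  maf <- round(maf, 3)  # calibration grid; r2 targeting is approximate anyway
  key <- sprintf("%.4f|%.3f", rho_target, maf)
  hit <- .latent_rho_cache[[key]]
  if (!is.null(hit)) return(hit)
  t <- qnorm(1 - maf)
  jointP <- function(r) {
    # P(Z1 > t, Z2 > t) for bivariate standard normal with correlation r
    f <- function(x) (1 - pnorm((t - r * x) / sqrt(1 - r^2))) * dnorm(x)
    stats::integrate(f, t, Inf)$value + 0
  }
  corrOf <- function(r) (jointP(r) - maf^2) / (maf * (1 - maf))
  out <- if (corrOf(0.999999) < rho_target) 0.999999
         else uniroot(function(r) corrOf(r) - rho_target, c(0, 0.999999),
                      tol = 1e-6)$root
  .latent_rho_cache[[key]] <- out
  out
}

#' Simulate a case-control GWAS with LD blocks and eQTL annotation
#'
#' Draws block-correlated genotypes, a logistic-model phenotype over the
#' causal SNPs (Bernoulli(1/2) under the complete null) and an eQTL catalog
#' whose flags hit the marginal `eqtlFraction`, with causal SNPs'
#' flag odds multiplied by `causalEqtlEnrichment`.  Fully reproducible from
#' the seed.
#'
#' @param cfg a [SimConfig-class] object.
#' @return list with elements `genotypes` (a [GenotypeData-class] with
#'   phenotype attached), `eqtl` (an [EqtlCatalog-class] over the flagged
#'   SNPs), `eqtlFlags` (logical per SNP), `causal` (integer indices of
#'   causal SNPs) and `config`.
#' @export
simulateStudy <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  n <- cfg@nIndividuals; m <- cfg@nSnps
  maf <- runif(m, cfg@mafRange[1], cfg@mafRange[2])

  # partition SNPs into LD blocks
  sizes <- integer(0)
  bsRange <- seq(cfg@blockSize[1], cfg@blockSize[2])
  while (sum(sizes) < m)
    sizes <- c(sizes, if (length(bsRange) == 1) bsRange
               else sample(bsRange, 1L))
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - m)
  sizes <- sizes[sizes > 0]
  block <- rep(seq_along(sizes), sizes)

  g <- matrix(0L, n, m)
  for (bl in seq_along(sizes)) {
    idx <- which(block == bl)
    s <- length(idx)
    # SNPs in strong LD have similar allele frequencies: shrink the
    # within-block MAFs toward the block mean by rho so the realized
    # allelic correlation tracks the target
    if (s > 1 && cfg@rho > 0)
      maf[idx] <- cfg@rho * mean(maf[idx]) + (1 - cfg@rho) * maf[idx]
    rz <- if (s > 1) .latent_rho(cfg@rho, mean(maf[idx])) else 0
    thr <- qnorm(1 - maf[idx])
    for (h in 1:2) {  # two independent haplotypes => HWE marginally
      shared <- rnorm(n)
      z <- sqrt(rz) * matrix(shared, n, s) +
           sqrt(1 - rz) * matrix(rnorm(n * s), n, s)
      g[, idx] <- g[, idx] + (z > matrix(thr, n, s, byrow = TRUE))
    }
  }

  causal <- if (cfg@nCausal > 0) sort(sample.int(m, cfg@nCausal)) else integer(0)
  if (cfg@nCausal > 0 && cfg@effectLogOdds != 0) {
    eta <- cfg@effectLogOdds * rowSums(g[, causal, drop = FALSE]) -
           cfg@effectLogOdds * sum(2 * maf[causal])  # center for ~50% prevalence
    y <- rbinom(n, 1, plogis(eta))
  } else {
    y <- rbinom(n, 1, 0.5)
  }

  # eQTL flags: solve the non-causal flag probability so the marginal
  # fraction matches eqtlFraction under the causal odds multiplier
  eps <- cfg@eqtlFraction
  f <- cfg@causalEqtlEnrichment
  nc <- length(causal)
  pFlag <- rep(eps, m)
  if (nc > 0 && f != 1 && eps > 0 && eps < 1) {
    target <- function(x) {
      pc <- f * x / (1 - x + f * x)
      (nc * pc + (m - nc) * x) / m - eps
    }
    x <- uniroot(target, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    pFlag <- rep(x, m)
    pFlag[causal] <- f * x / (1 - x + f * x)
  }
  flags <- runif(m) < pFlag
  snp <- sprintf("snp%05d", seq_len(m))
  eqtl <- if (any(flags)) {
    EqtlCatalog(snp[flags],
                10^(-runif(sum(flags), cfg@eqtlLogPRange[1],
                           cfg@eqtlLogPRange[2])))
  } else NULL

  G <- GenotypeData(g, snp = snp, chrom = "1",
                    pos = seq_len(m) * 1000L, phenotype = y)
  list(genotypes = G, eqtl = eqtl, eqtlFlags = flags, causal = causal,
       config = cfg)
}

#' Permutation size study of the weighted FWER procedures
#'
#' Permutes the phenotype among all individuals, refits the per-SNP
#' logistic scan for every permutation, forms the weighted p-values
#' Q = p/w for each supplied weight vector, and applies each procedure at
#' level `alpha`.  A permutation counts toward the FWER estimate iff it
#' produces at least one rejection (under a permuted phenotype every
#' rejection is a false positive).  Covariates travel with the individuals:
#' only the phenotype is permuted, deliberately breaking the
#' covariate-phenotype link.
#'
#' @param G a [GenotypeData-class] object.
#' @param y binary phenotype (defaults to `phenotype(G)`).
#' @param weights a named list of normalized [WeightVector-class]s (e.g.
#'   `list(original = unitWeights(a), binary = wb)`).
#' @param covar optional covariate matrix (defaults to `covariates(G)`).
#' @param alpha nominal FWER level.
#' @param nPerm number of permutations.
#' @param seed integer RNG seed.
#' @param procedures subset of `c("bonferroni", "holm")`.
#' @param effectiveRatio optional effective-test ratio applied uniformly to
#'   all procedures.
#' @return data.frame with one row per weight x procedure: alpha, n_perm,
#'   n_rejecting, fwer_hat and the Monte-Carlo standard error
#'   `sqrt(fwer_hat*(1-fwer_hat)/n_perm)`.
#' @export
fwerPermutationStudy <- function(G, y = phenotype(G), weights,
                                 covar = covariates(G), alpha = 0.05,
                                 nPerm = 500L, seed,
                                 procedures = c("bonferroni", "holm"),
                                 effectiveRatio = NULL) {
  stopifnot(is(G, "GenotypeData"), nPerm >= 1)
  if (missing(seed)) stop("seed is mandatory")
  if (is(weights, "WeightVector")) weights <- list(weights)
  if (is.null(names(weights)))
    names(weights) <- paste0("w", seq_along(weights))
  procedures <- match.arg(procedures, several.ok = TRUE)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("phenotype must be binary 0/1")
  m <- length(snpIds(G))
  count <- if (is.null(effectiveRatio)) m
           else effectiveTestCount(m, effectiveRatio)
  for (w in weights)
    if (!w@normalized) stop("all weight vectors must be normalized")
  set.seed(seed)
  hits <- matrix(0L, length(weights), length(procedures),
                 dimnames = list(names(weights), procedures))
  for (b in seq_len(nPerm)) {
    yp <- sample(y)
    scan <- logisticScan(G, y = yp, covar = covar)
    for (iw in seq_along(weights)) {
      q <- weightedPValues(scan, weights[[iw]])
      nb <- nh <- 0L
      if ("bonferroni" %in% procedures) {
        nb <- sum(!is.na(q@q) & q@q <= alpha / count)
        hits[iw, "bonferroni"] <- hits[iw, "bonferroni"] + (nb > 0L)
      }
      if ("holm" %in% procedures) {
        rep_h <- weightedHolm(scan, weights[[iw]], alpha = alpha,
                              count = count)
        nh <- sum(rep_h@reject)
        hits[iw, "holm"] <- hits[iw, "holm"] + (nh > 0L)
        if ("bonferroni" %in% procedures && nh < nb)
          stop("internal error: Holm rejected fewer than Bonferroni")
      }
    }
  }
  out <- expand.grid(weight = names(weights), procedure = procedures,
                     stringsAsFactors = FALSE)
  out$alpha <- alpha
  out$n_perm <- nPerm
  out$n_rejecting <- mapply(function(w, p) hits[w, p], out$weight,
                            out$procedure)
  out$fwer_hat <- out$n_rejecting / nPerm
  out$mc_se <- sqrt(out$fwer_hat * (1 - out$fwer_hat) / nPerm)
  out
}
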