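#' @import methods
#' @importFrom stats na.omit pnorm qnorm dnorm pchisq phyper ppois dhyper
#'   plogis binomial glm.fit runif rbinom rnorm setNames uniroot integrate
#' @importFrom utils write.table packageVersion head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom Rcpp evalCpp
#' @useDynLib eqtlWeights, .registration = TRUE
NULL

.fmt <- function(x) format(x, digits = 4, scientific = TRUE)

#' AssocResults: per-SNP association results
#'
#' Holds one association p-value per SNP, optionally with genomic
#' coordinates (1-based, PLINK/VCF convention).  This is the P_i vector that
#' the weighted multiple-testing procedures operate on.
#'
#' @slot snp character SNP identifiers, unique.
#' @slot chrom character chromosome labels (may be NA for summary-only use).
#' @slot pos integer 1-based base-pair positions (may be NA).
#' @slot p numeric association p-values in (0, 1]; NA only for SNPs whose
#'   model fit failed, in which case `note` says why.
#' @slot note character per-SNP fit annotation ("" when clean).
#' @export
setClass("AssocResults",
  representation(snp = "character", chrom = "character", pos = "integer",
                 p = "numeric", note = "character"))

setValidity("AssocResults", function(object) {
  n <- length(object@snp)
  if (n < 1) return("at least one SNP is required")
  if (any(!nzchar(object@snp))) return("empty snp_id")
  if (anyDuplicated(object@snp))
    return(sprintf("duplicate snp_id: %s",
                   object@snp[duplicated(object@snp)][1L]))
  if (length(object@p) != n || length(object@chrom) != n ||
      length(object@pos) != n || length(object@note) != n)
    return("slot lengths differ")
  bad <- which(!is.na(object@p) & (object@p <= 0 | object@p > 1))
  if (length(bad))
    return(sprintf("p-value outside (0,1] at row %d (%s)", bad[1L],
                   object@snp[bad[1L]]))
  if (any(!is.na(object@pos) & object@pos < 1L))
    return("positions must be >= 1 (1-based coordinates)")
  TRUE
})

#' EqtlCatalog: per-SNP best cis-eQTL evidence
#'
#' One row per SNP after collapsing probe-level records to the minimum eQTL
#' p-value (the collapse rule used when a SNP regulates several probes).
#'
#' @slot snp character SNP identifiers, unique after collapse.
#' @slot pEqtl numeric eQTL p-values in (0, 1).
#' @slot lod numeric LOD scores (NA when not supplied).
#' @slot gene character target gene (NA when not supplied).
#' @export
setClass("EqtlCatalog",
  representation(snp = "character", pEqtl = "numeric", lod = "numeric",
                 gene = "character"))

setValidity("EqtlCatalog", function(object) {
  n <- length(object@snp)
  if (n < 1) return("empty eQTL catalog")
  if (anyDuplicated(object@snp))
    return(sprintf("duplicate snp_id after collapse: %s",
                   object@snp[duplicated(object@snp)][1L]))
  if (length(object@pEqtl) != n || length(object@lod) != n ||
      length(object@gene) != n)
    return("slot lengths differ")
  if (any(object@pEqtl <= 0 | object@pEqtl >= 1))
    return("eQTL p-values must lie in (0, 1)")
  if (any(!is.na(object@lod) & object@lod < 0))
    return("LOD scores must be non-negative")
  TRUE
})

#' GenotypeData: individuals x SNPs dosage genotypes
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] storing
#' alt-allele dosages in {0,1,2,NA} as a SNPs x individuals assay named
#' `"dosage"`, SNP keys in `rowData` (snp, chrom, pos) and the optional
#' binary phenotype plus covariates in `colData`.
#'
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  g <- SummarizedExperiment::assay(object, "dosage")
  if (!all(is.na(g) | g %in% c(0, 1, 2)))
    return("dosages must be 0, 1, 2 or NA")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("snp", "chrom", "pos") %in% colnames(rd)))
    return("rowData must carry snp, chrom, pos")
  if (anyDuplicated(rd$snp)) return("duplicate snp_id in rowData")
  cd <- SummarizedExperiment::colData(object)
  if ("phenotype" %in% colnames(cd)) {
    y <- cd$phenotype
    if (!all(is.na(y) | y %in% c(0, 1)))
      return("phenotype must be binary 0/1")
  }
  TRUE
})

#' WeightVector: per-SNP multiple-testing weights
#'
#' Positive weights aligned index-for-index with an [AssocResults-class]
#' object.  Procedures require mean-one normalization (sum(w) = m), the
#' condition under which weighted Bonferroni/Holm/BH retain FWER/FDR control.
#'
#' @slot snp character SNP identifiers, aligned with the association table.
#' @slot w numeric positive weights.
#' @slot normalized logical, TRUE once rescaled to mean one.
#' @slot scheme character, e.g. "general", "binary", "unit" or "custom".
#' @export
setClass("WeightVector",
  representation(snp = "character", w = "numeric", normalized = "logical",
                 scheme = "character"))

setValidity("WeightVector", function(object) {
  if (length(object@w) != length(object@snp)) return("slot lengths differ")
  if (any(!is.finite(object@w)) || any(object@w <= 0))
    return("weights must be positive and finite")
  if (isTRUE(object@normalized) &&
      abs(mean(object@w) - 1) > 1e-12)
    return("normalized weights must have mean 1 within 1e-12")
  TRUE
})

#' BinaryWeightParams: two-valued weight specification
#'
#' An up-weight B for a prior-favored fraction epsilon of hypotheses and a
#' down-weight b for the rest, constrained to mean one:
#' epsilon*B + (1-epsilon)*b = 1.
#'
#' @slot epsilon numeric fraction of hypotheses up-weighted, in (0,1).
#' @slot alpha numeric error-rate level used by the solver.
#' @slot beta numeric complement of the target power used by the solver.
#' @slot m numeric number of hypotheses used by the solver.
#' @slot B numeric up-weight, B >= 1.
#' @slot b numeric down-weight, 0 < b <= 1.
#' @export
setClass("BinaryWeightParams",
  representation(epsilon = "numeric", alpha = "numeric", beta = "numeric",
                 m = "numeric", B = "numeric", b = "numeric"))

setValidity("BinaryWeightParams", function(object) {
  e <- object@epsilon
  if (e <= 0 || e >= 1) return("epsilon must lie in (0,1)")
  if (object@b <= 0) return("down-weight b must be positive")
  if (object@B < 1 || object@B > object@b + 1e-12 && object@b > 1)
    return("need B >= 1 >= b")
  if (abs(e * object@B + (1 - e) * object@b - 1) > 1e-6)
    return("mean-one constraint epsilon*B + (1-epsilon)*b = 1 violated")
  TRUE
})

#' WeightedPValues: the Q_i = P_i / W_i table
#'
#' Weighted p-values aligned with the association table they came from.
#' Q_i can exceed 1 and is not itself a p-value; procedures compare it to
#' modified thresholds.
#'
#' @slot snp character SNP identifiers.
#' @slot p numeric original p-values.
#' @slot w numeric mean-one weights.
#' @slot q numeric weighted p-values p/w.
#' @export
setClass("WeightedPValues",
  representation(snp = "character", p = "numeric", w = "numeric",
                 q = "numeric"))

setValidity("WeightedPValues", function(object) {
  n <- length(object@snp)
  if (length(object@p) != n || length(object@w) != n || length(object@q) != n)
    return("slot lengths differ")
  if (any(!is.na(object@q) & object@q <= 0)) return("q must be positive")
  TRUE
})

#' RejectionReport: decisions of one multiple-testing procedure
#'
#' @slot procedure character, "bonferroni", "holm" or "bh".
#' @slot alpha numeric nominal FWER or FDR level.
#' @slot count numeric test count used in thresholds (m or m_eff).
#' @slot snp character SNP identifiers in input order.
#' @slot q numeric weighted p-values in input order.
#' @slot reject logical per-SNP decision.
#' @slot threshold numeric per-SNP threshold the decision compared against.
#' @slot rejected character rejected SNP ids ordered by ascending q.
#' @export
setClass("RejectionReport",
  representation(procedure = "character", alpha = "numeric",
                 count = "numeric", snp = "character", q = "numeric",
                 reject = "logical", threshold = "numeric",
                 rejected = "character"))

setValidity("RejectionReport", function(object) {
  n <- length(object@snp)
  if (length(object@q) != n || length(object@reject) != n ||
      length(object@threshold) != n)
    return("slot lengths differ")
  if (!setequal(object@rejected, object@snp[object@reject]))
    return("rejected list inconsistent with per-SNP decisions")
  TRUE
})

#' LdTable: precomputed pairwise LD lookups
#'
#' Symmetric lookup of r-squared and D-prime between SNP pairs, e.g. from a
#' SNAP-style proxy search export.
#'
#' @slot snpA,snpB character pair members.
#' @slot r2 numeric r-squared in [0,1].
#' @slot dprime numeric D-prime in [0,1] (NA when not supplied).
#' @slot dist numeric inter-SNP distance in bp (NA when not supplied).
#' @export
setClass("LdTable",
  representation(snpA = "character", snpB = "character", r2 = "numeric",
                 dprime = "numeric", dist = "numeric"))

setValidity("LdTable", function(object) {
  n <- length(object@snpA)
  if (length(object@snpB) != n || length(object@r2) != n ||
      length(object@dprime) != n || length(object@dist) != n)
    return("slot lengths differ")
  if (n && (any(object@r2 < 0 | object@r2 > 1)))
    return("r2 must lie in [0,1]")
  if (any(!is.na(object@dprime) & (object@dprime < 0 | object@dprime > 1)))
    return("D' must lie in [0,1]")
  TRUE
})

#' LdEstimate: EM-estimated two-locus LD
#'
#' @slot r2 numeric r-squared.
#' @slot dprime numeric D-prime.
#' @slot D numeric raw disequilibrium coefficient.
#' @slot hapFreq numeric length-4 haplotype frequencies (AB, Ab, aB, ab where
#'   the capital allele is the alt allele), summing to one.
#' @slot nUsed integer individuals with complete data for the pair.
#' @export
setClass("LdEstimate",
  representation(r2 = "numeric", dprime = "numeric", D = "numeric",
                 hapFreq = "numeric", nUsed = "integer"))

setValidity("LdEstimate", function(object) {
  if (length(object@hapFreq) != 4) return("hapFreq must have length 4")
  if (any(object@hapFreq < -1e-12)) return("haplotype frequencies negative")
  if (abs(sum(object@hapFreq) - 1) > 1e-8)
    return("haplotype frequencies must sum to 1 within 1e-8")
  TRUE
})

#' EnrichmentCounts: hypergeometric enrichment summary
#'
#' @slot N integer background SNP count.
#' @slot K integer eQTL (annotated) count in the background.
#' @slot n integer query-set size.
#' @slot k integer annotated count in the query set.
#' @slot pEnrich numeric upper-tail enrichment p-value (NA when only counts
#'   were requested).
#' @slot method character tail variant used ("hypergeometric", "ease",
#'   "poisson").
#' @export
setClass("EnrichmentCounts",
  representation(N = "integer", K = "integer", n = "integer", k = "integer",
                 pEnrich = "numeric", method = "character"))

setValidity("EnrichmentCounts", function(object) {
  if (object@N < 1) return("background must be non-empty")
  if (object@K > object@N) return("K must not exceed N")
  if (object@n > object@N) return("n must not exceed N")
  if (object@k > min(object@K, object@n))
    return("k must not exceed min(K, n)")
  if (any(c(object@N, object@K, object@n, object@k) < 0))
    return("counts must be non-negative")
  if (!is.na(object@pEnrich) &&
      (object@pEnrich <= 0 || object@pEnrich > 1))
    return("p_enrich must lie in (0,1]")
  TRUE
})

#' SimConfig: synthetic GWAS study configuration
#'
#' Defaults emulate the shape of a childhood-asthma case-control GWAS with a
#' minority (10.6%) of SNPs flagged as cis eQTLs and eQTL p-values drawn as
#' 10^-U(4,16); genotypes come in LD blocks with a target within-block
#' allelic correlation rho.
#'
#' @slot nIndividuals integer sample size.
#' @slot nSnps integer number of SNPs.
#' @slot blockSize integer range (length 2) of LD-block sizes, drawn
#'   uniformly per block.
#' @slot rho numeric target within-block pairwise allelic correlation.
#' @slot mafRange numeric length-2 minor-allele-frequency range.
#' @slot eqtlFraction numeric marginal fraction of SNPs flagged as eQTLs.
#' @slot eqtlLogPRange numeric length-2 range of -log10 eQTL p-values.
#' @slot nCausal integer number of causal SNPs (0 = complete null).
#' @slot effectLogOdds numeric per-allele log-odds of each causal SNP.
#' @slot causalEqtlEnrichment numeric odds multiplier for a causal SNP to be
#'   flagged as an eQTL (1 = uninformative prior).
#' @slot seed integer RNG seed; mandatory.
#' @export
setClass("SimConfig",
  representation(nIndividuals = "integer", nSnps = "integer",
                 blockSize = "integer", rho = "numeric", mafRange = "numeric",
                 eqtlFraction = "numeric", eqtlLogPRange = "numeric",
                 nCausal = "integer", effectLogOdds = "numeric",
                 causalEqtlEnrichment = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nIndividuals < 2 || object@nSnps < 1) return("degenerate size")
  if (length(object@blockSize) != 2 || any(object@blockSize < 1))
    return("blockSize must be a positive length-2 range")
  if (object@rho < 0 || object@rho >= 1) return("rho must lie in [0,1)")
  if (length(object@mafRange) != 2 || any(object@mafRange <= 0) ||
      any(object@mafRange >= 0.5) || diff(object@mafRange) < 0)
    return("mafRange must be an increasing range within (0, 0.5)")
  if (object@eqtlFraction < 0 || object@eqtlFraction > 1)
    return("eqtlFraction must lie in [0,1]")
  if (object@nCausal > object@nSnps) return("more causal SNPs than SNPs")
  if (object@causalEqtlEnrichment <= 0)
    return("enrichment factor must be positive")
  if (is.na(object@seed)) return("seed is mandatory")
  TRUE
})
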