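#' Constructors for the core tabular objects
#'
#' `AssocResults()` builds a per-SNP association table; `EqtlCatalog()`
#' builds a per-SNP eQTL table, collapsing repeated SNP ids (one row per
#' expression probe) to the row with the minimal eQTL p-value.
#'
#' @param snp character SNP ids.
#' @param p numeric association p-values in (0,1].
#' @param chrom,pos optional coordinates (1-based).
#' @param note optional per-SNP annotation.
#' @param pEqtl numeric eQTL p-values in (0,1).
#' @param lod,gene optional LOD scores and target genes.
#' @param collapse collapse repeated snp ids to the minimum p row
#'   (default TRUE).
#' @return An [AssocResults-class] or [EqtlCatalog-class] object.
#' @examples
#' a <- AssocResults(c("rs1", "rs2"), p = c(0.02, 0.5))
#' pValues(a)
#' e <- EqtlCatalog(c("rsX", "rsX"), pEqtl = c(1e-4, 1e-7))
#' length(e)  # collapsed to one row
#' @export
AssocResults <- function(snp, p, chrom = NA, pos = NA, note = "") {
  n <- length(snp)
  new("AssocResults", snp = as.character(snp), p = as.numeric(p),
      chrom = rep_len(as.character(chrom), n),
      pos = rep_len(as.integer(pos), n),
      note = rep_len(as.character(note), n))
}

#' @rdname AssocResults
#' @export
EqtlCatalog <- function(snp, pEqtl, lod = NA, gene = NA, collapse = TRUE) {
  n <- length(snp)
  snp <- as.character(snp)
  pEqtl <- as.numeric(pEqtl)
  lod <- rep_len(as.numeric(lod), n)
  gene <- rep_len(as.character(gene), n)
  if (collapse && anyDuplicated(snp)) {
    # keep, per SNP, the row with the minimal p (first such row on ties),
    # preserving first-appearance order
    best <- tapply(seq_len(n), factor(snp, levels = unique(snp)),
                   function(i) i[which.min(pEqtl[i])])
    idx <- as.integer(best)
    snp <- snp[idx]; pEqtl <- pEqtl[idx]; lod <- lod[idx]; gene <- gene[idx]
  }
  new("EqtlCatalog", snp = snp, pEqtl = pEqtl, lod = lod, gene = gene)
}

#' Assemble a GenotypeData object
#'
#' @param dosage numeric matrix of alt-allele dosages, individuals in rows
#'   and SNPs in columns, entries in {0,1,2,NA}.
#' @param snp,chrom,pos SNP keys for the columns.
#' @param phenotype optional binary 0/1 phenotype per individual.
#' @param covariates optional numeric matrix of per-individual covariates.
#' @return A [GenotypeData-class] object (a `SummarizedExperiment` with a
#'   SNPs x individuals `"dosage"` assay).
#' @export
GenotypeData <- function(dosage, snp = colnames(dosage), chrom = NA, pos = NA,
                         phenotype = NULL, covariates = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(snp)) snp <- paste0("snp", seq_len(m))
  dimnames(dosage) <- NULL
  rd <- S4Vectors::DataFrame(snp = as.character(snp),
                             chrom = rep_len(as.character(chrom), m),
                             pos = rep_len(as.integer(pos), m))
  cd <- S4Vectors::DataFrame(row.names = seq_len(nrow(dosage)))
  if (!is.null(phenotype)) cd$phenotype <- as.numeric(phenotype)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("covar", seq_len(ncol(covariates)))
    for (j in colnames(covariates)) cd[[j]] <- covariates[, j]
    cd$.covar_names <- NULL
    S4Vectors::metadata(cd) <- list(covarNames = colnames(covariates))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dosage)), rowData = rd, colData = cd)
  new("GenotypeData", se)
}

## ---- accessors ----

#' Accessors for the core classes
#'
#' Small, obvious accessors: `snpIds()`, `pValues()`, `weightValues()`,
#' `qValues()`, `dosages()` (individuals x SNPs), `phenotype()`,
#' `covariates()`, `rejectedSnps()`, `decisions()`, `enrichmentP()`.
#'
#' @param x an object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
setMethod("snpIds", "AssocResults", function(x) x@snp)
#' @rdname accessors
setMethod("snpIds", "EqtlCatalog", function(x) x@snp)
#' @rdname accessors
setMethod("snpIds", "WeightVector", function(x) x@snp)
#' @rdname accessors
setMethod("snpIds", "WeightedPValues", function(x) x@snp)
#' @rdname accessors
setMethod("snpIds", "RejectionReport", function(x) x@snp)
#' @rdname accessors
setMethod("snpIds", "GenotypeData",
          function(x) SummarizedExperiment::rowData(x)$snp)

#' @rdname accessors
setMethod("pValues", "AssocResults", function(x) setNames(x@p, x@snp))
#' @rdname accessors
setMethod("pValues", "EqtlCatalog", function(x) setNames(x@pEqtl, x@snp))
#' @rdname accessors
setMethod("chromosomes", "AssocResults", function(x) x@chrom)
#' @rdname accessors
setMethod("positions", "AssocResults", function(x) x@pos)
#' @rdname accessors
setMethod("weightValues", "WeightVector", function(x) setNames(x@w, x@snp))
#' @rdname accessors
setMethod("weightValues", "WeightedPValues", function(x) setNames(x@w, x@snp))
#' @rdname accessors
setMethod("isNormalized", "WeightVector", function(x) x@normalized)
#' @rdname accessors
setMethod("qValues", "WeightedPValues", function(x) setNames(x@q, x@snp))
#' @rdname accessors
setMethod("qValues", "RejectionReport", function(x) setNames(x@q, x@snp))
#' @rdname accessors
setMethod("rejectedSnps", "RejectionReport", function(x) x@rejected)
#' @rdname accessors
setMethod("decisions", "RejectionReport",
          function(x) setNames(x@reject, x@snp))
#' @rdname accessors
setMethod("dosages", "GenotypeData",
          function(x) t(SummarizedExperiment::assay(x, "dosage")))
#' @rdname accessors
setMethod("phenotype", "GenotypeData", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("phenotype" %in% colnames(cd)) cd$phenotype else NULL
})
#' @rdname accessors
setMethod("covariates", "GenotypeData", function(x) {
  cd <- SummarizedExperiment::colData(x)
  nm <- S4Vectors::metadata(cd)$covarNames
  if (is.null(nm) || !length(nm)) return(NULL)
  as.matrix(as.data.frame(cd[, nm, drop = FALSE]))
})
#' @rdname accessors
setMethod("enrichmentP", "EnrichmentCounts", function(x) x@pEnrich)

#' @export
setMethod("length", "AssocResults", function(x) length(x@snp))
#' @export
setMethod("length", "EqtlCatalog", function(x) length(x@snp))
#' @export
setMethod("length", "WeightVector", function(x) length(x@w))
#' @export
setMethod("length", "WeightedPValues", function(x) length(x@q))

#' @export
setMethod("[", "AssocResults", function(x, i, j, ..., drop = TRUE) {
  i <- if (is.character(i)) match(i, x@snp) else i
  initialize(x, snp = x@snp[i], chrom = x@chrom[i], pos = x@pos[i],
             p = x@p[i], note = x@note[i])
})

## ---- coercion to data.frame (report-friendly) ----

#' @export
setMethod("as.data.frame", "AssocResults", function(x, ...) {
  data.frame(snp = x@snp, chrom = x@chrom, pos = x@pos, p = x@p,
             note = x@note, stringsAsFactors = FALSE)
})
#' @export
setMethod("as.data.frame", "EqtlCatalog", function(x, ...) {
  data.frame(snp = x@snp, p_eqtl = x@pEqtl, lod = x@lod, gene = x@gene,
             stringsAsFactors = FALSE)
})
#' @export
setMethod("as.data.frame", "RejectionReport", function(x, ...) {
  data.frame(snp = x@snp, q = x@q, threshold = x@threshold,
             reject = x@reject, q_exceeds_one = x@q > 1,
             stringsAsFactors = FALSE)
})
#' @export
setMethod("as.data.frame", "WeightedPValues", function(x, ...) {
  data.frame(snp = x@snp, p = x@p, w = x@w, q = x@q,
             stringsAsFactors = FALSE)
})
#' @export
setMethod("as.data.frame", "LdTable", function(x, ...) {
  data.frame(snp_a = x@snpA, snp_b = x@snpB, r2 = x@r2, dprime = x@dprime,
             dist = x@dist, stringsAsFactors = FALSE)
})
#' @export
setMethod("as.data.frame", "EnrichmentCounts", function(x, ...) {
  data.frame(N = x@N, K = x@K, n = x@n, k = x@k,
             fraction_background = x@K / x@N, fraction_query = x@k / x@n,
             p_enrich = x@pEnrich, method = x@method,
             stringsAsFactors = FALSE)
})

## ---- show methods ----

setMethod("show", "AssocResults", function(object) {
  cat(sprintf("AssocResults with %d SNPs; p in [%s, %s]\n", length(object),
              .fmt(min(object@p, na.rm = TRUE)),
              .fmt(max(object@p, na.rm = TRUE))))
  if (any(is.na(object@p)))
    cat(sprintf("  %d SNPs with failed fits (see note)\n",
                sum(is.na(object@p))))
})

setMethod("show", "EqtlCatalog", function(object) {
  cat(sprintf("EqtlCatalog with %d SNPs; best p_eqtl %s\n", length(object),
              .fmt(min(object@pEqtl))))
})

setMethod("show", "WeightVector", function(object) {
  cat(sprintf("WeightVector (%s) of length %d; mean %.6f; %s\n",
              object@scheme, length(object), mean(object@w),
              if (object@normalized) "normalized" else "raw"))
})

setMethod("show", "BinaryWeightParams", function(object) {
  cat(sprintf(
    "BinaryWeightParams: epsilon = %.4g, B = %.4g, b = %.4g (alpha = %.3g, beta = %.3g, m = %g)\n",
    object@epsilon, object@B, object@b, object@alpha, object@beta, object@m))
})

setMethod("show", "WeightedPValues", function(object) {
  cat(sprintf("WeightedPValues with %d SNPs; min q = %s; %d with q > 1\n",
              length(object), .fmt(min(object@q, na.rm = TRUE)),
              sum(object@q > 1, na.rm = TRUE)))
})

setMethod("show", "RejectionReport", function(object) {
  cat(sprintf(
    "RejectionReport [%s] at level %.3g (test count %.1f): %d of %d rejected\n",
    object@procedure, object@alpha, object@count, sum(object@reject),
    length(object@snp)))
  if (length(object@rejected))
    cat("  rejected:", paste(head(object@rejected, 8), collapse = ", "),
        if (length(object@rejected) > 8) "..." else "", "\n")
})

setMethod("show", "LdEstimate", function(object) {
  cat(sprintf("LdEstimate: r2 = %.4f, D' = %.4f (n = %d)\n",
              object@r2, object@dprime, object@nUsed))
})

setMethod("show", "LdTable", function(object) {
  cat(sprintf("LdTable with %d pairs\n", length(object@snpA)))
})

setMethod("show", "EnrichmentCounts", function(object) {
  cat(sprintf(
    "EnrichmentCounts: %d/%d (%.1f%%) annotated in query vs %d/%d (%.1f%%) in background\n",
    object@k, object@n, 100 * object@k / object@n, object@K, object@N,
    100 * object@K / object@N))
  if (!is.na(object@pEnrich))
    cat(sprintf("  upper-tail p (%s) = %s\n", object@method,
                .fmt(object@pEnrich)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d individuals x %d SNPs, blocks %d-%d (rho %.2f), %d causal, eQTL fraction %.3f, seed %d\n",
    object@nIndividuals, object@nSnps, object@blockSize[1],
    object@blockSize[2], object@rho, object@nCausal, object@eqtlFraction,
    object@seed))
})
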