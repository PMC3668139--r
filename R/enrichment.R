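## Hypergeometric eQTL enrichment of a SNP set against a background.

#' Exact enrichment test for annotated SNPs in a query set
#'
#' Upper-tail probability that a hypergeometric draw (population `N` with
#' `K` annotated members, `n` draws) yields at least `k` annotated members:
#' `P(X >= k)`, computed by exact summation (log-space, via
#' [stats::phyper]); no normal approximation.  Two historical variants are
#' provided: `"ease"` replaces k by k-1 (the jackknifed score of the EASE
#' software), and `"poisson"` uses the Poisson rate approximation with
#' `lambda = n*K/N` that some published enrichment values were computed
#' under.
#'
#' @param N background SNP count.
#' @param K annotated (eQTL) count in the background.
#' @param n query-set size.
#' @param k annotated count in the query set.
#' @param method `"hypergeometric"` (default, exact), `"ease"` or
#'   `"poisson"`.
#' @return An [EnrichmentCounts-class] object with `pEnrich` filled in.
#' @examples
#' enrichmentP(enrichmentTest(20, 10, 5, 5))  # 252/15504
#' @export
enrichmentTest <- function(N, K, n, k,
                           method = c("hypergeometric", "ease", "poisson")) {
  method <- match.arg(method)
  obj <- new("EnrichmentCounts", N = as.integer(N), K = as.integer(K),
             n = as.integer(n), k = as.integer(k), pEnrich = NA_real_,
             method = method)
  kk <- if (method == "ease") max(0L, obj@k - 1L) else obj@k
  p <- switch(method,
    hypergeometric = phyper(obj@k - 1L, obj@K, obj@N - obj@K, obj@n,
                            lower.tail = FALSE),
    ease = phyper(kk - 1L, obj@K, obj@N - obj@K, obj@n, lower.tail = FALSE),
    poisson = ppois(obj@k - 1L, lambda = obj@n * obj@K / obj@N,
                    lower.tail = FALSE))
  obj@pEnrich <- min(p, 1)
  validObject(obj)
  obj
}

#' Overlap counts between a query set, a background and an annotation
#'
#' Computes (N, K, n, k) by set intersection without the tail probability;
#' feed the counts to [enrichmentTest()] for the p-value.  Query SNPs
#' outside the background are dropped with a warning.
#'
#' @param query character SNP ids of the query set.
#' @param background character SNP ids of the background.
#' @param eqtlFlags character SNP ids carrying the annotation (e.g.
#'   [snpIds()] of an [EqtlCatalog-class]).
#' @return An [EnrichmentCounts-class] object with `pEnrich = NA`.
#' @export
overlapCounts <- function(query, background, eqtlFlags) {
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background set")
  query <- unique(as.character(query))
  out <- setdiff(query, background)
  if (length(out)) {
    warning(length(out), " query SNPs outside the background were dropped")
    query <- intersect(query, background)
  }
  eqtlFlags <- unique(as.character(eqtlFlags))
  new("EnrichmentCounts",
      N = length(background),
      K = length(intersect(eqtlFlags, background)),
      n = length(query),
      k = length(intersect(eqtlFlags, query)),
      pEnrich = NA_real_, method = "counts")
}
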