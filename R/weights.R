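## eQTL-derived weights for weighted multiple testing.
##
## Two schemes: the "general" weight sqrt(-log10 p_eqtl) for eQTL SNPs
## (1 otherwise), and the "binary" weight taking an up-value B on eQTL SNPs
## and a down-value b elsewhere with mean-one constraint eps*B + (1-eps)*b
## = 1.  Procedures require the final vector to have mean exactly 1.

#' General eQTL weights
#'
#' Raw weight `sqrt(-log10 p_eqtl)` for SNPs present in the eQTL catalog and
#' 1 for all others.  The square root tempers the up-weighting of the very
#' strongest eQTLs.  Raw general weights are floored at 1 for eQTL SNPs with
#' `p_eqtl > 0.1` (whose transform would fall below 1): an eQTL annotation
#' never down-weights a SNP.  Normalize with [normalizeWeights()] before use
#' in any testing procedure.
#'
#' @param assoc an [AssocResults-class] object (defines order and m).
#' @param eqtl a collapsed [EqtlCatalog-class] object.
#' @return A raw (unnormalized) [WeightVector-class].
#' @examples
#' a <- AssocResults(c("rs1", "rs2"), p = c(1e-6, 0.2))
#' e <- EqtlCatalog("rs1", 1e-4)
#' weightValues(generalWeights(a, e))  # 2 and 1
#' @export
generalWeights <- function(assoc, eqtl) {
  stopifnot(is(assoc, "AssocResults"), is(eqtl, "EqtlCatalog"))
  idx <- match(assoc@snp, eqtl@snp)
  w <- rep(1, length(assoc))
  hit <- !is.na(idx)
  pe <- eqtl@pEqtl[idx[hit]]
  if (any(pe >= 1))
    stop("eQTL p-value >= 1 would give a non-positive weight")
  w[hit] <- pmax(1, sqrt(-log10(pe)))
  new("WeightVector", snp = assoc@snp, w = w, normalized = FALSE,
      scheme = "general")
}

#' Binary weight parameters
#'
#' @param epsilon fraction of hypotheses up-weighted, in (0,1).
#' @param B up-weight; if omitted, `b` must be given and B is solved from
#'   the mean-one constraint (and vice versa).
#' @param b down-weight.
#' @param alpha,beta,m solver context (recorded; see
#'   [solveBinaryUpweight()]).
#' @return A [BinaryWeightParams-class] object satisfying
#'   `epsilon*B + (1-epsilon)*b = 1`.
#' @examples
#' binaryWeightParams(0.106, B = 3.70)  # b = 0.6799
#' @export
binaryWeightParams <- function(epsilon, B = NULL, b = NULL, alpha = 0.05,
                               beta = 0.4, m = NA_real_) {
  if (is.null(B) && is.null(b)) stop("give at least one of B, b")
  if (is.null(b)) {
    if (epsilon * B >= 1)
      stop("infeasible: epsilon*B >= 1 leaves no mass for the down-weight")
    b <- (1 - epsilon * B) / (1 - epsilon)
  }
  if (is.null(B)) B <- (1 - (1 - epsilon) * b) / epsilon
  new("BinaryWeightParams", epsilon = epsilon, alpha = alpha, beta = beta,
      m = as.numeric(m), B = B, b = b)
}

#' The reference binary-weight preset
#'
#' The published up-weight 3.70 for an eQTL fraction of 0.106 (with the
#' mean-one down-weight 0.68) ships as the default preset; pass a different
#' `B` to re-derive `b` for other settings.
#'
#' @param epsilon eQTL fraction (default 0.106).
#' @param B up-weight (default 3.70).
#' @return A [BinaryWeightParams-class] object.
#' @export
binaryWeightPreset <- function(epsilon = 0.106, B = 3.70) {
  binaryWeightParams(epsilon, B = B)
}

#' Binary eQTL weights
#'
#' Assigns `params@B` to flagged (eQTL) SNPs and `params@b` to the rest.
#' The vector is marked normalized only when the realized flag fraction
#' equals `epsilon`, so that its mean is exactly 1; otherwise normalize with
#' [normalizeWeights()].  Degenerate flag vectors (all TRUE or all FALSE)
#' are renormalized to unit weights with a warning.
#'
#' @param assoc an [AssocResults-class] object.
#' @param eqtlFlags logical per-SNP eQTL indicator aligned with `assoc`, or
#'   an [EqtlCatalog-class] whose membership defines the flags.
#' @param params a [BinaryWeightParams-class] object.
#' @return A [WeightVector-class].
#' @export
binaryWeights <- function(assoc, eqtlFlags, params) {
  stopifnot(is(assoc, "AssocResults"), is(params, "BinaryWeightParams"))
  if (is(eqtlFlags, "EqtlCatalog")) eqtlFlags <- assoc@snp %in% eqtlFlags@snp
  stopifnot(length(eqtlFlags) == length(assoc))
  w <- ifelse(eqtlFlags, params@B, params@b)
  frac <- mean(eqtlFlags)
  if ((frac == 0 || frac == 1) && params@B != params@b) {
    warning("degenerate eQTL flags (all ", frac == 1,
            "); renormalizing to unit weights")
    w <- rep(1, length(w))
    frac <- params@epsilon  # mean is now exactly 1
  }
  wv <- new("WeightVector", snp = assoc@snp, w = w,
            normalized = abs(mean(w) - 1) <= 1e-12, scheme = "binary")
  wv
}

#' Mean-one normalization of weights
#'
#' Divides every weight by the raw mean so that the output has mean exactly
#' 1 (the condition under which the weighted procedures control FWER/FDR).
#' Relative ordering is preserved; the operation is idempotent and
#' invariant to a positive rescaling of the input.
#'
#' @param w a [WeightVector-class] with positive raw weights.
#' @return A normalized [WeightVector-class].
#' @export
normalizeWeights <- function(w) {
  stopifnot(is(w, "WeightVector"))
  if (any(w@w <= 0)) stop("non-positive weight")
  new("WeightVector", snp = w@snp, w = w@w / mean(w@w), normalized = TRUE,
      scheme = w@scheme)
}

#' Unit weights
#'
#' Convenience constructor for the unweighted analysis (every procedure
#' reduces exactly to its classical form under unit weights).
#'
#' @param assoc an [AssocResults-class] object.
#' @return A normalized [WeightVector-class] of ones.
#' @export
unitWeights <- function(assoc) {
  new("WeightVector", snp = assoc@snp, w = rep(1, length(assoc)),
      normalized = TRUE, scheme = "unit")
}

#' Solve for the binary up-weight by a grid search
#'
#' Implements the documented numeric search for the two-valued weight:
#' per-test rejection is modelled as a one-sided normal test at level
#' `alpha * w / m`; for a candidate up-weight B, `xi(B)` is the effect size
#' at which the up-weighted group's power is exactly `1 - beta`; the search
#' reports the B maximizing the down-weighted group's power at `xi(B)` over
#' a grid on `[1, 1/epsilon)`.
#'
#' Under this default power model the down-weighted group's power is
#' monotone decreasing in B, so the unconstrained optimum sits at the lower
#' boundary B = 1 (no weighting).  The published pair (3.70, 0.68) for
#' epsilon = 0.106 arose from assumptions that are not printed; it is
#' available as [binaryWeightPreset()], and this solver exposes its own
#' assumptions (`sided`, grid resolution) as parameters rather than
#' guessing.  Pass `Bmin` to constrain the search away from the boundary.
#'
#' @param epsilon fraction of hypotheses to up-weight, in (0,1).
#' @param alpha error-rate level.
#' @param beta complement of the target power for the up-weighted group.
#' @param m number of hypotheses.
#' @param gridStep resolution of the B grid (default 1e-3).
#' @param sided 1 (default) or 2-sided normal test.
#' @param Bmin lower end of the searched B interval (default 1).
#' @return A [BinaryWeightParams-class] object.
#' @export
solveBinaryUpweight <- function(epsilon, alpha, beta, m, gridStep = 1e-3,
                                sided = 1, Bmin = 1) {
  stopifnot(epsilon > 0, epsilon < 1, alpha > 0, alpha < 1,
            beta > 0, beta < 1, m >= 1)
  if (epsilon * Bmin >= 1)
    stop("infeasible constraint: epsilon*B >= 1 over the whole grid")
  Bgrid <- seq(Bmin, 1 / epsilon - gridStep, by = gridStep)
  lvl <- function(w) alpha * w / m / sided
  zB <- qnorm(1 - lvl(Bgrid))
  xi <- zB + qnorm(1 - beta)              # up-group power(xi) = 1 - beta
  b <- (1 - epsilon * Bgrid) / (1 - epsilon)
  zb <- qnorm(1 - lvl(b))
  powerDown <- 1 - pnorm(zb - xi)
  best <- which.max(powerDown)
  binaryWeightParams(epsilon, B = Bgrid[best], alpha = alpha, beta = beta,
                     m = m)
}
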