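---
title: "eQTL-weighted multiple testing: models, parameters and design notes"
author: "eqtlWeights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eQTL-weighted multiple testing: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlWeights)
```

## The statistical model

A single-SNP association scan produces p-values $P_1,\dots,P_m$, one per
hypothesis $H_1,\dots,H_m$. Given positive weights $W_1,\dots,W_m$ with
$\sum_i W_i = m$ (mean one), the weighted p-value is $Q_i = P_i/W_i$.
$Q_i$ is not itself a p-value — it can exceed 1, and the package never
clips it — but classical procedures applied to $Q$ at their usual
thresholds retain their error-rate guarantees under mean-one weighting:

* weighted Bonferroni rejects $H_j$ iff $Q_j \le \alpha/m$ (FWER
  $\le \alpha$);
* weighted Holm steps down through the sorted $Q_{(i)}$ with thresholds
  $\alpha / \sum_{k \ge i} W_{(k)}$, stopping immediately if
  $Q_{(1)} \ge \alpha/m$ (FWER $\le \alpha$);
* weighted Benjamini–Hochberg steps up with thresholds
  $\alpha\, j/m$ (FDR $\le \alpha$ under the usual independence/PRDS
  conditions).

The guarantee holds for *any* mean-one weights, which is the practical
appeal: weights built from an external eQTL catalog can only help or
mildly hurt power, never invalidate the error control. `normalizeWeights()`
enforces the mean-one constraint exactly (tolerance $10^{-12}$ on the
mean), and every procedure refuses unnormalized weights.

### Effective number of tests

Dense SNP panels are correlated, so $m$ overstates the number of
independent tests. All procedures accept a test count
$m_\mathrm{eff} = m \times \mathrm{ratio}$ (`effectiveTestCount()`); the
ratio is a supplied parameter — 0.791 is a published value for a 300k
array, 0.30 for HapMap-imputed panels — and this package deliberately does
not estimate it. For Bonferroni and BH the substitution is direct. Holm's
thresholds are weight sums, not $m$, so there is an interpretation choice:
we rescale the denominator sums by $m_\mathrm{eff}/m$, which makes Holm's
first step reproduce the adjusted Bonferroni threshold
$\alpha/m_\mathrm{eff}$ and keeps the two procedures nested. The ratio is
applied uniformly to all procedures through one argument.

## Weight construction

**General weight.** $w_g = \sqrt{-\log_{10} p_\mathrm{eQTL}}$ for SNPs in
the eQTL catalog, $w_g = 1$ otherwise. The square root deliberately
tempers the up-weighting of extreme eQTLs (a $10^{-16}$ eQTL gets weight 4,
not 16); descriptions of this weight sometimes omit the square root, and
we document that the transform with the root is the one implemented. Raw
general weights are floored at 1 for catalog SNPs with
$p_\mathrm{eQTL} > 0.1$: an eQTL annotation never down-weights a SNP.
Curated eQTL catalogs thresholded at a LOD score (e.g. > 3.172 at 1% FDR)
cannot produce such rows, but synthetic or lightly filtered inputs can.

**Binary weight.** Up-weight $B$ on the flagged fraction $\epsilon$,
down-weight $b$ on the rest, tied by $\epsilon B + (1-\epsilon) b = 1$.
The reference preset (`binaryWeightPreset()`) is $B = 3.70$ at
$\epsilon = 0.106$, hence $b = 0.6799 \approx 0.68$. When the realized
flag fraction differs from $\epsilon$ the vector's mean is not exactly 1;
`normalizeWeights()` restores it.

**The up-weight solver.** `solveBinaryUpweight()` implements the
documented search for $(B, b)$: per-test rejection is modelled as a
one-sided normal test at level $\alpha w/m$; for candidate $B$, the effect
size $\xi(B)$ is fixed so the up-weighted group's power is exactly
$1-\beta$; the reported $B$ maximizes the down-weighted group's power at
$\xi(B)$ over a grid on $[1, 1/\epsilon)$ at resolution $10^{-3}$. Under
this power model the objective is monotone decreasing in $B$, so the
unconstrained search correctly returns the boundary $B = 1$ — i.e. the
model provides no reason to weight at all unless constrained. The
published pair (3.70, 0.68) evidently arose from additional assumptions
that are not printed anywhere we could verify; rather than guess them, the
solver exposes its own assumptions (`sided`, `gridStep`, `Bmin`) as
parameters and the reference pair ships as an explicit preset. Users with
their own power model can bypass the solver entirely via
`binaryWeightParams(epsilon, B = ...)`.

## Enrichment testing

`enrichmentTest(N, K, n, k)` computes the upper tail
$P(X \ge k)$ of the hypergeometric distribution (population $N$, $K$
annotated, $n$ drawn) by exact summation in log space — no normal
approximation. Two historical variants are provided because published
enrichment values were not always computed with the exact tail:
`method = "ease"` discounts one success ($k-1$; the jackknifed score of
the EASE software, more conservative for small $k$), and
`method = "poisson"` replaces the hypergeometric with a Poisson tail at
rate $\lambda = nK/N$. At the counts of the asthma-GWAS worked example
(251,826 background / 22,922 eQTLs / 38 query / 13 annotated), the exact
tail and the Poisson form differ by a factor of about four; the published
value for that example matches the Poisson form, which is why all three
variants are kept callable. The exact tail remains the default — it is
the statistically correct computation — and the test suite pins each
variant against an independent enumeration oracle and one-sided Fisher.

## Linkage disequilibrium

`pairwiseLd()` estimates two-locus haplotype frequencies from unphased
genotypes by maximum-likelihood EM. Only the double heterozygote is
phase-ambiguous; the E-step splits its mass between the cis (AB/ab) and
trans (Ab/aB) configurations in proportion to the current frequency
products. Numerical choices: initialization at linkage equilibrium
(allele-frequency products), convergence when no frequency moves more than
$10^{-8}$, a 1,000-iteration cap, and pairwise-complete individuals per
SNP pair. $r^2 = D^2/(p_A p_a p_B p_b)$ and $D' = |D|/D_{max}$ with the
standard $D_{max}$ by the sign of $D$. Monomorphic pairs are an error
($r^2$ undefined) rather than a silent 0 or 1.

`ldPrune()` mirrors the common sliding-window pruning (window 50 SNPs,
step 5, drop when $r^2 > 0.8$): within each window placement on each
chromosome, while an offending pair remains, the member with the lower
minor-allele frequency is dropped; on a MAF tie the SNP at the larger
position goes. This drop rule is a documented approximation of the
behavior of mainstream pruning tools, whose exact tie-breaking is not
public; the invariant the package tests is the one that matters — no
retained pair within any window exceeds the threshold, and pruning is
idempotent.

`extendWithProxies()` adds SNPs in strong LD ($r^2 \ge$ threshold,
default 0.8) with the input set — one hop, no transitive closure, with a
500 kb distance cap when the LD table carries distances.
`novelHits()` screens weighted-only findings: a hit is novel when its
$r^2$ against every unweighted hit is below the novelty threshold
(default 0.4, stricter than the proxy threshold on purpose). Pairs absent
from the LD table are treated as not in LD but flagged
`ld_known = FALSE`, so a novelty claim resting on missing LD data is
visible.

## Association scan and QC

`qcFilter()` removes SNPs with missing rate $\ge 5\%$, MAF $< 5\%$, or a
Hardy–Weinberg 1-df chi-square p-value $< 10^{-5}$ (all thresholds
settable); the removal log lists every rule each SNP violated. The
chi-square form of the HWE test was chosen over the exact test for speed
and because QC here feeds simulations rather than primary genotype
curation.

`logisticScan()` fits, per SNP, an additive-dosage logistic regression
(optionally with covariates) by IRLS and reports the two-sided Wald
p-value of the dosage coefficient — the default output of mainstream GWAS
software, chosen over the likelihood-ratio test for comparability;
the suite checks Wald/LRT agreement at large $n$. Individuals missing a
genotype are dropped for that SNP only. Convergence is on coefficient
change $< 10^{-8}$ with a 50-iteration cap. Failures are never silent:
monomorphic SNPs, separated fits ($|\hat\beta| > 15$ or collapsed
information) and non-convergent fits carry an `NA` p-value with a note,
and a genotype aliased with a covariate is an error. The covariate-free
path — the hot loop of permutation studies — runs through a compiled
per-SNP IRLS with a closed-form 2×2 solve; the test suite verifies it
against `stats::glm` to numerical precision. One caveat inherent to Wald
tests in moderate samples: extreme tails are slightly conservative
(Hauck–Donner effect), so empirical FWER estimates tend to sit below the
nominal level.

## The synthetic-data generator

`simulateStudy()` emulates the *shape* of a case-control GWAS with an
eQTL prior: block-structured genotypes, a binary phenotype from a logistic
model over a handful of causal SNPs, and an eQTL catalog covering a
minority of SNPs.

* **Genotypes.** Each haplotype allele is the indicator that a latent
  equicorrelated Gaussian exceeds the quantile of its allele frequency;
  a genotype is the sum of two independent haplotypes, so Hardy–Weinberg
  holds marginally by construction. The latent correlation is calibrated
  numerically (bivariate-normal tail integral + root finding, cached on a
  rounded MAF grid) so the realized *allelic* correlation matches the
  configured `rho`; because indicator correlation degrades with unequal
  thresholds, within-block MAFs are shrunk toward the block mean by `rho`
  — which is also realistic, since SNPs in tight LD have similar allele
  frequencies.
* **Defaults.** 500 individuals × 2,000 SNPs, block sizes 10–25 SNPs,
  `rho = 0.5`, MAF in (0.05, 0.45), eQTL fraction 0.106 with
  $-\log_{10} p_\mathrm{eQTL} \sim U(4, 16)$ — the fraction mirrors the
  cis-eQTL share of a 300k genotyping array, and the eQTL p-value range
  spans a LOD-thresholded catalog. `nCausal = 0` gives the complete null.
* **Informative priors.** `causalEqtlEnrichment` multiplies a causal
  SNP's *odds* of being eQTL-flagged; the non-causal base rate is solved
  so the marginal flag fraction still matches `eqtlFraction`. At
  enrichment 5 and fraction 0.106, roughly 36% of causal SNPs are
  flagged — an informative but far from clairvoyant prior, which is the
  realistic regime for eQTL weighting.
* **What it does not emulate.** Realistic recombination-driven LD decay,
  allele-frequency spectra, population stratification, genotyping error,
  or linkage between causal SNPs and their flags beyond the enrichment
  factor. Tests passing on this generator demonstrate the procedures'
  statistical properties (error control, reduction, nesting, power
  ordering), not performance on any particular cohort.

## The permutation size study

`fwerPermutationStudy()` estimates realized FWER under the complete null:
the phenotype is permuted among all individuals — covariates travel with
the individuals, so the covariate–phenotype link is deliberately broken,
matching the standard label-permutation design — the logistic scan is
refitted per permutation, and a permutation counts toward the estimate iff
any procedure rejection occurs. Bonferroni and Holm are tracked
separately (they almost always agree, and the code asserts in-loop that
Holm's rejection count is never below Bonferroni's). The estimate comes
with its Monte-Carlo standard error
$\sqrt{\hat f (1-\hat f)/n_\mathrm{perm}}$.

### Validation problem sizes

The package's own validation uses desk-scale versions of the full-cohort
analyses: the null size study runs 500 permutations over 500 × 2,000
simulated genotypes (FWER asserted $\le \alpha + 3$ MC-SE for unweighted,
general- and binary-weighted Bonferroni/Holm), and the power comparison
runs 200 replicates per arm of a 500 × 1,000 study with 20 causal SNPs of
per-allele log-odds 0.6 and MAF in (0.1, 0.4) — sized, by a normal
power calculation done when the fixture was designed, so that unweighted
Bonferroni power sits mid-range, where weighting can visibly move the
boundary. A genome-scale run (thousands of permutations over hundreds of
thousands of SNPs) is the same code on bigger inputs.

## Known limitations

* The up-weight solver's default power model cannot reproduce the
  reference pair (3.70, 0.68) from first principles (see above); the pair
  is available as a preset, not derived.
* LD pruning's drop rule approximates mainstream tools; kept-set
  equality with any specific external tool is not guaranteed.
* The logistic scan offers Wald p-values only (no Firth correction, no
  exact logistic regression), so very sparse genotype–phenotype tables
  rely on the separation flags rather than a corrected estimate.
* FDR control is the plain step-up procedure; permutation-based or
  adaptive FDR (q-value) methods are out of scope.
* The effective-test ratio is consumed, never estimated.
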