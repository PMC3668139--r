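test_that("simulation is deterministic given the seed", {
  cfg <- simConfig(nIndividuals = 80, nSnps = 60, nCausal = 3,
                   effectLogOdds = 0.5, seed = 123)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(dosages(s1$genotypes), dosages(s2$genotypes))
  expect_identical(phenotype(s1$genotypes), phenotype(s2$genotypes))
  expect_identical(s1$eqtlFlags, s2$eqtlFlags)
  expect_identical(s1$causal, s2$causal)
  # seed is mandatory
  expect_error(simConfig(nIndividuals = 10, nSnps = 5), "seed")
})

test_that("eQTL flag fraction matches the configured rate", {
  sim <- simulateStudy(simConfig(nIndividuals = 30, nSnps = 10000,
                                 seed = 5))
  se <- sqrt(0.106 * 0.894 / 10000)
  expect_lt(abs(mean(sim$eqtlFlags) - 0.106), 3 * se)
  expect_true(all(pValues(sim$eqtl) < 1e-3))  # -log10 p in (4, 16)
})

test_that("genotypes satisfy HWE marginally and hit the target MAF range", {
  sim <- simulateStudy(simConfig(nIndividuals = 2000, nSnps = 200,
                                 rho = 0.5, mafRange = c(0.1, 0.4),
                                 seed = 6))
  g <- dosages(sim$genotypes)
  hwe <- apply(g, 2, hweTest)
  # under marginal HWE roughly uniform p-values: few below 1e-3
  expect_lt(mean(hwe < 1e-3), 0.02)
  maf <- apply(g, 2, function(c) min(mean(c) / 2, 1 - mean(c) / 2))
  expect_true(all(maf > 0.03 & maf < 0.5))
})

test_that("within-block allelic correlation tracks the configured rho", {
  sim <- simulateStudy(simConfig(nIndividuals = 2000, nSnps = 60,
                                 blockSize = c(6, 6), rho = 0.9,
                                 mafRange = c(0.2, 0.4), seed = 7))
  g <- dosages(sim$genotypes)
  # adjacent pairs inside each 6-SNP block
  r2 <- sapply(seq(1, 55, by = 6), function(s)
    pairwiseLd(g[, s], g[, s + 1])@r2)
  expect_gt(mean(r2), 0.7)
  expect_lt(mean(r2), 0.95)
  # across-block pairs are essentially independent
  r2x <- sapply(seq(1, 48, by = 6), function(s)
    pairwiseLd(g[, s], g[, s + 6])@r2)
  expect_lt(mean(r2x), 0.05)
})

test_that("permutation p-values are uniform under the complete null", {
  sim <- simulateStudy(simConfig(nIndividuals = 300, nSnps = 150,
                                 rho = 0, seed = 8))
  set.seed(88)
  ps <- c()
  for (b in 1:12) {
    yp <- sample(phenotype(sim$genotypes))
    ps <- c(ps, unname(pValues(logisticScan(sim$genotypes, y = yp))))
  }
  # pooled histogram flat: chi-square GOF over 10 bins not rejected at 0.001
  obs <- table(cut(ps, seq(0, 1, 0.1)))
  stat <- sum((obs - length(ps) / 10)^2 / (length(ps) / 10))
  expect_lt(stat, qchisq(0.999, df = 9))
})

test_that("the size study estimates FWER with nested procedures", {
  sim <- simulateStudy(simConfig(nIndividuals = 150, nSnps = 300,
                                 seed = 9))
  a0 <- AssocResults(snpIds(sim$genotypes),
                     p = rep(0.5, 300))
  wb <- normalizeWeights(binaryWeights(a0, sim$eqtlFlags,
                                       binaryWeightPreset()))
  res <- fwerPermutationStudy(sim$genotypes,
                              weights = list(original = unitWeights(a0),
                                             binary = wb),
                              alpha = 0.5, nPerm = 40, seed = 10)
  expect_equal(nrow(res), 4)  # 2 weights x 2 procedures
  expect_true(all(res$fwer_hat >= 0 & res$fwer_hat <= 1))
  expect_equal(res$fwer_hat, res$n_rejecting / res$n_perm)
  expect_equal(res$mc_se,
               sqrt(res$fwer_hat * (1 - res$fwer_hat) / res$n_perm))
  # in-loop nesting assertion did not fire (Holm >= Bonferroni hits)
  byProc <- tapply(res$n_rejecting, res$procedure, sum)
  expect_gte(byProc[["holm"]], byProc[["bonferroni"]])
  # a single permutation with no rejections gives fwer_hat 0
  res1 <- fwerPermutationStudy(sim$genotypes,
                               weights = list(original = unitWeights(a0)),
                               alpha = 1e-6, nPerm = 1, seed = 11)
  expect_equal(res1$fwer_hat, c(0, 0))
})

test_that("the enrichment factor concentrates eQTL flags on causal SNPs", {
  # with a 5x odds multiplier the causal flag rate should sit near 0.36
  # while the marginal rate stays at 0.106
  fr <- pc <- numeric(40)
  for (r in 1:40) {
    sim <- simulateStudy(simConfig(nIndividuals = 20, nSnps = 1000,
                                   nCausal = 50, effectLogOdds = 0.3,
                                   causalEqtlEnrichment = 5,
                                   seed = 500 + r))
    fr[r] <- mean(sim$eqtlFlags)
    pc[r] <- mean(sim$eqtlFlags[sim$causal])
  }
  expect_lt(abs(mean(fr) - 0.106), 3 * sqrt(0.106 * 0.894 / 40000))
  # implied causal flag probability: 5x/(1-x+5x) at the solved base rate
  expect_gt(mean(pc), 0.30); expect_lt(mean(pc), 0.42)
})

test_that("up-weighting an eQTL SNP relaxes exactly its rejection threshold", {
  # deterministic fixture: a causal-like SNP with p between the unweighted
  # and up-weighted Bonferroni thresholds flips to significant iff flagged
  m <- 200
  p <- c(2 * 0.05 / m, rep(0.7, m - 1))
  a <- makeAssoc(p, snp = sprintf("s%03d", 1:m))
  flags <- c(TRUE, rep(FALSE, m - 1))
  flags[seq(10, 200, by = 10)] <- TRUE   # ~10% flagged overall
  wb <- normalizeWeights(binaryWeights(a, flags, binaryWeightPreset()))
  rej <- rejectedSnps(weightedBonferroni(weightedPValues(a, wb), 0.05))
  expect_equal(rej, "s001")
  expect_length(rejectedSnps(weightedBonferroni(
    weightedPValues(a, unitWeights(a)), 0.05)), 0)
})
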