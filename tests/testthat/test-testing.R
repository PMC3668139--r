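test_that("weighted p-values divide p by w and demand alignment", {
  a <- makeAssoc(c(4.32e-6, 7.64e-6, 8.49e-6),
                 snp = c("rs1877031", "rs2941504", "rs11191325"))
  w <- new("WeightVector", snp = snpIds(a), w = rep(3.70, 3),
           normalized = FALSE, scheme = "binary")
  q <- weightedPValues(a, w, requireNormalized = FALSE)
  expect_equal(signif(unname(qValues(q)), 3), c(1.17e-6, 2.06e-6, 2.29e-6))
  # unit weight: q is p exactly
  qu <- weightedPValues(a, unitWeights(a))
  expect_identical(unname(qValues(qu)), unname(pValues(a)))
  # misalignment names the first offender
  wBad <- new("WeightVector", snp = rev(snpIds(a)), w = rep(1, 3),
              normalized = TRUE, scheme = "unit")
  expect_error(weightedPValues(a, wBad), "rs1877031")
})

test_that("q can exceed 1 and is never clipped", {
  a <- makeAssoc(c(0.9, 0.5))
  w <- new("WeightVector", snp = snpIds(a), w = c(0.5, 1.5),
           normalized = TRUE, scheme = "custom")
  q <- weightedPValues(a, w)
  expect_equal(unname(qValues(q))[1], 1.8)
  expect_true(as.data.frame(weightedBonferroni(q, 0.05))$q_exceeds_one[1])
})

test_that("effective test count is plain multiplication with bounds", {
  expect_equal(effectiveTestCount(300821, 0.791), 300821 * 0.791)
  expect_equal(effectiveTestCount(2473850, 0.30), 742155)
  expect_equal(effectiveTestCount(100, 1), 100)
  expect_error(effectiveTestCount(100, 1.2), "\\(0, 1\\]")
})

test_that("weighted Bonferroni rejects exactly the sub-threshold set", {
  a <- makeAssoc(c(2.0e-7, 1.0e-3))
  q <- weightedPValues(a, unitWeights(a))
  cnt <- effectiveTestCount(300821, 0.791)
  r <- weightedBonferroni(q, 0.05, cnt)
  expect_equal(rejectedSnps(r), snpIds(a)[1])
  expect_equal(unique(as.data.frame(r)$threshold), 0.05 / cnt)
  # empty rejection set when all q exceed the threshold
  r2 <- weightedBonferroni(weightedPValues(makeAssoc(c(0.2, 0.9)),
                                           unitWeights(makeAssoc(c(0.2, 0.9)))),
                           0.05, 2)
  expect_length(rejectedSnps(r2), 0)
})

test_that("weighted Holm reproduces hand-enumerated step-downs", {
  # classical Holm, unit weights: thresholds 0.05/3, 0.05/2, 0.05
  a <- makeAssoc(c(0.01, 0.02, 0.9))
  r <- weightedHolm(a, unitWeights(a), 0.05)
  expect_setequal(rejectedSnps(r), snpIds(a)[1:2])
  # weighted example: q_(1) = 0.015 exceeds alpha/sum W = 0.0125 -> empty
  a4 <- makeAssoc(c(0.03, 0.012, 0.5, 0.9))
  w4 <- new("WeightVector", snp = snpIds(a4), w = c(2, 2/3, 2/3, 2/3),
            normalized = TRUE, scheme = "custom")
  r4 <- weightedHolm(a4, w4, 0.05)
  expect_length(rejectedSnps(r4), 0)
  # Q_(1) >= alpha/m stopping rule
  aStop <- makeAssoc(c(0.05, 0.9))
  expect_length(rejectedSnps(weightedHolm(aStop, unitWeights(aStop), 0.05)), 0)
})

test_that("weighted BH reproduces the hand-enumerated step-up", {
  a <- makeAssoc(c(0.001, 0.010, 0.030, 0.500))
  q <- weightedPValues(a, unitWeights(a))
  r <- weightedBH(q, 0.05, 4)
  expect_setequal(rejectedSnps(r), snpIds(a)[1:3])
  expect_length(rejectedSnps(weightedBH(
    weightedPValues(makeAssoc(c(0.6, 0.9)), unitWeights(makeAssoc(c(0.6, 0.9)))),
    0.05)), 0)
})

test_that("unit weights reduce every procedure to its classical form", {
  set.seed(31)
  for (i in 1:50) {
    m <- sample(3:60, 1)
    p <- runif(m)^sample(1:3, 1)
    a <- makeAssoc(p, snp = sprintf("s%03d", 1:m))
    wu <- unitWeights(a)
    q <- weightedPValues(a, wu)
    alpha <- runif(1, 0.01, 0.2)
    expect_identical(unname(decisions(weightedBonferroni(q, alpha))),
                     p <= alpha / m)
    expect_identical(unname(decisions(weightedHolm(a, wu, alpha))),
                     unname(p.adjust(p, "holm") <= alpha) &
                       !(sort(p)[1] >= alpha / m))
    expect_identical(unname(decisions(weightedBH(q, alpha))),
                     unname(p.adjust(p, "BH") <= alpha))
  }
})

test_that("weighted Holm and BH match independent sequential oracles", {
  set.seed(77)
  for (i in 1:60) {
    m <- sample(2:8, 1)
    # p drawn from a grid to exercise near-threshold configurations
    p <- sample(c(1e-4, 1e-3, 5e-3, 0.01, 0.02, 0.05, 0.1, 0.3, 0.8),
                m, replace = TRUE) * runif(m, 0.9, 1.1)
    p <- pmin(p, 1)
    w <- rexp(m) + 0.05
    w <- w / mean(w)
    a <- makeAssoc(p, snp = sprintf("s%d", 1:m))
    wv <- new("WeightVector", snp = snpIds(a), w = w, normalized = TRUE,
              scheme = "custom")
    alpha <- sample(c(0.01, 0.05, 0.2), 1)
    cnt <- if (runif(1) < 0.5) m else m * runif(1, 0.3, 1)
    got <- which(unname(decisions(weightedHolm(a, wv, alpha, cnt))))
    expect_equal(got, oracleHolm(p, w, alpha, cnt))
    q <- weightedPValues(a, wv)
    gotBH <- which(unname(decisions(weightedBH(q, alpha, cnt))))
    expect_equal(gotBH, oracleBH(p, w, alpha, cnt))
  }
})

test_that("Holm and BH rejection sets nest Bonferroni's", {
  set.seed(41)
  for (i in 1:100) {
    m <- sample(3:80, 1)
    p <- runif(m)^2
    w <- rexp(m) + 0.01; w <- w / mean(w)
    a <- makeAssoc(p, snp = sprintf("s%03d", 1:m))
    wv <- new("WeightVector", snp = snpIds(a), w = w, normalized = TRUE,
              scheme = "custom")
    q <- weightedPValues(a, wv)
    alpha <- 0.05
    rb <- rejectedSnps(weightedBonferroni(q, alpha))
    rh <- rejectedSnps(weightedHolm(a, wv, alpha))
    rbh <- rejectedSnps(weightedBH(q, alpha))
    expect_true(all(rb %in% rh))
    expect_true(all(rb %in% rbh))
  }
})

test_that("decreasing a p-value never shrinks a rejection set", {
  set.seed(53)
  for (i in 1:20) {
    m <- 30
    p <- runif(m)
    w <- rexp(m) + 0.1; w <- w / mean(w)
    a <- makeAssoc(p, snp = sprintf("s%03d", 1:m))
    wv <- new("WeightVector", snp = snpIds(a), w = w, normalized = TRUE,
              scheme = "custom")
    j <- sample(m, 1)
    p2 <- p; p2[j] <- p[j] * runif(1)
    a2 <- makeAssoc(p2, snp = snpIds(a))
    for (fn in list(
      function(aa) rejectedSnps(weightedHolm(aa, wv, 0.1)),
      function(aa) rejectedSnps(weightedBH(weightedPValues(aa, wv), 0.1)),
      function(aa) rejectedSnps(weightedBonferroni(weightedPValues(aa, wv), 0.1))))
      expect_true(all(fn(a) %in% fn(a2)))
  }
})

test_that("rank shifts favor up-weighted SNPs and vanish for unit weights", {
  set.seed(61)
  m <- 1000
  p <- runif(m)
  a <- makeAssoc(p, snp = sprintf("s%04d", 1:m))
  flags <- runif(m) < 0.10
  w <- ifelse(flags, 3.70, 0.68)
  wv <- normalizeWeights(new("WeightVector", snp = snpIds(a), w = w,
                             normalized = FALSE, scheme = "binary"))
  q <- weightedPValues(a, wv)
  rs <- rankShiftTable(a, q, flags)
  # up-weighted group's mean rank improves
  expect_lt(mean(rs$rank_by_q[rs$is_eqtl]), mean(rs$rank_by_p[rs$is_eqtl]))
  # every up-weighted SNP individually improves or holds its rank
  expect_true(all(rs$rank_by_q[rs$is_eqtl] <= rs$rank_by_p[rs$is_eqtl]))
  # unit weights leave ranks unchanged
  rsU <- rankShiftTable(a, weightedPValues(a, unitWeights(a)))
  expect_identical(rsU$rank_by_p, rsU$rank_by_q)
})

test_that("Q-Q tables pair sorted observed with -log10(j/(m+1)) quantiles", {
  p <- c(0.5, 0.01, 0.2, 0.9)
  qq <- qqTable(p)
  expect_equal(qq$observed, -log10(sort(p)))
  expect_equal(qq$expected, -log10((1:4) / 5))
})
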