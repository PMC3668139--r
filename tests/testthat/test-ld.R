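test_that("identical polymorphic columns are in perfect LD", {
  g <- c(0, 1, 2, 1, 0, 2, 1, 1)
  est <- pairwiseLd(g, g)
  expect_equal(est@r2, 1)
  expect_equal(est@dprime, 1)
  expect_equal(sum(est@hapFreq), 1, tolerance = 1e-12)
})

test_that("EM reproduces direct haplotype counting on ambiguity-free pairs", {
  freqs <- list(c(0.4, 0.1, 0.1, 0.4), c(0.25, 0.25, 0.25, 0.25),
                c(0.7, 0.05, 0.05, 0.2), c(0.1, 0.4, 0.4, 0.1))
  seeds <- 1:8
  for (f in freqs) for (s in seeds) {
    d <- drawPhasedPair(12, f, seed = s * 100 + which.max(f))
    est <- pairwiseLd(d$g1, d$g2)
    oracle <- d$hapCount / sum(d$hapCount)
    expect_equal(unname(est@hapFreq), oracle, tolerance = 1e-10)
    # r2 and D' recomputable from the oracle frequencies
    pA <- oracle[1] + oracle[2]; pB <- oracle[1] + oracle[3]
    D <- oracle[1] - pA * pB
    if (pA > 0 && pA < 1 && pB > 0 && pB < 1)
      expect_equal(est@r2, D^2 / (pA * (1 - pA) * pB * (1 - pB)),
                   tolerance = 1e-10)
  }
})

test_that("EM equals closed-form counting on all small double-het-free tables", {
  # exhaustively enumerate 3x3 genotype tables with n <= 5, empty (1,1)
  # cell; compare against an independently written per-cell haplotype
  # contribution ledger
  contrib <- function(a1, a2) {
    # returns haplotype counts (AB, Ab, aB, ab) contributed by one
    # individual with alt counts (a1, a2), a1 and a2 not both 1
    h <- c(0, 0, 0, 0)
    if (a1 == 1 && a2 == 1) stop("ambiguous")
    alt1 <- if (a1 == 2) c(TRUE, TRUE) else if (a1 == 1) c(TRUE, FALSE)
            else c(FALSE, FALSE)
    alt2 <- if (a2 == 2) c(TRUE, TRUE) else if (a2 == 1) c(TRUE, FALSE)
            else c(FALSE, FALSE)
    for (hap in 1:2) {
      idx <- if (alt1[hap] && alt2[hap]) 1 else if (alt1[hap]) 2
             else if (alt2[hap]) 3 else 4
      h[idx] <- h[idx] + 1
    }
    h
  }
  cells <- expand.grid(a1 = 0:2, a2 = 0:2)
  cells <- cells[!(cells$a1 == 1 & cells$a2 == 1), ]
  checked <- 0
  for (n in 2:5) {
    combos <- utils::combn(nrow(cells) + n - 1, n)  # weak compositions
    for (ci in seq_len(ncol(combos))) {
      picks <- combos[, ci] - seq_len(n) + 1
      tabCells <- cells[picks, , drop = FALSE]
      g1 <- rep(tabCells$a1, 1); g2 <- rep(tabCells$a2, 1)
      if (length(unique(g1)) < 2 || length(unique(g2)) < 2) next
      hap <- Reduce(`+`, lapply(seq_len(n),
                                function(i) contrib(g1[i], g2[i])))
      est <- pairwiseLd(g1, g2)
      expect_equal(unname(est@hapFreq), hap / (2 * n), tolerance = 1e-10)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 500)
})

test_that("independent SNPs at large n show near-zero r2", {
  set.seed(12)
  g1 <- rbinom(10000, 2, 0.3)
  g2 <- rbinom(10000, 2, 0.3)
  expect_lt(pairwiseLd(g1, g2)@r2, 0.01)
})

test_that("EM log-likelihood never decreases across iterations", {
  set.seed(5)
  for (i in 1:10) {
    hap <- sample.int(4, 120, replace = TRUE,
                      prob = c(0.35, 0.15, 0.15, 0.35))
    a1 <- c(1, 1, 0, 0)[hap]; a2 <- c(1, 0, 1, 0)[hap]
    g1 <- a1[1:60] + a1[61:120]
    g2 <- a2[1:60] + a2[61:120]
    est <- pairwiseLd(g1, g2, trace = TRUE)
    ll <- attr(est, "loglik")
    expect_true(all(diff(ll) >= -1e-9))
  }
})

test_that("monomorphic or data-poor pairs are errors", {
  expect_error(pairwiseLd(c(1, 1, 1, 1), c(0, 1, 2, 1)), "monomorphic")
  expect_error(pairwiseLd(c(1, NA), c(NA, 1)), ">= 2 individuals")
})

test_that("window pruning drops the lower-MAF member of an offending pair", {
  # SNP1 and SNP2 near-duplicates (r2 > 0.8); SNP2 has the lower MAF
  set.seed(21)
  g1 <- rbinom(400, 2, 0.4)
  g2 <- g1
  flip <- sample(400, 12)
  g2[flip] <- pmax(0, g2[flip] - 1)   # slightly fewer alt alleles
  g3 <- rbinom(400, 2, 0.3)
  G <- GenotypeData(cbind(g1, g2, g3), snp = c("s1", "s2", "s3"),
                    chrom = "1", pos = c(100L, 200L, 300L))
  kept <- ldPrune(G, window = 3, step = 1, r2max = 0.8)
  expect_equal(kept, c("s1", "s3"))
  # mutually independent SNPs: everything kept, order preserved
  set.seed(22)
  Gi <- GenotypeData(matrix(rbinom(400 * 6, 2, 0.3), 400, 6),
                     snp = sprintf("i%d", 1:6), chrom = "1",
                     pos = seq(100L, 600L, by = 100L))
  expect_equal(ldPrune(Gi, window = 4, step = 2, r2max = 0.8),
               sprintf("i%d", 1:6))
  # idempotence: pruning the kept set changes nothing
  Gk <- Gi[snpIds(Gi) %in% ldPrune(Gi, 4, 2, 0.8), ]
  expect_equal(ldPrune(Gk, 4, 2, 0.8), snpIds(Gk))
  # unordered positions are rejected
  Gu <- GenotypeData(cbind(g1, g3), snp = c("a", "b"), chrom = "1",
                     pos = c(300L, 100L))
  expect_error(ldPrune(Gu), "ordered")
})

test_that("proxy extension is one hop, threshold-strict and monotone", {
  ld <- LdTable(c("a", "b", "a"), c("b", "c", "d"), c(0.9, 0.9, 0.79))
  ext <- extendWithProxies("a", ld, r2min = 0.8)
  expect_setequal(ext, c("a", "b"))      # no transitive closure; d below 0.8
  # empty LD table: output = input
  expect_equal(extendWithProxies(c("x", "y"), LdTable()), c("x", "y"))
  # boundary: r2 exactly 0.8 is included
  ld2 <- LdTable("a", "e", 0.8)
  expect_true("e" %in% extendWithProxies("a", ld2))
  # monotone in the input set
  bigger <- extendWithProxies(c("a", "b"), ld)
  expect_true(all(ext %in% bigger))
  # distance cap honored when distances are present
  ld3 <- LdTable(c("a", "a"), c("near", "far"), c(0.9, 0.9),
                 dist = c(1e4, 6e5))
  expect_setequal(extendWithProxies("a", ld3), c("a", "near"))
})

test_that("novelty filter keeps only weighted-only hits clear of LD", {
  ld <- LdTable(c("x", "y"), c("u", "u"), c(0.7, 0.1))
  nov <- novelHits(c("x", "y"), "u", ld, r2max = 0.4)
  expect_equal(nov$snp_id, "y")
  expect_true(nov$ld_known)
  # weighted subset of unweighted: nothing novel
  expect_equal(nrow(novelHits("u", c("u", "v"), ld)), 0)
  # unknown pairs are reported novel but flagged as lacking LD data
  nov2 <- novelHits("z", "u", ld, r2max = 0.4)
  expect_equal(nov2$snp_id, "z")
  expect_false(nov2$ld_known)
})
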