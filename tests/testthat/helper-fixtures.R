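# Programmatic fixtures shared across test files.

# small association table
makeAssoc <- function(p, snp = sprintf("rs%03d", seq_along(p))) {
  AssocResults(snp, p, chrom = "1", pos = seq_along(p) * 100L)
}

# write a PLINK-shaped whitespace association file
writeAssocFixture <- function(rows, path = tempfile(fileext = ".assoc")) {
  writeLines(rows, path)
  path
}

# a tiny VCF and its matrix-TSV equivalent (same genotypes)
writeVcfFixture <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "I1", "I2", "I3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "1|1", "0/0", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "./.", "0/1", "1/1", sep = "\t")), path)
  path
}

writeMatrixFixture <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("rs1\trs2", "1\tNA", "2\t1", "0\t2"), path)
  path
}

# genotype column pair with known phased haplotypes and no double
# heterozygotes; returns genotypes plus the true haplotype counts
drawPhasedPair <- function(n, freq, seed) {
  set.seed(seed)
  repeat {
    haps <- sample.int(4, 2 * n, replace = TRUE, prob = freq)
    h1 <- haps[seq_len(n)]
    h2 <- haps[n + seq_len(n)]
    # haplotypes: 1=AB, 2=Ab, 3=aB, 4=ab (capital = alt)
    a1 <- c(1, 1, 0, 0)
    a2 <- c(1, 0, 1, 0)
    g1 <- a1[h1] + a1[h2]
    g2 <- a2[h1] + a2[h2]
    dh <- g1 == 1 & g2 == 1
    if (any(dh)) next  # resample until ambiguity-free
    if (length(unique(g1)) < 2 || length(unique(g2)) < 2) next
    return(list(g1 = g1, g2 = g2,
                hapCount = tabulate(c(h1, h2), nbins = 4)))
  }
}

# independent brute-force multiple-testing oracles (sequential definitions)
oracleHolm <- function(p, w, alpha, count = length(p)) {
  m <- length(p)
  scale <- count / m
  remaining <- seq_len(m)
  rejected <- integer(0)
  q <- p / w
  repeat {
    if (!length(remaining)) break
    i <- remaining[which.min(q[remaining])]
    thr <- alpha / (sum(w[remaining]) * scale)
    firstStep <- length(rejected) == 0
    if (firstStep && q[i] >= alpha / count) break
    if (q[i] > thr) break
    rejected <- c(rejected, i)
    remaining <- setdiff(remaining, i)
  }
  sort(rejected)
}

oracleBH <- function(p, w, alpha, count = length(p)) {
  q <- p / w
  ord <- order(q)
  m <- length(q)
  passing <- which(q[ord] <= alpha * seq_len(m) / count)
  j <- if (length(passing)) max(passing) else 0
  sort(ord[seq_len(j)])
}

# log-space hypergeometric upper tail by direct summation
oracleHyperTail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}
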