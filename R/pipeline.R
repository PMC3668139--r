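## End-to-end analysis orchestration: weights -> adjustment -> rank shift /
## Q-Q / novel-hit reports, plus a serializable run configuration.

#' Run configuration for the analysis pipeline
#'
#' A flat key-value configuration that round-trips through YAML unchanged.
#' Thresholds default to the reference analysis settings: FWER/FDR level
#' 0.05, LD pruning at r2 0.8, proxy extension at r2 0.8, novelty screen at
#' r2 0.4.
#'
#' @param assoc path to the association table.
#' @param eqtl path to the eQTL table.
#' @param ld optional path to a SNAP-shaped LD table.
#' @param outdir output directory.
#' @param scheme weight scheme: "general", "binary" or "both".
#' @param epsilon,upWeight binary-weight parameters (down-weight follows
#'   from the mean-one constraint).
#' @param alpha nominal FWER/FDR level.
#' @param methods procedures to run.
#' @param effectiveRatio optional effective-test ratio in (0,1].
#' @param pruneR2,proxyR2,noveltyR2 LD thresholds.
#' @param seed integer seed recorded in the manifest.
#' @param assocDialect,assocColumns,eqtlColumns input dialect overrides,
#'   passed to the readers.
#' @return A list of class `"RunConfig"`.
#' @export
runConfig <- function(assoc, eqtl, ld = NULL, outdir = ".",
                      scheme = c("both", "general", "binary"),
                      epsilon = 0.106, upWeight = 3.70, alpha = 0.05,
                      methods = c("bonferroni", "holm", "bh"),
                      effectiveRatio = NULL, pruneR2 = 0.8, proxyR2 = 0.8,
                      noveltyR2 = 0.4, seed = 1L,
                      assocDialect = "whitespace",
                      assocColumns = NULL, eqtlColumns = NULL) {
  scheme <- match.arg(scheme)
  methods <- match.arg(methods, several.ok = TRUE)
  for (thr in c(alpha, pruneR2, proxyR2, noveltyR2))
    if (thr <= 0 || thr > 1) stop("thresholds must lie in (0, 1]")
  if (!is.null(effectiveRatio) &&
      (effectiveRatio <= 0 || effectiveRatio > 1))
    stop("effectiveRatio must lie in (0, 1]")
  structure(list(assoc = assoc, eqtl = eqtl, ld = ld, outdir = outdir,
                 scheme = scheme, epsilon = epsilon, upWeight = upWeight,
                 alpha = alpha, methods = methods,
                 effectiveRatio = effectiveRatio, pruneR2 = pruneR2,
                 proxyR2 = proxyR2, noveltyR2 = noveltyR2,
                 seed = as.integer(seed), assocDialect = assocDialect,
                 assocColumns = assocColumns, eqtlColumns = eqtlColumns),
            class = "RunConfig")
}

#' @rdname runConfig
#' @param path YAML file.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(runConfig, vals)
}

#' @rdname runConfig
#' @param cfg a RunConfig.
#' @export
writeRunConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "RunConfig"))
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' Run the full weighted-testing pipeline
#'
#' Reads the association and eQTL tables, builds unweighted, general and/or
#' binary mean-one weight vectors, applies every requested procedure to
#' each, and writes per combination a rejection report and rank-shift
#' table, a Q-Q table per weighting, a novel-hit table (weighted-only hits
#' not in LD with any unweighted hit at the novelty r2) when an LD table is
#' supplied, and a manifest recording package version, seed and all
#' parameters.  Reruns with the same configuration are byte-identical.
#'
#' @param cfg a [runConfig()] object.
#' @return Invisibly, a list with the in-memory reports (`weights`,
#'   `reports`, `novel`, `manifest`).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  readArgs <- list(path = cfg$assoc, dialect = cfg$assocDialect)
  if (!is.null(cfg$assocColumns)) readArgs$columns <- cfg$assocColumns
  assoc <- do.call(readAssocTable, readArgs)
  eqtlArgs <- list(path = cfg$eqtl)
  if (!is.null(cfg$eqtlColumns)) eqtlArgs$columns <- cfg$eqtlColumns
  eqtl <- do.call(readEqtlTable, eqtlArgs)
  ld <- if (!is.null(cfg$ld)) readLdTable(cfg$ld) else NULL
  flags <- snpIds(assoc) %in% snpIds(eqtl)

  m <- length(assoc)
  count <- if (is.null(cfg$effectiveRatio)) m
           else effectiveTestCount(m, cfg$effectiveRatio)

  weights <- list(original = unitWeights(assoc))
  if (cfg$scheme %in% c("both", "general"))
    weights$general <- normalizeWeights(generalWeights(assoc, eqtl))
  if (cfg$scheme %in% c("both", "binary"))
    weights$binary <- normalizeWeights(
      binaryWeights(assoc, flags,
                    binaryWeightParams(cfg$epsilon, B = cfg$upWeight)))

  reports <- list()
  novel <- list()
  for (wn in names(weights)) {
    q <- weightedPValues(assoc, weights[[wn]])
    writeReportTable(as.data.frame(q),
                     file.path(cfg$outdir, sprintf("qtable_%s.tsv", wn)))
    writeReportTable(rankShiftTable(assoc, q, flags),
                     file.path(cfg$outdir, sprintf("rankshift_%s.tsv", wn)))
    writeReportTable(qqTable(q@q),
                     file.path(cfg$outdir, sprintf("qq_%s.tsv", wn)))
    for (meth in cfg$methods) {
      rr <- switch(meth,
        bonferroni = weightedBonferroni(q, cfg$alpha, count),
        holm = weightedHolm(assoc, weights[[wn]], cfg$alpha, count),
        bh = weightedBH(q, cfg$alpha, count))
      key <- paste(meth, wn, sep = "_")
      reports[[key]] <- rr
      writeReportTable(as.data.frame(rr),
                       file.path(cfg$outdir, sprintf("reject_%s.tsv", key)))
    }
  }

  if (!is.null(ld)) {
    for (meth in cfg$methods) {
      un <- rejectedSnps(reports[[paste(meth, "original", sep = "_")]])
      for (wn in setdiff(names(weights), "original")) {
        wrej <- rejectedSnps(reports[[paste(meth, wn, sep = "_")]])
        key <- paste(meth, wn, sep = "_")
        novel[[key]] <- novelHits(wrej, un, ld, r2max = cfg$noveltyR2)
        writeReportTable(novel[[key]],
                         file.path(cfg$outdir,
                                   sprintf("novel_%s.tsv", key)))
      }
    }
  }

  manifest <- list(
    package = "eqtlWeights",
    version = as.character(packageVersion("eqtlWeights")),
    seed = cfg$seed,
    m = m, test_count = count,
    parameters = Filter(Negate(is.null),
                        unclass(cfg)[setdiff(names(cfg), "outdir")]))
  yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))

  invisible(list(weights = weights, reports = reports, novel = novel,
                 manifest = manifest))
}
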