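## Tabular input/output.  All coordinates are 1-based inclusive (PLINK/VCF
## convention).  p-values are parsed as decimal or ASCII scientific notation;
## typeset forms such as "4.32 x 10^-6" are not an input dialect.

.read_delim <- function(path, dialect = c("tsv", "whitespace"),
                        header = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    as.data.frame(data.table::fread(path, sep = "\t", header = header,
                                    colClasses = "character",
                                    data.table = FALSE, showProgress = FALSE))
  } else {
    utils::read.table(path, header = header, colClasses = "character",
                      stringsAsFactors = FALSE, comment.char = "")
  }
}

## resolve a column spec (name or index) against a data.frame
.pick_col <- function(df, spec, what, required = TRUE) {
  if (is.null(spec) || (length(spec) == 1 && is.na(spec))) {
    if (required) stop("no column mapping given for '", what, "'")
    return(NULL)
  }
  if (is.character(spec)) {
    hit <- match(tolower(spec), tolower(colnames(df)))
    if (is.na(hit)) {
      if (required) stop("column '", spec, "' (", what, ") not found")
      return(NULL)
    }
    return(df[[hit]])
  }
  spec <- as.integer(spec)
  if (spec < 1 || spec > ncol(df)) {
    if (required) stop("column index ", spec, " (", what, ") out of range")
    return(NULL)
  }
  df[[spec]]
}

.parse_p <- function(x, what, open_upper = FALSE) {
  p <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(p))
  if (length(bad))
    stop("unparseable ", what, " at row ", bad[1L], ": '", x[bad[1L]], "'")
  out <- if (open_upper) which(p <= 0 | p >= 1) else which(p <= 0 | p > 1)
  if (length(out))
    stop(what, " outside ", if (open_upper) "(0,1)" else "(0,1]",
         " at row ", out[1L], ": ", p[out[1L]])
  p
}

#' Read a per-SNP association table
#'
#' Reads PLINK `.assoc`-shaped whitespace tables or TSV p-value lists.  The
#' column mapping is configurable because upstream sources disagree on
#' headers; give column names (matched case-insensitively) or 1-based
#' indices.
#'
#' @param path input file.
#' @param dialect `"whitespace"` (PLINK-style, default) or `"tsv"`.
#' @param columns list with entries `snp` and `p`, optionally `chrom` and
#'   `pos`; names or 1-based indices.
#' @param header does the file carry a header row?  Defaults to `TRUE` when
#'   `columns` uses names, `FALSE` for indices.
#' @return An [AssocResults-class] object, rows in file order.
#' @examples
#' f <- tempfile()
#' writeLines(c("rs1 1 100 0.02", "rs2 1 200 0.5"), f)
#' readAssocTable(f, columns = list(snp = 1, chrom = 2, pos = 3, p = 4))
#' @export
readAssocTable <- function(path, dialect = c("whitespace", "tsv"),
                           columns = list(snp = "SNP", chrom = "CHR",
                                          pos = "BP", p = "P"),
                           header = NA) {
  dialect <- match.arg(dialect)
  if (is.na(header)) header <- is.character(columns$snp)
  df <- .read_delim(path, dialect, header = header)
  if (!nrow(df)) stop("empty association table: ", path)
  snp <- .pick_col(df, columns$snp, "snp_id")
  p <- .parse_p(.pick_col(df, columns$p, "p"), "p-value")
  if (anyDuplicated(snp))
    stop("duplicate snp_id: ", snp[duplicated(snp)][1L])
  chrom <- .pick_col(df, columns$chrom, "chrom", required = FALSE)
  pos <- .pick_col(df, columns$pos, "pos", required = FALSE)
  AssocResults(snp, p,
               chrom = if (is.null(chrom)) NA else chrom,
               pos = if (is.null(pos)) NA else suppressWarnings(as.integer(pos)))
}

#' Write an association table as TSV
#'
#' Floats are written in scientific notation at full double precision so
#' that a read/write round trip is lossless.
#'
#' @param x an [AssocResults-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAssocTable <- function(x, path) {
  stopifnot(is(x, "AssocResults"))
  df <- data.frame(SNP = x@snp, CHR = x@chrom, BP = x@pos,
                   P = sprintf("%.17e", x@p), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an eQTL reference table
#'
#' A SNP may appear once per expression probe; repeated rows are collapsed
#' to the row with the minimal eQTL p-value (that row's LOD and gene are
#' kept).
#'
#' @inheritParams readAssocTable
#' @param columns list with entries `snp` and `p_eqtl`, optionally `lod`
#'   and `gene`.
#' @return An [EqtlCatalog-class] object, unique SNPs in first-appearance
#'   order.
#' @export
readEqtlTable <- function(path, dialect = c("tsv", "whitespace"),
                          columns = list(snp = "SNP", p_eqtl = "P_EQTL",
                                         lod = "LOD", gene = "GENE"),
                          header = NA) {
  dialect <- match.arg(dialect)
  if (is.na(header)) header <- is.character(columns$snp)
  df <- .read_delim(path, dialect, header = header)
  if (!nrow(df)) stop("empty eQTL table: ", path)
  snp <- .pick_col(df, columns$snp, "snp_id")
  p <- .parse_p(.pick_col(df, columns$p_eqtl, "p_eqtl"), "eQTL p-value",
                open_upper = TRUE)
  lod <- .pick_col(df, columns$lod, "lod", required = FALSE)
  gene <- .pick_col(df, columns$gene, "gene", required = FALSE)
  EqtlCatalog(snp, p,
              lod = if (is.null(lod)) NA else suppressWarnings(as.numeric(lod)),
              gene = if (is.null(gene)) NA else gene)
}

#' Read genotypes from a dosage matrix TSV or a VCF
#'
#' `matrix_tsv` holds one individual per row and one SNP per column with
#' entries 0/1/2/NA (missing token `"NA"`).  VCF diploid GT fields are
#' converted to alt-allele dosages (`0/1` -> 1, `1|1` -> 2, `./.` ->
#' missing); non-diploid GT values are an error.
#'
#' @param path input file.
#' @param format `"matrix_tsv"` or `"vcf"`.
#' @return A [GenotypeData-class] object (no phenotype attached).
#' @export
readGenotypes <- function(path, format = c("matrix_tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "matrix_tsv") {
    df <- utils::read.table(path, header = TRUE, na.strings = "NA",
                            check.names = FALSE, stringsAsFactors = FALSE)
    g <- as.matrix(df)
    mode(g) <- "numeric"
    bad <- which(!is.na(g) & !(g %in% c(0, 1, 2)))
    if (length(bad))
      stop("genotype entry outside {0,1,2,NA}: ", g[bad[1L]])
    GenotypeData(g, snp = colnames(df))
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    fix <- vcfR::getFIX(v)
    dos <- apply(gt, c(1, 2), .gt_to_dosage)
    GenotypeData(t(dos), snp = fix[, "ID"], chrom = fix[, "CHROM"],
                 pos = as.integer(fix[, "POS"]))
  }
}

.gt_to_dosage <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1L]]
  if (length(alleles) != 2L)
    stop("non-diploid GT '", gt, "' (ploidy ", length(alleles), ")")
  if (any(alleles == ".")) return(NA_real_)
  if (!all(alleles %in% c("0", "1")))
    stop("non-biallelic GT '", gt, "'")
  sum(alleles == "1")
}

#' Construct or read a pairwise LD table
#'
#' `LdTable()` builds the object from vectors; `readLdTable()` reads a
#' SNAP-shaped proxy-search export (columns SNP, Proxy, Distance, RSquared,
#' DPrime).  Lookups through [ldR2()] are symmetric in the pair.
#'
#' @param snpA,snpB SNP ids of each pair.
#' @param r2 r-squared values in [0,1].
#' @param dprime optional D-prime values.
#' @param dist optional inter-SNP distances (bp).
#' @return An [LdTable-class] object.
#' @export
LdTable <- function(snpA = character(), snpB = character(),
                    r2 = numeric(), dprime = NA, dist = NA) {
  n <- length(snpA)
  new("LdTable", snpA = as.character(snpA), snpB = as.character(snpB),
      r2 = as.numeric(r2), dprime = rep_len(as.numeric(dprime), n),
      dist = rep_len(as.numeric(dist), n))
}

#' @rdname LdTable
#' @param path SNAP-shaped TSV file.
#' @param dialect field separator dialect, as in [readAssocTable()].
#' @export
readLdTable <- function(path, dialect = c("tsv", "whitespace")) {
  df <- .read_delim(path, match.arg(dialect), header = TRUE)
  cols <- tolower(colnames(df))
  need <- c("snp", "proxy", "rsquared")
  if (!all(need %in% cols))
    stop("LD table needs columns SNP, Proxy, RSquared (SNAP export shape)")
  LdTable(df[[match("snp", cols)]], df[[match("proxy", cols)]],
          as.numeric(df[[match("rsquared", cols)]]),
          dprime = if ("dprime" %in% cols)
            suppressWarnings(as.numeric(df[[match("dprime", cols)]])) else NA,
          dist = if ("distance" %in% cols)
            suppressWarnings(as.numeric(df[[match("distance", cols)]])) else NA)
}

#' Symmetric LD lookup
#'
#' @param ld an [LdTable-class] object.
#' @param a,b SNP ids (vectorized; recycled to a common length).
#' @return numeric r-squared for each pair, `NA` where the pair is absent.
#' @export
setMethod("ldR2", "LdTable", function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  tab <- key(ld@snpA, ld@snpB)
  ld@r2[match(key(a, b), tab)]
})

#' Write a report table as TSV
#'
#' Machine-readable output: numeric columns in scientific notation with
#' full precision, stable column order, no quoting.
#'
#' @param df a data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReportTable <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.10e", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
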