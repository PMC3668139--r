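#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("weightValues", function(x) standardGeneric("weightValues"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname accessors
#' @export
setGeneric("rejectedSnps", function(x) standardGeneric("rejectedSnps"))

#' @rdname accessors
#' @export
setGeneric("decisions", function(x) standardGeneric("decisions"))

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname accessors
#' @export
setGeneric("enrichmentP", function(x) standardGeneric("enrichmentP"))

#' @rdname ldR2
#' @export
setGeneric("ldR2", function(ld, a, b) standardGeneric("ldR2"))
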