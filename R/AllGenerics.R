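#' @rdname observedAgreement
#' @export
setGeneric("observedAgreement", function(x) standardGeneric("observedAgreement"))

#' @rdname chanceAgreement
#' @export
setGeneric("chanceAgreement", function(x) standardGeneric("chanceAgreement"))

#' @rdname iqs
#' @export
setGeneric("iqs", function(x, tol = 1e-12) standardGeneric("iqs"))

#' @rdname ConfusionTable-accessors
#' @export
setGeneric("rowMarginals", function(x) standardGeneric("rowMarginals"))

#' @rdname ConfusionTable-accessors
#' @export
setGeneric("colMarginals", function(x) standardGeneric("colMarginals"))

#' @rdname ConfusionTable-accessors
#' @export
setGeneric("totalN", function(x) standardGeneric("totalN"))

#' @rdname ImputedGenotypes-accessors
#' @export
setGeneric("genotypeProbs", function(x, snp) standardGeneric("genotypeProbs"))

#' @rdname ImputedGenotypes-accessors
#' @export
setGeneric("trueGenotypes", function(x) standardGeneric("trueGenotypes"))

#' @rdname ImputedGenotypes-accessors
#' @export
setGeneric("expectedDosage", function(x) standardGeneric("expectedDosage"))

#' @rdname snpMetrics
#' @export
setGeneric("snpMetrics", function(x, ...) standardGeneric("snpMetrics"))

#' @rdname dosageTrendTest
#' @export
setGeneric("dosageTrendTest", function(x, phenotype, ...)
  standardGeneric("dosageTrendTest"))
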