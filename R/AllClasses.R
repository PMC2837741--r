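#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assays assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats median pchisq qchisq runif rbinom cor setNames complete.cases
#' @importFrom utils head packageVersion
NULL

GENOTYPE_LABELS <- c("AA", "AB", "BB")

#' ConfusionTable: 3x3 cross-classification of imputed vs true genotype mass
#'
#' The sufficient statistic for the imputation quality score. Rows index the
#' imputed genotype (AA, AB, BB), columns the true genotype. Cells hold the
#' posterior-probability mass accumulated over individuals and are therefore
#' nonnegative reals, not necessarily integers. The grand total equals the
#' number of individuals contributing (those with non-missing true genotype).
#'
#' @slot n 3x3 numeric matrix of nonnegative cell masses, rows = imputed
#'   genotype, columns = true genotype.
#' @seealso [confusionTable()], [iqs()], [observedAgreement()],
#'   [chanceAgreement()]
#' @export
setClass("ConfusionTable", representation(n = "matrix"))

setValidity("ConfusionTable", function(object) {
  n <- object@n
  if (!is.numeric(n) || !identical(dim(n), c(3L, 3L)))
    return("cell matrix must be numeric 3x3")
  if (any(!is.finite(n)))
    return("cells must be finite")
  if (any(n < 0))
    return("cells must be nonnegative")
  TRUE
})

#' ImputedGenotypes: a cohort of genotype posterior probabilities
#'
#' A \linkS4class{SummarizedExperiment} with rows = SNPs and columns =
#' individuals carrying three mandatory assays \code{pAA}, \code{pAB},
#' \code{pBB} (posterior probabilities of the three genotypes with allele A =
#' first/reference allele; each per-individual triplet sums to one) and an
#' optional integer assay \code{truth} holding true hard calls coded
#' 0 = AA, 1 = AB, 2 = BB, NA = missing. Variant annotation (snp_id,
#' chromosome, position, allele_a, allele_b) lives in \code{rowData}.
#'
#' @seealso [ImputedGenotypes()] constructor, [snpMetrics()], [readGen()],
#'   [readVcfGp()]
#' @export
setClass("ImputedGenotypes", contains = "SummarizedExperiment")

setValidity("ImputedGenotypes", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  need <- c("pAA", "pAB", "pBB")
  if (!all(need %in% an))
    return("assays pAA, pAB and pBB are required")
  if (nrow(object) == 0L || ncol(object) == 0L)
    return(TRUE)
  a <- SummarizedExperiment::assays(object)
  s <- a[["pAA"]] + a[["pAB"]] + a[["pBB"]]
  if (any(a[["pAA"]] < -1e-9) || any(a[["pAB"]] < -1e-9) ||
      any(a[["pBB"]] < -1e-9))
    return("posterior probabilities must be nonnegative")
  if (any(abs(s - 1) > 1e-6))
    return("posterior triplets must sum to 1 within 1e-6")
  if ("truth" %in% an) {
    tr <- a[["truth"]]
    bad <- !is.na(tr) & !(tr %in% 0:2)
    if (any(bad))
      return("truth assay entries must be 0, 1, 2 or NA")
  }
  TRUE
})

#' SimConfig: full specification of a synthetic cohort and its error model
#'
#' Captures everything needed to regenerate a synthetic imputation experiment:
#' cohort dimensions, the minor-allele-frequency sampler, the imputation error
#' model with its per-SNP parameters, and the seed. Every simulation function
#' in the package is a pure function of a SimConfig, so identical configs give
#' identical data.
#'
#' @slot nIndividuals integer, cohort size (>= 2).
#' @slot nSnps integer, number of SNPs (>= 1).
#' @slot maf list sampler spec for true minor allele frequencies:
#'   \code{list(dist = "uniform", min =, max =)} or
#'   \code{list(dist = "fixed", values =)}.
#' @slot errorModel one of \code{"soft_blend"}, \code{"random_hardcall"},
#'   \code{"major_bias"} — the error applied to non-biased SNPs.
#' @slot epsilon list sampler spec for the per-SNP error rate of the base
#'   error model (same forms as \code{maf}).
#' @slot biasFraction proportion of SNPs additionally given the major-homozygote
#'   bias model (cross-platform artifact emulation), in [0, 1].
#' @slot biasBeta probability mass moved to the major homozygote for biased
#'   SNPs, in [0, 1].
#' @slot seed integer seed; mandatory.
#' @seealso [simConfig()], [simulateTruth()], [emulateImputation()],
#'   [runSplitExperiment()]
#' @export
setClass("SimConfig", representation(
  nIndividuals = "integer",
  nSnps        = "integer",
  maf          = "list",
  errorModel   = "character",
  epsilon      = "list",
  biasFraction = "numeric",
  biasBeta     = "numeric",
  seed         = "integer"
))

.checkSampler <- function(sp, what, lo, hi) {
  if (!is.list(sp) || is.null(sp$dist))
    return(sprintf("%s sampler must be a list with a 'dist' element", what))
  if (sp$dist == "uniform") {
    if (!is.numeric(sp$min) || !is.numeric(sp$max) || sp$min > sp$max ||
        sp$min < lo || sp$max > hi)
      return(sprintf("%s uniform sampler needs lo <= min <= max <= hi", what))
  } else if (sp$dist == "fixed") {
    v <- sp$values
    if (!is.numeric(v) || length(v) < 1L || any(v < lo | v > hi))
      return(sprintf("%s fixed sampler values out of range", what))
  } else {
    return(sprintf("unknown %s sampler '%s'", what, sp$dist))
  }
  NULL
}

setValidity("SimConfig", function(object) {
  if (length(object@nIndividuals) != 1L || object@nIndividuals < 2L)
    return("nIndividuals must be a single integer >= 2")
  if (length(object@nSnps) != 1L || object@nSnps < 1L)
    return("nSnps must be a single integer >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed is mandatory")
  if (!object@errorModel %in% c("soft_blend", "random_hardcall", "major_bias"))
    return("errorModel must be soft_blend, random_hardcall or major_bias")
  msg <- .checkSampler(object@maf, "maf", 0, 0.5)
  if (!is.null(msg)) return(msg)
  msg <- .checkSampler(object@epsilon, "epsilon", 0, 1)
  if (!is.null(msg)) return(msg)
  if (object@biasFraction < 0 || object@biasFraction > 1)
    return("biasFraction must be in [0, 1]")
  if (object@biasBeta < 0 || object@biasBeta > 1)
    return("biasBeta must be in [0, 1]")
  TRUE
})

#' FilterRule: a single SNP-retention rule on a quality metric
#'
#' @slot metric metric name, one of iqs, accuracy, efficiency, info_score,
#'   variance_ratio, maf, maf_difference.
#' @slot comparator one of ">", ">=", "<", "<=".
#' @slot threshold numeric threshold within the metric's range.
#' @seealso [filterRule()], [applyFilter()]
#' @export
setClass("FilterRule", representation(
  metric     = "character",
  comparator = "character",
  threshold  = "numeric"
))

FILTER_METRICS <- c("iqs", "accuracy", "efficiency", "info_score",
                    "variance_ratio", "maf", "maf_difference")

setValidity("FilterRule", function(object) {
  if (!object@metric %in% FILTER_METRICS)
    return(sprintf("unknown metric '%s'", object@metric))
  if (!object@comparator %in% c(">", ">=", "<", "<="))
    return("comparator must be one of >, >=, <, <=")
  rng <- if (object@metric == "iqs") c(-Inf, 1)
         else if (object@metric == "variance_ratio") c(0, Inf)
         else if (object@metric %in% c("maf", "maf_difference")) c(0, 0.5)
         else c(0, 1)
  if (object@threshold < rng[1] || object@threshold > rng[2])
    return(sprintf("threshold %g outside range of metric '%s'",
                   object@threshold, object@metric))
  TRUE
})
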