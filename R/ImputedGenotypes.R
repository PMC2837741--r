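#' Construct an ImputedGenotypes container
#'
#' Bundles per-SNP genotype posterior probabilities (and optionally true hard
#' calls) for a cohort into a \linkS4class{SummarizedExperiment}-derived
#' object with rows = SNPs and columns = individuals.
#'
#' @param pAA,pAB,pBB numeric matrices (SNPs x individuals) of posterior
#'   probabilities for the three genotypes; elementwise triplets must sum
#'   to 1 within 1e-6.
#' @param truth optional integer matrix of true genotypes (0/1/2/NA), same
#'   dimensions.
#' @param variants optional data.frame of variant annotation with columns
#'   among \code{snp_id, chromosome, position, allele_a, allele_b}; defaults
#'   to generated ids.
#' @param sampleIds optional character vector of individual ids.
#' @param metadata list of free-form metadata.
#' @return an \linkS4class{ImputedGenotypes} object.
#' @examples
#' ig <- ImputedGenotypes(
#'   pAA = matrix(c(1, 0), 1), pAB = matrix(c(0, 1), 1),
#'   pBB = matrix(0, 1, 2), truth = matrix(c(0L, 1L), 1)
#' )
#' snpMetrics(ig)
#' @export
ImputedGenotypes <- function(pAA, pAB, pBB, truth = NULL, variants = NULL,
                             sampleIds = NULL, metadata = list()) {
  stopifnot(is.matrix(pAA), is.matrix(pAB), is.matrix(pBB))
  if (!all(dim(pAA) == dim(pAB)) || !all(dim(pAA) == dim(pBB)))
    stop("pAA, pAB and pBB must have identical dimensions")
  m <- nrow(pAA); n <- ncol(pAA)
  if (is.null(variants)) {
    variants <- data.frame(snp_id = sprintf("snp%06d", seq_len(m)))
  }
  if (is.null(variants$snp_id))
    stop("variants must carry a snp_id column")
  if (nrow(variants) != m)
    stop("variants has ", nrow(variants), " rows but there are ", m, " SNPs")
  if (is.null(sampleIds)) sampleIds <- sprintf("ind%05d", seq_len(n))
  if (length(sampleIds) != n)
    stop("sampleIds length does not match the number of individuals")
  assays <- list(pAA = pAA, pAB = pAB, pBB = pBB)
  if (!is.null(truth)) {
    if (!is.matrix(truth) || !all(dim(truth) == dim(pAA)))
      stop("truth must be a matrix with the same dimensions as the posteriors")
    storage.mode(truth) <- "integer"
    assays$truth <- truth
  }
  assays <- lapply(assays, function(a) {
    dimnames(a) <- list(variants$snp_id, sampleIds)
    a
  })
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(variants),
    colData = S4Vectors::DataFrame(sample_id = sampleIds,
                                   row.names = sampleIds),
    metadata = metadata
  )
  new("ImputedGenotypes", se)
}

#' Accessors for ImputedGenotypes
#'
#' \code{genotypeProbs(x, snp)} returns the N x 3 posterior matrix of one SNP
#' (by index or snp_id), the per-SNP representation used by the scalar
#' metric functions; \code{trueGenotypes(x)} the true hard-call matrix or
#' NULL; \code{expectedDosage(x)} the SNPs x individuals matrix of expected
#' allele-B dosages \code{pAB + 2 pBB}.
#'
#' @param x an \linkS4class{ImputedGenotypes}
#' @param snp SNP index or snp_id
#' @name ImputedGenotypes-accessors
NULL

#' @rdname ImputedGenotypes-accessors
#' @export
setMethod("genotypeProbs", "ImputedGenotypes", function(x, snp) {
  if (is.character(snp)) {
    snp <- match(snp, SummarizedExperiment::rowData(x)$snp_id)
    if (is.na(snp)) stop("snp_id not found")
  }
  a <- SummarizedExperiment::assays(x)
  p <- cbind(AA = a[["pAA"]][snp, ], AB = a[["pAB"]][snp, ],
             BB = a[["pBB"]][snp, ])
  rownames(p) <- colnames(x)
  p
})

#' @rdname ImputedGenotypes-accessors
#' @export
setMethod("trueGenotypes", "ImputedGenotypes", function(x) {
  a <- SummarizedExperiment::assays(x)
  if ("truth" %in% names(a)) a[["truth"]] else NULL
})

#' @rdname ImputedGenotypes-accessors
#' @export
setMethod("expectedDosage", "ImputedGenotypes", function(x) {
  a <- SummarizedExperiment::assays(x)
  a[["pAB"]] + 2 * a[["pBB"]]
})

setMethod("show", "ImputedGenotypes", function(object) {
  cat("ImputedGenotypes:", nrow(object), "SNPs x", ncol(object),
      "individuals\n")
  cat("  truth assay:", if (!is.null(trueGenotypes(object))) "present"
      else "absent", "\n")
  extra <- setdiff(colnames(SummarizedExperiment::rowData(object)), "snp_id")
  if (length(extra))
    cat("  rowData:", paste(extra, collapse = ", "), "\n")
})
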