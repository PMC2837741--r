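.checkProbMatrix <- function(probs, n = NULL, tol = 1e-6) {
  if (!is.matrix(probs) || ncol(probs) != 3L || !is.numeric(probs))
    stop("posterior probabilities must be an N x 3 numeric matrix (AA, AB, BB)")
  if (!is.null(n) && nrow(probs) != n)
    stop("truth and posterior probabilities differ in length (",
         n, " vs ", nrow(probs), ")")
  if (any(probs < -tol))
    stop("posterior probabilities must be nonnegative")
  s <- rowSums(probs)
  if (any(abs(s - 1) > tol))
    stop("posterior triplets must sum to 1 within ", format(tol))
  invisible(TRUE)
}

.checkTruth <- function(truth) {
  if (!is.numeric(truth) && !all(is.na(truth)))
    stop("truth must be a numeric/integer vector coded 0 (AA), 1 (AB), 2 (BB)")
  bad <- !is.na(truth) & !(truth %in% 0:2)
  if (any(bad))
    stop("truth contains calls outside {0, 1, 2, NA}")
  invisible(TRUE)
}

.newConfusion <- function(n) {
  dimnames(n) <- list(imputed = GENOTYPE_LABELS, true = GENOTYPE_LABELS)
  new("ConfusionTable", n = n)
}

#' Cross-classify true genotypes against imputed posterior probabilities
#'
#' Builds the 3x3 table whose cell (j, i) accumulates, over individuals whose
#' true genotype is i, the posterior probability that imputation assigned to
#' genotype j. Because probabilities rather than hard calls are tabulated, the
#' cells are generally not integers. Individuals with missing true genotype
#' are excluded; the grand total of the table equals the number of individuals
#' retained.
#'
#' @param truth integer vector of true genotypes coded 0 = AA, 1 = AB,
#'   2 = BB, NA = missing.
#' @param probs numeric matrix with one row per individual and columns
#'   (AA, AB, BB) of posterior genotype probabilities; rows must sum to 1.
#' @return A \linkS4class{ConfusionTable}.
#' @examples
#' ct <- confusionTable(c(0, 1), rbind(c(0.8, 0.2, 0), c(0.1, 0.6, 0.3)))
#' as.matrix(ct)
#' iqs(ct)
#' @export
confusionTable <- function(truth, probs) {
  .checkTruth(truth)
  .checkProbMatrix(probs, n = length(truth))
  keep <- !is.na(truth)
  if (!any(keep))
    stop("all true genotypes are missing: confusion table undefined")
  tr <- truth[keep]
  p <- probs[keep, , drop = FALSE]
  onehot <- cbind(tr == 0, tr == 1, tr == 2)
  storage.mode(onehot) <- "double"
  .newConfusion(crossprod(p, onehot))
}

#' Cross-platform confusion table from two posterior sets
#'
#' When the same individuals are imputed from two different genotyping
#' platforms, neither posterior set is the truth; agreement between the two is
#' scored by summing, per individual, the outer product of the two probability
#' triplets. Row marginals are platform-a masses, column marginals platform-b
#' masses, and the downstream IQS is computed from the table exactly as in the
#' genotyped-truth case. Alleles must already be harmonized to one strand and
#' coding (see [harmonizeAlleles()]).
#'
#' If the two probability sets come from disjoint cohorts there is no
#' per-individual pairing; with \code{paired = FALSE} the table falls back to
#' the product of marginal mean probabilities (\code{N * mean(a_i) * mean(b_j)})
#' and a warning is emitted, since the statistic then only measures marginal
#' compatibility.
#'
#' @param probsA,probsB N x 3 posterior probability matrices over the same
#'   individuals in the same order (for \code{paired = TRUE}).
#' @param paired logical; pair individuals row by row (default) or use the
#'   marginal fallback for disjoint cohorts.
#' @return A \linkS4class{ConfusionTable} (rows = platform a, cols = platform b).
#' @export
crossPlatformConfusion <- function(probsA, probsB, paired = TRUE) {
  .checkProbMatrix(probsA)
  .checkProbMatrix(probsB)
  if (paired) {
    if (nrow(probsA) != nrow(probsB))
      stop("paired cross-platform tabulation needs equal cohort sizes (",
           nrow(probsA), " vs ", nrow(probsB), ")")
    .newConfusion(crossprod(probsA, probsB))
  } else {
    warning("disjoint cohorts: using marginal-product fallback; ",
            "the statistic reflects marginal compatibility only")
    N <- (nrow(probsA) + nrow(probsB)) / 2
    .newConfusion(N * tcrossprod(colMeans(probsA), colMeans(probsB)))
  }
}

#' @describeIn confusionTable coerce a ConfusionTable to its 3x3 cell matrix
#' @param x a ConfusionTable
#' @param ... ignored
#' @export
setMethod("as.matrix", "ConfusionTable", function(x, ...) x@n)

#' Marginals and total of a ConfusionTable
#'
#' \code{rowMarginals} returns the imputed-genotype masses,
#' \code{colMarginals} the true-genotype masses, and \code{totalN} the grand
#' total (the number of individuals tabulated).
#'
#' @param x a \linkS4class{ConfusionTable}
#' @return numeric vector of length 3, or a single number for \code{totalN}.
#' @name ConfusionTable-accessors
NULL

#' @rdname ConfusionTable-accessors
#' @export
setMethod("rowMarginals", "ConfusionTable", function(x) rowSums(x@n))

#' @rdname ConfusionTable-accessors
#' @export
setMethod("colMarginals", "ConfusionTable", function(x) colSums(x@n))

#' @rdname ConfusionTable-accessors
#' @export
setMethod("totalN", "ConfusionTable", function(x) sum(x@n))

setMethod("show", "ConfusionTable", function(object) {
  cat("ConfusionTable (rows = imputed, cols = true), N =",
      format(totalN(object)), "\n")
  print(round(object@n, 4))
  po <- tryCatch(observedAgreement(object), error = function(e) NA_real_)
  pc <- tryCatch(chanceAgreement(object), error = function(e) NA_real_)
  k <- tryCatch(iqs(object), error = function(e) NA_real_)
  cat(sprintf("P_o = %.4f  P_c = %.4f  IQS = %s\n", po, pc,
              if (is.na(k)) "undefined" else sprintf("%.4f", k)))
})

#' Observed proportion of agreement
#'
#' The diagonal mass of the true-vs-imputed table divided by the number of
#' individuals: the probability-weighted concordance rate between imputation
#' and truth. Not chance-corrected, so it overestimates reliability for SNPs
#' whose marginal genotype distribution is concentrated (low minor allele
#' frequency).
#'
#' @param x a \linkS4class{ConfusionTable}
#' @return proportion in [0, 1]
#' @export
#' @name observedAgreement
setMethod("observedAgreement", "ConfusionTable", function(x) {
  N <- sum(x@n)
  if (N <= 0) stop("empty confusion table: agreement undefined")
  sum(diag(x@n)) / N
})

#' Chance proportion of agreement
#'
#' The agreement expected if imputed genotypes were assigned at random with
#' the observed marginal rates: the sum over genotypes of the products of the
#' matching row and column marginal frequencies.
#'
#' @param x a \linkS4class{ConfusionTable}
#' @return proportion in [0, 1]
#' @export
#' @name chanceAgreement
setMethod("chanceAgreement", "ConfusionTable", function(x) {
  N <- sum(x@n)
  if (N <= 0) stop("empty confusion table: agreement undefined")
  sum(rowSums(x@n) * colSums(x@n)) / N^2
})

#' Imputation quality score (IQS)
#'
#' Chance-corrected concordance between imputed and true genotypes:
#' \deqn{IQS = (P_o - P_c) / (1 - P_c)}
#' where \eqn{P_o} is the observed and \eqn{P_c} the chance proportion of
#' agreement of the 3x3 genotype cross-classification. One indicates a
#' perfect match, zero agreement no better than chance, and negative values
#' that imputation performed worse than chance. The statistic is the
#' probability-mass analogue of Cohen's unweighted kappa and reduces to it
#' exactly on integer hard-call tables.
#'
#' When the marginals are fully concentrated (monomorphic SNP), the
#' denominator \eqn{1 - P_c} vanishes and the score is undefined; it is then
#' reported as \code{NA} rather than an error, mirroring the usual practice of
#' excluding such SNPs (e.g. MAF < 0.01) from IQS-based analyses.
#'
#' @param x a \linkS4class{ConfusionTable}
#' @param tol degeneracy tolerance: the score is \code{NA} when
#'   \code{1 - P_c <= tol} (default 1e-12).
#' @return a number <= 1, or \code{NA} when undefined.
#' @examples
#' ct <- confusionTable(
#'   truth = rep(c(0, 1, 2), times = c(50, 30, 20)),
#'   probs = diag(3)[rep(c(1, 2, 3), times = c(50, 30, 20)), ]
#' )
#' iqs(ct)  # perfect imputation: 1
#' @export
#' @name iqs
setMethod("iqs", "ConfusionTable", function(x, tol = 1e-12) {
  po <- observedAgreement(x)
  pc <- chanceAgreement(x)
  if (1 - pc <= tol) return(NA_real_)
  (po - pc) / (1 - pc)
})

#' Best-guess genotype calls from posterior probabilities
#'
#' Hard-calls each individual as the genotype with maximum posterior
#' probability; ties are broken deterministically toward the lowest genotype
#' index (AA before AB before BB).
#'
#' @param probs N x 3 posterior probability matrix (AA, AB, BB).
#' @return integer vector of calls in \{0, 1, 2\}.
#' @export
bestGuessCalls <- function(probs) {
  .checkProbMatrix(probs)
  max.col(probs, ties.method = "first") - 1L
}

#' Imputation accuracy
#'
#' Proportion of individuals whose best-guess imputed genotype (maximum
#' posterior probability, ties toward the lower genotype index) equals the
#' true genotype. Individuals with missing truth are excluded. Accuracy is
#' not chance-corrected: for a rare SNP, always calling the major homozygote
#' already achieves accuracy near one, which is the failure mode IQS corrects.
#'
#' @inheritParams confusionTable
#' @return proportion in [0, 1]
#' @export
imputationAccuracy <- function(truth, probs) {
  .checkTruth(truth)
  .checkProbMatrix(probs, n = length(truth))
  keep <- !is.na(truth)
  if (!any(keep))
    stop("all true genotypes are missing: accuracy undefined")
  calls <- bestGuessCalls(probs)
  mean(calls[keep] == truth[keep])
}

#' Imputation efficiency
#'
#' Fraction of individuals whose maximum posterior probability strictly
#' exceeds the calling threshold (default 0.9) — the proportion of
#' confidently imputable genotypes.
#'
#' @param probs N x 3 posterior probability matrix.
#' @param threshold calling threshold (default 0.9).
#' @return proportion in [0, 1]
#' @export
imputationEfficiency <- function(probs, threshold = 0.9) {
  .checkProbMatrix(probs)
  mean(pmax(probs[, 1], probs[, 2], probs[, 3]) > threshold)
}

#' Estimated minor allele frequency from posterior probabilities
#'
#' The allele-B frequency implied by the expected dosages,
#' \eqn{\sum_k (p_{AB,k} + 2 p_{BB,k}) / (2N)}, folded to the minor side
#' \eqn{\min(f, 1-f)}.
#'
#' @param probs N x 3 posterior probability matrix.
#' @param fold fold to the minor allele (default TRUE); with
#'   \code{fold = FALSE} the raw allele-B frequency is returned.
#' @return frequency in [0, 0.5] (folded) or [0, 1] (unfolded).
#' @export
estimatedMAF <- function(probs, fold = TRUE) {
  .checkProbMatrix(probs)
  if (nrow(probs) == 0L) stop("no individuals: allele frequency undefined")
  f <- sum(probs[, 2] + 2 * probs[, 3]) / (2 * nrow(probs))
  if (fold) min(f, 1 - f) else f
}
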