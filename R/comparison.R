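# Truth-free imputation quality statistics that IQS is benchmarked against.
# Both are functions of the expected dosage e_k = p_AB,k + 2 p_BB,k alone.

#' Dosage variance ratio (MACH rsq_hat style)
#'
#' Ratio of the empirically observed variance of the expected allele dosage
#' to the variance expected under binomial sampling at the estimated allele
#' frequency. As the information available to impute a SNP vanishes, every
#' individual receives the same (marginal) posterior, the dosage variance
#' collapses and the ratio approaches zero; for confidently imputed genotypes
#' in Hardy-Weinberg proportions it is close to one.
#'
#' Conventions (recorded in the result's attributes): the numerator is the
#' population variance of the dosages (divisor N, not N-1) and the
#' denominator is \eqn{2\hat p(1-\hat p)} with
#' \eqn{\hat p = \mathrm{mean}(dosage)/2} — the dosage-scale binomial
#' variance. The ratio can exceed one in finite samples.
#'
#' @param probs N x 3 posterior probability matrix (AA, AB, BB).
#' @return nonnegative ratio, or \code{NA} when the estimated allele
#'   frequency is 0 or 1 (monomorphic; denominator zero). Attributes
#'   \code{variance} = "population", \code{denominator} = "2p(1-p)".
#' @seealso [infoScore()], [iqs()]
#' @export
varianceRatio <- function(probs) {
  .checkProbMatrix(probs)
  N <- nrow(probs)
  if (N < 2L) stop("variance ratio needs at least 2 individuals")
  d <- probs[, 2] + 2 * probs[, 3]
  p <- mean(d) / 2
  out <- if (p <= 0 || p >= 1) NA_real_ else {
    v <- mean(d^2) - mean(d)^2
    v / (2 * p * (1 - p))
  }
  structure(out, variance = "population", denominator = "2p(1-p)")
}

#' Imputed information score (IMPUTE-style)
#'
#' The standard information measure for an imputed SNP based on the missing
#' information of the genotype posteriors:
#' \deqn{info = 1 - \frac{\sum_k (f_k - e_k^2)}{2N\hat\theta(1-\hat\theta)}}
#' with \eqn{e_k = p_{AB,k} + 2 p_{BB,k}} (expected dosage),
#' \eqn{f_k = p_{AB,k} + 4 p_{BB,k}} (expected squared dosage) and
#' \eqn{\hat\theta = \sum_k e_k / (2N)}. It equals 1 when all genotypes are
#' certain and decays toward 0 (and can go below 0 for worse-than-marginal
#' posteriors) as uncertainty grows; an info of 0.75 is conventionally read
#' as the SNP carrying the information of 75% of the sample precisely
#' genotyped.
#'
#' This is the IMPUTE/SNPTEST-family information measure computed directly
#' from the posteriors; variants of the measure based on Newton estimation of
#' the observed information differ slightly for uncertain genotypes, and
#' outputs are labelled with the convention used (attribute
#' \code{measure = "impute_info"}).
#'
#' @param probs N x 3 posterior probability matrix (AA, AB, BB).
#' @return score (at most 1 up to floating error), or \code{NA} when the
#'   estimated allele frequency is 0 or 1.
#' @seealso [varianceRatio()]
#' @export
infoScore <- function(probs) {
  .checkProbMatrix(probs)
  N <- nrow(probs)
  if (N < 2L) stop("info score needs at least 2 individuals")
  e <- probs[, 2] + 2 * probs[, 3]
  f <- probs[, 2] + 4 * probs[, 3]
  theta <- sum(e) / (2 * N)
  out <- if (theta <= 0 || theta >= 1) NA_real_ else
    1 - sum(f - e^2) / (2 * N * theta * (1 - theta))
  structure(out, measure = "impute_info")
}

#' Minor-allele-frequency difference against a reference panel
#'
#' Absolute difference between the cohort-estimated and the reference-panel
#' minor allele frequency. Large differences flag SNPs whose imputation
#' drifted toward the reference panel's allele frequency — a hallmark of
#' poorly imputed SNPs when cases and controls come from different platforms.
#'
#' @param estimated estimated minor allele frequency in [0, 0.5].
#' @param reference reference-panel minor allele frequency in [0, 0.5];
#'   \code{NA} when the SNP is missing from the reference table (the SNP then
#'   passes no MAF-difference filter).
#' @return absolute difference, \code{NA} when the reference entry is missing.
#' @export
mafDifference <- function(estimated, reference) {
  bad <- function(x) !is.na(x) & (x < 0 | x > 0.5)
  if (any(bad(estimated)) || any(bad(reference)))
    stop("minor allele frequencies must lie in [0, 0.5]")
  abs(estimated - reference)
}

#' Read a reference allele-frequency table
#'
#' Two-column tab-separated file \code{snp_id <TAB> maf} with header, giving
#' the reference-panel minor allele frequency per SNP. Gzip input is handled
#' transparently.
#'
#' @param path path to the TSV file.
#' @return named numeric vector of reference MAFs keyed by snp_id.
#' @export
readReferenceFrequencies <- function(path) {
  dt <- .freadText(path, header = TRUE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2L)
    stop("reference frequency table needs columns snp_id and maf")
  ids <- as.character(dt[[1]])
  maf <- as.numeric(dt[[2]])
  if (anyDuplicated(ids))
    stop("duplicate snp_id in reference frequency table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!is.na(maf) & (maf < 0 | maf > 0.5)))
    stop("reference MAFs must lie in [0, 0.5]")
  setNames(maf, ids)
}
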