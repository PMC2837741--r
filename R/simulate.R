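# Seeded synthetic cohort generator: HWE truth genotypes plus emulated
# imputation output with controllable per-SNP error, including the
# major-homozygote bias mode that manufactures cross-platform artifacts.

.subSeed <- function(seed, k) {
  s <- (as.numeric(seed) + 1000003 * k) %% 2147483647
  as.integer(s)
}

.sampleValues <- function(spec, n) {
  switch(spec$dist,
         uniform = runif(n, spec$min, spec$max),
         fixed   = rep_len(spec$values, n),
         stop("unknown sampler '", spec$dist, "'"))
}

#' Specify a synthetic imputation experiment
#'
#' Collects cohort dimensions, the minor-allele-frequency distribution, the
#' imputation error model and the seed into a validated
#' \linkS4class{SimConfig}. All simulation entry points are deterministic
#' functions of this object.
#'
#' Error models (applied per SNP with error rate \eqn{\epsilon} drawn from
#' \code{epsilon}):
#' \describe{
#'   \item{soft_blend}{posterior row = \eqn{(1-\epsilon)} one-hot(truth)
#'     \eqn{+\ \epsilon \pi}, where \eqn{\pi} is the realized genotype
#'     distribution of the SNP. Deterministic given the truth; downstream
#'     IQS equals \eqn{1-\epsilon} exactly, independent of MAF, while
#'     accuracy rises as MAF falls — the wedge between the two statistics.}
#'   \item{random_hardcall}{with probability \eqn{1-\epsilon} the true
#'     genotype is reported as a certain call, otherwise a random genotype
#'     drawn from \eqn{\pi} is reported.}
#'   \item{major_bias}{posterior row = \eqn{(1-\beta)} one-hot(truth)
#'     \eqn{+\ \beta} one-hot(AA), moving mass \eqn{\beta} to the major
#'     homozygote — the over-assignment of the major genotype that drives
#'     cross-platform false positives.}
#' }
#' Independently of the base model, a random fraction \code{biasFraction} of
#' SNPs is given the major_bias model with mass \code{biasBeta}.
#'
#' @param nIndividuals cohort size (>= 2).
#' @param nSnps number of SNPs.
#' @param maf MAF sampler: \code{list(dist = "uniform", min =, max =)},
#'   \code{list(dist = "fixed", values =)}, or a numeric vector (shorthand
#'   for a fixed sampler).
#' @param errorModel base error model, one of \code{"soft_blend"},
#'   \code{"random_hardcall"}, \code{"major_bias"}.
#' @param epsilon per-SNP error-rate sampler (same forms as \code{maf}, or
#'   a single number).
#' @param biasFraction fraction of SNPs given the major-bias model on top of
#'   the base model (default 0).
#' @param biasBeta major-homozygote mass for biased SNPs (default 0.6).
#' @param seed integer seed (mandatory).
#' @return a \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nIndividuals = 100, nSnps = 50, seed = 7,
#'                  maf = list(dist = "uniform", min = 0.05, max = 0.5),
#'                  errorModel = "soft_blend", epsilon = 0.1)
#' @export
simConfig <- function(nIndividuals, nSnps,
                      maf = list(dist = "uniform", min = 0.01, max = 0.5),
                      errorModel = c("soft_blend", "random_hardcall",
                                     "major_bias"),
                      epsilon = 0, biasFraction = 0, biasBeta = 0.6, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  norm <- function(x) {
    if (is.numeric(x)) list(dist = "fixed", values = as.numeric(x)) else x
  }
  new("SimConfig",
      nIndividuals = as.integer(nIndividuals), nSnps = as.integer(nSnps),
      maf = norm(maf), errorModel = match.arg(errorModel),
      epsilon = norm(epsilon), biasFraction = as.numeric(biasFraction),
      biasBeta = as.numeric(biasBeta), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d SNPs x %d individuals, model %s (bias %.0f%% @ beta %.2f), seed %d\n",
    object@nSnps, object@nIndividuals, object@errorModel,
    100 * object@biasFraction, object@biasBeta, object@seed))
})

#' Simulate true genotypes under Hardy-Weinberg equilibrium
#'
#' Draws, for each SNP, a minor allele frequency from the configured sampler
#' and i.i.d. genotypes from the Hardy-Weinberg proportions
#' \eqn{(p^2, 2pq, q^2)} (allele B minor, so genotype = number of B alleles
#' ~ Binomial(2, q)). SNPs are independent: the statistic under study is
#' per-SNP, so linkage structure is deliberately not modelled.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{truth} (SNPs x individuals integer matrix of
#'   0/1/2), \code{maf} (true per-SNP MAF) and \code{snp_id}.
#' @export
simulateTruth <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  m <- config@nSnps; n <- config@nIndividuals
  set.seed(.subSeed(config@seed, 1L))
  maf <- .sampleValues(config@maf, m)
  # prob recycles over rows within each column: row i keeps maf[i]
  truth <- matrix(rbinom(m * n, size = 2L, prob = maf), nrow = m, ncol = n)
  storage.mode(truth) <- "integer"
  list(truth = truth, maf = maf, snp_id = sprintf("snp%06d", seq_len(m)))
}

.realizedDist <- function(truth) {
  list(p0 = rowMeans(truth == 0L), p1 = rowMeans(truth == 1L),
       p2 = rowMeans(truth == 2L))
}

#' Emulate imputation output over known truth
#'
#' Applies the configured error model to a matrix of true genotypes and
#' returns posterior probability triplets of controllable quality (see
#' [simConfig()] for the models). Per-SNP error rates and the biased SNP
#' set are drawn from the config seed unless supplied explicitly, which is
#' how split-half analyses impose the identical error model on two
#' independent halves.
#'
#' @param truth SNPs x individuals integer matrix of true genotypes (0/1/2).
#' @param config a \linkS4class{SimConfig}.
#' @param epsilon optional per-SNP error rates overriding the config sampler.
#' @param biased optional logical vector marking SNPs given the major-bias
#'   model, overriding \code{biasFraction}.
#' @param rngSeed optional seed for the stochastic draws (random_hardcall),
#'   defaulting to one derived from the config seed.
#' @param snpIds,mafTrue optional annotation carried into \code{rowData}.
#' @return an \linkS4class{ImputedGenotypes} with the \code{truth} assay and
#'   rowData columns \code{epsilon}, \code{biased} and (when given)
#'   \code{maf_true}.
#' @export
emulateImputation <- function(truth, config, epsilon = NULL, biased = NULL,
                              rngSeed = NULL, snpIds = NULL, mafTrue = NULL) {
  stopifnot(is(config, "SimConfig"), is.matrix(truth))
  m <- nrow(truth); n <- ncol(truth)
  set.seed(.subSeed(config@seed, 2L))
  if (is.null(epsilon)) epsilon <- .sampleValues(config@epsilon, m)
  stopifnot(length(epsilon) == m, all(epsilon >= 0 & epsilon <= 1))
  if (is.null(biased)) {
    biased <- logical(m)
    nb <- round(config@biasFraction * m)
    if (nb > 0) biased[sample.int(m, nb)] <- TRUE
  }
  set.seed(if (is.null(rngSeed)) .subSeed(config@seed, 3L) else rngSeed)

  pi <- .realizedDist(truth)
  T0 <- truth == 0L; T1 <- truth == 1L; T2 <- truth == 2L
  storage.mode(T0) <- storage.mode(T1) <- storage.mode(T2) <- "double"

  if (config@errorModel == "soft_blend") {
    pAA <- (1 - epsilon) * T0 + epsilon * pi$p0
    pAB <- (1 - epsilon) * T1 + epsilon * pi$p1
    pBB <- (1 - epsilon) * T2 + epsilon * pi$p2
  } else if (config@errorModel == "random_hardcall") {
    wrong <- matrix(runif(m * n), m, n) < epsilon
    v <- matrix(runif(m * n), m, n)
    draw <- (v >= pi$p0) + (v >= pi$p0 + pi$p1)  # categorical from pi
    call <- ifelse(wrong, draw, truth)
    pAA <- (call == 0) * 1; pAB <- (call == 1) * 1; pBB <- (call == 2) * 1
  } else {  # major_bias as base model
    b <- config@biasBeta
    pAA <- (1 - b) * T0 + b
    pAB <- (1 - b) * T1
    pBB <- (1 - b) * T2
  }
  if (any(biased) && config@errorModel != "major_bias") {
    b <- config@biasBeta
    w <- which(biased)
    pAA[w, ] <- (1 - b) * T0[w, , drop = FALSE] + b
    pAB[w, ] <- (1 - b) * T1[w, , drop = FALSE]
    pBB[w, ] <- (1 - b) * T2[w, , drop = FALSE]
  }
  if (is.null(snpIds)) snpIds <- sprintf("snp%06d", seq_len(m))
  variants <- data.frame(snp_id = snpIds, epsilon = epsilon, biased = biased)
  if (!is.null(mafTrue)) variants$maf_true <- mafTrue
  ImputedGenotypes(pAA, pAB, pBB, truth = truth, variants = variants,
                   metadata = list(error_model = config@errorModel,
                                   bias_beta = config@biasBeta,
                                   seed = config@seed))
}

#' Simulate a full cohort: truth plus emulated imputation
#'
#' Convenience wrapper running [simulateTruth()] then [emulateImputation()]
#' under one config.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return an \linkS4class{ImputedGenotypes} with the truth assay and true
#'   MAFs in \code{rowData$maf_true}.
#' @export
simulateCohort <- function(config) {
  tr <- simulateTruth(config)
  emulateImputation(tr$truth, config, snpIds = tr$snp_id, mafTrue = tr$maf)
}

#' Cross-platform case/control split experiment
#'
#' Emulates, at desk scale, the validation design in which cases and
#' controls are genotyped on different platforms: the cohort is halved at
#' random into "cases" and "controls"; controls keep their true genotypes
#' as certain posteriors; cases receive emulated imputation (base error
#' model on most SNPs, major-homozygote bias on a random
#' \code{biasFraction} of them). Because the phenotype is a random label,
#' every genome-wide significant SNP is an imputation-driven false
#' positive. The function computes per-SNP quality metrics against the
#' known truth, runs the dosage trend test on all SNPs, and reports hit
#' counts, genomic inflation and retention before and after each filter.
#'
#' @param config a \linkS4class{SimConfig}; \code{biasFraction} and
#'   \code{biasBeta} control the artifact SNPs.
#' @param alpha genome-wide significance threshold (default 5e-8, strict).
#' @param filters named list/character vector of filter rules evaluated on
#'   the case-side metrics (default the IQS > 0.9 filter and the accuracy
#'   > 0.99 comparison filter).
#' @return list with elements \code{assoc} (per-SNP trend results),
#'   \code{metrics} (case-side [snpMetrics()] table plus \code{biased}
#'   flag), \code{hits_before}, \code{lambda_before} and \code{summary}
#'   (one row per filter: n_retained, retention, hits, lambda).
#' @export
runSplitExperiment <- function(config, alpha = 5e-8,
                               filters = c(iqs = "iqs>0.9",
                                           accuracy = "accuracy>0.99")) {
  stopifnot(is(config, "SimConfig"))
  n <- config@nIndividuals
  if (n < 4L) stop("need at least 4 individuals to split into cases/controls")
  tr <- simulateTruth(config)
  set.seed(.subSeed(config@seed, 4L))
  perm <- sample.int(n)
  caseIdx <- perm[seq_len(n %/% 2)]
  ctrlIdx <- perm[(n %/% 2 + 1L):n]

  cases <- emulateImputation(tr$truth[, caseIdx, drop = FALSE], config,
                             snpIds = tr$snp_id, mafTrue = tr$maf)
  metrics <- snpMetrics(cases)
  metrics$biased <- SummarizedExperiment::rowData(cases)$biased

  dosage <- cbind(expectedDosage(cases),
                  tr$truth[, ctrlIdx, drop = FALSE] * 1.0)
  rownames(dosage) <- tr$snp_id
  pheno <- rep(c(1, 0), c(length(caseIdx), length(ctrlIdx)))
  assoc <- dosageTrendTest(dosage, pheno)

  hitsBefore <- countGenomewideHits(assoc, alpha)
  lambdaBefore <- genomicLambda(assoc)

  if (is.null(names(filters))) names(filters) <- as.character(filters)
  summary <- do.call(rbind, lapply(names(filters), function(nm) {
    res <- applyFilter(metrics, filters[[nm]])
    sub <- assoc[assoc$snp_id %in% res$snp_id, , drop = FALSE]
    data.frame(filter = nm, rule = as.character(filters[[nm]]),
               n_retained = res$n_retained, retention = res$retention,
               hits = countGenomewideHits(sub, alpha),
               lambda = if (nrow(sub)) suppressWarnings(genomicLambda(sub))
                        else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(assoc = assoc, metrics = metrics, hits_before = hitsBefore,
       lambda_before = lambdaBefore, summary = summary, alpha = alpha,
       n_cases = length(caseIdx), n_controls = length(ctrlIdx))
}

#' Split-half robustness of per-SNP IQS
#'
#' Halves the cohort at random, applies the identical per-SNP error model
#' independently in each half (same per-SNP error rates, independent random
#' draws), computes IQS against truth separately in the two halves, and
#' returns the Pearson correlation over SNPs with true MAF above
#' \code{mafMin} (default 0.01; below that the IQS denominator approaches
#' zero and the score is unstable). High correlation means a SNP's IQS is a
#' stable property of the imputation task, supporting reuse of IQS values
#' computed once (a database) to filter future imputations.
#'
#' @param config a \linkS4class{SimConfig} with \code{nIndividuals >= 200}.
#' @param mafMin MAF exclusion threshold (default 0.01).
#' @return list with \code{correlation}, \code{n_snps_used} and
#'   \code{per_snp} (snp_id, maf, iqs_half1, iqs_half2).
#' @export
runSplitHalfRobustness <- function(config, mafMin = 0.01) {
  stopifnot(is(config, "SimConfig"))
  if (config@nIndividuals < 200L)
    stop("split-half robustness needs at least 200 individuals")
  tr <- simulateTruth(config)
  m <- config@nSnps; n <- config@nIndividuals
  set.seed(.subSeed(config@seed, 5L))
  eps <- .sampleValues(config@epsilon, m)
  biased <- logical(m)
  nb <- round(config@biasFraction * m)
  if (nb > 0) biased[sample.int(m, nb)] <- TRUE
  perm <- sample.int(n)
  h1 <- perm[seq_len(n %/% 2)]
  h2 <- perm[(n %/% 2 + 1L):(2 * (n %/% 2))]

  iqsOf <- function(idx, k) {
    ig <- emulateImputation(tr$truth[, idx, drop = FALSE], config,
                            epsilon = eps, biased = biased,
                            rngSeed = .subSeed(config@seed, k),
                            snpIds = tr$snp_id)
    snpMetrics(ig)$iqs
  }
  i1 <- iqsOf(h1, 6L)
  i2 <- iqsOf(h2, 7L)
  keep <- tr$maf > mafMin & !is.na(i1) & !is.na(i2)
  if (sum(keep) < 2L)
    stop("fewer than 2 SNPs with defined IQS in both halves")
  list(correlation = cor(i1[keep], i2[keep]),
       n_snps_used = sum(keep),
       per_snp = data.frame(snp_id = tr$snp_id[keep], maf = tr$maf[keep],
                            iqs_half1 = i1[keep], iqs_half2 = i2[keep],
                            stringsAsFactors = FALSE))
}

#' Certain posteriors from hard calls
#'
#' Wraps a matrix of true genotypes as one-hot posterior probabilities — how
#' directly genotyped individuals enter analyses alongside imputed ones.
#'
#' @param truth SNPs x individuals integer matrix of genotypes (0/1/2).
#' @param snpIds optional snp_id vector.
#' @return an \linkS4class{ImputedGenotypes} with certain posteriors and the
#'   truth assay.
#' @export
certainPosteriors <- function(truth, snpIds = NULL) {
  stopifnot(is.matrix(truth))
  if (is.null(snpIds)) snpIds <- sprintf("snp%06d", seq_len(nrow(truth)))
  ImputedGenotypes((truth == 0L) * 1, (truth == 1L) * 1, (truth == 2L) * 1,
                   truth = truth,
                   variants = data.frame(snp_id = snpIds))
}
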