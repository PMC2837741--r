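# Case/control association machinery for the cross-platform validation
# protocol: probability-weighted trend tests, genomic inflation, Q-Q data,
# genome-wide hit counting and metric-based filtering.

CHI1_MEDIAN <- qchisq(0.5, 1)  # 0.4549364...

.phenoTo01 <- function(phenotype, n) {
  if (is.factor(phenotype) || is.character(phenotype)) {
    lab <- tolower(as.character(phenotype))
    if (!all(lab %in% c("case", "control")))
      stop("phenotype labels must be 'case'/'control' (or a 0/1 vector)")
    y <- as.numeric(lab == "case")
  } else {
    if (!all(phenotype %in% c(0, 1)))
      stop("numeric phenotype must be coded 0 = control, 1 = case")
    y <- as.numeric(phenotype)
  }
  if (length(y) != n)
    stop("phenotype length (", length(y), ") does not match cohort size (",
         n, ")")
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one case and one control")
  y
}

#' Dosage trend test for case/control association
#'
#' One-degree-of-freedom score (trend) test comparing expected allele dosage
#' between cases and controls, the probability-weighted analogue of the
#' Cochran-Armitage trend test: with \eqn{d_k} the expected dosage of
#' individual \eqn{k} and \eqn{y_k \in \{0,1\}} the phenotype,
#' \deqn{X^2 = \frac{\left[\sum_k (y_k - \bar y) d_k\right]^2}
#'   {\bar y (1-\bar y) \sum_k (d_k - \bar d)^2}}
#' which follows a chi-square with 1 df under the null. On certain (hard
#' call) genotypes it reduces exactly to the classical Cochran-Armitage
#' trend chi-square of the 2x3 table. Imputation uncertainty enters through
#' the dosages, so the test is first-order equivalent to logistic regression
#' on genotype probabilities for the near-null effects relevant to
#' false-positive screening.
#'
#' SNPs with zero dosage variance are reported with statistic 0, p = 1 and
#' \code{flag = "zero_variance"}.
#'
#' @param x an \linkS4class{ImputedGenotypes}, or a SNPs x individuals
#'   matrix of expected dosages.
#' @param phenotype vector of length = number of individuals: "case"/
#'   "control" labels (character or factor) or 0/1 numeric.
#' @param snpIds optional snp_id vector for the matrix method.
#' @param ... unused.
#' @return data.frame with columns \code{snp_id, statistic, p_value, n_used,
#'   flag}; \code{p_value} is the upper chi-square(1) tail of
#'   \code{statistic}.
#' @examples
#' d <- matrix(c(0, 0, 2, 2), 1)  # one SNP, complete separation
#' dosageTrendTest(d, c("control", "control", "case", "case"))
#' @export
#' @name dosageTrendTest
setMethod("dosageTrendTest", "matrix", function(x, phenotype,
                                                snpIds = NULL, ...) {
  n <- ncol(x)
  y <- .phenoTo01(phenotype, n)
  ybar <- mean(y)
  u <- as.vector(x %*% (y - ybar))
  ss <- rowSums(x^2) - n * rowMeans(x)^2
  denom <- ybar * (1 - ybar) * ss
  stat <- ifelse(denom > 0, u^2 / denom, 0)
  # guard tiny negative ss from floating cancellation
  stat[ss <= 1e-12 * pmax(1, rowMeans(x)^2) * n] <- 0
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (is.null(snpIds)) snpIds <- rownames(x)
  if (is.null(snpIds)) snpIds <- sprintf("snp%06d", seq_len(nrow(x)))
  data.frame(snp_id = snpIds, statistic = stat, p_value = p, n_used = n,
             flag = ifelse(stat == 0 & denom <= 0, "zero_variance", ""),
             stringsAsFactors = FALSE)
})

#' @rdname dosageTrendTest
#' @export
setMethod("dosageTrendTest", "ImputedGenotypes", function(x, phenotype, ...) {
  d <- expectedDosage(x)
  rownames(d) <- SummarizedExperiment::rowData(x)$snp_id
  dosageTrendTest(d, phenotype)
})

#' Genomic inflation factor
#'
#' Median-based genomic control lambda: the median of the observed 1-df
#' chi-square statistics divided by the null chi-square(1) median
#' (about 0.4549). Values well above 1 indicate systematic inflation of the
#' association statistics; note that a small number of grossly inflated SNPs
#' (as produced by cross-platform imputation artifacts) can leave lambda
#' near 1 while still distorting the Q-Q tail.
#'
#' @param results a data.frame from [dosageTrendTest()] or a numeric vector
#'   of 1-df chi-square statistics.
#' @return the inflation factor lambda.
#' @export
genomicLambda <- function(results) {
  stat <- if (is.data.frame(results)) results$statistic else as.numeric(results)
  if (length(stat) == 0L) stop("no association results: lambda undefined")
  if (length(stat) < 100L)
    warning("fewer than 100 statistics: lambda estimate is unstable")
  median(stat) / CHI1_MEDIAN
}

#' Q-Q plot coordinates for association p-values
#'
#' Pairs the sorted observed p-values with their uniform-order expectations
#' on the -log10 scale: the k-th smallest p (of m) is plotted against
#' \eqn{-\log_{10}((k - 0.5)/m)}. Rows are ordered from least to most
#' significant.
#'
#' @param results a data.frame with a \code{p_value} column or a numeric
#'   vector of p-values.
#' @return data.frame with columns \code{expected} and \code{observed}
#'   (-log10 p), equal lengths, ordered by increasing significance.
#' @export
qqPoints <- function(results) {
  p <- if (is.data.frame(results)) results$p_value else as.numeric(results)
  if (length(p) == 0L) stop("no p-values supplied")
  m <- length(p)
  obs <- -log10(sort(p, decreasing = TRUE))
  exp <- -log10((m:1 - 0.5) / m)
  data.frame(expected = exp, observed = obs)
}

#' Count genome-wide significant results
#'
#' Number of SNPs with p strictly below the genome-wide threshold
#' (default 5e-8). In the validation protocol, where the phenotype is a
#' random split of one cohort, every hit is by construction a false
#' positive.
#'
#' @param results data.frame with a \code{p_value} column or numeric vector
#'   of p-values.
#' @param alpha significance threshold (default 5e-8, strict inequality).
#' @return integer count.
#' @export
countGenomewideHits <- function(results, alpha = 5e-8) {
  p <- if (is.data.frame(results)) results$p_value else as.numeric(results)
  sum(p < alpha, na.rm = TRUE)
}

#' Construct a SNP filter rule
#'
#' @param metric metric name: one of \code{iqs, accuracy, efficiency,
#'   info_score, variance_ratio, maf, maf_difference}.
#' @param comparator one of \code{">", ">=", "<", "<="}.
#' @param threshold numeric threshold within the metric's range.
#' @return a \linkS4class{FilterRule}.
#' @examples
#' filterRule("iqs", ">", 0.9)
#' @export
filterRule <- function(metric, comparator, threshold) {
  new("FilterRule", metric = metric, comparator = comparator,
      threshold = threshold)
}

#' Parse a filter rule from text such as "iqs>0.9"
#'
#' @param text a string \code{metric<op>threshold}, e.g. \code{"maf>=0.01"}.
#' @return a \linkS4class{FilterRule}.
#' @export
parseFilterRule <- function(text) {
  m <- regmatches(text, regexec("^\\s*([a-z_]+)\\s*(>=|<=|>|<)\\s*([-0-9.eE]+)\\s*$",
                                text))[[1]]
  if (length(m) != 4L)
    stop("cannot parse filter rule '", text, "' (expected metric>threshold)")
  filterRule(m[2], m[3], as.numeric(m[4]))
}

setMethod("show", "FilterRule", function(object) {
  cat(sprintf("FilterRule: %s %s %g\n", object@metric, object@comparator,
              object@threshold))
})

#' Apply filter rules to a SNP metrics table
#'
#' Retains the SNPs whose metric values satisfy every rule (intersection
#' semantics for multiple rules). SNPs whose metric value is undefined
#' (\code{NA}) fail the rule — an unscorable SNP is never retained.
#'
#' @param metrics data.frame from [snpMetrics()] (or any data.frame with
#'   \code{snp_id} and the rule's metric columns).
#' @param rules a \linkS4class{FilterRule}, a list of them, or character
#'   rules parseable by [parseFilterRule()].
#' @return list with \code{snp_id} (retained ids), \code{n_retained},
#'   \code{n_total} and \code{retention} (proportion retained).
#' @examples
#' df <- data.frame(snp_id = c("a", "b"), iqs = c(0.95, 0.5))
#' applyFilter(df, "iqs>0.9")
#' @export
applyFilter <- function(metrics, rules) {
  if (is(rules, "FilterRule")) rules <- list(rules)
  if (is.character(rules)) rules <- lapply(rules, parseFilterRule)
  keep <- rep(TRUE, nrow(metrics))
  for (rule in rules) {
    stopifnot(is(rule, "FilterRule"))
    if (!rule@metric %in% colnames(metrics))
      stop("metric '", rule@metric, "' not present in the metrics table")
    v <- metrics[[rule@metric]]
    ok <- switch(rule@comparator,
                 ">"  = v >  rule@threshold,
                 ">=" = v >= rule@threshold,
                 "<"  = v <  rule@threshold,
                 "<=" = v <= rule@threshold)
    ok[is.na(ok)] <- FALSE
    keep <- keep & ok
  }
  list(snp_id = metrics$snp_id[keep], n_retained = sum(keep),
       n_total = nrow(metrics), retention = sum(keep) / nrow(metrics))
}
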