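# Allele/strand harmonization between two codings of the same SNP.

.complementBase <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  unname(map[toupper(x)])
}

.isAmbiguousPair <- function(a1, a2) {
  p <- sort(toupper(c(a1, a2)))
  identical(p, c("A", "T")) || identical(p, c("C", "G"))
}

#' Harmonize allele coding between two variant records
#'
#' Aligns the posterior probabilities of a SNP reported under coding
#' \code{b} to the allele coding of record \code{a}. If \code{b}'s alleles
#' are the same pair in swapped order, the probability triplet is reversed;
#' if they match only after strand complementation the triplet is kept (or
#' reversed when the complemented pair is also swapped). Strand-ambiguous
#' A/T and C/G SNPs cannot be resolved from allele labels alone and are
#' excluded by default, as are allele pairs incompatible under every
#' transformation.
#'
#' @param a,b variant records: list/data.frame/named vector carrying
#'   \code{allele_a} and \code{allele_b} (single-base or indel strings), or
#'   an unnamed character vector of length 2.
#' @param probsB N x 3 posterior matrix reported under \code{b}'s coding
#'   (may be NULL to only classify the relationship).
#' @return list with \code{action} (one of \code{"identical"},
#'   \code{"swap"}, \code{"flip"}, \code{"flip_swap"}, \code{"exclude"}),
#'   \code{reason} (for exclusions: \code{"strand-ambiguous"} or
#'   \code{"incompatible-alleles"}) and \code{probs} (the aligned matrix,
#'   or NULL when excluded or not supplied).
#' @examples
#' harmonizeAlleles(c("A", "G"), c("G", "A"),
#'                  matrix(c(0.7, 0.2, 0.1), 1))$probs
#' harmonizeAlleles(c("A", "T"), c("A", "T"))$reason
#' @export
harmonizeAlleles <- function(a, b, probsB = NULL) {
  pair <- function(x) {
    if (is.list(x) || is.data.frame(x))
      toupper(c(x$allele_a[1], x$allele_b[1]))
    else if (!is.null(names(x)) && all(c("allele_a", "allele_b") %in% names(x)))
      toupper(unname(x[c("allele_a", "allele_b")]))
    else toupper(as.character(x)[1:2])
  }
  A <- pair(a); B <- pair(b)
  if (any(is.na(A)) || any(is.na(B)) || any(!nzchar(c(A, B))) ||
      A[1] == A[2] || B[1] == B[2])
    stop("alleles must be non-empty and distinct")
  done <- function(action, reason = NULL, flipProbs = FALSE) {
    p <- NULL
    if (!is.null(probsB) && action != "exclude") {
      .checkProbMatrix(probsB)
      p <- if (flipProbs) probsB[, 3:1, drop = FALSE] else probsB
      colnames(p) <- GENOTYPE_LABELS
    }
    list(action = action, reason = reason, probs = p)
  }
  if (.isAmbiguousPair(A[1], A[2]))
    return(done("exclude", "strand-ambiguous"))
  if (identical(B, A)) return(done("identical"))
  if (identical(B, rev(A))) return(done("swap", flipProbs = TRUE))
  cB <- .complementBase(B)
  if (!any(is.na(cB))) {
    if (identical(cB, A)) return(done("flip"))
    if (identical(cB, rev(A))) return(done("flip_swap", flipProbs = TRUE))
  }
  done("exclude", "incompatible-alleles")
}
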