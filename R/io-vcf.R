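# VCF input: genotype posterior probabilities from the GP FORMAT field
# (REF/REF, REF/ALT, ALT/ALT) and hard calls from GT when present.

#' Read genotype probabilities (GP) and hard calls (GT) from a VCF
#'
#' Maps the GP field of a biallelic VCF to posterior triplets
#' (AA, AB, BB) with allele A = REF, and the GT field (when present) to
#' true hard calls stored in the \code{truth} assay. For samples with a GT
#' call but no GP value, a certain one-hot posterior is substituted and the
#' record is flagged in \code{rowData$n_gp_fallback}; samples with neither
#' get an uninformative uniform row (\code{rowData$n_missing}).
#' Multi-allelic records are skipped with a warning giving the count.
#'
#' @param path VCF file (plain or bgzip/gzip).
#' @return an \linkS4class{ImputedGenotypes} with rowData columns snp_id,
#'   chromosome, position, allele_a, allele_b and the flag counts above.
#' @export
readVcfGp <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic records in ", path)

  gp <- tryCatch(vcfR::extract.gt(vcf, element = "GP"),
                 error = function(e) NULL)
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                 error = function(e) NULL)
  if (is.null(gp) && is.null(gt))
    stop("VCF ", path, " carries neither GP nor GT")
  m <- nrow(fix)
  n <- if (!is.null(gp)) ncol(gp) else ncol(gt)
  sampleIds <- colnames(if (!is.null(gp)) gp else gt)

  truth <- NULL
  if (!is.null(gt)) {
    g <- gsub("|", "/", gt, fixed = TRUE)
    truth <- matrix(NA_integer_, m, n)
    truth[g == "0/0"] <- 0L
    truth[g %in% c("0/1", "1/0")] <- 1L
    truth[g == "1/1"] <- 2L
  }

  pAA <- matrix(NA_real_, m, n); pAB <- pBB <- pAA
  if (!is.null(gp)) {
    ok <- !is.na(gp)
    if (any(ok)) {
      parts <- strsplit(gp[ok], ",", fixed = TRUE)
      if (any(lengths(parts) != 3L))
        stop("GP fields with other than 3 probabilities in ", path)
      vals <- matrix(as.numeric(unlist(parts)), ncol = 3L, byrow = TRUE)
      pAA[ok] <- vals[, 1]; pAB[ok] <- vals[, 2]; pBB[ok] <- vals[, 3]
    }
  }
  noGp <- is.na(pAA)
  fallback <- noGp & !is.null(truth) & !is.na(if (is.null(truth))
    matrix(NA, m, n) else truth)
  if (any(fallback)) {
    pAA[fallback] <- (truth[fallback] == 0L) * 1
    pAB[fallback] <- (truth[fallback] == 1L) * 1
    pBB[fallback] <- (truth[fallback] == 2L) * 1
  }
  missing <- is.na(pAA)
  pAA[missing] <- pAB[missing] <- pBB[missing] <- 1 / 3
  s <- pAA + pAB + pBB
  pAA <- pAA / s; pAB <- pAB / s; pBB <- pBB / s

  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  variants <- data.frame(
    snp_id = ids, chromosome = fix[, "CHROM"],
    position = as.integer(fix[, "POS"]),
    allele_a = fix[, "REF"], allele_b = fix[, "ALT"],
    n_gp_fallback = rowSums(fallback), n_missing = rowSums(missing),
    stringsAsFactors = FALSE
  )
  ImputedGenotypes(pAA, pAB, pBB, truth = truth, variants = variants,
                   sampleIds = sampleIds)
}
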