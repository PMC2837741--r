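# Oxford GEN/SAMPLE reading and writing. One GEN line per SNP: five leading
# columns (snp_id, rsid, position, alleleA, alleleB) then one probability
# triplet (AA, AB, BB) per individual, probabilities relative to alleleA.

.openText <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

# fread wrapper that decompresses .gz through base R connections
.freadText <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- .openText(path)
    on.exit(close(con))
    data.table::fread(text = readLines(con), ...)
  } else {
    data.table::fread(path, ...)
  }
}

.checkRectangular <- function(path) {
  con <- .openText(path)
  on.exit(close(con))
  nf <- utils::count.fields(con, sep = "")
  if (length(nf) == 0L) stop("empty GEN file: ", path)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != stats::median(nf))[1]
    stop("malformed GEN file ", path, ": line ", bad, " has ", nf[bad],
         " fields, expected ", stats::median(nf))
  }
  nf[1]
}

#' Read an Oxford GEN file of genotype probabilities
#'
#' Parses the IMPUTE-native GEN dialect into an
#' \linkS4class{ImputedGenotypes}: five leading columns (snp_id, rsid,
#' 1-based position, allele A, allele B) followed by N probability triplets
#' ordered (AA, AB, BB) with respect to allele A. Gzip input is transparent.
#'
#' Probability triplets are renormalized when their sum lies within 1e-3 of
#' one (absorbing the usual 3-decimal rounding of GEN files); all-zero
#' triplets (the GEN missing-data convention) become uninformative uniform
#' rows; records containing triplets whose sum is further than 1e-3 from
#' one are renormalized but flagged in \code{rowData$n_bad_triplets}, with
#' a warning. After normalization rows sum to one within 1e-6.
#'
#' @param path GEN file (optionally .gz).
#' @param samplePath optional Oxford SAMPLE file; supplies individual ids
#'   and must agree with the GEN triplet count.
#' @return an \linkS4class{ImputedGenotypes} with rowData columns snp_id,
#'   rsid, position, allele_a, allele_b, n_bad_triplets, n_missing_triplets.
#' @export
readGen <- function(path, samplePath = NULL) {
  nfields <- .checkRectangular(path)
  if (nfields < 8L || (nfields - 5L) %% 3L != 0L)
    stop("GEN file ", path, " has ", nfields,
         " fields per line; expected 5 + 3*N")
  n <- (nfields - 5L) %/% 3L
  dt <- as.data.frame(.freadText(
    path, header = FALSE, sep = " ",
    colClasses = c(rep("character", 5), rep("numeric", nfields - 5L))))
  if (anyNA(as.matrix(dt[, -(1:5)])))
    stop("malformed numeric field in GEN file ", path)
  sampleIds <- NULL
  if (!is.null(samplePath)) {
    sampleIds <- readSampleFile(samplePath)
    if (length(sampleIds) != n)
      stop("SAMPLE file lists ", length(sampleIds),
           " individuals but GEN file has ", n, " probability triplets")
  }
  prob <- as.matrix(dt[, -(1:5)])
  pAA <- prob[, seq(1L, ncol(prob), by = 3L), drop = FALSE]
  pAB <- prob[, seq(2L, ncol(prob), by = 3L), drop = FALSE]
  pBB <- prob[, seq(3L, ncol(prob), by = 3L), drop = FALSE]
  s <- pAA + pAB + pBB
  missingTrip <- s == 0
  badTrip <- !missingTrip & abs(s - 1) > 1e-3
  renorm <- !missingTrip & !badTrip & abs(s - 1) > 1e-6
  if (any(missingTrip)) {
    pAA[missingTrip] <- pAB[missingTrip] <- pBB[missingTrip] <- 1 / 3
    s[missingTrip] <- 1
  }
  pAA <- pAA / s; pAB <- pAB / s; pBB <- pBB / s
  if (any(renorm))
    warning(sum(renorm), " probability triplet(s) in ", path,
            " summed within 1 +/- 1e-3 and were renormalized")
  nBad <- rowSums(badTrip)
  if (any(nBad > 0))
    warning(sum(nBad > 0), " record(s) in ", path,
            " contain probability triplets summing outside 1 +/- 1e-3; ",
            "renormalized and flagged")
  variants <- data.frame(
    snp_id = dt[[1]], rsid = dt[[2]], position = as.integer(dt[[3]]),
    allele_a = dt[[4]], allele_b = dt[[5]],
    n_bad_triplets = nBad, n_missing_triplets = rowSums(missingTrip),
    stringsAsFactors = FALSE
  )
  ImputedGenotypes(pAA, pAB, pBB, variants = variants, sampleIds = sampleIds)
}

#' Read an Oxford SAMPLE file
#'
#' @param path SAMPLE file: two header lines then one row per individual
#'   whose first column is the individual id.
#' @return character vector of individual ids.
#' @export
readSampleFile <- function(path) {
  con <- .openText(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) < 3L)
    stop("SAMPLE file ", path, " has no individual rows")
  vapply(strsplit(trimws(lines[-(1:2)]), "\\s+"), `[`, character(1), 1L)
}

#' Write an ImputedGenotypes to Oxford GEN (and optionally SAMPLE) format
#'
#' @param x an \linkS4class{ImputedGenotypes}.
#' @param path output GEN path (gzip if it ends in .gz).
#' @param samplePath optional SAMPLE output path.
#' @param digits probability decimal places (default 6).
#' @return invisibly, \code{path}.
#' @export
writeGen <- function(x, path, samplePath = NULL, digits = 6) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  m <- nrow(x); n <- ncol(x)
  if (is.null(rd$rsid)) rd$rsid <- rd$snp_id
  if (is.null(rd$position)) rd$position <- seq_len(m)
  if (is.null(rd$allele_a)) rd$allele_a <- "A"
  if (is.null(rd$allele_b)) rd$allele_b <- "B"
  a <- SummarizedExperiment::assays(x)
  prob <- matrix(0, m, 3L * n)
  prob[, seq(1L, 3L * n, by = 3L)] <- round(a[["pAA"]], digits)
  prob[, seq(2L, 3L * n, by = 3L)] <- round(a[["pAB"]], digits)
  prob[, seq(3L, 3L * n, by = 3L)] <- round(a[["pBB"]], digits)
  out <- data.table::data.table(
    rd$snp_id, rd$rsid, rd$position, rd$allele_a, rd$allele_b)
  out <- cbind(out, data.table::as.data.table(prob))
  data.table::fwrite(out, path, sep = " ", col.names = FALSE, quote = FALSE)
  if (!is.null(samplePath)) writeSampleFile(colnames(x), samplePath)
  invisible(path)
}

#' Write an Oxford SAMPLE file
#'
#' @param ids character vector of individual ids.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSampleFile <- function(ids, path) {
  writeLines(c("ID_1 ID_2 missing", "0 0 0", paste(ids, ids, "0")), path)
  invisible(path)
}
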