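# Metric table and IQS database serialization: plain TSV, 6-decimal
# numeric precision, undefined values written as "NA".

.roundNumerics <- function(df, digits = 6) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- round(df[[j]], digits)
  df
}

#' Write / read a per-SNP metrics table
#'
#' Tab-separated with header, one row per SNP, numeric fields at 6
#' decimals, undefined values (e.g. IQS at monomorphic SNPs) as
#' \code{NA}. Reading reproduces written values to 1e-6 and rejects
#' duplicated snp_ids.
#'
#' @param metrics data.frame from [snpMetrics()].
#' @param path TSV path (gzip transparent).
#' @return \code{writeMetrics}: invisibly, \code{path};
#'   \code{readMetrics}: the metrics data.frame.
#' @export
writeMetrics <- function(metrics, path) {
  data.table::fwrite(.roundNumerics(metrics), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeMetrics
#' @export
readMetrics <- function(path) {
  df <- as.data.frame(.freadText(path, header = TRUE, sep = "\t",
                                        na.strings = "NA"))
  if (is.null(df$snp_id)) stop("metrics table lacks an snp_id column")
  df$snp_id <- as.character(df$snp_id)
  dup <- unique(df$snp_id[duplicated(df$snp_id)])
  if (length(dup))
    stop("duplicate snp_id in ", path, ": ", paste(dup, collapse = ", "))
  df
}

#' Build IQS database records from a metrics table
#'
#' An IQS database stores, for a given imputation task (source platform,
#' target platform, population), the per-SNP IQS computed once on a cohort
#' genotyped both ways, so that future studies can filter the same
#' imputation without re-genotyping. The format is a 7-column TSV:
#' snp_id, source_platform, target_platform, population, iqs, maf, n.
#'
#' @param metrics data.frame from [snpMetrics()].
#' @param sourcePlatform,targetPlatform,population labels identifying the
#'   imputation task.
#' @return data.frame of database records.
#' @export
buildIqsDatabase <- function(metrics, sourcePlatform, targetPlatform,
                             population) {
  data.frame(
    snp_id = metrics$snp_id,
    source_platform = sourcePlatform, target_platform = targetPlatform,
    population = population,
    iqs = metrics$iqs, maf = metrics$maf, n = metrics$n_effective,
    stringsAsFactors = FALSE
  )
}

#' Write / read an IQS database file
#'
#' @param db data.frame of records (see [buildIqsDatabase()]).
#' @param path TSV path (gzip transparent).
#' @return \code{writeIqsDatabase}: invisibly, \code{path};
#'   \code{readIqsDatabase}: the validated records, undefined IQS parsed
#'   as \code{NA}.
#' @export
writeIqsDatabase <- function(db, path) {
  need <- c("snp_id", "source_platform", "target_platform", "population",
            "iqs", "maf", "n")
  if (!all(need %in% colnames(db)))
    stop("IQS database needs columns: ", paste(need, collapse = ", "))
  data.table::fwrite(.roundNumerics(db[, need]), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeIqsDatabase
#' @export
readIqsDatabase <- function(path) {
  db <- as.data.frame(.freadText(path, header = TRUE, sep = "\t",
                                        na.strings = "NA"))
  db$snp_id <- as.character(db$snp_id)
  dup <- unique(db$snp_id[duplicated(db$snp_id)])
  if (length(dup))
    stop("duplicate snp_id in IQS database ", path, ": ",
         paste(dup, collapse = ", "))
  if (any(!is.na(db$iqs) & db$iqs > 1 + 1e-9))
    stop("IQS values above 1 in ", path)
  if (any(is.na(db$n) | db$n < 1))
    stop("database records must have n >= 1")
  db
}

#' Filter a cohort's SNPs by a pre-computed IQS database
#'
#' Intersection semantics: a SNP is retained only if it is present in the
#' database with a defined IQS exceeding \code{minIqs}. SNPs absent from
#' the database, or with undefined IQS, fail the filter.
#'
#' @param snpIds character vector of the cohort's SNP ids (or a data.frame
#'   with an \code{snp_id} column).
#' @param db database records from [readIqsDatabase()].
#' @param minIqs retention threshold (default 0.9, strict).
#' @return list with \code{snp_id} (retained), \code{n_retained},
#'   \code{n_total}, \code{retention}.
#' @export
applyIqsDatabase <- function(snpIds, db, minIqs = 0.9) {
  if (is.data.frame(snpIds)) snpIds <- snpIds$snp_id
  good <- db$snp_id[!is.na(db$iqs) & db$iqs > minIqs]
  keep <- snpIds %in% good
  list(snp_id = snpIds[keep], n_retained = sum(keep),
       n_total = length(snpIds), retention = sum(keep) / length(snpIds))
}
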