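#' Construct a GenotypeDataset
#'
#' @param calls integer matrix of minor-allele counts with subjects in rows
#'   and SNPs in columns (the analysis orientation); entries 0/1/2/NA.
#'   Stored internally SNPs x subjects following SummarizedExperiment
#'   convention.
#' @param subjects data.frame with columns \code{subject_id}, \code{status}
#'   ("case"/"control"), and optionally \code{subtype} ("BDI"/"BDII"/
#'   "unknown") and \code{arm_id}; one row per subject, in row order of
#'   \code{calls}.
#' @param snps data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos_bp}, \code{allele_major}, \code{allele_minor} and optionally
#'   \code{maf}; one row per SNP in column order of \code{calls}. When
#'   \code{maf} is absent it is computed from the calls (minor-allele count
#'   over twice the non-missing subjects).
#' @return A \linkS4class{GenotypeDataset}.
#' @export
GenotypeDataset <- function(calls, subjects, snps) {
  stopifnot(is.matrix(calls), nrow(calls) == nrow(subjects),
            ncol(calls) == nrow(snps))
  subjects <- as.data.frame(subjects)
  snps <- as.data.frame(snps)
  if (is.null(subjects$subtype)) subjects$subtype <- "unknown"
  subjects$subtype[subjects$status == "control"] <- "unknown"
  if (is.null(subjects$arm_id)) subjects$arm_id <- "arm1"
  if (is.null(snps$maf)) {
    freq <- colSums(calls, na.rm = TRUE) / (2 * colSums(!is.na(calls)))
    flip <- !is.na(freq) & freq > 0.5
    if (any(flip)) {
      # re-polarise to the sample minor allele
      calls[, flip] <- 2L - calls[, flip]
      tmp <- snps$allele_major[flip]
      snps$allele_major[flip] <- snps$allele_minor[flip]
      snps$allele_minor[flip] <- tmp
      freq[flip] <- 1 - freq[flip]
    }
    snps$maf <- freq
  }
  m <- t(calls)
  dimnames(m) <- list(snps$snp_id, subjects$subject_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = m),
    rowData = S4Vectors::DataFrame(snps, row.names = snps$snp_id),
    colData = S4Vectors::DataFrame(subjects,
                                   row.names = subjects$subject_id))
  new("GenotypeDataset", se)
}

#' @describeIn GenotypeDataset SNP map as a DataFrame
#' @param x a GenotypeDataset
#' @export
setMethod("snpInfo", "GenotypeDataset",
          function(x) SummarizedExperiment::rowData(x))

#' @describeIn GenotypeDataset subject phenotype table
#' @export
setMethod("subjectInfo", "GenotypeDataset",
          function(x) SummarizedExperiment::colData(x))

#' @describeIn GenotypeDataset calls in analysis orientation (subjects x SNPs)
#' @export
setMethod("callMatrix", "GenotypeDataset",
          function(x) t(SummarizedExperiment::assay(x, "calls")))

#' @describeIn GenotypeDataset subject identifiers
#' @export
setMethod("subjectIds", "GenotypeDataset", function(x) colnames(x))

#' @describeIn GenotypeDataset SNP identifiers
#' @export
setMethod("snpIds", "GenotypeDataset", function(x) rownames(x))

#' @describeIn GenotypeDataset identifiers of case subjects
#' @export
setMethod("caseIds", "GenotypeDataset", function(x)
  colnames(x)[SummarizedExperiment::colData(x)$status == "case"])

#' @describeIn GenotypeDataset identifiers of control subjects
#' @export
setMethod("controlIds", "GenotypeDataset", function(x)
  colnames(x)[SummarizedExperiment::colData(x)$status == "control"])

setMethod("show", "GenotypeDataset", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("GenotypeDataset:", ncol(object), "subjects (",
      sum(cd$status == "case"), "cases /",
      sum(cd$status == "control"), "controls ) x",
      nrow(object), "SNPs\n")
  cat("  arms:", paste(unique(cd$arm_id), collapse = ", "), "\n")
  cat("  maf range: [",
      sprintf("%.3f", min(SummarizedExperiment::rowData(object)$maf)), ",",
      sprintf("%.3f", max(SummarizedExperiment::rowData(object)$maf)), "]\n")
})

#' Minor-allele frequencies recomputed from the stored calls
#'
#' @param ds a \linkS4class{GenotypeDataset}
#' @return named numeric vector of per-SNP minor-allele frequencies
#' @export
snpMaf <- function(ds) {
  cc <- SummarizedExperiment::assay(ds, "calls")
  setNames(rowSums(cc, na.rm = TRUE) / (2 * rowSums(!is.na(cc))),
           rownames(cc))
}
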