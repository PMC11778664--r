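#' GenotypeDataset: subjects x SNPs minor-allele counts with metadata
#'
#' Container for a case/control genotype study arm, extending
#' \linkS4class{SummarizedExperiment}. The single assay \code{"calls"} holds
#' minor-allele counts (0/1/2, \code{NA} = missing) with SNPs in rows and
#' subjects in columns. Row metadata carries the SNP map (\code{snp_id},
#' \code{chrom}, \code{pos_bp}, \code{allele_major}, \code{allele_minor},
#' \code{maf}); column metadata carries the phenotype (\code{subject_id},
#' \code{status} in \{case, control\}, \code{subtype} in \{BDI, BDII,
#' unknown\}, \code{arm_id}).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @export
setClass("GenotypeDataset", contains = "SummarizedExperiment")

setValidity("GenotypeDataset", function(object) {
  msg <- character(0)
  if (!("calls" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'calls' is required")
  else {
    cc <- SummarizedExperiment::assay(object, "calls")
    bad <- cc[!is.na(cc)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
      msg <- c(msg, "calls must be 0, 1, 2 or NA")
  }
  cd <- SummarizedExperiment::colData(object)
  rd <- SummarizedExperiment::rowData(object)
  need_cd <- c("subject_id", "status", "subtype", "arm_id")
  need_rd <- c("snp_id", "chrom", "pos_bp", "allele_major", "allele_minor",
               "maf")
  if (!all(need_cd %in% colnames(cd)))
    msg <- c(msg, paste("colData needs columns:",
                        paste(setdiff(need_cd, colnames(cd)), collapse = ", ")))
  if (!all(need_rd %in% colnames(rd)))
    msg <- c(msg, paste("rowData needs columns:",
                        paste(setdiff(need_rd, colnames(rd)), collapse = ", ")))
  if (all(need_cd %in% colnames(cd))) {
    if (anyDuplicated(cd$subject_id))
      msg <- c(msg, "duplicate subject IDs")
    if (!all(cd$status %in% c("case", "control")))
      msg <- c(msg, "status must be 'case' or 'control'")
    if (!all(cd$subtype %in% c("BDI", "BDII", "unknown")))
      msg <- c(msg, "subtype must be BDI, BDII or unknown")
    if (any(cd$status == "control" & cd$subtype != "unknown"))
      msg <- c(msg, "subtype must be 'unknown' for controls")
  }
  if (all(need_rd %in% colnames(rd))) {
    if (anyDuplicated(rd$snp_id)) msg <- c(msg, "duplicate SNP IDs")
    if (any(rd$pos_bp < 1)) msg <- c(msg, "pos_bp must be >= 1")
    if (any(rd$maf < 0 | rd$maf > 0.5 + 1e-12))
      msg <- c(msg, "maf must lie in [0, 0.5]")
  }
  if (length(msg)) msg else TRUE
})

#' ComboMatrix: subjects x allele-combinations in signed presence encoding
#'
#' Each SNP contributes three binary features (allele-combinations):
#' homozygous major, heterozygous, homozygous minor. Entries are +1 when the
#' subject exhibits the combination, -1 when not, and \code{NA} when the
#' underlying genotype call is missing (all three combinations of that SNP
#' are then \code{NA}). For every non-missing SNP exactly one of the three
#' combinations is +1.
#'
#' @slot values numeric matrix, subjects x combos, entries in \{-1, +1, NA\}
#' @slot comboInfo \code{DataFrame} with columns \code{combo_id},
#'   \code{snp_id}, \code{kind}
#' @export
setClass("ComboMatrix",
  representation(values = "matrix", comboInfo = "DataFrame"))

setValidity("ComboMatrix", function(object) {
  msg <- character(0)
  v <- object@values
  ci <- object@comboInfo
  if (ncol(v) != nrow(ci))
    msg <- c(msg, "comboInfo rows must match value columns")
  if (!all(c("combo_id", "snp_id", "kind") %in% colnames(ci)))
    msg <- c(msg, "comboInfo needs combo_id, snp_id, kind")
  else if (!all(ci$kind %in% c("hom_major", "het", "hom_minor")))
    msg <- c(msg, "kind must be hom_major, het or hom_minor")
  ok <- v[!is.na(v)]
  if (length(ok) && !all(ok %in% c(-1, 1)))
    msg <- c(msg, "values must be +1, -1 or NA")
  if (is.null(rownames(v))) msg <- c(msg, "values must have subject rownames")
  if (length(msg)) msg else TRUE
})

#' HalfLoopTrajectory: the recorded output of a half-loop run
#'
#' Iteration 0 is the full case submatrix; iteration \code{i} is the state
#' after \code{i} elimination passes. \code{rowRemoveIter[j]} is the first
#' iteration at which case \code{j} is absent (0 = retained throughout);
#' likewise \code{colRemoveIter} for allele-combinations. Null-ensemble slots
#' are filled by \code{\link{runHalfLoop}} / \code{\link{shuffledNull}}.
#'
#' @slot iterations data.frame with iter, M, N, traceRaw, trace, z, p
#' @slot rowRemoveIter named integer, one per case
#' @slot colRemoveIter named integer, one per combo
#' @slot schedule integer matrix of per-pass removal counts (rows, cols)
#' @slot nullTraces numeric matrix, one row per label-shuffled trial
#' @slot nullColRemove integer matrix of combo removal iterations per trial
#' @slot pOverall overall empirical p-value (max-z statistic)
#' @slot config list snapshot of the configuration used
#' @export
setClass("HalfLoopTrajectory",
  representation(iterations = "data.frame",
                 rowRemoveIter = "integer",
                 colRemoveIter = "integer",
                 schedule = "matrix",
                 nullTraces = "matrix",
                 nullColRemove = "matrix",
                 pOverall = "numeric",
                 config = "list"))

setValidity("HalfLoopTrajectory", function(object) {
  it <- object@iterations
  msg <- character(0)
  if (!all(c("iter", "M", "N", "trace") %in% colnames(it)))
    msg <- c(msg, "iterations needs iter, M, N, trace")
  else if (nrow(it) > 1 && any(diff(it$M) >= 0))
    msg <- c(msg, "M must be strictly decreasing")
  if (length(msg)) msg else TRUE
})
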