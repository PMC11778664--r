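#' Construct a ComboMatrix directly
#'
#' Usually produced by \code{\link{expandAlleleCombinations}}.
#'
#' @param values numeric matrix, subjects x combos, entries +1/-1/NA, with
#'   subject rownames and combo colnames
#' @param comboInfo data.frame/DataFrame with combo_id, snp_id, kind
#' @return A \linkS4class{ComboMatrix}.
#' @export
ComboMatrix <- function(values, comboInfo) {
  ci <- S4Vectors::DataFrame(as.data.frame(comboInfo))
  rownames(ci) <- ci$combo_id
  colnames(values) <- ci$combo_id
  new("ComboMatrix", values = values, comboInfo = ci)
}

#' @describeIn ComboMatrix combo metadata (combo_id, snp_id, kind)
#' @param x a ComboMatrix
#' @export
setMethod("comboInfo", "ComboMatrix", function(x) x@comboInfo)

#' @describeIn ComboMatrix the signed presence matrix (subjects x combos)
#' @export
setMethod("comboValues", "ComboMatrix", function(x) x@values)

#' @describeIn ComboMatrix combo identifiers
#' @export
setMethod("comboIds", "ComboMatrix", function(x) x@comboInfo$combo_id)

#' @describeIn ComboMatrix subject identifiers (row order)
#' @export
setMethod("subjectIds", "ComboMatrix", function(x) rownames(x@values))

setMethod("show", "ComboMatrix", function(object) {
  cat("ComboMatrix:", nrow(object@values), "subjects x",
      ncol(object@values), "allele-combinations (",
      length(unique(object@comboInfo$snp_id)), "SNPs )\n")
  nmiss <- sum(is.na(object@values))
  if (nmiss) cat("  missing entries:", nmiss, "\n")
})

#' Subset a ComboMatrix by subject IDs
#'
#' @param cm a \linkS4class{ComboMatrix}
#' @param ids subject identifiers to keep, in the requested order
#' @return a \linkS4class{ComboMatrix} with the selected rows
#' @export
subsetSubjects <- function(cm, ids) {
  miss <- setdiff(ids, rownames(cm@values))
  if (length(miss))
    stop("unknown subject IDs: ", paste(head(miss, 5), collapse = ", "))
  ComboMatrix(cm@values[ids, , drop = FALSE], cm@comboInfo)
}
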