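#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @export
setGeneric("subjectInfo", function(x) standardGeneric("subjectInfo"))
#' @export
setGeneric("callMatrix", function(x) standardGeneric("callMatrix"))
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @export
setGeneric("caseIds", function(x) standardGeneric("caseIds"))
#' @export
setGeneric("controlIds", function(x) standardGeneric("controlIds"))
#' @export
setGeneric("comboInfo", function(x) standardGeneric("comboInfo"))
#' @export
setGeneric("comboValues", function(x) standardGeneric("comboValues"))
#' @export
setGeneric("comboIds", function(x) standardGeneric("comboIds"))
#' @export
setGeneric("retainedCases", function(x, iter) standardGeneric("retainedCases"))
#' @export
setGeneric("retainedCombos",
           function(x, iter) standardGeneric("retainedCombos"))
#' @export
setGeneric("trajectoryTable", function(x) standardGeneric("trajectoryTable"))
#' @export
setGeneric("peakIteration", function(x) standardGeneric("peakIteration"))
#' @export
setGeneric("pOverall", function(x) standardGeneric("pOverall"))
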