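#' @describeIn HalfLoopTrajectory case ids retained in J(iter)
#' @param x a HalfLoopTrajectory
#' @param iter iteration index (0 = full case set)
#' @export
setMethod("retainedCases", "HalfLoopTrajectory", function(x, iter) {
  ri <- x@rowRemoveIter
  names(ri)[ri == 0L | ri > iter]
})

#' @describeIn HalfLoopTrajectory combo ids retained in K(iter)
#' @export
setMethod("retainedCombos", "HalfLoopTrajectory", function(x, iter) {
  ci <- x@colRemoveIter
  names(ci)[ci == 0L | ci > iter]
})

#' @describeIn HalfLoopTrajectory per-iteration table (iter, M, N, trace, z, p)
#' @export
setMethod("trajectoryTable", "HalfLoopTrajectory",
          function(x) x@iterations)

#' @describeIn HalfLoopTrajectory iteration with the maximal z-score
#' @export
setMethod("peakIteration", "HalfLoopTrajectory", function(x) {
  it <- x@iterations
  if (all(is.na(it$z))) stop("run the null ensemble first (runHalfLoop)")
  it$iter[which.max(it$z)]
})

#' @describeIn HalfLoopTrajectory overall empirical p-value (max-z statistic)
#' @export
setMethod("pOverall", "HalfLoopTrajectory", function(x) x@pOverall)

setMethod("show", "HalfLoopTrajectory", function(object) {
  it <- object@iterations
  cat("HalfLoopTrajectory:", nrow(it), "iterations, M(0) =", it$M[1],
      ", N(0) =", it$N[1], "\n")
  if (nrow(object@nullTraces)) {
    cat("  null ensemble:", nrow(object@nullTraces), "label-shuffled trials\n")
    cat("  peak z =", sprintf("%.2f", max(it$z)), "at iteration",
        it$iter[which.max(it$z)], "\n")
    cat("  overall p =", format(object@pOverall), "\n")
  } else {
    cat("  (no null ensemble attached)\n")
  }
})

#' Retained-set recovery against a planted ground truth
#'
#' Set-overlap metrics between the retained case set J(i) / combo set K(i)
#' and the planted bicluster of a synthetic dataset.
#'
#' @param traj a \linkS4class{HalfLoopTrajectory}
#' @param truth a ground-truth record from \code{\link{generateArm}}
#' @param iteration iteration index at which to evaluate
#' @return list with rowPrecision, rowRecall, colPrecision, colRecall,
#'   rowJaccard, colJaccard
#' @export
recoveryMetrics <- function(traj, truth, iteration) {
  it <- traj@iterations
  if (!iteration %in% it$iter) stop("iteration outside trajectory")
  J <- retainedCases(traj, iteration)
  K <- retainedCombos(traj, iteration)
  planted <- intersect(truth$plantedCaseIds, names(traj@rowRemoveIter))
  plantedK <- intersect(truth$plantedComboIds, names(traj@colRemoveIter))
  ovr <- function(sel, tru) {
    i <- length(intersect(sel, tru))
    c(precision = if (length(sel)) i / length(sel) else NA_real_,
      recall = if (length(tru)) i / length(tru) else NA_real_,
      jaccard = i / length(union(sel, tru)))
  }
  r <- ovr(J, planted)
  k <- ovr(K, plantedK)
  list(rowPrecision = r[["precision"]], rowRecall = r[["recall"]],
       colPrecision = k[["precision"]], colRecall = k[["recall"]],
       rowJaccard = r[["jaccard"]], colJaccard = k[["jaccard"]])
}
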