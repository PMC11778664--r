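#' Configuration for the half-loop biclustering search
#'
#' @param gamma fraction of remaining cases and allele-combinations removed
#'   per iteration; default \code{0.5^8} (~0.004), small enough that the
#'   elimination path is effectively converged in the removal fraction
#' @param nShuffles number of label-shuffled null trials (default 128)
#' @param seed master RNG seed; per-shuffle seeds are derived from it by a
#'   fixed counter scheme
#' @param correct logical: apply the covariate (kernel-reweighting)
#'   correction to the differential-expression scores
#' @param selectedCovariates covariate column indices used for the kernel
#'   and the shuffling strata (typically from \code{\link{selectCovariates}})
#' @param bandwidthScale Gaussian kernel bandwidth multiplier (see
#'   \code{\link{kernelWeights}})
#' @param nStrata number of covariate strata for label shuffling
#'   (default \code{max(1, floor(n/500))})
#' @return a list of class \code{hetloop_config}
#' @export
halfLoopConfig <- function(gamma = 0.5^8, nShuffles = 128L, seed = 1L,
                           correct = TRUE, selectedCovariates = integer(0),
                           bandwidthScale = 1, nStrata = NULL) {
  stopifnot(gamma > 0, gamma < 1, nShuffles >= 1)
  structure(list(gamma = gamma, nShuffles = as.integer(nShuffles),
                 seed = as.integer(seed), correct = correct,
                 selectedCovariates = selectedCovariates,
                 bandwidthScale = bandwidthScale, nStrata = nStrata),
            class = "hetloop_config")
}

#' Case-versus-control differential-expression scores
#'
#' For case j and allele-combination k, [D<-D](j,k) is the (weighted)
#' fraction of other cases whose +1/-1 state at k agrees with case j's
#' (self excluded, weights renormalised), and [D<-X](j,k) is the agreeing
#' fraction of controls. Q(j,k) = [D<-D](j,k) - [D<-X](j,k) measures how
#' much of case j's state at k is shared by cases beyond controls. Missing
#' entries are excluded from numerator and denominator; Q(j,k) = 0 when the
#' focal entry is missing or a reference set is empty at k.
#'
#' @param D case \linkS4class{ComboMatrix}
#' @param X control \linkS4class{ComboMatrix} (same combo panel)
#' @param weights optional \code{hetloop_kernel} built on the pooled
#'   subjects (cases and controls); NULL = uniform weights
#' @return list of class \code{hetloop_scores}: \code{Q} (cases x combos),
#'   \code{Qrow}, \code{Qcol}, \code{traceRaw} and the size-normalised
#'   \code{trace}
#' @export
differentialScores <- function(D, X, weights = NULL) {
  dv <- comboValues(D)
  xv <- comboValues(X)
  if (!identical(colnames(dv), colnames(xv)))
    stop("case and control combo panels differ")
  if (nrow(dv) < 2) stop("need at least two cases (self-exclusion)")
  if (nrow(xv) < 1) stop("need at least one control")
  sD <- .engineMatrix(dv)
  sX <- .engineMatrix(xv)
  aD <- abs(sD)
  aX <- abs(sX)
  if (is.null(weights) || (inherits(weights, "hetloop_kernel") &&
                           weights$uniform)) {
    SD <- colSums(sD)
    CD <- colSums(aD)
    SX <- colSums(sX)
    CX <- colSums(aX)
    dd <- sweep(sD, 2, SD, "*") - aD            # p*SD - 1 at valid entries
    Q <- sweep(dd, 2, 2 * pmax(CD - 1, 1), "/") -
      sweep(sD, 2, ifelse(CX > 0, SX / (2 * CX), 0), "*")
    bad <- (CD - 1 <= 0) | (CX <= 0)
    Q[, bad] <- 0
    Q[aD == 0] <- 0
  } else {
    W <- kernelMatrix(weights)
    di <- match(rownames(dv), rownames(W))
    xi <- match(rownames(xv), rownames(W))
    if (anyNA(di) || anyNA(xi))
      stop("kernel does not cover all subjects")
    Wdd <- W[di, di, drop = FALSE]
    Wdx <- W[di, xi, drop = FALSE]
    TDs <- Wdd %*% sD
    TDc <- Wdd %*% aD
    TXs <- Wdx %*% sX
    TXc <- Wdx %*% aX
    Q <- 0.5 * sD * (ifelse(TDc > 0, TDs / pmax(TDc, 1e-300), 0) -
                     ifelse(TXc > 0, TXs / pmax(TXc, 1e-300), 0))
    Q[aD == 0 | TDc <= 0 | TXc <= 0] <- 0
  }
  dimnames(Q) <- dimnames(dv)
  tr <- sum(Q)
  structure(list(Q = Q, Qrow = rowSums(Q), Qcol = colSums(Q),
                 traceRaw = tr, trace = tr / (nrow(Q) * ncol(Q))),
            class = "hetloop_scores")
}

# Internal: run the elimination engine. Returns the raw engine output.
.runEngine <- function(P, caseRows, ctrlRows, schedule, W) {
  .hl_engine(P, as.integer(caseRows - 1L), as.integer(ctrlRows - 1L),
             schedule, if (is.null(W)) matrix(0, 0, 0) else W)
}

#' Run the half-loop elimination on the data labels (single pass)
#'
#' Iteratively removes the cases and allele-combinations with the lowest
#' row/column scores, max(1, round(gamma * remaining)) of each per
#' iteration (ties broken by original index), recording the size-normalised
#' trace at every iteration until no cases (or combos) remain. The
#' elimination schedule is stored for reuse by the label-shuffled null.
#'
#' @param D case \linkS4class{ComboMatrix}
#' @param X control \linkS4class{ComboMatrix}
#' @param cov covariate table (rows named by subject) or NULL
#' @param cfg a \code{\link{halfLoopConfig}}
#' @return a \linkS4class{HalfLoopTrajectory} (null slots empty; see
#'   \code{\link{runHalfLoop}} for the full pipeline)
#' @export
halfLoop <- function(D, X, cov = NULL, cfg = halfLoopConfig()) {
  dv <- comboValues(D)
  xv <- comboValues(X)
  if (!identical(colnames(dv), colnames(xv)))
    stop("case and control combo panels differ")
  P <- rbind(.engineMatrix(dv), .engineMatrix(xv))
  caseRows <- seq_len(nrow(dv))
  ctrlRows <- nrow(dv) + seq_len(nrow(xv))
  W <- .pooledKernel(cfg, cov, rownames(P))
  schedule <- .removalSchedule(nrow(dv), ncol(dv), cfg$gamma)
  eng <- .runEngine(P, caseRows, ctrlRows, schedule, W)
  .trajectoryFromEngine(eng, schedule, rownames(dv), colnames(dv), cfg)
}

.pooledKernel <- function(cfg, cov, ids) {
  if (!isTRUE(cfg$correct) || is.null(cov) ||
      !length(cfg$selectedCovariates)) return(NULL)
  kw <- kernelWeights(.alignCovariates(cov, ids),
                      cfg$selectedCovariates, cfg$bandwidthScale)
  kernelMatrix(kw)
}

.trajectoryFromEngine <- function(eng, schedule, caseIds, comboIds, cfg) {
  it <- data.frame(iter = seq_along(eng$M) - 1L, M = eng$M, N = eng$N,
                   traceRaw = eng$traceRaw, trace = eng$trace,
                   z = NA_real_, p = NA_real_)
  new("HalfLoopTrajectory",
      iterations = it,
      rowRemoveIter = setNames(eng$rowRemoveIter, caseIds),
      colRemoveIter = setNames(eng$colRemoveIter, comboIds),
      schedule = schedule,
      nullTraces = matrix(numeric(0), 0, nrow(it)),
      nullColRemove = matrix(integer(0), 0, length(comboIds)),
      pOverall = NA_real_,
      config = unclass(cfg))
}

#' Label-shuffled null ensemble on a fixed elimination schedule
#'
#' Draws samples from the null hypothesis that genotype structure is
#' independent of the case/control labels: labels are permuted within
#' covariate strata (preserving per-stratum case/control counts), D and X
#' are rebuilt, and the half-loop is rerun forced onto the data run's
#' elimination schedule so per-iteration null distributions are
#' size-matched.
#'
#' @param D,X case and control \linkS4class{ComboMatrix} objects
#' @param cov covariate table or NULL
#' @param strata a stratum assignment from \code{\link{buildStrata}}
#'   (NULL = one stratum, plain shuffling)
#' @param cfg a \code{\link{halfLoopConfig}}
#' @param schedule elimination schedule to force (from the data run)
#' @return list with \code{traces} (nShuffles x iterations) and
#'   \code{colRemove} (nShuffles x combos removal iterations)
#' @export
shuffledNull <- function(D, X, cov = NULL, strata = NULL,
                         cfg = halfLoopConfig(), schedule) {
  dv <- comboValues(D)
  xv <- comboValues(X)
  P <- rbind(.engineMatrix(dv), .engineMatrix(xv))
  ids <- rownames(P)
  nD <- nrow(dv)
  n <- nrow(P)
  W <- .pooledKernel(cfg, cov, ids)
  if (is.null(strata)) strata <- list(stratum = setNames(rep(1L, n), ids))
  st <- strata$stratum[ids]
  isCase <- c(rep(TRUE, nD), rep(FALSE, n - nD))
  degenerate <- vapply(split(isCase, st),
                       function(z) all(z) || !any(z), logical(1))
  if (any(degenerate))
    message(sum(degenerate),
            " stratum/strata contain a single class; labels fixed there")
  nIter <- 0L
  traces <- NULL
  colRemove <- matrix(0L, cfg$nShuffles, ncol(dv))
  for (t in seq_len(cfg$nShuffles)) {
    set.seed(.deriveSeed(cfg$seed, 1000L + t))
    newCase <- logical(n)
    for (s in unique(st)) {
      idx <- which(st == s)
      k <- sum(isCase[idx])
      newCase[idx[sample.int(length(idx), k)]] <- TRUE
    }
    eng <- .runEngine(P, which(newCase), which(!newCase), schedule, W)
    if (is.null(traces)) {
      nIter <- length(eng$trace)
      traces <- matrix(NA_real_, cfg$nShuffles, nIter)
    }
    traces[t, ] <- eng$trace[seq_len(nIter)]
    colRemove[t, ] <- eng$colRemoveIter
  }
  list(traces = traces, colRemove = colRemove)
}

#' Per-iteration and overall significance of a trace trajectory
#'
#' z(i) compares the data trace at iteration i with the null ensemble at
#' that iteration; p(i) is the add-one empirical upper tail. The overall
#' p-value uses the maximum-over-iterations z statistic, with each null
#' trial z-scored leave-one-out against the remaining trials.
#'
#' @param dataTrace numeric vector of per-iteration traces from the data run
#' @param nullTraces matrix of null traces (trials x iterations)
#' @return list with \code{z}, \code{p}, \code{pOverall}, \code{zMax},
#'   \code{nullZMax}
#' @export
trajectorySignificance <- function(dataTrace, nullTraces) {
  if (ncol(nullTraces) != length(dataTrace))
    stop("trace length mismatch between data and null ensemble")
  S <- nrow(nullTraces)
  if (S < 2) stop("need at least two null traces")
  mu <- colMeans(nullTraces)
  sg <- apply(nullTraces, 2, sd)
  z <- ifelse(sg > 0, (dataTrace - mu) / sg, 0)
  exceed <- colSums(sweep(nullTraces, 2, dataTrace, ">="))
  p <- (1 + exceed) / (1 + S)
  # leave-one-out z-scores for each null trial
  nullZMax <- vapply(seq_len(S), function(t) {
    rest <- nullTraces[-t, , drop = FALSE]
    m <- colMeans(rest)
    s <- apply(rest, 2, sd)
    max(ifelse(s > 0, (nullTraces[t, ] - m) / s, 0))
  }, numeric(1))
  zMax <- max(z)
  pOverall <- (1 + sum(nullZMax >= zMax)) / (1 + S)
  list(z = z, p = p, pOverall = pOverall, zMax = zMax, nullZMax = nullZMax)
}

#' Full half-loop analysis: data pass, stratified null, significance
#'
#' Convenience wrapper running \code{\link{halfLoop}},
#' \code{\link{buildStrata}}, \code{\link{shuffledNull}} and
#' \code{\link{trajectorySignificance}}, returning a completed trajectory.
#'
#' @inheritParams halfLoop
#' @param strata optional precomputed stratum assignment
#' @return a \linkS4class{HalfLoopTrajectory} with null ensemble, z, p and
#'   overall p filled in
#' @export
runHalfLoop <- function(D, X, cov = NULL, cfg = halfLoopConfig(),
                        strata = NULL) {
  traj <- halfLoop(D, X, cov, cfg)
  ids <- c(rownames(comboValues(D)), rownames(comboValues(X)))
  if (is.null(strata)) {
    if (!is.null(cov) && length(cfg$selectedCovariates)) {
      strata <- buildStrata(.alignCovariates(cov, ids),
                            cfg$selectedCovariates,
                            nStrata = cfg$nStrata,
                            seed = .deriveSeed(cfg$seed, 77L))
    } else {
      strata <- list(stratum = setNames(rep(1L, length(ids)), ids))
    }
  }
  nul <- shuffledNull(D, X, cov, strata, cfg, traj@schedule)
  sig <- trajectorySignificance(traj@iterations$trace, nul$traces)
  traj@iterations$z <- sig$z
  traj@iterations$p <- sig$p
  traj@nullTraces <- nul$traces
  traj@nullColRemove <- nul$colRemove
  traj@pOverall <- sig$pOverall
  traj
}

#' Search for control-side biclusters
#'
#' Identical to the case-side search with the roles of cases and controls
#' exchanged: finds genetic signatures more prevalent among controls.
#'
#' @inheritParams runHalfLoop
#' @return a \linkS4class{HalfLoopTrajectory} over the control subjects
#' @export
controlSearch <- function(D, X, cov = NULL, cfg = halfLoopConfig(),
                          strata = NULL) {
  runHalfLoop(X, D, cov, cfg, strata)
}

#' Ratio and enrichment of a binary case label along the trajectory
#'
#' Tracks, per iteration, the ratio of label-positive to label-negative
#' cases among the retained set J(i), with an exact hypergeometric upper
#' tail for observing at least that many positives when drawing |J(i)|
#' cases from the iteration-0 composition. Typical use: BDI vs BDII
#' enrichment inside a discovered bicluster.
#'
#' @param traj a \linkS4class{HalfLoopTrajectory}
#' @param label logical vector named by case id (TRUE = positive)
#' @return data.frame with iter, nPos, nNeg, ratio, p, minusLog10P
#' @export
labelEnrichmentTrajectory <- function(traj, label) {
  ids <- names(traj@rowRemoveIter)
  if (!all(ids %in% names(label)))
    stop("label must cover every case")
  lab <- label[ids]
  K <- sum(lab)
  Kn <- sum(!lab)
  it <- traj@iterations$iter
  res <- lapply(it, function(i) {
    inJ <- traj@rowRemoveIter == 0L | traj@rowRemoveIter > i
    np <- sum(lab[inJ])
    nn <- sum(!lab[inJ])
    p <- phyper(np - 1, K, Kn, np + nn, lower.tail = FALSE)
    data.frame(iter = i, nPos = np, nNeg = nn,
               ratio = if (nn == 0) Inf else np / nn,
               p = p, minusLog10P = -log10(p))
  })
  do.call(rbind, res)
}

#' Scramble a bicluster submatrix in place
#'
#' Independently permutes each selected column's entries across the
#' selected rows (preserving within-submatrix column sums exactly), leaving
#' all other entries untouched. Used to erase a discovered bicluster before
#' searching for secondary structure.
#'
#' @param D a \linkS4class{ComboMatrix}
#' @param rows subject ids of the bicluster rows
#' @param cols combo ids of the bicluster columns
#' @param seed RNG seed
#' @return a \linkS4class{ComboMatrix} with the submatrix scrambled
#' @export
scrambleBicluster <- function(D, rows, cols, seed = 1) {
  v <- comboValues(D)
  ri <- match(rows, rownames(v))
  ci <- match(cols, colnames(v))
  if (anyNA(ri) || anyNA(ci)) stop("rows/cols must exist in the matrix")
  set.seed(seed)
  for (k in ci) v[ri, k] <- v[ri[sample(length(ri))], k]
  ComboMatrix(v, D@comboInfo)
}
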