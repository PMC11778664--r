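#' Dominant principal component of a bicluster submatrix
#'
#' Centers the columns of the signed case submatrix D[J(i), K'(i)] by their
#' means over J(i) and returns the top right-singular vector. The stored
#' column centers are reused when projecting replication subjects, so no
#' replication-arm information leaks into the component. The sign is fixed
#' so that training cases project higher than training controls on average
#' (when a control matrix is supplied; otherwise the largest-magnitude
#' loading is made positive).
#'
#' @param D training-case \linkS4class{ComboMatrix}
#' @param rows case ids J(i)
#' @param combos combo ids K'(i)
#' @param X optional training-control \linkS4class{ComboMatrix} used for
#'   the sign convention
#' @return list of class \code{hetloop_component}: \code{v} (unit vector
#'   named by combo), \code{centers}, \code{rows}
#' @export
biclusterComponent <- function(D, rows, combos, X = NULL) {
  v <- comboValues(D)
  ri <- match(rows, rownames(v))
  ci <- match(combos, colnames(v))
  if (anyNA(ri) || anyNA(ci)) stop("unknown row/combo ids")
  if (length(ri) < 2) stop("need at least two bicluster rows")
  B <- v[ri, ci, drop = FALSE]
  centers <- colMeans(B, na.rm = TRUE)
  centers[is.nan(centers)] <- 0
  Bc <- sweep(B, 2, centers)
  Bc[is.na(Bc)] <- 0
  if (all(abs(Bc) < 1e-12)) stop("all-constant submatrix: no dominant direction")
  sv <- svd(Bc, nu = 0, nv = 1)
  vec <- drop(sv$v)
  comp <- structure(list(v = setNames(vec, colnames(B)),
                         centers = setNames(centers, colnames(B)),
                         rows = rows),
                    class = "hetloop_component")
  if (!is.null(X)) {
    uD <- projectScores(D, comp)
    uX <- projectScores(X, comp)
    if (mean(uD) - mean(uX) < 0) comp$v <- -comp$v
  } else if (vec[which.max(abs(vec))] < 0) {
    comp$v <- -comp$v
  }
  comp
}

#' Project subjects onto a bicluster component
#'
#' u_j = sum_k (B(j,k) - center_k) v_k over the component's combos;
#' missing entries contribute 0.
#'
#' @param cm a \linkS4class{ComboMatrix} containing the component's combos
#' @param component a \code{hetloop_component}
#' @return named numeric vector of bicluster-scores
#' @export
projectScores <- function(cm, component) {
  v <- comboValues(cm)
  miss <- setdiff(names(component$v), colnames(v))
  if (length(miss))
    stop("combos absent from the matrix: ",
         paste(head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5))
  B <- v[, names(component$v), drop = FALSE]
  Bc <- sweep(B, 2, component$centers)
  Bc[is.na(Bc)] <- 0
  drop(Bc %*% component$v)
}

#' Covariate-corrected AUC between case and control scores
#'
#' Scores are residualised jointly on the selected covariates (see
#' \code{\link{residualize}}), then the AUC is the Mann-Whitney statistic
#' over case/control pairs with ties counted 1/2.
#'
#' @param caseScores,controlScores named numeric score vectors
#' @param cov covariate table or NULL (no correction)
#' @param selected covariate column indices
#' @param nPerm optional number of label permutations for an empirical
#'   p-value (0 = none)
#' @param seed RNG seed for the permutations
#' @return list with \code{auc} and (when requested) \code{p}
#' @export
correctedAuc <- function(caseScores, controlScores, cov = NULL,
                         selected = NULL, nPerm = 0, seed = 1) {
  n1 <- length(caseScores)
  n2 <- length(controlScores)
  if (!n1 || !n2) stop("both groups must be non-empty")
  s <- c(caseScores, controlScores)
  if (!is.null(cov) && length(selected))
    s <- residualize(s, cov, selected)
  auc <- .rankAuc(s[seq_len(n1)], s[n1 + seq_len(n2)])
  out <- list(auc = auc)
  if (nPerm > 0) {
    r <- rank(s)
    set.seed(seed)
    nullAuc <- vapply(seq_len(nPerm), function(t) {
      idx <- sample(n1 + n2, n1)
      (sum(r[idx]) - n1 * (n1 + 1) / 2) / (n1 * n2)
    }, numeric(1))
    out$p <- (1 + sum(nullAuc >= auc)) / (1 + nPerm)
  }
  out
}

#' Evaluate replication of a discovered bicluster in another arm
#'
#' For each iteration i of the interval: intersect the retained combo set
#' K(i) with the replication arm's panel, compute the dominant principal
#' component v(i) of the training bicluster restricted to those combos,
#' project training and replication subjects, and record the
#' covariate-corrected AUCs A(i) (training) and A'(i) (replication).
#' The interval average Abar' summarises replication strength; its
#' significance comes from \code{\link{replicationSignificance}}.
#'
#' When \code{interval} is NULL it is selected from the training trajectory
#' as the maximal contiguous run of iterations whose trace p-value and
#' training-AUC permutation p-value are both at or below \code{alpha}.
#'
#' @param traj training-arm \linkS4class{HalfLoopTrajectory}
#' @param trainD,trainX training case/control \linkS4class{ComboMatrix}
#' @param repD,repX replication case/control \linkS4class{ComboMatrix}
#' @param trainCov,repCov covariate tables for the two arms (or NULL)
#' @param selected covariate columns used for AUC correction
#' @param interval integer vector of iterations, or NULL to auto-select
#' @param alpha significance level for interval auto-selection
#' @param nPerm permutations for the per-iteration AUC p-values
#' @param seed RNG seed
#' @return list of class \code{hetloop_replication}: per-iteration table
#'   (i, A, pA, Aprime, pAprime), \code{AbarPrime}, components, and the
#'   stored replication scores needed by
#'   \code{\link{replicationSignificance}}
#' @export
replicateBicluster <- function(traj, trainD, trainX, repD, repX,
                               trainCov = NULL, repCov = NULL,
                               selected = NULL, interval = NULL,
                               alpha = 0.05, nPerm = 200, seed = 1) {
  repPanel <- unique(comboInfo(repD)$snp_id)
  it <- traj@iterations
  if (is.null(interval)) {
    cand <- it$iter[!is.na(it$p) & it$p <= alpha & it$M >= 2]
    if (!length(cand)) stop("no significant iterations to build an interval")
    runs <- split(cand, cumsum(c(1, diff(cand) != 1)))
    lens <- vapply(runs, length, integer(1))
    interval <- runs[[which.max(lens)]]
  }
  interval <- interval[interval %in% it$iter]
  trainIdsD <- rownames(comboValues(trainD))
  trainIdsX <- rownames(comboValues(trainX))
  repIdsD <- rownames(comboValues(repD))
  repIdsX <- rownames(comboValues(repX))
  nRep <- length(repIdsD) + length(repIdsX)
  repScores <- matrix(NA_real_, nRep, length(interval),
                      dimnames = list(c(repIdsD, repIdsX), interval))
  rows <- list()
  comps <- list()
  set.seed(seed)
  for (w in seq_along(interval)) {
    i <- interval[w]
    J <- retainedCases(traj, i)
    K <- retainedCombos(traj, i)
    Ki <- K[comboInfo(trainD)$snp_id[match(K, comboIds(trainD))] %in%
              repPanel]
    if (length(J) < 2 || !length(Ki)) next
    comp <- tryCatch(biclusterComponent(trainD, J, Ki, X = trainX),
                     error = function(e) NULL)  # degenerate submatrix
    if (is.null(comp)) next
    uD <- projectScores(trainD, comp)
    uX <- projectScores(trainX, comp)
    a <- correctedAuc(uD, uX, trainCov, selected, nPerm = nPerm,
                      seed = .deriveSeed(seed, 10L + i))
    upD <- projectScores(repD, comp)
    upX <- projectScores(repX, comp)
    ap <- correctedAuc(upD, upX, repCov, selected, nPerm = nPerm,
                       seed = .deriveSeed(seed, 20L + i))
    # store residualised replication scores for the interval-level null
    s <- c(upD, upX)
    if (!is.null(repCov) && length(selected))
      s <- residualize(s, repCov, selected)
    repScores[, w] <- s
    comps[[as.character(i)]] <- comp
    rows[[length(rows) + 1L]] <-
      data.frame(iter = i, M = length(J), Nprime = length(Ki),
                 A = a$auc, pA = if (nPerm > 0) a$p else NA_real_,
                 Aprime = ap$auc,
                 pAprime = if (nPerm > 0) ap$p else NA_real_)
  }
  if (!length(rows)) stop("no evaluable iterations in the interval")
  tab <- do.call(rbind, rows)
  structure(list(table = tab, interval = tab$iter,
                 AbarPrime = mean(tab$Aprime),
                 components = comps,
                 repScores = repScores[, colnames(repScores) %in%
                                         as.character(tab$iter),
                                       drop = FALSE],
                 repStatus = c(rep("case", length(repIdsD)),
                               rep("control", length(repIdsX)))),
            class = "hetloop_replication")
}

#' Permutation significance of the interval-averaged replication AUC
#'
#' Permutes the replication arm's case/control labels within covariate
#' strata, recomputes A'(i) over the interval with the components fixed,
#' and compares the interval average to its null distribution (add-one
#' counting).
#'
#' @param res a \code{hetloop_replication} from
#'   \code{\link{replicateBicluster}}
#' @param strata stratum assignment for the replication subjects (NULL =
#'   one stratum)
#' @param nShuffles number of label permutations (default 128)
#' @param seed RNG seed
#' @return list with \code{AbarPrime}, \code{p}, \code{nullAbar}
#' @export
replicationSignificance <- function(res, strata = NULL, nShuffles = 128,
                                    seed = 1) {
  stopifnot(inherits(res, "hetloop_replication"))
  sc <- res$repScores
  isCase <- res$repStatus == "case"
  n <- length(isCase)
  st <- if (is.null(strata)) rep(1L, n) else
    strata$stratum[rownames(sc)]
  ranks <- apply(sc, 2, rank)
  n1 <- sum(isCase)
  n2 <- n - n1
  nullAbar <- numeric(nShuffles)
  for (t in seq_len(nShuffles)) {
    set.seed(.deriveSeed(seed, 3000L + t))
    newCase <- logical(n)
    for (s in unique(st)) {
      idx <- which(st == s)
      newCase[idx[sample.int(length(idx), sum(isCase[idx]))]] <- TRUE
    }
    nullAbar[t] <- mean((colSums(ranks[newCase, , drop = FALSE]) -
                           n1 * (n1 + 1) / 2) / (n1 * n2))
  }
  p <- (1 + sum(nullAbar >= res$AbarPrime)) / (1 + nShuffles)
  list(AbarPrime = res$AbarPrime, p = p, nullAbar = nullAbar)
}

#' Degrade the SNP overlap of a replication panel
#'
#' Removes SNPs (all three combos) from the replication matrix, drawn
#' uniformly from its intersection with the training panel, until the
#' overlap coefficient with the training panel first reaches the target.
#' Used to study how replication strength depends on cross-platform panel
#' overlap.
#'
#' @param cm replication \linkS4class{ComboMatrix}
#' @param trainingPanel SNP ids of the training panel
#' @param targetOverlap desired overlap coefficient (must not exceed the
#'   current one)
#' @param seed RNG seed
#' @return a \linkS4class{ComboMatrix} with reduced panel
#' @export
degradeOverlap <- function(cm, trainingPanel, targetOverlap, seed = 1) {
  panel <- unique(comboInfo(cm)$snp_id)
  cur <- snpOverlapCoefficient(panel, trainingPanel)
  if (targetOverlap > cur + 1e-12)
    stop("target overlap exceeds the current overlap")
  set.seed(seed)
  shared <- intersect(panel, trainingPanel)
  while (cur > targetOverlap && length(shared) > 0) {
    drop <- sample(shared, 1)
    panel <- setdiff(panel, drop)
    shared <- setdiff(shared, drop)
    if (!length(panel)) stop("cannot reach the target overlap")
    cur <- snpOverlapCoefficient(panel, trainingPanel)
  }
  if (cur > targetOverlap)
    stop("cannot reach the target overlap")
  restrictToPanel(cm, panel)
}
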