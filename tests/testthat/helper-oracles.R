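# Independent brute-force reimplementations used as oracles. Explicit
# double/triple loops, no matrix algebra, kept deliberately naive.

# Dv, Xv: signed matrices (+1/-1/NA), cases and controls.
# W: pooled kernel matrix ordered cases-then-controls (diag 0), or NULL.
oracle_differential_scores <- function(Dv, Xv, W = NULL) {
  M <- nrow(Dv)
  N <- ncol(Dv)
  nX <- nrow(Xv)
  Q <- matrix(0, M, N)
  for (j in seq_len(M)) {
    for (k in seq_len(N)) {
      if (is.na(Dv[j, k])) next
      numD <- denD <- 0
      for (j2 in seq_len(M)) {
        if (j2 == j || is.na(Dv[j2, k])) next
        w <- if (is.null(W)) 1 else W[j, j2]
        denD <- denD + w
        if (Dv[j2, k] == Dv[j, k]) numD <- numD + w
      }
      numX <- denX <- 0
      for (jx in seq_len(nX)) {
        if (is.na(Xv[jx, k])) next
        w <- if (is.null(W)) 1 else W[j, M + jx]
        denX <- denX + w
        if (Xv[jx, k] == Dv[j, k]) numX <- numX + w
      }
      if (denD > 0 && denX > 0)
        Q[j, k] <- numD / denD - numX / denX
    }
  }
  list(Q = Q, Qrow = rowSums(Q), Qcol = colSums(Q), traceRaw = sum(Q),
       trace = sum(Q) / (M * N))
}

# Full elimination path with the same removal rule; returns per-iteration
# retained index sets and normalised traces.
oracle_half_loop <- function(Dv, Xv, gamma, W = NULL) {
  rows <- seq_len(nrow(Dv))
  cols <- seq_len(ncol(Dv))
  J <- list()
  K <- list()
  trace <- numeric(0)
  repeat {
    if (!length(rows) || !length(cols)) break
    sc <- oracle_differential_scores(
      Dv[rows, cols, drop = FALSE], Xv[, cols, drop = FALSE],
      if (is.null(W)) NULL else
        W[c(rows, nrow(Dv) + seq_len(nrow(Xv))),
          c(rows, nrow(Dv) + seq_len(nrow(Xv)))])
    J[[length(J) + 1L]] <- rows
    K[[length(K) + 1L]] <- cols
    trace <- c(trace, sc$trace)
    nr <- min(length(rows), max(1L, as.integer(round(gamma * length(rows)))))
    nc <- min(length(cols), max(1L, as.integer(round(gamma * length(cols)))))
    # scores are rationals with coarse denominators; exact ties (e.g. two
    # columns with identical signed/valid counts) re-emerge only after
    # rounding away summation-order noise, so the index tie-break applies
    # to the same tie classes as the closed-form implementation
    rOrd <- order(round(sc$Qrow, 9), seq_along(rows))
    cOrd <- order(round(sc$Qcol, 9), seq_along(cols))
    rows <- sort(rows[-rOrd[seq_len(nr)]])
    cols <- sort(cols[-cOrd[seq_len(nc)]])
  }
  list(J = J, K = K, trace = trace)
}

# AUC by exhaustive pair enumeration, ties counted 1/2.
oracle_auc <- function(caseScores, controlScores) {
  tot <- 0
  for (a in caseScores)
    for (b in controlScores)
      tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(caseScores) * length(controlScores))
}

# Hypergeometric upper tail by exhaustive subset enumeration.
oracle_hyper <- function(k, nSelected, nPathway, nUniverse) {
  sets <- utils::combn(nUniverse, nSelected)
  hits <- colSums(sets <= nPathway)  # first nPathway elements = pathway
  mean(hits >= k)
}

# Monte-Carlo AUC of the liability-threshold model: simulate (g, L),
# threshold L at prevalence K, empirical AUC of g between groups.
oracle_liability_auc <- function(r2, K, n = 4e5, seed = 1) {
  set.seed(seed)
  g <- rnorm(n, sd = sqrt(r2))
  L <- g + rnorm(n, sd = sqrt(1 - r2))
  case <- L > qnorm(1 - K)
  r <- rank(g)
  n1 <- sum(case)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * (n - n1))
}
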