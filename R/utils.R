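# Internal helpers shared across modules.

# Elimination schedule: rows removed per pass are max(1, round(gamma * M))
# until either margin is exhausted. Uses R's round() (round-half-even), so
# the schedule is reproducible from (M0, N0, gamma) alone; null runs reuse
# the data run's schedule by construction.
.removalSchedule <- function(M0, N0, gamma) {
  stopifnot(M0 >= 1, N0 >= 1, gamma > 0, gamma < 1)
  M <- M0
  N <- N0
  nr <- integer(0)
  nc <- integer(0)
  while (M > 0 && N > 0) {
    r <- min(M, max(1L, as.integer(round(gamma * M))))
    k <- min(N, max(1L, as.integer(round(gamma * N))))
    nr <- c(nr, r)
    nc <- c(nc, k)
    M <- M - r
    N <- N - k
  }
  cbind(rows = nr, cols = nc)
}

# Counter-based seed derivation: one master seed, deterministic per-purpose
# offsets, kept within 32-bit integer range.
.deriveSeed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + as.numeric(offset)) %% 2147483647)
}

.assertScalarFraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%g, %g]", name, lo, hi))
  invisible(x)
}

# Pooled signed matrix with NA encoded as 0 for the C++ engine.
.engineMatrix <- function(values) {
  m <- values
  m[is.na(m)] <- 0
  storage.mode(m) <- "double"
  m
}

# Rank-based AUC (Mann-Whitney / (n1*n2)); ties counted 1/2 via midranks.
.rankAuc <- function(caseScores, controlScores) {
  n1 <- length(caseScores)
  n2 <- length(controlScores)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(caseScores, controlScores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
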