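test_that("differential scores match the hand-enumerated two-case example", {
  # 2 cases both +1 at a combo, 1 control -1 there: Q = 1 - 0 = 1
  calls <- matrix(c(2L, 2L, 0L), 3, 1,
                  dimnames = list(c("d1", "d2", "x1"), "rs1"))
  ds <- GenotypeDataset(calls,
    data.frame(subject_id = rownames(calls),
               status = c("case", "case", "control")),
    data.frame(snp_id = "rs1", chrom = "1", pos_bp = 1,
               allele_major = "A", allele_minor = "B", maf = 0.4))
  cm <- expandAlleleCombinations(ds)
  sc <- differentialScores(subsetSubjects(cm, c("d1", "d2")),
                           subsetSubjects(cm, "x1"))
  # hom_minor combo: both cases +1, control -1
  expect_equal(unname(sc$Q[, "rs1_hom_minor"]), c(1, 1))
  # het: cases and control all -1, agreement on both sides cancels
  expect_equal(unname(sc$Q[, "rs1_het"]), c(0, 0))
  expect_error(differentialScores(subsetSubjects(cm, "d1"),
                                  subsetSubjects(cm, "x1")),
               "two cases")
})

test_that("differential scores agree with the brute-force oracle", {
  for (seed in 1:4) {
    pair <- randomComboPair(nCases = 8, nControls = 6, nSnps = 5,
                            seed = seed,
                            missingRate = if (seed > 2) 0.1 else 0)
    sc <- differentialScores(pair$D, pair$X)
    or <- oracle_differential_scores(comboValues(pair$D),
                                     comboValues(pair$X))
    expect_equal(unname(sc$Q), or$Q, tolerance = 1e-12)
    expect_equal(unname(sc$Qrow), or$Qrow, tolerance = 1e-12)
    expect_equal(sc$trace, or$trace, tolerance = 1e-12)
  }
})

test_that("weighted differential scores agree with the oracle", {
  pair <- randomComboPair(nCases = 7, nControls = 5, nSnps = 4, seed = 9)
  ids <- c(subjectIds(pair$D), subjectIds(pair$X))
  cov <- data.frame(U1 = rnorm(length(ids)), U2 = rnorm(length(ids)),
                    row.names = ids)
  kw <- kernelWeights(cov, 1:2, bandwidthScale = 0.7)
  sc <- differentialScores(pair$D, pair$X, weights = kw)
  or <- oracle_differential_scores(comboValues(pair$D),
                                   comboValues(pair$X),
                                   W = kernelMatrix(kw)[ids, ids])
  expect_equal(unname(sc$Q), or$Q, tolerance = 1e-12)
})

test_that("identical per-combo frequencies give near-zero expected trace", {
  traces <- vapply(1:60, function(s) {
    pair <- randomComboPair(nCases = 30, nControls = 30, nSnps = 10,
                            seed = 1000 + s)
    differentialScores(pair$D, pair$X)$trace
  }, numeric(1))
  expect_lt(abs(mean(traces)), 0.01)
})

test_that("self-copy controls differ from [D<-D] only by self-exclusion", {
  pair <- randomComboPair(nCases = 10, nControls = 10, nSnps = 4, seed = 5)
  Dv <- comboValues(pair$D)
  Xcopy <- ComboMatrix(Dv, pair$D@comboInfo)
  rownames(Xcopy@values) <- paste0("copy_", rownames(Dv))
  sc <- differentialScores(pair$D, Xcopy)
  M <- nrow(Dv)
  # [D<-X] counts the self-copy, [D<-D] excludes self: analytic difference
  or <- oracle_differential_scores(Dv, Dv)
  expect_equal(unname(sc$Q), or$Q, tolerance = 1e-12)
  expect_true(all(sc$Q <= 0 + 1e-12))  # including self always helps X side
})

test_that("half-loop trajectory equals the brute-force elimination oracle", {
  for (seed in 1:3) {
    pair <- randomComboPair(nCases = 12, nControls = 8, nSnps = 6,
                            seed = 20 + seed)
    cfg <- halfLoopConfig(gamma = 0.1, nShuffles = 2, correct = FALSE)
    traj <- halfLoop(pair$D, pair$X, NULL, cfg)
    or <- oracle_half_loop(comboValues(pair$D), comboValues(pair$X), 0.1)
    expect_equal(length(or$trace), nrow(trajectoryTable(traj)))
    expect_equal(trajectoryTable(traj)$trace, or$trace, tolerance = 1e-10)
    caseIds <- subjectIds(pair$D)
    comboIds <- comboIds(pair$D)
    for (i in seq_along(or$J)) {
      expect_identical(sort(retainedCases(traj, i - 1)),
                       sort(caseIds[or$J[[i]]]))
      expect_identical(sort(retainedCombos(traj, i - 1)),
                       sort(comboIds[or$K[[i]]]))
    }
  }
})

test_that("covariate-weighted half-loop matches the weighted oracle", {
  pair <- randomComboPair(nCases = 9, nControls = 7, nSnps = 5, seed = 31)
  ids <- c(subjectIds(pair$D), subjectIds(pair$X))
  set.seed(4)
  cov <- data.frame(U1 = rnorm(length(ids)), row.names = ids)
  cfg <- halfLoopConfig(gamma = 0.15, correct = TRUE,
                        selectedCovariates = 1, bandwidthScale = 0.8)
  traj <- halfLoop(pair$D, pair$X, cov, cfg)
  W <- kernelMatrix(kernelWeights(cov, 1, 0.8))[ids, ids]
  or <- oracle_half_loop(comboValues(pair$D), comboValues(pair$X), 0.15,
                         W = W)
  expect_equal(trajectoryTable(traj)$trace, or$trace, tolerance = 1e-10)
})

test_that("elimination schedule follows max(1, round(gamma * size))", {
  expect_equal(max(1, round((1 / 256) * 2524)), 10)  # first-pass row count
  sch <- hetloop:::.removalSchedule(2524, 6000, 1 / 256)
  expect_equal(unname(sch[1, "rows"]), 10)
  pair <- randomComboPair(nCases = 20, nControls = 10, nSnps = 8, seed = 3)
  cfg <- halfLoopConfig(gamma = 0.2, correct = FALSE)
  traj <- halfLoop(pair$D, pair$X, NULL, cfg)
  tt <- trajectoryTable(traj)
  expect_equal(diff(tt$M), -pmin(head(tt$M, -1),
                                 pmax(1, round(0.2 * head(tt$M, -1)))))
  expect_equal(diff(tt$N), -pmin(head(tt$N, -1),
                                 pmax(1, round(0.2 * head(tt$N, -1)))))
  # nesting: J(i+1) strictly inside J(i), K(i+1) within K(i)
  for (i in tt$iter[-1]) {
    expect_true(all(retainedCases(traj, i) %in% retainedCases(traj, i - 1)))
    expect_lt(length(retainedCases(traj, i)),
              length(retainedCases(traj, i - 1)))
    expect_true(all(retainedCombos(traj, i) %in%
                      retainedCombos(traj, i - 1)))
  }
})

test_that("null runs share the schedule and are seed-reproducible", {
  pair <- randomComboPair(nCases = 15, nControls = 15, nSnps = 6, seed = 8)
  cfg <- halfLoopConfig(gamma = 0.12, nShuffles = 5, seed = 42,
                        correct = FALSE)
  traj <- halfLoop(pair$D, pair$X, NULL, cfg)
  n1 <- shuffledNull(pair$D, pair$X, NULL, NULL, cfg, traj@schedule)
  n2 <- shuffledNull(pair$D, pair$X, NULL, NULL, cfg, traj@schedule)
  expect_identical(n1$traces, n2$traces)
  expect_equal(ncol(n1$traces), nrow(trajectoryTable(traj)))
  expect_false(any(is.na(n1$traces)))
})

test_that("significance machinery counts with the add-one convention", {
  set.seed(1)
  nulls <- matrix(rnorm(40), 8, 5)
  dat <- nulls[3, ]  # data identical to one null trace
  sig <- trajectorySignificance(dat, nulls)
  expect_true(all(sig$p >= 2 / 9))
  expect_gte(sig$pOverall, 2 / 9)
  expect_error(trajectorySignificance(dat[-1], nulls), "mismatch")
  # constant null column -> z forced to 0
  nulls0 <- cbind(nulls, 1)
  expect_equal(trajectorySignificance(c(dat, 1), nulls0)$z[6], 0)
})

test_that("label enrichment follows the exact hypergeometric tail", {
  pair <- randomComboPair(nCases = 20, nControls = 5, nSnps = 4, seed = 13)
  cfg <- halfLoopConfig(gamma = 0.3, correct = FALSE)
  traj <- halfLoop(pair$D, pair$X, NULL, cfg)
  lab <- setNames(rep(c(TRUE, FALSE), each = 10), subjectIds(pair$D))
  tab <- labelEnrichmentTrajectory(traj, lab)
  expect_equal(tab$p[1], 1)  # J(0) = all cases
  expect_equal(tab$ratio[1], 1)
  # 10/10 pool, 5 drawn all positive: p = C(10,5)/C(20,5)
  expect_equal(phyper(4, 10, 10, 5, lower.tail = FALSE), 252 / 15504)
  i5 <- which(tab$nPos + tab$nNeg == 5)
  if (length(i5)) {
    np <- tab$nPos[i5[1]]
    expect_equal(tab$p[i5[1]],
                 phyper(np - 1, 10, 10, 5, lower.tail = FALSE))
  }
})

test_that("scrambling preserves within-submatrix column sums", {
  pair <- randomComboPair(nCases = 12, nControls = 4, nSnps = 6, seed = 77)
  rows <- subjectIds(pair$D)[1:6]
  cols <- comboIds(pair$D)[c(2, 5, 9)]
  sc <- scrambleBicluster(pair$D, rows, cols, seed = 5)
  v0 <- comboValues(pair$D)
  v1 <- comboValues(sc)
  expect_equal(colSums(v1[rows, cols]), colSums(v0[rows, cols]))
  untouched <- setdiff(colnames(v0), cols)
  expect_identical(v1[, untouched], v0[, untouched])
  expect_identical(v1[setdiff(rownames(v0), rows), ],
                   v0[setdiff(rownames(v0), rows), ])
  # single-row selection is the identity
  one <- scrambleBicluster(pair$D, rows[1], cols, seed = 5)
  expect_identical(comboValues(one), v0)
})

test_that("control search is the half-loop with roles exchanged", {
  pair <- randomComboPair(nCases = 10, nControls = 12, nSnps = 5, seed = 55)
  cfg <- halfLoopConfig(gamma = 0.2, nShuffles = 4, seed = 9,
                        correct = FALSE)
  a <- controlSearch(pair$D, pair$X, NULL, cfg)
  b <- runHalfLoop(pair$X, pair$D, NULL, cfg)
  expect_identical(trajectoryTable(a), trajectoryTable(b))
  expect_identical(a@rowRemoveIter, b@rowRemoveIter)
  expect_identical(a@nullTraces, b@nullTraces)
  expect_identical(pOverall(a), pOverall(b))
})
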