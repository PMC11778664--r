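gwasFixture <- function(n = 400, shift = 0.2, seed = 1) {
  set.seed(seed)
  ids <- sprintf("s%04d", 1:n)
  status <- rep(c("case", "control"), each = n / 2)
  p0 <- c(0.25, 0.45, 0.35)
  calls <- sapply(seq_along(p0), function(s)
    rbinom(n, 2, p0[s] + ifelse(status == "case" & s == 1, shift, 0)))
  dimnames(calls) <- list(ids, c("hit", "null1", "null2"))
  ds <- GenotypeDataset(calls,
    data.frame(subject_id = ids, status = status),
    data.frame(snp_id = colnames(calls), chrom = "1",
               pos_bp = c(1e4, 2e6, 4e6), allele_major = "A",
               allele_minor = "B"))
  ds
}

test_that("gwas recovers a frequency-shifted SNP and flags degenerates", {
  ds <- gwasFixture(n = 2000, shift = 0.2, seed = 2)
  st <- runGwas(ds)
  expect_equal(st$n_cases[1], 1000)
  expect_gt(st$beta[st$snp_id == "hit"], 0)
  expect_lt(st$p[st$snp_id == "hit"], 1e-6)
  expect_gt(min(st$p[st$snp_id != "hit"]), 1e-4)
  # zero-variance SNP: emitted with beta 0, p 1 and a flag
  calls <- callMatrix(ds)
  calls[, "null2"] <- 1L
  ds0 <- GenotypeDataset(calls, as.data.frame(subjectInfo(ds)),
                         as.data.frame(snpInfo(ds))[1:5])
  st0 <- runGwas(ds0)
  expect_equal(st0$beta[3], 0)
  expect_equal(st0$p[3], 1)
  expect_equal(st0$flag[3], "zero_variance")
})

test_that("null SNP p-values are roughly uniform across replicates", {
  ps <- vapply(1:60, function(s) {
    ds <- gwasFixture(n = 300, shift = 0, seed = 100 + s)
    runGwas(ds)$p[2]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, punif)$p.value), 0.01)
})

test_that("bicluster gwas with all cases equals the population-wide scan", {
  ds <- gwasFixture(n = 300, seed = 9)
  a <- runGwas(ds)
  b <- runGwas(ds, caseSubset = caseIds(ds))
  expect_equal(a, b)
})

test_that("separation triggers the ridge-stabilised refit", {
  n <- 60
  ids <- sprintf("s%03d", 1:n)
  status <- rep(c("case", "control"), each = n / 2)
  calls <- cbind(sep = ifelse(status == "case", 2L, 0L))
  set.seed(1)
  calls <- cbind(calls, ok = rbinom(n, 2, 0.4))
  rownames(calls) <- ids
  ds <- GenotypeDataset(calls,
    data.frame(subject_id = ids, status = status),
    data.frame(snp_id = colnames(calls), chrom = "1", pos_bp = 1:2,
               allele_major = "A", allele_minor = "B"))
  st <- runGwas(ds)
  expect_equal(st$flag[1], "ridge")
  expect_gt(st$beta[1], 1)
  expect_true(is.finite(st$beta[1]) && is.finite(st$se[1]))
})

test_that("clumping keeps the most significant SNP per LD neighbourhood", {
  set.seed(7)
  n <- 200
  ids <- sprintf("s%03d", 1:n)
  base <- rbinom(n, 2, 0.4)
  calls <- cbind(a = base, b = base,                      # perfect LD pair
                 c = rbinom(n, 2, 0.3), d = rbinom(n, 2, 0.45))
  rownames(calls) <- ids
  ds <- GenotypeDataset(calls,
    data.frame(subject_id = ids,
               status = rep(c("case", "control"), each = n / 2)),
    data.frame(snp_id = colnames(calls), chrom = "1",
               pos_bp = c(1e5, 1e5 + 1000, 3e6, 9e6),
               allele_major = "A", allele_minor = "B"))
  st <- data.frame(snp_id = colnames(calls), chrom = "1",
                   pos_bp = c(1e5, 1e5 + 1000, 3e6, 9e6),
                   p = c(0.01, 0.001, 0.5, 0.2),
                   beta = c(0.2, 0.3, 0.1, -0.1),
                   maf = c(0.4, 0.4, 0.3, 0.45))
  surv <- clumpSnps(st, ds)
  expect_true("b" %in% surv)      # smaller p of the identical pair
  expect_false("a" %in% surv)
  expect_true(all(c("c", "d") %in% surv))
  # same pair > 500 kb apart: both survive
  st2 <- st
  st2$pos_bp[2] <- st2$pos_bp[1] + 6e5
  sn <- as.data.frame(snpInfo(ds))
  sn$pos_bp[2] <- st2$pos_bp[2]
  ds2 <- GenotypeDataset(callMatrix(ds), as.data.frame(subjectInfo(ds)),
                         sn[1:5])
  expect_setequal(clumpSnps(st2, ds2), colnames(calls))
  # maf filter removes low-frequency SNPs first
  st3 <- st
  st3$maf[3] <- 0.01
  expect_false("c" %in% clumpSnps(st3, ds))
  # independent columns all survive
  expect_setequal(clumpSnps(st[3:4, ], ds), c("c", "d"))
})

test_that("PRS scores are linear sums with mean imputation for missing", {
  ds <- gwasFixture(n = 20, seed = 3)
  st <- data.frame(snp_id = c("hit", "null1", "null2"), chrom = "1",
                   pos_bp = c(1, 2, 3), beta = c(1, -0.5, 2),
                   p = c(0.001, 0.01, 0.6), maf = 0.3)
  model <- buildPrsModel(st, threshold = 1)
  sc <- scorePrs(ds, model)
  calls <- callMatrix(ds)
  expect_equal(as.numeric(sc), unname(calls %*% c(2, 1, -0.5))[, 1] * 0 +
                 unname(calls[, "hit"] * 1 + calls[, "null1"] * -0.5 +
                          calls[, "null2"] * 2))
  # thresholding drops SNPs; empty model errors
  sc2 <- scorePrs(ds, model, threshold = 0.05)
  expect_equal(as.numeric(sc2),
               unname(calls[, "hit"] - 0.5 * calls[, "null1"]))
  expect_error(scorePrs(ds, model, threshold = 1e-9), "empty model")
  # doubling betas doubles scores (AUC invariant under monotone maps)
  model2 <- model
  model2$beta <- 2 * model2$beta
  expect_equal(as.numeric(scorePrs(ds, model2)), 2 * as.numeric(sc))
  # SNP absent from the arm contributes zero and is logged
  dsSub <- ds[snpIds(ds) != "null2", ]
  sc3 <- scorePrs(dsSub, model)
  expect_equal(attr(sc3, "missingSnps"), "null2")
  expect_equal(as.numeric(sc3),
               unname(calls[, "hit"] - 0.5 * calls[, "null1"]))
  # missing call imputed by the arm mean
  calls4 <- callMatrix(ds)
  calls4[1, "hit"] <- NA
  ds4 <- GenotypeDataset(calls4, as.data.frame(subjectInfo(ds)),
                         as.data.frame(snpInfo(ds))[1:5])
  sc4 <- scorePrs(ds4, model, threshold = 0.002)
  expect_equal(unname(sc4[1]), mean(calls4[-1, "hit"]))
})

test_that("liability conversion inverts the threshold model", {
  expect_equal(liabilityR2(0.5, 0.02), 0)
  expect_equal(liabilityR2(0.5, 0.3, P = 0.4), 0)
  # strict monotonicity on (0.5, 1)
  grid <- seq(0.52, 0.95, by = 0.043)
  r2s <- vapply(grid, liabilityR2, numeric(1), K = 0.02)
  expect_true(all(diff(r2s) > 0))
  expect_true(all(r2s >= 0 & r2s <= 1))
  # symmetric complement
  expect_equal(liabilityR2(0.3, 0.02), liabilityR2(0.7, 0.02))
  # round trip through the forward map
  for (r2 in c(0.05, 0.2, 0.5)) {
    expect_equal(liabilityR2(aucFromLiabilityR2(r2, 0.01), 0.01), r2,
                 tolerance = 1e-5)
  }
  # spot agreement with the Monte-Carlo threshold-model oracle
  for (r2 in c(0.1, 0.4)) {
    aucMc <- oracle_liability_auc(r2, K = 0.02, n = 6e5, seed = 3)
    expect_equal(aucFromLiabilityR2(r2, 0.02), aucMc, tolerance = 0.01)
    expect_equal(liabilityR2(aucMc, 0.02), r2, tolerance = 0.05)
  }
})

test_that("PRS evaluation converts AUC and respects subtype filters", {
  set.seed(4)
  n <- 200
  ids <- sprintf("s%03d", 1:n)
  status <- rep(c("case", "control"), each = n / 2)
  subtype <- ifelse(status == "case",
                    sample(c("BDI", "BDII"), n, TRUE), "unknown")
  subj <- data.frame(subject_id = ids, status = status, subtype = subtype)
  sc <- setNames(rnorm(n) + (status == "case"), ids)
  evAll <- evaluatePrs(sc, subj, prevalence = 0.02)
  expect_gt(evAll$auc, 0.6)
  expect_gt(evAll$r2, 0)
  evI <- evaluatePrs(sc, subj, subtypeFilter = "BDI", prevalence = 0.01)
  expect_equal(evI$nCases, sum(subtype == "BDI"))
  expect_equal(evI$nControls, n / 2)
  expect_error(evaluatePrs(sc, subj[subj$subtype != "BDII", ],
                           subtypeFilter = "BDII"), "BDII")
  # permuted labels give chance-level AUC and near-zero r2
  aucs <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    evaluatePrs(setNames(sample(sc), ids), subj)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("threshold sweep reports monotone SNP counts and all survivors", {
  ds <- gwasFixture(n = 400, shift = 0.25, seed = 11)
  st <- runGwas(ds)
  sw <- thresholdSweep(st, ds, ds, thresholds = c(1e-4, 0.05, 0.5, 1))
  expect_true(all(diff(sw$nSnps[order(sw$threshold)]) >= 0))
  expect_equal(max(sw$nSnps), length(clumpSnps(st, ds)))
  expect_true(all(sw$auc >= 0 & sw$auc <= 1))
})
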