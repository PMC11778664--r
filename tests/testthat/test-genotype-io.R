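test_that("write/read round-trips preserve calls, labels and map fields", {
  ds <- tinyDataset()
  for (fmt in c("dosage", "ped_map")) {
    dir <- withr::local_tempdir()
    paths <- writeGenotypes(ds, dir, fmt, prefix = "t")
    back <- if (fmt == "dosage")
      readGenotypes(paths[["genotypes"]], paths[["phenotype"]],
                    format = "dosage", snpPath = paths[["snps"]])
    else
      readGenotypes(paths[["genotypes"]], paths[["phenotype"]],
                    format = "ped_map", mapPath = paths[["map"]])
    expect_identical(unname(callMatrix(back)), unname(callMatrix(ds)),
                     info = fmt)
    expect_identical(as.data.frame(subjectInfo(back)),
                     as.data.frame(subjectInfo(ds)), info = fmt)
    sn0 <- as.data.frame(snpInfo(ds))
    sn1 <- as.data.frame(snpInfo(back))
    expect_identical(sn1[, c("snp_id", "chrom", "pos_bp")],
                     sn0[, c("snp_id", "chrom", "pos_bp")], info = fmt)
    expect_equal(sn1$maf, sn0$maf, info = fmt)
  }
})

test_that("ped parsing computes maf by allele count and validates tokens", {
  dir <- withr::local_tempdir()
  # 6 subjects, 1 SNP: allele G appears 2 of 12 times
  ped <- c("s1 s1 0 0 0 2 A A", "s2 s2 0 0 0 2 A G", "s3 s3 0 0 0 1 A A",
           "s4 s4 0 0 0 1 A G", "s5 s5 0 0 0 1 A A", "s6 s6 0 0 0 1 A A")
  writeLines(ped, file.path(dir, "x.ped"))
  writeLines("1\trs1\t0\t100", file.path(dir, "x.map"))
  ds <- readGenotypes(file.path(dir, "x.ped"), format = "ped_map")
  expect_equal(unname(snpInfo(ds)$maf), 2 / 12)
  expect_equal(snpInfo(ds)$allele_minor, "G")
  expect_equal(unname(callMatrix(ds)[, 1]), c(0, 1, 0, 1, 0, 0))
  # third allele token -> validation error
  writeLines(c(ped[-1], "s7 s7 0 0 0 1 T A"), file.path(dir, "y.ped"))
  writeLines("1\trs1\t0\t100", file.path(dir, "y.map"))
  expect_error(readGenotypes(file.path(dir, "y.ped"), format = "ped_map"),
               "more than two alleles")
  # truncated line -> error naming the line number
  writeLines(c(ped[1], "s2 s2 0 0 0 2 A"), file.path(dir, "z.ped"))
  writeLines("1\trs1\t0\t100", file.path(dir, "z.map"))
  expect_error(readGenotypes(file.path(dir, "z.ped"), format = "ped_map"),
               "line 2")
})

test_that("phenotype/genotype subject mismatches are reported", {
  dir <- withr::local_tempdir()
  ds <- tinyDataset()
  paths <- writeGenotypes(ds, dir, "dosage", prefix = "t")
  ph <- read.table(paths[["phenotype"]], header = TRUE, sep = "\t")
  ph$subject_id[1] <- "intruder"
  write.table(ph, paths[["phenotype"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(
    readGenotypes(paths[["genotypes"]], paths[["phenotype"]],
                  format = "dosage", snpPath = paths[["snps"]]),
    "mismatch.*s1.*intruder")
})

test_that("maf filter is strict, idempotent and leaves subjects alone", {
  set.seed(42)
  n <- 40
  calls <- cbind(
    rbinom(n, 2, 0.10), rbinom(n, 2, 0.30), rbinom(n, 2, 0.50))
  rownames(calls) <- sprintf("s%02d", 1:n)
  colnames(calls) <- c("low", "mid", "high")
  ds <- GenotypeDataset(calls,
    data.frame(subject_id = rownames(calls),
               status = rep(c("case", "control"), n / 2)),
    data.frame(snp_id = colnames(calls), chrom = "1", pos_bp = 1:3,
               allele_major = "A", allele_minor = "B"))
  # force exact mafs for the boundary check
  SummarizedExperiment::rowData(ds)$maf <- c(0.10, 0.30, 0.50)
  f <- filterByMaf(ds, 0.25)
  expect_identical(snpIds(f), c("mid", "high"))
  expect_identical(subjectIds(f), subjectIds(ds))
  expect_identical(snpIds(filterByMaf(f, 0.25)), snpIds(f))  # idempotent
  expect_identical(nrow(filterByMaf(ds, 0.5)), 0L)  # maf <= 0.5 always
  expect_identical(snpIds(filterByMaf(ds, 0.05)), snpIds(ds))
})

test_that("allele-combination expansion follows the signed encoding", {
  calls <- matrix(c(0L, 1L, 2L, NA), 4, 1,
                  dimnames = list(paste0("s", 1:4), "rs1"))
  ds <- GenotypeDataset(calls,
    data.frame(subject_id = rownames(calls),
               status = c("case", "case", "control", "control")),
    data.frame(snp_id = "rs1", chrom = "1", pos_bp = 1,
               allele_major = "A", allele_minor = "B", maf = 0.4))
  cm <- expandAlleleCombinations(ds)
  v <- comboValues(cm)
  expect_equal(unname(v[1, ]), c(1, -1, -1))
  expect_equal(unname(v[2, ]), c(-1, 1, -1))
  expect_equal(unname(v[3, ]), c(-1, -1, 1))
  expect_true(all(is.na(v[4, ])))
  expect_equal(comboInfo(cm)$kind, c("hom_major", "het", "hom_minor"))
})

test_that("expansion yields 3 combos per SNP, rows sum to -1, invertible", {
  pair <- randomComboPair(6, 4, 7, seed = 11)
  v <- comboValues(pair$cm)
  expect_equal(ncol(v), 3 * 7)
  expect_true(all(colSums(matrix(v[1, ], nrow = 3)) == -1))
  # exactly one +1 per subject/SNP triple -> genotype recoverable
  calls <- callMatrix(pair$ds)
  for (s in 1:7) {
    tri <- v[, (3 * s - 2):(3 * s)]
    expect_equal(unname(max.col(tri) - 1), unname(calls[, s]))
  }
})

test_that("overlap coefficient matches |A n B| / min(|A|,|B|)", {
  expect_equal(snpOverlapCoefficient(letters[1:5], letters[1:5]), 1)
  expect_equal(snpOverlapCoefficient(letters[1:5], letters[6:10]), 0)
  expect_equal(snpOverlapCoefficient(letters[1:5], letters[3:10]), 3 / 5)
  expect_error(snpOverlapCoefficient(character(0), "a"), "empty")
  # symmetry and containment => 1
  for (i in 1:5) {
    a <- sample(letters, sample(3:10, 1))
    b <- sample(letters, sample(3:10, 1))
    expect_equal(snpOverlapCoefficient(a, b), snpOverlapCoefficient(b, a))
    expect_equal(snpOverlapCoefficient(a, sample(a, 2)), 1)
  }
})

test_that("panel restriction keeps 3 combos per retained SNP in order", {
  pair <- randomComboPair(4, 3, 10, seed = 2)
  panel <- sprintf("s%03d", c(2, 5, 7, 9))
  r <- restrictToPanel(pair$D, panel)
  expect_equal(ncol(comboValues(r)), 12)
  expect_true(all(comboInfo(r)$snp_id %in% panel))
  full <- restrictToPanel(pair$D, sprintf("s%03d", 1:10))
  expect_identical(comboValues(full), comboValues(pair$D))
  expect_equal(ncol(comboValues(restrictToPanel(pair$D, character(0)))), 0)
})

test_that("gene-set and annotation readers parse the text formats", {
  dir <- withr::local_tempdir()
  writeLines(c("pwA\tdesc\tg1\tg2\tg3", "pwB\tdesc\tg2\tg4"),
             file.path(dir, "sets.gmt"))
  gmt <- readGmt(file.path(dir, "sets.gmt"))
  expect_equal(gmt$pathways$pwA, c("g1", "g2", "g3"))
  expect_setequal(gmt$universe, c("g1", "g2", "g3", "g4"))
  writeLines(c("gene_id\tsnp_id", "g1\trs1", "g1\trs2", "g2\trs3"),
             file.path(dir, "ann.tsv"))
  ann <- readGeneSnpAnnotation(file.path(dir, "ann.tsv"))
  expect_equal(nrow(ann), 3)
})
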