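# Small fixture builders used across tests.

# Random signed ComboMatrix pair with a shared combo panel. nSnps SNPs give
# 3*nSnps combos built from random genotype calls so the exactly-one-of-
# three invariant holds.
randomComboPair <- function(nCases, nControls, nSnps, seed = 1,
                            missingRate = 0) {
  set.seed(seed)
  n <- nCases + nControls
  calls <- matrix(rbinom(n * nSnps, 2, runif(nSnps, 0.25, 0.5)[
    rep(seq_len(nSnps), each = n)]), n, nSnps)
  if (missingRate > 0)
    calls[runif(length(calls)) < missingRate] <- NA
  ids <- c(sprintf("case%02d", seq_len(nCases)),
           sprintf("ctrl%02d", seq_len(nControls)))
  rownames(calls) <- ids
  colnames(calls) <- sprintf("s%03d", seq_len(nSnps))
  ds <- GenotypeDataset(
    calls,
    data.frame(subject_id = ids,
               status = rep(c("case", "control"), c(nCases, nControls)),
               stringsAsFactors = FALSE),
    data.frame(snp_id = colnames(calls), chrom = "1",
               pos_bp = seq_len(nSnps), allele_major = "A",
               allele_minor = "B", stringsAsFactors = FALSE))
  cm <- expandAlleleCombinations(ds)
  list(D = subsetSubjects(cm, ids[seq_len(nCases)]),
       X = subsetSubjects(cm, ids[nCases + seq_len(nControls)]),
       ds = ds, cm = cm)
}

# Tiny deterministic GenotypeDataset for IO tests.
tinyDataset <- function() {
  calls <- matrix(c(0L, 1L, 1L, 1L, NA, 0L), nrow = 3,
                  dimnames = list(c("s1", "s2", "s3"), c("rsA", "rsB")))
  GenotypeDataset(
    calls,
    data.frame(subject_id = c("s1", "s2", "s3"),
               status = c("case", "case", "control"),
               subtype = c("BDI", "BDII", "unknown"),
               arm_id = "arm1", stringsAsFactors = FALSE),
    data.frame(snp_id = c("rsA", "rsB"), chrom = c("1", "2"),
               pos_bp = c(1000L, 5000L), allele_major = c("A", "C"),
               allele_minor = c("G", "T"), stringsAsFactors = FALSE))
}
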