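# hetloop

Case/control genotype biclustering for genetic heterogeneity analysis.

Complex-disease case populations are often genetically heterogeneous: a
subset of cases may share a pattern of genotype states — across a subset of
SNPs — that neither the remaining cases nor the controls exhibit. `hetloop`
finds such *biclusters* directly from case/control genotype data (no
subphenotype labels required) and carries a discovered bicluster through the
downstream analyses that make it useful: replication in independent arms,
bicluster-informed polygenic risk scoring, and gene-set over-representation.

## The method in brief

Genotypes over common SNPs (maf > 0.25) are expanded into three signed
allele-combination features per SNP (homozygous major / heterozygous /
homozygous minor, encoded ±1). For case *j* and combination *k* the
differential-expression score is

> Q(j,k) = [D←D](j,k) − [D←X](j,k),

the fraction of other cases agreeing with case *j*'s state at *k* minus the
agreeing fraction of controls. The *half-loop* algorithm iteratively removes
the `max(1, round(γ·remaining))` cases and combinations with the lowest
row/column score sums (γ = 0.5⁸ by default) and records the size-normalised
trace Q̄(i); an elevated trace against a label-shuffled null ensemble —
labels permuted within covariate strata, each null run forced onto the data
run's elimination schedule — signals a bicluster, with per-iteration
z-scores and a max-z overall permutation p-value. Ancestry covariates
(genome-wide principal components, supplied as input) are corrected for by
Gaussian-kernel reweighting of the agreement fractions and by
covariate-matched shuffling.

Downstream, the retained bicluster `D[J(i), K(i)]` is summarised by its
dominant principal component; projections give every subject a
*bicluster-score* whose covariate-corrected AUC measures separation in
training and replication arms. A bicluster-informed GWAS (retained cases vs
all controls) feeds LD-clumped, p-value-thresholded polygenic risk scores,
with AUCs convertible to liability-scale R² under the threshold model.
Pathway over-representation of the genes whose allele-combinations survive
uses exact hypergeometric tails plus a permutation z̄ against the same null
ensemble.

A fully seeded synthetic-data module generates multi-arm studies with
ancestry structure, controlled cross-arm SNP-panel overlap
(default 0.85/0.50/0.30) and planted biclusters, so every stage can be
validated end to end. See the methods vignette
(`vignettes/halfloop-methods.Rmd`) for models, assumptions, parameter
choices and limitations.

## Worked example

```r
library(hetloop)

cfg <- syntheticConfig(nCases = 100, nControls = 100, nSnps = 300,
                       biclusterCaseFraction = 0.4,
                       biclusterSnpFraction = 0.25,
                       effectDelta = 0.6, ancestryLoadingSd = 0,
                       armOverlaps = 0.85, seed = 42)
arms <- generateStudy(cfg)          # arm 1 = discovery, arm 2 = replication

ds <- arms[[1]]$dataset
cm <- expandAlleleCombinations(filterByMaf(ds, 0.25))
D <- subsetSubjects(cm, caseIds(ds))
X <- subsetSubjects(cm, controlIds(ds))

traj <- runHalfLoop(D, X, cfg = halfLoopConfig(nShuffles = 32, seed = 7,
                                               correct = FALSE))
traj
#> HalfLoopTrajectory: 100 iterations, M(0) = 100 , N(0) = 882
#>   null ensemble: 32 label-shuffled trials
#>   peak z = 24.11 at iteration 56
#>   overall p = 0.03030303

pOverall(traj)                       # 1/33: the permutation-test floor
unlist(recoveryMetrics(traj, arms[[1]]$truth, peakIteration(traj)))
#> rowPrecision    rowRecall colPrecision    colRecall   rowJaccard ...
#>    0.9090909    1.0000000    0.2843137    0.9022222    0.9090909
```

The overall p-value of 1/33 is the smallest achievable with 32 label
shuffles — the trace is above every null trajectory — and at the peak-z
iteration the retained case set recovers the planted subgroup (40 of 100
cases) at row precision 0.91 and recall 1. Replication in the second arm:

```r
ds2 <- arms[[2]]$dataset
cm2 <- expandAlleleCombinations(ds2)
rep <- replicateBicluster(traj, D, X,
                          subsetSubjects(cm2, caseIds(ds2)),
                          subsetSubjects(cm2, controlIds(ds2)),
                          nPerm = 0, seed = 3)
rep$AbarPrime                        # interval-averaged replication AUC
#> [1] 0.6231909
replicationSignificance(rep, nShuffles = 99, seed = 5)$p
#> [1] 0.01
```

An interval-averaged replication AUC of 0.62 with the minimal permutation p
(1/100) says the case/control separation learned in arm 1 transfers to
fresh subjects genotyped on an 85%-overlapping SNP panel.

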