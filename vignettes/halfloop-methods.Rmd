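---
title: "Detecting genetic subgroups with covariate-corrected case/control biclustering"
author: "hetloop package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genetic subgroups with covariate-corrected case/control biclustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Complex diseases such as bipolar disorder are genetically heterogeneous:
the case population may contain a subgroup of subjects sharing a pattern of
genotype states that neither the remaining cases nor the controls exhibit.
`hetloop` searches for such subgroups — *biclusters* — directly in
case/control genotype data, without using subphenotype labels, and then
exploits a discovered bicluster downstream: out-of-sample replication
scoring, bicluster-informed polygenic risk scores (PRS), and gene-set
over-representation.

## Data representation

Genotypes are minor-allele counts (0/1/2) over common SNPs; by default the
analysis is restricted to SNPs with minor-allele frequency above 0.25
(`filterByMaf`), the regime in which subgroup signals are detectable at
realistic sample sizes. Each SNP is expanded into three binary
*allele-combinations* (homozygous major, heterozygous, homozygous minor),
encoded ±1 (`expandAlleleCombinations`). The signed encoding makes
"agreement" between two subjects at a combination symmetric in presence
and absence, which is what the loop-counting scores below measure. A
missing call yields missing values for all three combinations of that SNP
and is excluded from both numerator and denominator of every agreement
fraction.

## The half-loop algorithm

With case matrix $D$ ($M$ cases × $N$ combinations) and control matrix
$X$, the per-entry differential-expression score is

$$Q(j,k) \;=\; [D\!\leftarrow\!D](j,k) \;-\; [D\!\leftarrow\!X](j,k),$$

where $[D\!\leftarrow\!D](j,k)$ is the (weighted) fraction of *other*
cases whose ±1 state at combination $k$ agrees with case $j$'s, and
$[D\!\leftarrow\!X](j,k)$ the agreeing fraction of controls. Row scores
$Q^{\mathrm{row}}(j)=\sum_k Q(j,k)$, column scores
$Q^{\mathrm{col}}(k)=\sum_j Q(j,k)$, and the *trace*
$\bar Q = \sum_{j,k} Q(j,k)$ summarise how much case-specific structure
remains. At each iteration the algorithm removes the
$\max(1,\mathrm{round}(\gamma M))$ cases and
$\max(1,\mathrm{round}(\gamma N))$ combinations with the lowest scores
(ties broken by original index) and re-scores, until no cases remain. A
bicluster manifests as an elevated size-normalised trace $\bar Q(i)$ over
a range of iterations; the retained sets $J(i)$, $K(i)$ approximate its
rows and columns.

The default elimination fraction is $\gamma = 0.5^8 \approx 0.004$, small
enough that the elimination path is effectively converged in $\gamma$;
coarser values (e.g. $1/24$–$1/64$) are useful in unit-test-sized
problems. The removal schedule depends only on $(M_0, N_0, \gamma)$, so
label-shuffled null runs are forced onto *exactly* the data run's
schedule, making the per-iteration null distributions size-matched.

### Significance

The null hypothesis H0 is that genotype structure is independent of the
case/control labels. Null samples permute the labels (swapping rows
between $D$ and $X$) within covariate strata (k-means on the selected
covariates, `buildStrata`), preserving per-stratum class counts. Each
iteration's trace is turned into a z-score against the null ensemble;
per-iteration p-values use add-one counting. The overall p-value compares
the data's maximum-over-iterations z to the same statistic of each null
trial, z-scored leave-one-out against the remaining trials — so with $S$
shuffles the smallest achievable p is $1/(S+1)$ (default $S = 128$).

### Covariate correction

Ancestry (proxied by genome-wide principal components, supplied as input)
can generate case/control differential expression that is not
disease-related. Two mechanisms address this:

* **Kernel reweighting of the scores.** The agreement fractions weight
  reference subjects by a Gaussian kernel in covariate space,
  $w(j,s) \propto \exp(-\|c_j-c_s\|^2/2h^2)$ with
  $h = \texttt{bandwidthScale} \times$ median pairwise distance. A focal
  case is then compared to covariate-similar cases and controls, so
  structure that merely tracks covariates contributes little.
* **Covariate-matched shuffling.** Because null labels are permuted within
  covariate strata, any residual covariate-driven elevation appears in the
  null traces too and cancels in the z-scores.

At the sample sizes used in the test-suite (n ≈ 160 subjects) we stratify
at roughly ten subjects per stratum and use `bandwidthScale = 0.3`; the
package default for the stratum count, `max(1, floor(n/500))`, targets
cohort-scale data. Strata that end up single-class keep their labels fixed
(and are logged) — the extreme tails of a strong confound are exactly the
regions where no exchangeable relabelling exists. Which covariates enter
is decided by a forward likelihood-ratio selection on nested logistic
models (`selectCovariates`, α = 0.05) in the discovery arm; replication
and PRS stages use a configured evaluation set.

## Replication

For iteration $i$, the training bicluster $D[J(i), K'(i)]$ (columns
intersected with the replication arm's panel) is summarised by its
dominant principal component $v(i)$: columns are centred by their means
over $J(i)$, and both the centres and $v(i)$ are reused verbatim when
projecting replication subjects, so no replication information leaks into
the component. The stated sign rule "mean projection of the bicluster rows
non-negative" is vacuous under this centring (those projections sum to
zero by construction), so the sign is fixed by the equivalent operational
convention that training cases project above training controls on average.

Projections give each subject a scalar *bicluster-score*; covariate
correction residualises the scores on the selected covariates (ordinary
least squares with intercept) before computing a rank-based AUC with ties
counted ½. Replication strength is the average $\bar A'$ of the
replication AUC over an iteration interval — by default the maximal
contiguous run of iterations whose trace p-value is significant; in
simulation studies we additionally restrict it to the plateau retaining
20–60% of the cases, mirroring the fraction range a real discovery
interval spans. Significance of $\bar A'$ comes from label permutations
within the replication arm (components fixed).

`degradeOverlap` studies how replication decays as the shared SNP panel
shrinks. SNPs are removed uniformly *from the intersection* with the
training panel: removing uniformly from the whole replication panel leaves
the overlap coefficient $|A\cap B|/\min(|A|,|B|)$ a martingale whenever
the replication panel is the smaller one, so the literal uniform variant
cannot reach a lower target; intersection-restricted removal reaches any
target to one SNP's granularity and matches the intent of the experiment.

## Polygenic risk scores

`runGwas` fits per-SNP logistic regressions (status ~ dosage + covariates)
over a chosen case subset and all controls; the *bicluster-informed*
variant simply passes $J(i)$ as the case subset, and with all cases it is
identical to the population-wide scan. Complete separation or
non-convergence triggers a ridge-stabilised refit (penalty $10^{-3}$,
flagged); zero-variance SNPs are emitted with $\beta = 0$, $p = 1$ and a
flag. Greedy LD clumping (`clumpSnps`) uses the defaults $r^2 > 0.1$
within ±500 kb, maf ≥ 0.05, with ties on p broken by position then SNP id
(the reference tool's internal order is unspecified). Scores are
$\sum_s \beta_s \cdot \mathrm{calls}(j,s)$ over SNPs passing the p-value
threshold $\tilde p$; missing calls contribute the arm-mean call, model
SNPs absent from an arm contribute zero and are logged. Raw 0/1/2 calls
stand in for imputed dosages (imputation is out of scope), so the
info-score clump filter does not apply.

### Liability-scale conversion

Observed AUCs are converted to variance explained on the liability scale
under the standard threshold model: liability $L = g + e$ with
$\mathrm{Var}(L)=1$, $\mathrm{Var}(g)=R^2$, cases defined by
$L > \Phi^{-1}(1-K)$ for prevalence $K$ (defaults: 0.02 for the broad
phenotype, 0.01 for each subtype). `aucFromLiabilityR2` evaluates the
model-implied AUC of $g$ between cases and controls by numerical
integration, and `liabilityR2` inverts it with `uniroot`. This exact
inversion satisfies $\mathcal{R}^2(0.5)=0$, strict monotonicity, and
$\mathcal{R}^2(a)=\mathcal{R}^2(1-a)$; it is validated in the tests
against an independent Monte-Carlo simulation of the threshold model
rather than against any closed-form approximation. The sample case
fraction does not enter the AUC route; the argument is retained for
interface compatibility.

## Gene-set over-representation

A gene is *retained* at iteration $i$ when strictly more than half of its
originally annotated allele-combinations survive in $K(i)$. Per pathway,
the retained-gene overlap $\kappa(i,l)$ gets an exact hypergeometric upper
tail, and a permutation z-score against the κ values of the same
label-shuffled trajectories used for the trace (no fresh shuffles); the
interval-and-pathway average $\bar z$ gets an add-one permutation p with
leave-one-out normalisation. Gene-to-SNP annotation and pathway content
(GMT) are inputs; pathway filtering is by name pattern, not hard-coded.

## The synthetic-data generator

`syntheticConfig`/`generateArm` emulate a multi-platform case/control
study: per-SNP maf drawn uniformly from [0.25, 0.5]; genotypes
Binomial(2, p) with logit p = logit(maf) + loadings·covariates, loadings
N(0, `ancestryLoadingSd`²) per covariate and standard-normal covariates
(cases optionally mean-shifted — the confounding scenario); a planted
bicluster shifting the minor-allele probability of chosen cases × SNPs by
`effectDelta` (clipped to [0.01, 0.99]); BDI/BDII labels Bernoulli with a
higher rate inside the planted set and the complementary rate outside so
the configured marginal is preserved; replication arms with fresh subjects
and panels built from one shared master panel to hit the target overlap
coefficients (defaults 0.85/0.50/0.30) exactly to rounding; optionally a
mirror bicluster among controls and a single latent-AR(1) adjacent-SNP
correlation parameter. Generation is bit-reproducible from the config
seed; SNPs whose planted shift pushes the designated allele past 0.5 are
re-polarised to the sample minor allele, as a real pipeline would.

What the generator does *not* emulate: realistic LD block structure,
imputation uncertainty, batch effects, relatedness, rare variants, or
platform-specific missingness. Passing tests therefore demonstrate the
machinery's correctness and calibration, not performance on real cohort
data.

A note on readouts used in the test-suite: the planted signal is a
frequency shift, so its detectability grows with `effectDelta`. Around
0.6 the signature is near-deterministic (shifted probabilities 0.85–0.99)
and the z-score peaks where the bicluster is isolated, giving row
precision/recall near 1 at the peak. At weaker shifts the trace is already
elevated at iteration 0 and the z-peak occurs before any purification —
the honest behaviour of the statistic, documented rather than hidden.
Because rows and columns are eliminated at the same fractional rate, the
retained column set at the row-recovery iteration necessarily contains
several-fold more columns than were planted; column precision at that
iteration is bounded near (planted columns)/(retained columns) ≈ 0.24
under the 30% × 10% plant, and the weakly informative heterozygous
combinations of planted SNPs are typically eliminated while rows are still
mixed. Row-level recovery is the meaningful readout for this generator.

## Numerical and implementation choices

* The iteration engine is C++ (Rcpp/RcppArmadillo); uniform-weight scores
  use closed-form column statistics (O(MN) per iteration), kernel-weighted
  scores use dense matrix products. Brute-force R reimplementations serve
  as oracles in the tests (agreement to 1e-10).
* `Q(j,k)` is defined as 0 when the focal entry is missing or either
  reference set is empty at that combination.
* Traces are reported size-normalised; because null runs share the
  elimination schedule, z-scores are invariant to this choice.
* One master seed; every shuffle/draw derives its seed by a fixed counter
  scheme, so all outputs are byte-reproducible.
* Problem sizes in the test-suite: oracle checks at ≤ 25 × 20 cases ×
  15 SNPs; null calibration over 200 exchangeable replicates at
  100 + 100 subjects × 500 SNPs with 32 shuffles; recovery at
  300 + 300 × 2000 with a 30% × 10% plant; 50 confounding replicates at
  80 + 80 × 200; 20 replication and 20 PRS replicates at comparable
  sizes. These are chosen to exercise the full algorithm at meaningful
  scale while keeping a complete run of the suite in the minutes range on
  one CPU.

## Known limitations

* The kernel-reweighting correction promises the tested contract
  (covariate-driven structure suppressed at the stated settings), not
  equivalence to any particular published reweighting scheme.
* The "share" statistic counts state agreement in the ±1 encoding;
  a possession-only variant would weight rare combinations differently.
* Replication projections centre but do not standardise combo columns.
* With very strong, fully planted signals the overall p saturates at its
  permutation floor; more shuffles are the only way to sharpen it.
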