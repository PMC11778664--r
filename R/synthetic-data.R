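#' Configuration for the synthetic multi-arm genotype generator
#'
#' The generator emulates the structure of a multi-platform case/control
#' genotype study: common SNPs (maf drawn from \code{mafRange}),
#' Hardy-Weinberg genotypes whose allele frequencies follow continuous
#' ancestry covariates through per-SNP logit-scale loadings, a planted
#' bicluster (a subset of cases whose minor-allele probability is shifted
#' by \code{effectDelta} on a subset of the discovery panel's SNPs, absent
#' from controls), case subtype labels enriched inside the planted set, and
#' replication arms with fresh subjects whose SNP panels overlap the
#' discovery panel at controlled Szymkiewicz-Simpson coefficients.
#'
#' @param nCases,nControls subjects per arm
#' @param nSnps SNPs per arm panel
#' @param mafRange interval the per-SNP minor-allele frequency is drawn
#'   from; default [0.25, 0.5], the common-variant regime
#' @param nCovariates number of continuous ancestry covariates (default 2)
#' @param ancestryLoadingSd spread of per-SNP logit-scale covariate
#'   loadings (0 = no population structure)
#' @param biclusterCaseFraction,biclusterSnpFraction planted bicluster size
#'   as fractions of the cases and of the discovery panel
#' @param effectDelta allele-frequency-scale shift of the planted
#'   signature; shifted probabilities are clipped to [0.01, 0.99]
#' @param subtypeBaseFraction marginal fraction of cases labelled BDI
#' @param subtypeBiclusterFraction BDI fraction inside the planted set (the
#'   outside rate is chosen so the marginal matches
#'   \code{subtypeBaseFraction})
#' @param armOverlaps target overlap coefficients of replication-arm panels
#'   with the discovery panel (arm 1); default c(0.85, 0.50, 0.30)
#' @param controlBicluster optional list(fraction, snpFraction, effectDelta)
#'   planting a mirror bicluster in the controls
#' @param confoundShift covariate mean shift applied to cases (scalar =
#'   first covariate, or one value per covariate): makes case/control
#'   differences purely covariate-driven when \code{effectDelta = 0}
#' @param ldRho latent adjacent-SNP autocorrelation (0 = independent SNPs)
#' @param seed master seed; generation is bit-reproducible given the config
#' @return list of class \code{hetloop_simconfig}
#' @export
syntheticConfig <- function(nCases = 300, nControls = 300, nSnps = 2000,
                            mafRange = c(0.25, 0.5), nCovariates = 2,
                            ancestryLoadingSd = 0.3,
                            biclusterCaseFraction = 0.3,
                            biclusterSnpFraction = 0.1,
                            effectDelta = 0.4,
                            subtypeBaseFraction = 0.65,
                            subtypeBiclusterFraction = 0.75,
                            armOverlaps = c(0.85, 0.5, 0.3),
                            controlBicluster = NULL,
                            confoundShift = 0, ldRho = 0, seed = 1) {
  .assertScalarFraction(biclusterCaseFraction, "biclusterCaseFraction")
  .assertScalarFraction(biclusterSnpFraction, "biclusterSnpFraction")
  .assertScalarFraction(subtypeBaseFraction, "subtypeBaseFraction")
  .assertScalarFraction(subtypeBiclusterFraction, "subtypeBiclusterFraction")
  stopifnot(length(mafRange) == 2, mafRange[1] >= 0, mafRange[2] <= 0.5,
            mafRange[1] <= mafRange[2], effectDelta >= 0,
            ancestryLoadingSd >= 0, abs(ldRho) < 1)
  if (length(armOverlaps) && (any(armOverlaps <= 0) || any(armOverlaps > 1)))
    stop("arm overlap targets must lie in (0, 1]")
  structure(list(nCases = nCases, nControls = nControls, nSnps = nSnps,
                 mafRange = mafRange, nCovariates = nCovariates,
                 ancestryLoadingSd = ancestryLoadingSd,
                 biclusterCaseFraction = biclusterCaseFraction,
                 biclusterSnpFraction = biclusterSnpFraction,
                 effectDelta = effectDelta,
                 subtypeBaseFraction = subtypeBaseFraction,
                 subtypeBiclusterFraction = subtypeBiclusterFraction,
                 armOverlaps = armOverlaps,
                 controlBicluster = controlBicluster,
                 confoundShift = confoundShift, ldRho = ldRho,
                 seed = as.integer(seed)),
            class = "hetloop_simconfig")
}

# Master structure shared by all arms: SNP map, per-SNP maf and covariate
# loadings, arm panels with the target overlaps, planted SNP sets.
# Deterministic given the config (own seed stream).
.masterStructure <- function(cfg) {
  nArms <- 1L + length(cfg$armOverlaps)
  nShare <- as.integer(round(cfg$armOverlaps * cfg$nSnps))
  if (length(nShare) &&
      any(abs(nShare / cfg$nSnps - cfg$armOverlaps) > 0.01))
    stop("infeasible overlap target given the panel size")
  extra <- if (length(nShare)) max(cfg$nSnps - nShare) else 0L
  nMaster <- cfg$nSnps + extra
  set.seed(.deriveSeed(cfg$seed, 1L))
  snpIds <- sprintf("snp%06d", seq_len(nMaster))
  maf <- runif(nMaster, cfg$mafRange[1], cfg$mafRange[2])
  loadings <- matrix(rnorm(nMaster * cfg$nCovariates,
                           sd = cfg$ancestryLoadingSd),
                     nMaster, cfg$nCovariates)
  perm <- sample.int(nMaster)
  arm1 <- sort(perm[seq_len(cfg$nSnps)])
  outside <- setdiff(seq_len(nMaster), arm1)
  panels <- vector("list", nArms)
  panels[[1]] <- arm1
  for (k in seq_along(cfg$armOverlaps)) {
    shared <- sort(sample(arm1, nShare[k]))
    rest <- sort(sample(outside, cfg$nSnps - nShare[k]))
    panels[[k + 1L]] <- sort(c(shared, rest))
  }
  nPlant <- as.integer(round(cfg$biclusterSnpFraction * cfg$nSnps))
  plantedSnps <- sort(sample(arm1, nPlant))
  ctrlSnps <- integer(0)
  if (!is.null(cfg$controlBicluster)) {
    nCtrl <- as.integer(round(cfg$controlBicluster$snpFraction * cfg$nSnps))
    ctrlSnps <- sort(sample(setdiff(arm1, plantedSnps), nCtrl))
  }
  list(nArms = nArms, snpIds = snpIds, maf = maf, loadings = loadings,
       panels = panels, plantedSnps = plantedSnps, ctrlSnps = ctrlSnps,
       pos = seq_len(nMaster) * 50000L, chrom = rep("1", nMaster))
}

# Latent-AR(1) binomial genotypes: each allele copy thresholds an AR(1)
# Gaussian across adjacent SNPs, so marginals stay Binomial(2, p).
.drawCalls <- function(p, ldRho) {
  n <- nrow(p)
  S <- ncol(p)
  if (ldRho == 0)
    return(matrix(rbinom(n * S, 2L, as.vector(p)), n, S))
  q <- qnorm(p)
  calls <- matrix(0L, n, S)
  for (copy in 1:2) {
    z <- matrix(0, n, S)
    z[, 1] <- rnorm(n)
    for (s in 2:S)
      z[, s] <- ldRho * z[, s - 1] + sqrt(1 - ldRho^2) * rnorm(n)
    calls <- calls + (z < q)
  }
  calls
}

#' Generate one arm of a synthetic case/control genotype study
#'
#' Arm 1 is the discovery arm; higher indices are replication arms with
#' fresh subjects, the same planted SNP signature restricted to that arm's
#' panel, and a panel overlapping arm 1's at the configured coefficient.
#' Master-level structure (SNP map, allele frequencies, loadings, panels,
#' planted SNP set) is deterministic given the config, so arms generated
#' separately are mutually consistent.
#'
#' @param cfg a \code{\link{syntheticConfig}}
#' @param armIndex 1 for the discovery arm, 2.. for replication arms
#' @return list with \code{dataset} (a \linkS4class{GenotypeDataset}),
#'   \code{covariates} (data.frame, rows named by subject) and
#'   \code{truth} (planted case/SNP/combo ids, arm panels, covariates)
#' @export
generateArm <- function(cfg, armIndex = 1L) {
  ms <- .masterStructure(cfg)
  if (armIndex < 1 || armIndex > ms$nArms)
    stop("armIndex must be in 1..", ms$nArms)
  set.seed(.deriveSeed(cfg$seed, 100L + armIndex))
  panel <- ms$panels[[armIndex]]
  S <- length(panel)
  nCa <- cfg$nCases
  nCo <- cfg$nControls
  ids <- c(sprintf("a%d_case%04d", armIndex, seq_len(nCa)),
           sprintf("a%d_ctrl%04d", armIndex, seq_len(nCo)))
  n <- nCa + nCo
  cov <- matrix(rnorm(n * cfg$nCovariates), n, cfg$nCovariates)
  shift <- rep(0, cfg$nCovariates)
  shift[seq_along(cfg$confoundShift)] <- cfg$confoundShift
  cov[seq_len(nCa), ] <- sweep(cov[seq_len(nCa), , drop = FALSE], 2,
                               shift, "+")
  plantedCases <- sort(sample(seq_len(nCa),
                              round(cfg$biclusterCaseFraction * nCa)))
  p <- plogis(sweep(cov %*% t(ms$loadings[panel, , drop = FALSE]), 2,
                    qlogis(ms$maf[panel]), "+"))
  plantCols <- which(panel %in% ms$plantedSnps)
  if (length(plantCols) && length(plantedCases) && cfg$effectDelta > 0)
    p[plantedCases, plantCols] <-
      pmin(pmax(p[plantedCases, plantCols] + cfg$effectDelta, 0.01), 0.99)
  plantedCtrl <- integer(0)
  if (!is.null(cfg$controlBicluster)) {
    plantedCtrl <- nCa + sort(sample(seq_len(nCo),
      round(cfg$controlBicluster$fraction * nCo)))
    cCols <- which(panel %in% ms$ctrlSnps)
    if (length(cCols) && length(plantedCtrl))
      p[plantedCtrl, cCols] <- pmin(pmax(
        p[plantedCtrl, cCols] + cfg$controlBicluster$effectDelta,
        0.01), 0.99)
  }
  calls <- .drawCalls(p, cfg$ldRho)
  dimnames(calls) <- list(ids, ms$snpIds[panel])
  # subtype labels: enriched inside the planted set, marginal preserved
  fIn <- cfg$subtypeBiclusterFraction
  fc <- length(plantedCases) / nCa
  fOut <- if (fc >= 1) cfg$subtypeBaseFraction else
    min(max((cfg$subtypeBaseFraction - fc * fIn) / (1 - fc), 0), 1)
  rate <- rep(fOut, nCa)
  rate[plantedCases] <- fIn
  subtype <- ifelse(rbinom(nCa, 1, rate) == 1, "BDI", "BDII")
  subjects <- data.frame(
    subject_id = ids,
    status = rep(c("case", "control"), c(nCa, nCo)),
    subtype = c(subtype, rep("unknown", nCo)),
    arm_id = sprintf("arm%d", armIndex), stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = ms$snpIds[panel], chrom = ms$chrom[panel],
                     pos_bp = ms$pos[panel],
                     allele_major = "A", allele_minor = "B",
                     stringsAsFactors = FALSE)
  ds <- GenotypeDataset(calls, subjects, snps)
  covDf <- as.data.frame(cov)
  colnames(covDf) <- paste0("U", seq_len(cfg$nCovariates))
  rownames(covDf) <- ids
  kinds <- c("hom_major", "het", "hom_minor")
  plantedPanelSnps <- ms$snpIds[intersect(panel, ms$plantedSnps)]
  truth <- structure(list(
    plantedCaseIds = ids[plantedCases],
    plantedSnpIds = ms$snpIds[ms$plantedSnps],
    plantedComboIds = as.vector(t(outer(plantedPanelSnps, kinds,
                                        paste, sep = "_"))),
    plantedControlIds = ids[plantedCtrl],
    controlSnpIds = ms$snpIds[ms$ctrlSnps],
    armPanels = lapply(ms$panels, function(px) ms$snpIds[px]),
    covariates = covDf, armIndex = armIndex), class = "hetloop_truth")
  list(dataset = ds, covariates = covDf, truth = truth)
}

#' Generate every arm of the configured study
#'
#' @param cfg a \code{\link{syntheticConfig}}
#' @return list of per-arm results from \code{\link{generateArm}}
#' @export
generateStudy <- function(cfg) {
  ms <- .masterStructure(cfg)
  lapply(seq_len(ms$nArms), function(a) generateArm(cfg, a))
}
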