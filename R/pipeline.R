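#' Run the staged heterogeneity-analysis pipeline
#'
#' Config-driven orchestration of simulate -> discover -> replicate ->
#' prs -> enrich with one master seed. Every stage writes self-describing
#' text outputs (TSV tables plus JSON sidecars carrying the config echo and
#' seeds) under \code{outDir}; re-running with the same config reproduces
#' all numeric tables byte-for-byte.
#'
#' The config is a named list (or path to a YAML file) with entries:
#' \describe{
#'   \item{stages}{subset of c("simulate","discover","replicate","prs",
#'     "enrich"); default all}
#'   \item{simulate}{arguments for \code{\link{syntheticConfig}}}
#'   \item{arms}{alternatively, per-arm input paths: list of
#'     list(genotypes, phenotype, snps, covariates) read by
#'     \code{\link{readGenotypes}}}
#'   \item{discover}{list(gamma, nShuffles, bandwidthScale, nStrata,
#'     alpha); discovery covariates are selected by the nested-model
#'     forward test unless \code{discoveryCovariates} is given}
#'   \item{evaluationCovariates}{covariate columns for replication/PRS AUC
#'     correction (default: the discovery selection)}
#'   \item{interval}{c(lo, hi) iteration interval; default auto-selected}
#'   \item{prs}{list(thresholds, r2Threshold, windowBp, mafThreshold,
#'     prevalence)}
#'   \item{enrich}{list(gmt, annotation): file paths for gene sets and the
#'     gene-to-SNP table}
#'   \item{seed}{master seed}
#' }
#'
#' @param config named list or YAML file path
#' @param outDir output directory
#' @param seed optional master-seed override
#' @return invisibly, a list with the per-stage in-memory results
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed)) config$seed <- 1L
  stages <- config$stages %||%
    c("simulate", "discover", "replicate", "prs", "enrich")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.configEcho(config), file.path(outDir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  state <- list(config = config)

  if ("simulate" %in% stages) {
    simArgs <- config$simulate %||% list()
    simArgs$seed <- config$seed
    cfg <- do.call(syntheticConfig, simArgs)
    arms <- generateStudy(cfg)
    for (a in seq_along(arms)) {
      writeGenotypes(arms[[a]]$dataset, outDir, "dosage",
                     prefix = sprintf("arm%d", a))
      covOut <- data.frame(subject_id = rownames(arms[[a]]$covariates),
                           arms[[a]]$covariates)
      write.table(covOut,
                  file.path(outDir, sprintf("arm%d.covariates.tsv", a)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    tr <- arms[[1]]$truth
    jsonlite::write_json(
      list(plantedCaseIds = tr$plantedCaseIds,
           plantedSnpIds = tr$plantedSnpIds,
           plantedComboIds = tr$plantedComboIds),
      file.path(outDir, "truth.json"), auto_unbox = FALSE)
    state$arms <- arms
  } else if (!is.null(config$arms)) {
    state$arms <- lapply(config$arms, function(a) {
      ds <- readGenotypes(a$genotypes, a$phenotype, format = "dosage",
                          snpPath = a$snps)
      list(dataset = ds,
           covariates = if (!is.null(a$covariates))
             readCovariateTable(a$covariates) else NULL)
    })
  }
  if (!length(stages[stages != "simulate"])) return(invisible(state))
  if (is.null(state$arms)) stop("no arms available: simulate or supply paths")

  arm1 <- state$arms[[1]]
  if (!length(caseIds(arm1$dataset)))
    stop("discovery arm contains zero cases")
  dcfg <- config$discover %||% list()
  ds1 <- filterByMaf(arm1$dataset, dcfg$mafThreshold %||% 0.25)
  cm1 <- expandAlleleCombinations(ds1)
  D1 <- subsetSubjects(cm1, caseIds(ds1))
  X1 <- subsetSubjects(cm1, controlIds(ds1))
  cov1 <- arm1$covariates
  selDisc <- config$discoveryCovariates %||%
    (if (!is.null(cov1)) selectCovariates(ds1, cov1,
                                          dcfg$alpha %||% 0.05)
     else integer(0))
  selEval <- config$evaluationCovariates %||% selDisc
  hcfg <- halfLoopConfig(
    gamma = dcfg$gamma %||% 0.5^8,
    nShuffles = dcfg$nShuffles %||% 128L,
    seed = .deriveSeed(config$seed, 11L),
    correct = length(selDisc) > 0,
    selectedCovariates = selDisc,
    bandwidthScale = dcfg$bandwidthScale %||% 1,
    nStrata = dcfg$nStrata)

  if ("discover" %in% stages) {
    traj <- runHalfLoop(D1, X1, cov1, hcfg)
    tab <- trajectoryTable(traj)
    write.table(tab, file.path(outDir, "trajectory.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(traj@nullTraces, file.path(outDir, "null_traces.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    pk <- peakIteration(traj)
    writeLines(retainedCases(traj, pk),
               file.path(outDir, "retained_cases.txt"))
    writeLines(retainedCombos(traj, pk),
               file.path(outDir, "retained_combos.txt"))
    jsonlite::write_json(
      list(pOverall = pOverall(traj), peakIteration = pk,
           selectedCovariates = selDisc, seed = config$seed),
      file.path(outDir, "discovery.json"), auto_unbox = TRUE)
    state$trajectory <- traj
    state$selected <- list(discovery = selDisc, evaluation = selEval)
  }

  if ("replicate" %in% stages && length(state$arms) >= 2) {
    traj <- state$trajectory
    if (is.null(traj)) stop("replicate stage requires discover")
    arm2 <- state$arms[[2]]
    ds2 <- arm2$dataset
    cm2 <- expandAlleleCombinations(ds2)
    interval <- if (!is.null(config$interval))
      seq(config$interval[1], config$interval[2]) else NULL
    rep <- replicateBicluster(
      traj, D1, X1,
      subsetSubjects(cm2, caseIds(ds2)),
      subsetSubjects(cm2, controlIds(ds2)),
      trainCov = cov1, repCov = arm2$covariates, selected = selEval,
      interval = interval, seed = .deriveSeed(config$seed, 21L))
    sig <- replicationSignificance(
      rep, nShuffles = dcfg$nShuffles %||% 128L,
      seed = .deriveSeed(config$seed, 22L))
    write.table(rep$table, file.path(outDir, "replication.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(AbarPrime = rep$AbarPrime, p = sig$p,
           interval = range(rep$interval)),
      file.path(outDir, "replication.json"), auto_unbox = TRUE)
    state$replication <- rep
    state$replicationP <- sig$p
  }

  if ("prs" %in% stages && length(state$arms) >= 2) {
    traj <- state$trajectory
    if (is.null(traj)) stop("prs stage requires discover")
    pcfg <- config$prs %||% list()
    arm2 <- state$arms[[2]]
    pk <- peakIteration(traj)
    Jpk <- retainedCases(traj, pk)
    statsWide <- runGwas(ds1, cov = cov1, selected = selEval)
    statsBicl <- runGwas(ds1, caseSubset = Jpk, cov = cov1,
                         selected = selEval)
    sweepArgs <- list(refDs = ds1, armDs = arm2$dataset,
                      armCov = arm2$covariates, selected = selEval,
                      prevalence = pcfg$prevalence %||% 0.02,
                      r2Threshold = pcfg$r2Threshold %||% 0.1,
                      windowBp = pcfg$windowBp %||% 5e5,
                      mafThreshold = pcfg$mafThreshold %||% 0.05)
    if (!is.null(pcfg$thresholds)) sweepArgs$thresholds <- pcfg$thresholds
    curves <- rbind(
      do.call(thresholdSweep, c(list(stats = statsWide,
                                     provenance = "wide"), sweepArgs)),
      do.call(thresholdSweep,
              c(list(stats = statsBicl,
                     provenance = sprintf("bicluster(i=%d)", pk)),
                sweepArgs)))
    write.table(curves, file.path(outDir, "prs_curves.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    state$prs <- curves
  }

  if ("enrich" %in% stages && !is.null(config$enrich)) {
    traj <- state$trajectory
    if (is.null(traj)) stop("enrich stage requires discover")
    gmt <- readGmt(config$enrich$gmt)
    annTab <- readGeneSnpAnnotation(config$enrich$annotation)
    ann <- buildComboAnnotation(annTab, D1)
    pk <- peakIteration(traj)
    interval <- if (!is.null(config$interval))
      seq(config$interval[1], config$interval[2]) else pk
    interval <- intersect(interval, trajectoryTable(traj)$iter)
    enr <- permutationEnrichment(traj, ann, gmt$pathways, interval)
    write.table(enr$table, file.path(outDir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(zBar = enr$zBar, p = enr$p),
                         file.path(outDir, "enrichment.json"),
                         auto_unbox = TRUE)
    state$enrichment <- enr
  }
  invisible(state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.configEcho <- function(config) {
  config$package <- as.character(utils::packageVersion("hetloop"))
  config
}
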