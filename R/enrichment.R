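#' Restrict a gene-to-SNP annotation to an analysis combo panel
#'
#' Expands each gene's SNPs to their three allele-combinations and records,
#' per gene, which combos exist in the panel. Genes with no annotated combo
#' in the panel are excluded with a warning.
#'
#' @param annotation data.frame (gene_id, snp_id) from
#'   \code{\link{readGeneSnpAnnotation}}
#' @param cm the analysis \linkS4class{ComboMatrix} (defines the panel)
#' @return named list, gene_id -> character vector of panel combo_ids, with
#'   attribute \code{originalCounts}
#' @export
buildComboAnnotation <- function(annotation, cm) {
  kinds <- c("hom_major", "het", "hom_minor")
  panel <- comboIds(cm)
  genes <- split(annotation$snp_id, annotation$gene_id)
  ann <- lapply(genes, function(snps) {
    combos <- as.vector(t(outer(unique(snps), kinds, paste, sep = "_")))
    intersect(combos, panel)
  })
  empty <- lengths(ann) == 0
  if (any(empty))
    warning(sum(empty), " gene(s) with no annotated combos in the panel ",
            "were excluded")
  ann <- ann[!empty]
  attr(ann, "originalCounts") <- lengths(ann)
  ann
}

#' Genes retained by a surviving combo set
#'
#' A gene is retained at iteration i when strictly more than half of its
#' originally annotated allele-combinations survive in K(i).
#'
#' @param survivingCombos combo ids in K(i)
#' @param annotation panel annotation from
#'   \code{\link{buildComboAnnotation}}
#' @return character vector of retained gene ids
#' @export
retainedGenes <- function(survivingCombos, annotation) {
  orig <- attr(annotation, "originalCounts")
  keep <- vapply(seq_along(annotation), function(g) {
    sum(annotation[[g]] %in% survivingCombos) > 0.5 * orig[g]
  }, logical(1))
  names(annotation)[keep]
}

#' Hypergeometric over-representation p-value
#'
#' Upper tail P[X >= k] for X ~ Hypergeometric(universe, pathway, draws):
#' the chance of at least k pathway genes among the selected genes when
#' selecting at random from the universe.
#'
#' @param k observed overlap count
#' @param nSelected number of selected genes
#' @param nPathway pathway size within the universe
#' @param nUniverse universe size
#' @return p-value in (0, 1]
#' @export
overrepresentationP <- function(k, nSelected, nPathway, nUniverse) {
  if (k > min(nSelected, nPathway) || min(nSelected, nPathway) > nUniverse ||
      k < 0 || nPathway > nUniverse || nSelected > nUniverse)
    stop("inconsistent counts")
  phyper(k - 1, nPathway, nUniverse - nPathway, nSelected,
         lower.tail = FALSE)
}

#' Permutation-calibrated pathway enrichment along a trajectory
#'
#' For each iteration i of the interval and each pathway, counts the
#' retained genes kappa(i, l) = |G(i) n pathway| for the data run and for
#' every label-shuffled null trajectory (the same ensemble used for the
#' trace significance), z-scores the data count against the null
#' distribution, and averages z over the interval and pathways. The
#' overall p-value compares that average to the leave-one-out null
#' averages (add-one counting). Hypergeometric p-values for the data
#' counts are reported alongside.
#'
#' @param traj a \linkS4class{HalfLoopTrajectory} with a null ensemble
#' @param annotation panel annotation from
#'   \code{\link{buildComboAnnotation}}
#' @param pathways named list of gene-id vectors (e.g. from
#'   \code{\link{readGmt}})
#' @param interval iterations over which to average
#' @param universe gene universe (default: all annotated genes)
#' @return list of class \code{hetloop_enrichment}: per-iteration/pathway
#'   table, \code{zBar}, \code{p}
#' @export
permutationEnrichment <- function(traj, annotation, pathways, interval,
                                  universe = names(annotation)) {
  it <- traj@iterations$iter
  if (!all(interval %in% it)) stop("interval outside trajectory")
  if (!nrow(traj@nullColRemove))
    stop("trajectory carries no null ensemble (use runHalfLoop)")
  S <- nrow(traj@nullColRemove)
  comboIds <- names(traj@colRemoveIter)
  pw <- lapply(pathways, intersect, y = universe)
  nU <- length(universe)
  genesAt <- function(colRemove, i) {
    surv <- comboIds[colRemove == 0L | colRemove > i]
    retainedGenes(surv, annotation)
  }
  rows <- list()
  zMat <- matrix(NA_real_, length(interval), length(pw))
  nullK <- array(NA_real_, c(S, length(interval), length(pw)))
  for (w in seq_along(interval)) {
    i <- interval[w]
    G <- genesAt(traj@colRemoveIter, i)
    nullG <- lapply(seq_len(S), function(t)
      genesAt(traj@nullColRemove[t, ], i))
    for (l in seq_along(pw)) {
      k <- length(intersect(G, pw[[l]]))
      kn <- vapply(nullG, function(g) length(intersect(g, pw[[l]])),
                   numeric(1))
      nullK[, w, l] <- kn
      mu <- mean(kn)
      sg <- sd(kn)
      z <- if (sg > 0) (k - mu) / sg else 0
      zMat[w, l] <- z
      rows[[length(rows) + 1L]] <- data.frame(
        iter = i, pathway = names(pw)[l], kappa = k,
        pHyper = overrepresentationP(k, length(G), length(pw[[l]]), nU),
        z = z, stringsAsFactors = FALSE)
    }
  }
  zBar <- mean(zMat)
  # leave-one-out null averages of the same statistic
  nullZBar <- vapply(seq_len(S), function(t) {
    rest <- nullK[-t, , , drop = FALSE]
    mu <- apply(rest, c(2, 3), mean)
    sg <- apply(rest, c(2, 3), sd)
    zt <- ifelse(sg > 0, (nullK[t, , ] - mu) / sg, 0)
    mean(zt)
  }, numeric(1))
  p <- (1 + sum(nullZBar >= zBar)) / (1 + S)
  structure(list(table = do.call(rbind, rows), zBar = zBar, p = p,
                 nullZBar = nullZBar),
            class = "hetloop_enrichment")
}
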