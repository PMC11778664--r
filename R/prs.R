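#' Per-SNP case/control association scan (GWAS summary statistics)
#'
#' Logistic regression of case status on the minor-allele count plus an
#' intercept and the selected covariates, over the supplied case subset and
#' all controls. The bicluster-informed variant passes the retained case
#' set J(i) as \code{caseSubset}; with all cases it reduces to the
#' population-wide scan. Complete separation or non-convergence triggers a
#' ridge-stabilised refit (penalty 1e-3) flagged per SNP; zero-variance
#' SNPs are emitted with beta 0, p 1 and a flag.
#'
#' @param ds a \linkS4class{GenotypeDataset}
#' @param caseSubset case subject ids to contrast (default: all cases)
#' @param cov covariate table or NULL
#' @param selected covariate column indices
#' @return data.frame: snp_id, chrom, pos_bp, effect_allele, beta, se, p,
#'   maf, n_cases, flag
#' @export
runGwas <- function(ds, caseSubset = NULL, cov = NULL, selected = NULL) {
  si <- subjectInfo(ds)
  if (is.null(caseSubset)) caseSubset <- caseIds(ds)
  if (!length(caseSubset)) stop("empty case subset")
  keep <- si$subject_id %in% caseSubset | si$status == "control"
  ids <- si$subject_id[keep]
  y <- as.integer(si$status[keep] == "case")
  if (!any(y == 0)) stop("no controls present")
  calls <- callMatrix(ds)[ids, , drop = FALSE]
  C <- if (!is.null(cov) && length(selected))
    as.matrix(.alignCovariates(cov, ids))[, selected, drop = FALSE] else
    matrix(0, length(ids), 0)
  sn <- as.data.frame(snpInfo(ds))
  res <- lapply(seq_len(ncol(calls)), function(s) {
    x <- calls[, s]
    ok <- !is.na(x)
    if (sum(ok) < ncol(C) + 3 || length(unique(x[ok])) < 2)
      return(data.frame(beta = 0, se = NA_real_, p = 1,
                        flag = "zero_variance"))
    X <- cbind(1, x[ok], C[ok, , drop = FALSE])
    fit <- suppressWarnings(glm.fit(X, y[ok], family = binomial()))
    cf <- fit$coefficients
    covm <- try(chol2inv(qr.R(structure(fit$qr, class = "qr"))),
                silent = TRUE)
    se <- if (inherits(covm, "try-error")) NA_real_ else sqrt(covm[2, 2])
    bad <- !fit$converged || anyNA(cf) || abs(cf[2]) > 15 ||
      !is.finite(se) || se > 100
    if (bad) {
      rf <- .ridgeLogistic(X, y[ok], lambda = 1e-3)
      return(data.frame(beta = rf$beta[2], se = rf$se[2],
                        p = 2 * pnorm(-abs(rf$beta[2] / rf$se[2])),
                        flag = "ridge"))
    }
    data.frame(beta = cf[2], se = se,
               p = 2 * pnorm(-abs(cf[2] / se)), flag = "")
  })
  out <- do.call(rbind, res)
  data.frame(snp_id = sn$snp_id, chrom = sn$chrom, pos_bp = sn$pos_bp,
             effect_allele = sn$allele_minor, beta = out$beta, se = out$se,
             p = pmax(out$p, .Machine$double.xmin), maf = sn$maf,
             n_cases = sum(y == 1), flag = out$flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Ridge-penalised logistic regression via IRLS; penalty on all terms
# except the intercept. Used as a separation-robust fallback.
.ridgeLogistic <- function(X, y, lambda = 1e-3, maxIter = 100) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (i in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X * w, X) + pen
    bNew <- drop(solve(A, crossprod(X * w, z)))
    if (max(abs(bNew - beta)) < 1e-8) {
      beta <- bNew
      break
    }
    beta <- bNew
  }
  Ainv <- solve(A)
  list(beta = beta, se = sqrt(diag(Ainv)))
}

#' Greedy LD clumping of GWAS summary statistics
#'
#' After dropping SNPs below the maf threshold, repeatedly claims the most
#' significant unclaimed SNP as an index (ties by position then snp_id) and
#' removes unclaimed SNPs on the same chromosome within the window whose
#' squared Pearson correlation of minor-allele counts with the index
#' (computed in the supplied reference genotypes) exceeds the r2 threshold.
#'
#' @param stats summary statistics from \code{\link{runGwas}}
#' @param ds reference \linkS4class{GenotypeDataset} for LD
#' @param r2Threshold squared-correlation threshold (default 0.1)
#' @param windowBp genomic window radius in bp (default 500000)
#' @param mafThreshold minimum maf (default 0.05)
#' @return character vector of surviving snp_ids in claim order
#' @export
clumpSnps <- function(stats, ds, r2Threshold = 0.1, windowBp = 5e5,
                      mafThreshold = 0.05) {
  st <- stats[stats$maf >= mafThreshold, , drop = FALSE]
  if (!nrow(st)) return(character(0))
  ord <- order(st$p, st$pos_bp, st$snp_id)
  st <- st[ord, , drop = FALSE]
  calls <- callMatrix(ds)
  claimed <- character(0)
  alive <- rep(TRUE, nrow(st))
  for (i in seq_len(nrow(st))) {
    if (!alive[i]) next
    alive[i] <- FALSE
    claimed <- c(claimed, st$snp_id[i])
    near <- which(alive & st$chrom == st$chrom[i] &
                    abs(st$pos_bp - st$pos_bp[i]) <= windowBp)
    if (!length(near)) next
    x <- calls[, st$snp_id[i]]
    r2 <- vapply(near, function(j) {
      r <- suppressWarnings(cor(x, calls[, st$snp_id[j]],
                                use = "pairwise.complete.obs"))
      if (is.na(r)) 0 else r^2
    }, numeric(1))
    alive[near[r2 > r2Threshold]] <- FALSE
  }
  claimed
}

#' Assemble a polygenic-score model from clumped summary statistics
#'
#' @param stats summary statistics from \code{\link{runGwas}}
#' @param survivors clump survivors from \code{\link{clumpSnps}} (default:
#'   all stats SNPs in p order)
#' @param threshold p-value threshold applied at scoring time
#' @param provenance label, e.g. "wide" or "bicluster(i=200)"
#' @return list of class \code{hetloop_prs}: snp_id, beta, p, threshold,
#'   provenance
#' @export
buildPrsModel <- function(stats, survivors = NULL, threshold = 1,
                          provenance = "wide") {
  if (is.null(survivors))
    survivors <- stats$snp_id[order(stats$p, stats$pos_bp, stats$snp_id)]
  idx <- match(survivors, stats$snp_id)
  stopifnot(!anyNA(idx))
  structure(list(snp_id = stats$snp_id[idx], beta = stats$beta[idx],
                 p = stats$p[idx], threshold = threshold,
                 provenance = provenance),
            class = "hetloop_prs")
}

#' Score subjects with a polygenic-score model
#'
#' score_j = sum over model SNPs with p <= threshold of beta * calls(j, s).
#' Missing calls contribute the arm-mean call of the SNP; model SNPs absent
#' from the arm contribute 0 and are recorded in the \code{missingSnps}
#' attribute.
#'
#' @param ds target \linkS4class{GenotypeDataset}
#' @param model a \code{hetloop_prs}
#' @param threshold override of the model's p-value threshold
#' @return named numeric vector of per-subject scores
#' @export
scorePrs <- function(ds, model, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$threshold
  keep <- model$p <= threshold
  if (!any(keep)) stop("empty model after thresholding at ", threshold)
  snp <- model$snp_id[keep]
  beta <- model$beta[keep]
  present <- snp %in% snpIds(ds)
  calls <- callMatrix(ds)[, snp[present], drop = FALSE]
  if (anyNA(calls)) {
    mu <- colMeans(calls, na.rm = TRUE)
    for (k in which(colSums(is.na(calls)) > 0))
      calls[is.na(calls[, k]), k] <- mu[k]
  }
  scores <- drop(calls %*% beta[present])
  attr(scores, "missingSnps") <- snp[!present]
  attr(scores, "nSnps") <- sum(present)
  scores
}

#' Exact AUC of the liability-threshold model
#'
#' Forward map used by \code{\link{liabilityR2}}: with liability
#' L = g + e (Var L = 1, Var g = r2), cases defined by L above the
#' prevalence-K threshold, the AUC separating case from control values of g
#' is computed by numerical integration of the bivariate-normal threshold
#' model.
#'
#' @param r2 liability variance explained, in [0, 1]
#' @param K disease prevalence in (0, 1)
#' @return the AUC in [0.5, 1]
#' @export
aucFromLiabilityR2 <- function(r2, K) {
  stopifnot(r2 >= 0, r2 <= 1, K > 0, K < 1)
  if (r2 == 0) return(0.5)
  if (r2 >= 1 - 1e-12) return(1)
  t <- qnorm(1 - K)
  cc <- sqrt(r2 / (2 * (1 - r2)))
  inner <- Vectorize(function(l1)
    integrate(function(l2) pnorm(cc * (l1 - l2)) * dnorm(l2),
              -Inf, t, rel.tol = 1e-9)$value * dnorm(l1))
  A <- integrate(inner, t, Inf, rel.tol = 1e-8)$value
  A / (K * (1 - K))
}

#' Liability-scale variance explained from an observed AUC
#'
#' Inverts the liability-threshold forward map
#' \code{\link{aucFromLiabilityR2}}: returns the r2 on the liability scale
#' whose model-implied AUC equals the observed one, given prevalence K.
#' AUC values below 0.5 are mapped through their complement (score
#' negation leaves the variance explained unchanged). The sample case
#' fraction \code{P} is accepted for interface compatibility; the
#' AUC-based route is invariant to it.
#'
#' @param auc observed covariate-corrected AUC in [0, 1]
#' @param K disease prevalence in (0, 1)
#' @param P sample case fraction (unused by the AUC route)
#' @return liability-scale R2 in [0, 1]
#' @export
liabilityR2 <- function(auc, K, P = NULL) {
  stopifnot(auc >= 0, auc <= 1, K > 0, K < 1)
  a <- max(auc, 1 - auc)
  if (abs(a - 0.5) < 1e-12) return(0)
  if (a >= 1 - 1e-10) return(1)
  uniroot(function(r2) aucFromLiabilityR2(r2, K) - a,
          lower = 1e-12, upper = 1 - 1e-9, tol = 1e-9)$root
}

#' Covariate-corrected, optionally subtype-restricted PRS evaluation
#'
#' @param scores per-subject scores from \code{\link{scorePrs}}
#' @param subjects phenotype table (subject_id, status, subtype) or a
#'   \linkS4class{GenotypeDataset}
#' @param cov covariate table or NULL
#' @param selected covariate column indices
#' @param subtypeFilter "all", "BDI" or "BDII": restrict the cases compared
#'   against all controls
#' @param prevalence disease prevalence K for the liability conversion
#' @return list with auc, r2 (liability scale), nCases, nControls, nSnps
#' @export
evaluatePrs <- function(scores, subjects, cov = NULL, selected = NULL,
                        subtypeFilter = c("all", "BDI", "BDII"),
                        prevalence = 0.02) {
  subtypeFilter <- match.arg(subtypeFilter)
  if (is(subjects, "GenotypeDataset"))
    subjects <- as.data.frame(subjectInfo(subjects))
  nSnps <- attr(scores, "nSnps")
  scores <- scores[names(scores) %in% subjects$subject_id]
  subjects <- subjects[match(names(scores), subjects$subject_id), ]
  isCase <- subjects$status == "case"
  if (subtypeFilter != "all")
    isCase <- isCase & subjects$subtype == subtypeFilter
  isCtrl <- subjects$status == "control"
  if (!any(isCase))
    stop("no cases left after subtype filter '", subtypeFilter, "'")
  a <- correctedAuc(scores[isCase], scores[isCtrl], cov, selected)$auc
  list(auc = a,
       r2 = liabilityR2(a, prevalence,
                        P = sum(isCase) / (sum(isCase) + sum(isCtrl))),
       nCases = sum(isCase), nControls = sum(isCtrl),
       nSnps = nSnps)
}

#' AUC / liability-R2 curve across p-value thresholds
#'
#' Evaluates a clumped PRS model on a target arm across a grid of p-value
#' thresholds, reporting the number of SNPs used at each.
#'
#' @param stats summary statistics (training arm)
#' @param refDs LD reference \linkS4class{GenotypeDataset} (training arm)
#' @param armDs evaluation arm \linkS4class{GenotypeDataset}
#' @param armCov evaluation-arm covariates or NULL
#' @param selected covariate column indices
#' @param thresholds p-value grid (default log-spaced up to 1)
#' @param subtypeFilter passed to \code{\link{evaluatePrs}}
#' @param prevalence liability prevalence K
#' @param provenance model label carried into the output
#' @param ... passed to \code{\link{clumpSnps}}
#' @return data.frame: provenance, threshold, nSnps, auc, r2
#' @export
thresholdSweep <- function(stats, refDs, armDs, armCov = NULL,
                           selected = NULL,
                           thresholds = c(1e-4, 1e-3, 0.01, 0.05, 0.1,
                                          0.2, 0.5, 1),
                           subtypeFilter = "all", prevalence = 0.02,
                           provenance = "wide", ...) {
  survivors <- clumpSnps(stats, refDs, ...)
  model <- buildPrsModel(stats, survivors, threshold = 1,
                         provenance = provenance)
  rows <- lapply(thresholds, function(pt) {
    if (!any(model$p <= pt)) return(NULL)
    sc <- scorePrs(armDs, model, threshold = pt)
    ev <- evaluatePrs(sc, armDs, armCov, selected,
                      subtypeFilter = subtypeFilter,
                      prevalence = prevalence)
    data.frame(provenance = provenance, threshold = pt, nSnps = ev$nSnps,
               auc = ev$auc, r2 = ev$r2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
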