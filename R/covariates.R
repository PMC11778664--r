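#' Forward selection of case/control-associated covariates
#'
#' Candidates are tested in column order by a likelihood-ratio test of the
#' nested logistic models status ~ selected + candidate versus
#' status ~ selected; a candidate is added when its test is significant at
#' \code{alpha}. Typical use: selecting which genome-wide principal
#' components to correct for in the discovery arm.
#'
#' @param ds a \linkS4class{GenotypeDataset} (supplies case/control status)
#' @param cov covariate data.frame/matrix, rows aligned to (and named by)
#'   the subjects of \code{ds}
#' @param alpha significance level for inclusion (default 0.05)
#' @return integer vector of selected covariate column indices
#' @export
selectCovariates <- function(ds, cov, alpha = 0.05) {
  cov <- .alignCovariates(cov, subjectIds(ds))
  if (!all(is.finite(as.matrix(cov)))) stop("non-finite covariates")
  y <- as.integer(subjectInfo(ds)$status == "case")
  if (sum(y) < 2 || sum(1 - y) < 2)
    stop("need at least two subjects per class")
  selected <- integer(0)
  if (!ncol(cov)) return(selected)
  for (k in seq_len(ncol(cov))) {
    x0 <- cbind(1, as.matrix(cov)[, selected, drop = FALSE])
    x1 <- cbind(x0, as.matrix(cov)[, k])
    f0 <- glm.fit(x0, y, family = binomial())
    f1 <- glm.fit(x1, y, family = binomial())
    p <- pchisq(f0$deviance - f1$deviance, df = 1, lower.tail = FALSE)
    if (!is.na(p) && p < alpha) selected <- c(selected, k)
  }
  selected
}

#' Partition subjects into covariate-space strata
#'
#' k-means on the standardised selected covariate columns. Used to restrict
#' label shuffling to subjects that are mutually close in covariate space.
#'
#' @param cov covariate data.frame/matrix with subject rownames
#' @param selected covariate column indices (empty = single stratum)
#' @param nStrata number of strata; default \code{max(1, floor(n/500))}
#' @param seed RNG seed for the k-means initialisation
#' @return list with \code{stratum} (named integer vector) and
#'   \code{counts} (per-stratum subject counts)
#' @export
buildStrata <- function(cov, selected = seq_len(ncol(cov)),
                        nStrata = NULL, seed = 1) {
  n <- nrow(cov)
  if (is.null(nStrata)) nStrata <- max(1L, floor(n / 500))
  if (nStrata < 1) stop("nStrata must be >= 1")
  if (nStrata > n) stop("more strata than subjects")
  ids <- rownames(cov)
  if (nStrata == 1 || !length(selected)) {
    stratum <- setNames(rep(1L, n), ids)
  } else {
    x <- scale(as.matrix(cov)[, selected, drop = FALSE])
    x[, !is.finite(colSums(x))] <- 0   # constant columns scale to NaN
    set.seed(seed)
    km <- kmeans(x, centers = nStrata, nstart = 5, iter.max = 50)
    stratum <- setNames(as.integer(km$cluster), ids)
  }
  list(stratum = stratum, counts = table(stratum))
}

#' Gaussian kernel weights over covariate space
#'
#' Builds a pairwise weight provider used to covariate-correct the half-loop
#' differential-expression scores: the contribution of reference subject s
#' to focal subject j is proportional to exp(-||c_j - c_s||^2 / (2 h^2)),
#' with bandwidth h = \code{bandwidthScale} times the median pairwise
#' distance over the selected covariates. An infinite \code{bandwidthScale}
#' or an empty selection yields uniform weights (no correction).
#'
#' @param cov covariate data.frame/matrix with subject rownames
#' @param selected covariate column indices
#' @param bandwidthScale positive bandwidth multiplier (default 1)
#' @return an object of class \code{hetloop_kernel}; see
#'   \code{\link{kernelMatrix}} and \code{\link{pairWeights}}
#' @export
kernelWeights <- function(cov, selected = seq_len(ncol(cov)),
                          bandwidthScale = 1) {
  if (!is.infinite(bandwidthScale) && bandwidthScale <= 0)
    stop("bandwidthScale must be positive")
  ids <- rownames(cov)
  uniform <- !length(selected) || is.infinite(bandwidthScale)
  x <- if (uniform) matrix(0, nrow(cov), 0) else
    as.matrix(cov)[, selected, drop = FALSE]
  h <- NA_real_
  if (!uniform) {
    dd <- as.vector(dist(x))
    h <- bandwidthScale * median(dd)
    if (!is.finite(h) || h <= 0) uniform <- TRUE
  }
  structure(list(ids = ids, x = x, h = h, uniform = uniform),
            class = "hetloop_kernel")
}

#' Full kernel matrix of a weight provider
#'
#' Unnormalised kernel values with a zero diagonal (self-exclusion); the
#' engine normalises per focal subject over each reference set. Returns
#' \code{NULL} for a uniform provider.
#'
#' @param kw a \code{hetloop_kernel} from \code{\link{kernelWeights}}
#' @return numeric matrix (subjects x subjects) or NULL
#' @export
kernelMatrix <- function(kw) {
  stopifnot(inherits(kw, "hetloop_kernel"))
  if (kw$uniform) return(NULL)
  d2 <- as.matrix(dist(kw$x))^2
  W <- exp(-d2 / (2 * kw$h^2))
  diag(W) <- 0
  dimnames(W) <- list(kw$ids, kw$ids)
  W
}

#' Normalised weights of a focal subject over a reference set
#'
#' @param kw a \code{hetloop_kernel}
#' @param focal a subject id
#' @param reference non-empty vector of reference subject ids
#' @return weights summing to 1 over the reference set (self excluded)
#' @export
pairWeights <- function(kw, focal, reference) {
  stopifnot(inherits(kw, "hetloop_kernel"))
  if (!length(reference)) stop("empty reference set")
  if (kw$uniform) {
    w <- as.numeric(reference != focal)
    if (sum(w) == 0) stop("reference set empty after self-exclusion")
    return(setNames(w / sum(w), reference))
  }
  fi <- match(focal, kw$ids)
  ri <- match(reference, kw$ids)
  if (anyNA(c(fi, ri))) stop("unknown subject id")
  d2 <- colSums((t(kw$x[ri, , drop = FALSE]) - kw$x[fi, ])^2)
  w <- exp(-d2 / (2 * kw$h^2))
  w[reference == focal] <- 0   # self-exclusion
  if (sum(w) <= 0) stop("degenerate weights (all zero)")
  setNames(w / sum(w), reference)
}

#' Residualise scores on selected covariates
#'
#' Ordinary least squares of the scores on an intercept plus the selected
#' covariate columns, fitted over all supplied subjects jointly; returns the
#' residuals. This is the mechanism behind the covariate-corrected AUC.
#'
#' @param scores named numeric vector of per-subject scores
#' @param cov covariate data.frame/matrix with subject rownames
#' @param selected covariate column indices (empty = centre only)
#' @return residual scores, same names and order as \code{scores}
#' @export
residualize <- function(scores, cov, selected = seq_len(ncol(cov))) {
  cov <- .alignCovariates(cov, names(scores))
  X <- cbind(1, as.matrix(cov)[, selected, drop = FALSE])
  if (length(scores) < ncol(X) + 1)
    stop("need at least |selected| + 2 subjects")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate design")
  fit <- lm.fit(X, scores)
  setNames(fit$residuals, names(scores))
}

.alignCovariates <- function(cov, ids) {
  cov <- as.data.frame(cov)
  if (is.null(rownames(cov)) || is.null(ids))
    stop("covariates and subjects must both carry subject ids")
  miss <- setdiff(ids, rownames(cov))
  if (length(miss))
    stop("covariates missing for subjects: ",
         paste(head(miss, 5), collapse = ", "))
  cov[ids, , drop = FALSE]
}
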