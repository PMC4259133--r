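## Model selection by cross-validated partial likelihood: the held-out
## contribution of fold f is l(beta_(-f)) - l_(-f)(beta_(-f)), the
## difference between the full-data and the training-data partial
## log-likelihoods at the coefficients fitted without the fold. CVPL is
## the mean contribution over folds and is maximized.

# fold assignment; redraws until every training complement and every
# held-out fold contains at least one event
.make_folds <- function(status, k) {
  n <- length(status)
  if (k < 2L || k > n) stop("need 2 <= k <= n folds", call. = FALSE)
  for (try in 1:100) {
    f <- sample(rep_len(seq_len(k), n))
    ev <- vapply(seq_len(k), function(i) sum(status[f == i]), 0L)
    if (all(sum(status) - ev >= 1L)) {
      if (try > 1L) message("fold assignment redrawn (", try - 1L,
                            " draw(s) left a fold without events)")
      return(f)
    }
  }
  stop("could not build folds with events in every training set",
       call. = FALSE)
}

# eta = X beta exploiting sparsity of beta
.eta_sparse <- function(X, beta) {
  nz <- which(beta != 0)
  if (!length(nz)) return(rep(0, nrow(X)))
  drop(X[, nz, drop = FALSE] %*% beta[nz])
}

# held-out contribution of one fold at fixed (original-scale) beta
.cvpl_contrib <- function(data, holdout, beta) {
  eta <- .eta_sparse(data@covariates, beta)
  lAll <- .partial_loglik_eta(data@time, data@status, eta)
  tr <- setdiff(seq_len(nSubjects(data)), holdout)
  lTrain <- .partial_loglik_eta(data@time[tr], data@status[tr], eta[tr])
  lAll - lTrain
}

#' Cross-validated partial likelihood of a fitting rule
#'
#' Splits the data into \code{k} folds; for each fold the rule is fitted
#' on the complement and the fold's contribution \eqn{l(\hat\beta_{(-f)})
#' - l_{(-f)}(\hat\beta_{(-f)})} to the full-data partial likelihood is
#' recorded. The mean contribution is returned; larger is better.
#' \code{k = n} gives the per-subject leave-one-out form.
#'
#' @param data a [SurvivalData-class].
#' @param fit either a fixed coefficient vector (evaluated as-is on every
#'   fold), or \code{function(trainData)} returning a coefficient vector
#'   on the original covariate scale.
#' @param k number of folds (default 5).
#' @param folds optional explicit fold assignment (integer vector in
#'   \code{1..k}).
#' @return mean held-out log partial-likelihood contribution.
#' @export
cvpl <- function(data, fit, k = 5L, folds = NULL) {
  stopifnot(is(data, "SurvivalData"))
  if (is.null(folds)) folds <- .make_folds(data@status, k)
  k <- max(folds)
  contrib <- vapply(seq_len(k), function(f) {
    hold <- which(folds == f)
    beta <- if (is.function(fit)) fit(data[-hold]) else as.numeric(fit)
    .cvpl_contrib(data, hold, beta)
  }, 0)
  mean(contrib)
}

# candidate path positions: the points where the active-set size
# changes, thinned evenly to at most maxCandidates; terminal point
# always kept
.candidate_v <- function(path, maxCandidates = 100L) {
  if (!length(path@v)) return(numeric(0))
  chg <- which(diff(c(0L, path@nnz)) != 0L)
  vv <- sort(unique(c(path@v[chg],
                      path@v[length(path@v)])))
  if (length(vv) > maxCandidates)
    vv <- vv[unique(round(seq(1, length(vv), length.out = maxCandidates)))]
  vv
}

#' Select the shrinkage parameter and path point by CVPL
#'
#' Fits the full-data coefficient path for every candidate shrinkage
#' parameter, then refits on each cross-validation training set and scores
#' every candidate path point by its mean held-out partial-likelihood
#' contribution. The exhaustive (a, v) maximizer is returned, read off the
#' full-data path; ties are broken toward sparser models, then smaller a,
#' then smaller v. Candidate positions are the points of the full-data
#' path where the active set changes, capped at \code{maxCandidates} per
#' a.
#'
#' @param data a [SurvivalData-class].
#' @param aValues shrinkage-parameter grid inside (1, 2).
#' @param k number of CV folds.
#' @param control a [PathControl-class] for all path fits.
#' @param maxCandidates cap on evaluated path points per a.
#' @param seed optional integer; fixes fold assignment for
#'   reproducibility.
#' @return a [HarmonicCoxFit-class].
#' @examples
#' scn <- simScenario(n = 80, p = 15, beta = c(1.2, -1.2, rep(0, 13)))
#' d <- makeDataset(scn, seed = 7)
#' fit <- selectModel(d, aValues = c(1.3, 1.7), k = 3,
#'                    control = pathControl(maxInnerSteps = 400,
#'                                          maxOuterIters = 2), seed = 1)
#' which(coef(fit) != 0)
#' @export
selectModel <- function(data, aValues = c(1.1, 1.3, 1.5, 1.7, 1.9),
                        k = 5L, control = pathControl(),
                        maxCandidates = 100L, seed = NULL) {
  stopifnot(is(data, "SurvivalData"))
  for (a in aValues) .check_a(a)
  folds <- .with_seed(seed, .make_folds(data@status, k))
  k <- max(folds)
  n <- nSubjects(data)

  std <- .standardize(data)
  approx0 <- quadraticApprox(std$data, rep(0, nFeatures(data)),
                             hessian = control@hessian)
  fullPaths <- lapply(aValues, function(a)
    .fit_path(std, a, control, approx0 = approx0))
  names(fullPaths) <- as.character(aValues)
  cand <- lapply(fullPaths, .candidate_v, maxCandidates = maxCandidates)
  vMaxA <- vapply(cand, function(v) if (length(v)) max(v) else 0, 0)

  # per fold: one standardization + shared beta=0 expansion, then one
  # capped path per a; contributions evaluated at every candidate point
  contrib <- lapply(seq_along(aValues), function(ia)
    matrix(0, length(cand[[ia]]), k))
  for (f in seq_len(k)) {
    hold <- which(folds == f)
    dtr <- data[-hold]
    stdf <- .standardize(dtr)
    approx0f <- quadraticApprox(stdf$data, rep(0, nFeatures(dtr)),
                                hessian = control@hessian)
    for (ia in seq_along(aValues)) {
      if (!length(cand[[ia]])) next
      pf <- .fit_path(stdf, aValues[ia], control, vMax = vMaxA[ia],
                      approx0 = approx0f)
      B <- pathCoef(pf, cand[[ia]])
      for (j in seq_along(cand[[ia]]))
        contrib[[ia]][j, f] <- .cvpl_contrib(data, hold, B[, j])
    }
  }

  grid <- do.call(rbind, lapply(seq_along(aValues), function(ia) {
    vv <- cand[[ia]]
    if (!length(vv))
      return(data.frame(a = numeric(0), v = numeric(0), nnz = integer(0),
                        cvpl = numeric(0)))
    B <- pathCoef(fullPaths[[ia]], vv)
    data.frame(a = aValues[ia], v = vv, nnz = colSums(B != 0),
               cvpl = rowMeans(contrib[[ia]]))
  }))
  if (!nrow(grid))
    stop("no candidate path points; paths were empty", call. = FALSE)

  best <- order(-grid$cvpl, grid$nnz, grid$a, grid$v)[1]
  aStar <- grid$a[best]
  vStar <- grid$v[best]
  betaStar <- drop(pathCoef(fullPaths[[as.character(aStar)]], vStar))
  new("HarmonicCoxFit", beta = betaStar, a = aStar, v = vStar,
      cvpl = grid$cvpl[best], path = fullPaths[[as.character(aStar)]],
      grid = grid)
}

#' @describeIn selectModel coefficients of the selected model (original
#'   covariate scale).
#' @param object a \code{HarmonicCoxFit}.
#' @param ... ignored.
#' @export
setMethod("coef", "HarmonicCoxFit", function(object, ...) object@beta)

setMethod("show", "HarmonicCoxFit", function(object) {
  cat("HarmonicCoxFit: a =", object@a, ", path point v =", object@v, "\n")
  cat("  selected variables:", sum(object@beta != 0), "of",
      length(object@beta), "\n")
  cat("  CVPL:", format(object@cvpl), "\n")
})

#' Write a CVPL selection report as delimited text
#'
#' @param fit a [HarmonicCoxFit-class].
#' @param file output path.
#' @export
writeSelectionReport <- function(fit, file) {
  utils::write.table(fit@grid, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
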