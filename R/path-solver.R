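#' Solver control for the generalized path-seeking algorithm
#'
#' @param deltaV path step increment on standardized covariates.
#' @param tauTol convergence tolerance on \eqn{\max_j|\tau_j|}; the printed
#'   termination condition "all \eqn{\tau_j = 0}" is unattainable with
#'   finite steps, so the inner loop stops when every ratio falls below
#'   this tolerance.
#' @param maxInnerSteps cap on single-coordinate moves per inner loop.
#' @param maxOuterIters cap on relinearizations of the partial likelihood.
#' @param outerTol relative change in the terminal coefficient vector below
#'   which the outer loop is declared converged.
#' @param relinearizeEvery relinearize after this many inner steps even if
#'   the inner loop has not reached \code{tauTol} (\code{Inf} = only when
#'   the inner loop terminates).
#' @param hessian \code{"full"} n x n partial-likelihood curvature, or
#'   \code{"diag"} for its diagonal approximation.
#' @return a [PathControl-class].
#' @export
pathControl <- function(deltaV = 0.01, tauTol = 1e-4,
                        maxInnerSteps = 20000L, maxOuterIters = 20L,
                        outerTol = 1e-4, relinearizeEvery = Inf,
                        hessian = c("full", "diag")) {
  new("PathControl", deltaV = deltaV, tauTol = tauTol,
      maxInnerSteps = as.integer(maxInnerSteps),
      maxOuterIters = as.integer(maxOuterIters),
      outerTol = outerTol, relinearizeEvery = relinearizeEvery,
      hessian = match.arg(hessian))
}

#' Wrap a plain least-squares problem as a QuadraticApprox
#'
#' Identity-curvature seam (\eqn{M = I}, so \eqn{\hat X = X},
#' \eqn{\hat y = y}): lets the path solver run on an ordinary squared-error
#' problem, which is how its behaviour is checked against known lasso /
#' forward-stagewise paths.
#'
#' @param X design matrix.
#' @param y response vector.
#' @return a [QuadraticApprox-class].
#' @export
leastSquaresApprox <- function(X, y) {
  X <- as.matrix(X)
  new("QuadraticApprox", xhat = X, yhat = as.numeric(y),
      eta = rep(0, nrow(X)), X = X, M = diag(nrow(X)), z = as.numeric(y))
}

#' Gradient-to-penalty-slope ratios
#'
#' \eqn{\tau_j = g_j / p_j} with \eqn{g_j = (1/n)\sum_i (\hat y_i -
#' \hat x_i \beta)\hat x_{ij}} (the negative working-loss gradient) and
#' \eqn{p_j = P'(|\beta_j|)} the harmonic penalty slope. The coordinate
#' with the largest \eqn{|\tau_j|} is the one the path moves next.
#'
#' @param approx a [QuadraticApprox-class].
#' @param beta current coefficients (on the approx's design scale).
#' @param a shrinkage parameter in (1, 2).
#' @return numeric vector \eqn{\tau} of length p.
#' @export
computeTau <- function(approx, beta, a) {
  stopifnot(is(approx, "QuadraticApprox"))
  a <- .as_a(a)
  beta <- as.numeric(beta)
  n <- nrow(approx@X)
  r <- approx@z - drop(approx@X %*% beta)
  g <- drop(crossprod(approx@X, approx@M %*% r)) / n
  g / penaltyDerivative(abs(beta), a)
}

# package an inner-loop result (list from the C++ kernel) as a path object
.as_path <- function(res, p, a, center, scale, nm, converged, outerIters) {
  new("CoefficientPath",
      v = as.numeric(res$v), coord = as.integer(res$coord),
      value = as.numeric(res$value), nnz = as.integer(res$nnz),
      p = as.integer(p), a = a, center = center, scale = scale,
      featureNames = nm, converged = converged,
      outerIters = as.integer(outerIters))
}

#' One inner path-seeking pass on a fixed quadratic approximation
#'
#' Runs the single-coordinate loop: compute \eqn{\tau}, identify the
#' sign-mismatch set \eqn{S = \{j : \tau_j \beta_j < 0\}}, move the
#' largest-\eqn{|\tau|} coordinate (within \eqn{S} if nonempty) by
#' \eqn{\Delta v\,\mathrm{sign}(\tau)}, clamping moves that would cross
#' zero onto zero, until \eqn{\max_j|\tau_j| \le} \code{tauTol} or the
#' step cap. The design in \code{approx} is used as-is (no
#' standardization).
#'
#' @param approx a [QuadraticApprox-class].
#' @param beta0 starting coefficients (default all zero).
#' @param a shrinkage parameter in (1, 2).
#' @param control a [PathControl-class].
#' @return a [CoefficientPath-class]; its \code{converged} slot reports
#'   whether the tau tolerance was reached (a cap hit leaves it
#'   \code{FALSE} with a warning).
#' @export
gpsInnerPath <- function(approx, beta0 = NULL, a = 1.5,
                         control = pathControl()) {
  stopifnot(is(approx, "QuadraticApprox"), is(control, "PathControl"))
  a <- .as_a(a)
  p <- ncol(approx@X)
  if (is.null(beta0)) beta0 <- rep(0, p)
  res <- .gps_inner_cpp(approx@X, approx@M, approx@z, as.numeric(beta0), a,
                        control@deltaV, control@tauTol,
                        control@maxInnerSteps, 0, Inf)
  if (!res$converged)
    warning("inner path stopped at the step cap before reaching tauTol",
            call. = FALSE)
  nm <- colnames(approx@X)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  .as_path(res, p, a, rep(0, p), rep(1, p), nm, res$converged, 1L)
}

#' Fit the harmonic-regularized Cox coefficient path
#'
#' The full solver: covariates are centered and scaled to unit variance,
#' the partial likelihood is expanded to a working least-squares problem
#' at the current coefficients, the path-seeking inner loop is run on it,
#' and the expansion is refreshed at the inner terminus until the terminal
#' coefficients stabilize. The recorded path concatenates all inner loops
#' with the path position \eqn{v} increasing throughout; regularization
#' strength is the position along this path (no explicit tuning
#' multiplier), and [selectModel()] picks the point by cross-validated
#' partial likelihood.
#'
#' @param data a [SurvivalData-class].
#' @param a shrinkage parameter in (1, 2).
#' @param control a [PathControl-class].
#' @param vMax optional cap on total path length.
#' @return a [CoefficientPath-class]; coefficients extracted from it
#'   ([pathCoef()], [stats::coef()]) are on the original covariate scale.
#' @examples
#' scn <- simScenario(n = 60, p = 10, beta = c(1.5, rep(0, 9)))
#' d <- makeDataset(scn, seed = 1)
#' path <- harmonicCoxPath(d, a = 1.5,
#'                         control = pathControl(maxInnerSteps = 500,
#'                                               maxOuterIters = 2))
#' path
#' @export
harmonicCoxPath <- function(data, a = 1.5, control = pathControl(),
                            vMax = Inf) {
  stopifnot(is(data, "SurvivalData"))
  std <- .standardize(data)
  .fit_path(std, a, control, vMax = vMax)
}

# center/scale covariates; zero-variance columns get scale 1 (they can
# never be selected: their working gradient is identically zero)
.standardize <- function(data) {
  X <- data@covariates
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  list(data = survivalData(Xs, data@time, data@status),
       center = ctr, scale = scl, names = colnames(X))
}

# outer loop on an already-standardized dataset; approx0 lets callers share
# the beta = 0 expansion (it does not depend on a)
.fit_path <- function(std, a, control, vMax = Inf, approx0 = NULL) {
  a <- .as_a(a)
  dstd <- std$data
  p <- nFeatures(dstd)
  beta <- rep(0, p)
  v <- 0
  acc <- list(v = numeric(0), coord = integer(0), value = numeric(0),
              nnz = integer(0))
  innerCap <- as.integer(min(control@maxInnerSteps, control@relinearizeEvery,
                             .Machine$integer.max))
  converged <- FALSE
  halted <- FALSE
  k <- 0L
  while (k < control@maxOuterIters) {
    qa <- if (k == 0L && !is.null(approx0)) approx0
          else quadraticApprox(dstd, beta, hessian = control@hessian)
    res <- .gps_inner_cpp(qa@X, qa@M, qa@z, beta, a, control@deltaV,
                          control@tauTol, innerCap, v, vMax)
    acc$v <- c(acc$v, res$v); acc$coord <- c(acc$coord, res$coord)
    acc$value <- c(acc$value, res$value); acc$nnz <- c(acc$nnz, res$nnz)
    newbeta <- res$beta
    v <- res$vEnd
    k <- k + 1L
    eta <- drop(dstd@covariates %*% newbeta)
    if (max(abs(eta)) > 30) {
      warning("linear predictor diverging (|eta| > 30); path halted",
              call. = FALSE)
      beta <- newbeta
      halted <- TRUE
      break
    }
    relchg <- sqrt(sum((newbeta - beta)^2)) / max(1, sqrt(sum(beta^2)))
    beta <- newbeta
    if (res$converged && relchg < control@outerTol) { converged <- TRUE; break }
    if (v >= vMax) break
  }
  .as_path(acc, p, a, std$center, std$scale, std$names,
           converged && !halted, k)
}

#' Reconstruct coefficients at points along a path
#'
#' @param path a [CoefficientPath-class].
#' @param v numeric vector of path positions; for each, the coefficients
#'   after the last recorded move at position \code{<= v} are returned
#'   (all zero for \code{v} before the first move).
#' @return matrix with one column per requested position, rows named by
#'   feature, on the original covariate scale.
#' @export
pathCoef <- function(path, v) {
  stopifnot(is(path, "CoefficientPath"))
  v <- as.numeric(v)
  ord <- order(v)
  beta <- rep(0, path@p)
  out <- matrix(0, path@p, length(v),
                dimnames = list(path@featureNames, NULL))
  s <- 1L
  nstep <- length(path@v)
  for (i in ord) {
    while (s <= nstep && path@v[s] <= v[i]) {
      beta[path@coord[s]] <- path@value[s]
      s <- s + 1L
    }
    out[, i] <- beta / path@scale
  }
  out
}

#' @describeIn pathCoef terminal coefficients of the path (original scale).
#' @param object a \code{CoefficientPath}.
#' @param ... ignored.
#' @export
setMethod("coef", "CoefficientPath", function(object, ...) {
  if (!length(object@v)) {
    b <- rep(0, object@p)
    names(b) <- object@featureNames
    return(b)
  }
  drop(pathCoef(object, max(object@v)))
})

#' @describeIn pathCoef data.frame of recorded moves
#'   (v, coordinate, new value, active-set size).
#' @export
pathStates <- function(path) {
  data.frame(v = path@v, coord = path@coord, value = path@value,
             nnz = path@nnz)
}

setMethod("show", "CoefficientPath", function(object) {
  cat("CoefficientPath: a =", object@a, "|", length(object@v), "moves,",
      object@outerIters, "relinearization(s)\n")
  if (length(object@v)) {
    cat("  v range: [0,", format(max(object@v)), "], terminal nnz:",
        object@nnz[length(object@nnz)], "of", object@p, "\n")
  }
  cat("  converged:", object@converged, "\n")
})

#' Export a coefficient path as delimited text
#'
#' One row per recorded path point: position, active-set size, and the
#' nonzero coefficients sparsely encoded as \code{index:value} pairs.
#'
#' @param path a [CoefficientPath-class].
#' @param file output path.
#' @param every keep every \code{every}-th recorded point (thins large
#'   paths).
#' @export
writePath <- function(path, file, every = 1L) {
  idx <- seq(1L, length(path@v), by = every)
  B <- pathCoef(path, path@v[idx])
  rows <- vapply(seq_along(idx), function(i) {
    nz <- which(B[, i] != 0)
    paste(path@v[idx[i]], path@nnz[idx[i]],
          paste(sprintf("%d:%.6g", nz, B[nz, i]), collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(c("v\tnnz\tcoefficients", rows), file)
  invisible(file)
}

#' Read solver control from a flat key=value file
#'
#' Lines of the form \code{key=value}; keys matching [pathControl()]
#' arguments override its defaults. Blank lines and \code{#} comments are
#' ignored.
#'
#' @param file path to the config file.
#' @return a [PathControl-class].
#' @export
readPathControl <- function(file) {
  ln <- trimws(readLines(file))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  args <- list()
  for (i in seq_along(keys)) {
    if (keys[i] == "hessian") args[[keys[i]]] <- vals[i]
    else args[[keys[i]]] <- as.numeric(vals[i])
  }
  bad <- setdiff(names(args), names(formals(pathControl)))
  if (length(bad))
    stop("unknown control key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pathControl, args)
}
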