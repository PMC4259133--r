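#' @import methods
NULL

#' Survival dataset with high-dimensional covariates
#'
#' Container for right-censored survival data: an \code{n x p} covariate
#' matrix together with observed times and event indicators. This is the
#' universal input to the fitting, selection and evaluation functions.
#'
#' @slot covariates numeric matrix, subjects in rows, features in columns.
#' @slot time numeric vector of observed times, strictly positive.
#' @slot status integer vector, 1 = event observed, 0 = right-censored.
#'
#' @seealso [survivalData()], [readSurvivalData()]
#' @export
setClass("SurvivalData",
  representation(covariates = "matrix", time = "numeric", status = "integer"))

setValidity("SurvivalData", function(object) {
  msg <- character()
  n <- nrow(object@covariates)
  if (n < 2L) msg <- c(msg, "need at least 2 subjects")
  if (length(object@time) != n || length(object@status) != n)
    msg <- c(msg, "time/status length must match nrow(covariates)")
  if (anyNA(object@covariates) || anyNA(object@time) || anyNA(object@status))
    msg <- c(msg, "missing values are not allowed")
  if (any(object@time <= 0)) msg <- c(msg, "all times must be strictly positive")
  if (!all(object@status %in% c(0L, 1L)))
    msg <- c(msg, "status must be 0 (censored) or 1 (event)")
  if (sum(object@status) < 1L)
    msg <- c(msg, "at least one event is required (partial likelihood degenerate)")
  if (length(msg)) msg else TRUE
})

#' The harmonic penalty family
#'
#' The concave penalty \eqn{P(b) = \sqrt{q\,b + c^2} - c} on coefficient
#' magnitudes \eqn{b = |\beta_j|}, with \eqn{q = 2/(a(a-1))} and
#' \eqn{c = (2-a)/(a-1)}, indexed by a shrinkage parameter
#' \eqn{a \in (1, 2)}. As \eqn{a \to 1} the penalty approaches \eqn{|b|}
#' (lasso); as \eqn{a \to 2} it approaches \eqn{\sqrt{b}} (L1/2). Its
#' derivative is finite at the origin, which is what makes direct path
#' seeking applicable.
#'
#' @slot a numeric scalar, the shrinkage parameter, strictly inside (1, 2).
#'
#' @seealso [harmonicPenalty()], [penaltyValue()], [penaltyDerivative()]
#' @export
setClass("HarmonicPenalty", representation(a = "numeric"))

setValidity("HarmonicPenalty", function(object) {
  a <- object@a
  if (length(a) != 1L || !is.finite(a)) return("a must be a finite scalar")
  if (a <= 1 || a >= 2) return("a must lie strictly inside (1, 2)")
  TRUE
})

#' Working least-squares approximation of the Cox partial likelihood
#'
#' Second-order expansion of the negative partial log-likelihood in the
#' linear-predictor space, packaged as a least-squares problem
#' \eqn{\|\hat y - \hat X \beta\|^2} with \eqn{\hat y = C z},
#' \eqn{\hat X = C X}, \eqn{z = \eta + A^- \mu} and \eqn{C^T C = A + \epsilon I}.
#'
#' @slot xhat transformed design matrix \eqn{C X}.
#' @slot yhat working response \eqn{C z}.
#' @slot eta linear predictor at the expansion point.
#' @slot X original (standardized) design used to build the expansion.
#' @slot M the jittered Hessian \eqn{A + \epsilon I} (equals \eqn{C^T C}).
#' @slot z working response in \eqn{\eta}-space.
#'
#' @seealso [quadraticApprox()]
#' @export
setClass("QuadraticApprox",
  representation(xhat = "matrix", yhat = "numeric", eta = "numeric",
                 X = "matrix", M = "matrix", z = "numeric"))

#' Per-subject predicted survival step functions
#'
#' Right-continuous step functions \eqn{S(t|x_i)}: value 1 before the first
#' knot, then \code{surv[i, k]} on \code{[times[k], times[k+1])}. Produced
#' by [predictSurvival()] from a Breslow baseline; consumed by the Brier
#' score machinery.
#'
#' @slot times increasing knot times (the training event times).
#' @slot surv n x length(times) matrix of survival probabilities.
#'
#' @seealso [predictSurvival()], [survAt()], [brierScore()]
#' @export
setClass("PredictedSurvival",
  representation(times = "numeric", surv = "matrix"))

setValidity("PredictedSurvival", function(object) {
  msg <- character()
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (ncol(object@surv) != length(object@times))
    msg <- c(msg, "ncol(surv) must equal length(times)")
  if (any(object@surv < 0 | object@surv > 1))
    msg <- c(msg, "survival probabilities must be in [0, 1]")
  if (ncol(object@surv) > 1 &&
      any(object@surv[, -1, drop = FALSE] >
          object@surv[, -ncol(object@surv), drop = FALSE] + 1e-12))
    msg <- c(msg, "survival curves must be nonincreasing")
  if (length(msg)) msg else TRUE
})

#' Control parameters for the path-seeking solver
#'
#' @slot deltaV step increment along the path (on standardized covariates).
#' @slot tauTol stopping tolerance on \eqn{\max_j |\tau_j|}.
#' @slot maxInnerSteps cap on steps per inner path-seeking loop.
#' @slot maxOuterIters cap on outer relinearizations.
#' @slot outerTol relative change in terminal coefficients declaring outer
#'   convergence.
#' @slot relinearizeEvery optional: relinearize after this many inner steps
#'   even if the inner loop has not terminated (\code{Inf} = never).
#' @slot hessian \code{"full"} (the n x n partial-likelihood Hessian) or
#'   \code{"diag"} (its diagonal approximation).
#'
#' @seealso [pathControl()]
#' @export
setClass("PathControl",
  representation(deltaV = "numeric", tauTol = "numeric",
                 maxInnerSteps = "integer", maxOuterIters = "integer",
                 outerTol = "numeric", relinearizeEvery = "numeric",
                 hessian = "character"))

setValidity("PathControl", function(object) {
  msg <- character()
  if (object@deltaV <= 0) msg <- c(msg, "deltaV must be positive")
  if (object@tauTol <= 0) msg <- c(msg, "tauTol must be positive")
  if (object@maxInnerSteps < 1L) msg <- c(msg, "maxInnerSteps must be >= 1")
  if (object@maxOuterIters < 1L) msg <- c(msg, "maxOuterIters must be >= 1")
  if (object@outerTol <= 0) msg <- c(msg, "outerTol must be positive")
  if (!object@hessian %in% c("full", "diag"))
    msg <- c(msg, "hessian must be 'full' or 'diag'")
  if (length(msg)) msg else TRUE
})

#' A coefficient path from the path-seeking solver
#'
#' The path is stored compactly as the sequence of single-coordinate moves:
#' at path position \code{v[s]} coordinate \code{coord[s]} was set to
#' \code{value[s]} (standardized scale); all other coordinates are carried
#' forward. [pathCoef()] reconstructs full coefficient vectors on the
#' original covariate scale.
#'
#' @slot v path positions, strictly increasing, one per recorded move.
#' @slot coord coordinate moved at each step.
#' @slot value new (standardized-scale) value of that coordinate.
#' @slot nnz number of nonzero coefficients after each step.
#' @slot p number of covariates.
#' @slot a shrinkage parameter the path was built with.
#' @slot center,scale standardization applied to the covariates.
#' @slot featureNames column names of the design.
#' @slot converged logical: did the final inner loop reach the tau tolerance?
#' @slot outerIters number of relinearizations performed.
#'
#' @seealso [harmonicCoxPath()], [gpsInnerPath()], [pathCoef()]
#' @export
setClass("CoefficientPath",
  representation(v = "numeric", coord = "integer", value = "numeric",
                 nnz = "integer", p = "integer", a = "numeric",
                 center = "numeric", scale = "numeric",
                 featureNames = "character",
                 converged = "logical", outerIters = "integer"))

#' A fitted, CVPL-selected harmonic-regularized Cox model
#'
#' @slot beta selected coefficient vector (original covariate scale).
#' @slot a selected shrinkage parameter.
#' @slot v selected path position.
#' @slot cvpl cross-validated partial likelihood at the selected point.
#' @slot path the full-data [CoefficientPath-class] the model was read from.
#' @slot grid data.frame of all (a, v, nnz, cvpl) candidates evaluated.
#'
#' @seealso [selectModel()]
#' @export
setClass("HarmonicCoxFit",
  representation(beta = "numeric", a = "numeric", v = "numeric",
                 cvpl = "numeric", path = "CoefficientPath",
                 grid = "data.frame"))

#' A simulation scenario for the survival-data generator
#'
#' Describes one cell of the simulation design: equicorrelated Gaussian
#' predictors, Gompertz proportional-hazards survival times with extra
#' lognormal frailty noise, and independent exponential censoring
#' calibrated to a target censoring fraction.
#'
#' @slot n training sample size.
#' @slot p number of predictors.
#' @slot rho pairwise predictor correlation, in \[0, 1).
#' @slot sigma noise scale multiplying the N(0,1) error added to the linear
#'   predictor.
#' @slot beta true coefficient vector (length p).
#' @slot gamma Gompertz shape parameter (> 0).
#' @slot omega Gompertz scale parameter (> 0).
#' @slot censorTarget target fraction of right-censored subjects, in (0, 1).
#' @slot theta exponential censoring rate; NA until calibrated.
#'
#' @seealso [simScenario()], [makeDataset()], [calibrateCensoring()]
#' @export
setClass("SimulationScenario",
  representation(n = "integer", p = "integer", rho = "numeric",
                 sigma = "numeric", beta = "numeric", gamma = "numeric",
                 omega = "numeric", censorTarget = "numeric",
                 theta = "numeric"))

setValidity("SimulationScenario", function(object) {
  msg <- character()
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (object@p < 1L) msg <- c(msg, "p must be >= 1")
  if (object@rho < 0 || object@rho >= 1) msg <- c(msg, "rho must be in [0, 1)")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (length(object@beta) != object@p)
    msg <- c(msg, "beta must have length p")
  if (object@gamma <= 0 || object@omega <= 0)
    msg <- c(msg, "gamma and omega must be positive")
  if (object@censorTarget <= 0 || object@censorTarget >= 1)
    msg <- c(msg, "censorTarget must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Aggregated results of a simulation study
#'
#' @slot summary one row per scenario: average number of selected variables,
#'   recovery rate, mean test-set IBS and concordance.
#' @slot replicates per-replicate records the summary is computed from.
#'
#' @seealso [runStudy()]
#' @export
setClass("StudyReport",
  representation(summary = "data.frame", replicates = "data.frame"))
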