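## Synthetic survival data: equicorrelated Gaussian predictors, Gompertz
## proportional-hazards times with lognormal frailty noise, independent
## exponential censoring calibrated to a target censoring fraction.

#' Default sparse coefficient vector for simulation scenarios
#'
#' Five signal variables \code{(1, 0.8, -1, -0.8, 1)} in the first five
#' positions, zero elsewhere.
#'
#' @param p total number of predictors (>= 5).
#' @return numeric vector of length p.
#' @export
defaultSignal <- function(p) {
  if (p < 5L) stop("p must be >= 5 for the default signal", call. = FALSE)
  c(1, 0.8, -1, -0.8, 1, rep(0, p - 5L))
}

#' Define a simulation scenario
#'
#' @param n training sample size.
#' @param p number of predictors.
#' @param rho pairwise predictor correlation in \[0, 1).
#' @param sigma noise scale on the linear predictor.
#' @param beta true coefficients (default [defaultSignal()]).
#' @param gamma,omega Gompertz shape and scale of the baseline hazard
#'   \eqn{h_0(t) = \omega e^{\gamma t}}; defaults 1 and 1 put event times
#'   on an O(1) scale.
#' @param censorTarget target right-censoring fraction.
#' @param theta exponential censoring rate; leave \code{NA} to have it
#'   calibrated by [calibrateCensoring()] when the scenario is first used.
#' @return a [SimulationScenario-class].
#' @export
simScenario <- function(n, p = 1000L, rho = 0.1, sigma = 0.2,
                        beta = defaultSignal(p), gamma = 1, omega = 1,
                        censorTarget = 0.25, theta = NA_real_) {
  new("SimulationScenario", n = as.integer(n), p = as.integer(p),
      rho = rho, sigma = sigma, beta = as.numeric(beta), gamma = gamma,
      omega = omega, censorTarget = censorTarget, theta = theta)
}

setMethod("show", "SimulationScenario", function(object) {
  cat("SimulationScenario: n =", object@n, ", p =", object@p, "\n")
  cat("  rho =", object@rho, ", sigma =", object@sigma,
      ", signal vars:", sum(object@beta != 0), "\n")
  cat("  Gompertz(gamma =", object@gamma, ", omega =", object@omega,
      "), censoring target", object@censorTarget,
      if (is.na(object@theta)) "(theta uncalibrated)"
      else paste0("(theta = ", format(object@theta), ")"), "\n")
})

#' Equicorrelated Gaussian predictors
#'
#' \eqn{x_{ij} = \gamma_{ij}\sqrt{1-\rho} + \gamma_{i0}\sqrt{\rho}} with
#' iid standard-normal \eqn{\gamma}: each column is marginally N(0, 1)
#' and every pair of columns has correlation \eqn{\rho} through the
#' shared subject factor \eqn{\gamma_{i0}}.
#'
#' @param n,p dimensions.
#' @param rho correlation in \[0, 1).
#' @param seed optional RNG seed.
#' @return n x p matrix.
#' @export
genPredictors <- function(n, p, rho, seed = NULL) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  .with_seed(seed, {
    shared <- stats::rnorm(n)
    matrix(stats::rnorm(n * p), n, p) * sqrt(1 - rho) + shared * sqrt(rho)
  })
}

#' Gompertz proportional-hazards survival times
#'
#' Inverse-transform sampling under the Gompertz baseline
#' \eqn{h_0(t) = \omega e^{\gamma t}}:
#' \deqn{t' = \frac{1}{\gamma}\log\Big(1 - \frac{\gamma \log U}
#'   {\omega\,\exp(x^T\beta + \sigma\varepsilon)}\Big),}
#' with \eqn{U \sim} Uniform(0,1) and \eqn{\varepsilon \sim} N(0,1).
#' Since \eqn{\log U < 0} the log argument exceeds 1 and all times are
#' positive; larger linear predictors give stochastically shorter
#' survival.
#'
#' @param X covariate matrix.
#' @param beta true coefficients.
#' @param sigma noise scale on the linear predictor.
#' @param gamma,omega Gompertz shape and scale.
#' @param seed optional RNG seed.
#' @param U,eps optional explicit uniform draws / normal errors (testing
#'   seam; both length n).
#' @return vector of n positive survival times.
#' @export
genSurvivalTimes <- function(X, beta, sigma, gamma = 1, omega = 1,
                             seed = NULL, U = NULL, eps = NULL) {
  stopifnot(gamma > 0, omega > 0, sigma >= 0)
  X <- as.matrix(X)
  n <- nrow(X)
  .with_seed(seed, {
    if (is.null(U)) U <- stats::runif(n)
    if (is.null(eps)) eps <- stats::rnorm(n)
    lp <- .eta_sparse(X, as.numeric(beta)) + sigma * eps
    log1p(-gamma * log(U) / (omega * exp(lp))) / gamma
  })
}

# censoring fraction at rate theta given frozen draws (common random
# numbers keep the curve monotone in theta for the bisection)
.censor_frac <- function(theta, tPrime, V) {
  if (theta <= 0) return(0)
  mean(-log(V) / theta < tPrime)
}

#' Calibrate the exponential censoring rate
#'
#' Finds the rate \eqn{\theta} of the independent censoring distribution
#' Exp(\eqn{\theta}) such that the expected fraction of right-censored
#' subjects matches the scenario's target. Uses bisection on the censoring
#' fraction estimated from \code{nrep} simulated replicates of
#' \code{ncal} subjects with common random numbers, so the objective is
#' monotone and deterministic within a call. Only the columns carrying
#' nonzero true coefficients are simulated: the remaining predictors do
#' not enter the survival times.
#'
#' @param scenario a [SimulationScenario-class].
#' @param tol calibration tolerance on the censoring fraction.
#' @param nrep,ncal replicates and subjects per replicate used for
#'   calibration.
#' @param seed optional RNG seed (calibration draws are seed-isolated
#'   from evaluation data).
#' @param maxIter bisection cap.
#' @return \eqn{\theta}, with attribute \code{achieved} (the calibrated
#'   censoring fraction).
#' @export
calibrateCensoring <- function(scenario, tol = 0.01, nrep = 20L,
                               ncal = 1000L, seed = NULL, maxIter = 60L) {
  stopifnot(is(scenario, "SimulationScenario"))
  target <- scenario@censorTarget
  nz <- which(scenario@beta != 0)
  N <- nrep * ncal
  draws <- .with_seed(seed, {
    Xs <- genPredictors(N, max(length(nz), 1L), scenario@rho)
    bs <- scenario@beta[nz]
    if (!length(nz)) bs <- rep(0, 1L)
    tP <- genSurvivalTimes(Xs, bs, scenario@sigma, scenario@gamma,
                           scenario@omega)
    list(tP = tP, V = stats::runif(N))
  })
  lo <- 1e-9
  hi <- 1
  it <- 0L
  while (.censor_frac(hi, draws$tP, draws$V) < target && it < 60L) {
    hi <- hi * 2
    it <- it + 1L
  }
  if (.censor_frac(hi, draws$tP, draws$V) < target)
    stop("censoring target unattainable at any finite rate", call. = FALSE)
  for (i in seq_len(maxIter)) {
    mid <- sqrt(lo * hi)
    fr <- .censor_frac(mid, draws$tP, draws$V)
    if (abs(fr - target) <= tol) break
    if (fr < target) lo <- mid else hi <- mid
  }
  theta <- mid
  achieved <- .censor_frac(theta, draws$tP, draws$V)
  if (abs(achieved - target) > tol)
    stop(sprintf(
      "censoring calibration did not reach %.3f +/- %.3f (achieved %.3f)",
      target, tol, achieved), call. = FALSE)
  attr(theta, "achieved") <- achieved
  theta
}

#' Generate one dataset from a scenario
#'
#' Draws predictors, Gompertz survival times \eqn{t'}, exponential
#' censoring times \eqn{t'' \sim} Exp(\eqn{\theta}), and returns the
#' observed pairs \eqn{t = \min(t', t'')},
#' \eqn{\delta = 1(t' \le t'')}. \code{theta = 0} disables censoring.
#'
#' @param scenario a [SimulationScenario-class].
#' @param seed optional RNG seed; identical seeds give identical
#'   datasets.
#' @param theta overrides the scenario's censoring rate; when both are
#'   missing the rate is calibrated on the fly (seed-isolated).
#' @param n overrides the scenario's sample size (e.g. for test sets).
#' @return a [SurvivalData-class] with attributes \code{trueBeta} and
#'   \code{theta}.
#' @export
makeDataset <- function(scenario, seed = NULL, theta = NULL, n = NULL) {
  stopifnot(is(scenario, "SimulationScenario"))
  if (is.null(theta)) theta <- scenario@theta
  if (is.na(theta)) {
    calSeed <- if (is.null(seed)) NULL else seed + 313L
    theta <- as.numeric(calibrateCensoring(scenario, seed = calSeed))
  }
  if (is.null(n)) n <- scenario@n
  .with_seed(seed, {
    X <- genPredictors(n, scenario@p, scenario@rho)
    tP <- genSurvivalTimes(X, scenario@beta, scenario@sigma,
                           scenario@gamma, scenario@omega)
    tC <- if (theta > 0) stats::rexp(n, rate = theta) else rep(Inf, n)
    d <- survivalData(X, pmin(tP, tC), as.integer(tP <= tC))
    attr(d, "trueBeta") <- scenario@beta
    attr(d, "theta") <- theta
    d
  })
}
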