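## Cox partial likelihood and its working least-squares linearization.
## Risk sets use the Breslow convention R_i = {j : t_j >= t_i}.

# log partial likelihood as a function of the linear predictor eta;
# shift-invariance of l lets us recentre eta to guard against overflow
.partial_loglik_eta <- function(time, status, eta) {
  eta <- eta - max(eta)
  cs <- cumsum(exp(eta[order(time, decreasing = TRUE)]))
  # risk-set mass for subject i is the cumsum entry at #{j : t_j >= t_i}
  k <- length(time) - rank(time, ties.method = "min") + 1L
  ev <- status == 1L
  sum(eta[ev]) - sum(log(cs[k[ev]]))
}

#' Cox partial log-likelihood
#'
#' Breslow-convention partial log-likelihood
#' \eqn{l(\beta) = \sum_i \delta_i [x_i^T\beta - \log \sum_{j: t_j \ge t_i}
#' \exp(x_j^T\beta)]}.
#'
#' @param data a [SurvivalData-class].
#' @param beta coefficient vector of length \code{nFeatures(data)}.
#' @return scalar log partial likelihood.
#' @examples
#' d <- survivalData(matrix(0, 2, 1), time = c(1, 2), status = c(1, 1))
#' partialLoglik(d, 0)  # -log(2)
#' @export
partialLoglik <- function(data, beta) {
  stopifnot(is(data, "SurvivalData"))
  beta <- as.numeric(beta)
  if (length(beta) != nFeatures(data))
    stop("beta must have length ", nFeatures(data), call. = FALSE)
  eta <- drop(data@covariates %*% beta)
  .partial_loglik_eta(data@time, data@status, eta)
}

# risk-share matrix W (events x n): W[i, k] = 1(t_k >= t_i) exp(eta_k) / S_i
.risk_shares <- function(time, status, eta) {
  eta <- eta - max(eta)
  ev <- which(status == 1L)
  w <- exp(eta)
  inrisk <- outer(time[ev], time, "<=")        # events x n membership
  W <- inrisk * rep(w, each = length(ev))
  W / rowSums(W)
}

#' Gradient and Hessian of the negative partial likelihood in eta-space
#'
#' Returns \eqn{\mu = -\partial l/\partial \eta} and
#' \eqn{A = -\partial^2 l/\partial\eta\,\partial\eta^T}. \eqn{A} is symmetric
#' positive semidefinite with zero row sums (the partial likelihood ignores
#' constant shifts of the linear predictor).
#'
#' @inheritParams partialLoglik
#' @param diagOnly return only the diagonal of A (as a vector in \code{A}).
#' @return list with components \code{mu} (length n) and \code{A}
#'   (n x n matrix, or n-vector when \code{diagOnly}).
#' @export
etaGradHess <- function(data, beta, diagOnly = FALSE) {
  stopifnot(is(data, "SurvivalData"))
  eta <- drop(data@covariates %*% as.numeric(beta))
  W <- .risk_shares(data@time, data@status, eta)
  colw <- colSums(W)
  mu <- -(as.numeric(data@status) - colw)
  if (diagOnly) {
    Adiag <- colw - colSums(W^2)
    return(list(mu = mu, A = Adiag))
  }
  A <- -crossprod(W)
  diag(A) <- diag(A) + colw
  list(mu = mu, A = A)
}

#' Working least-squares approximation of the Cox likelihood
#'
#' Builds the quadratic expansion of the negative partial log-likelihood at
#' \code{beta}: with \eqn{\mu} and \eqn{A} from [etaGradHess()], the
#' jittered curvature \eqn{M = A + \epsilon I} (\eqn{\epsilon =
#' 10^{-8}\,\mathrm{tr}(A)/n}) is factored as \eqn{M = C^T C} (Choleski),
#' the working response is \eqn{z = \eta + M^{-1}(\partial l/\partial\eta)}
#' and \eqn{\hat y = C z}, \eqn{\hat X = C X}. Then
#' \eqn{\|\hat y - \hat X\beta\|^2 / 2} matches the second-order Taylor
#' value of \eqn{-l(\beta)} up to an additive constant.
#'
#' @inheritParams partialLoglik
#' @param hessian \code{"full"} or \code{"diag"} (diagonal curvature
#'   approximation; then C is diagonal).
#' @return a [QuadraticApprox-class].
#' @export
quadraticApprox <- function(data, beta, hessian = c("full", "diag")) {
  stopifnot(is(data, "SurvivalData"))
  hessian <- match.arg(hessian)
  X <- data@covariates
  n <- nrow(X)
  beta <- as.numeric(beta)
  eta <- drop(X %*% beta)
  gh <- etaGradHess(data, beta, diagOnly = (hessian == "diag"))
  if (hessian == "diag") {
    d <- pmax(gh$A, 0)
    eps <- 1e-8 * sum(d) / n + 1e-12
    dm <- d + eps
    z <- eta + (-gh$mu) / dm
    Csq <- sqrt(dm)
    xhat <- X * Csq
    yhat <- z * Csq
    M <- diag(dm, n)
  } else {
    A <- gh$A
    eps <- 1e-8 * sum(diag(A)) / n + 1e-12
    M <- A + diag(eps, n)
    C <- tryCatch(chol(M), error = function(e) {
      # severe rank deficiency: escalate the jitter and retry (logged)
      message("quadraticApprox: Choleski failed, increasing ridge jitter")
      M <<- A + diag(1e-4 * sum(diag(A)) / n + 1e-8, n)
      chol(M)
    })
    # z = eta + M^{-1} (dl/deta); mu = -dl/deta; two triangular solves
    z <- eta + backsolve(C, forwardsolve(t(C), -gh$mu))
    xhat <- C %*% X
    yhat <- drop(C %*% z)
  }
  new("QuadraticApprox", xhat = as.matrix(xhat), yhat = yhat, eta = eta,
      X = X, M = as.matrix(M), z = z)
}

setMethod("show", "QuadraticApprox", function(object) {
  cat("QuadraticApprox:", nrow(object@X), "subjects,",
      ncol(object@X), "covariates\n")
  cat("  |eta|_max =", format(max(abs(object@eta))), "\n")
})

#' Breslow cumulative baseline hazard
#'
#' \eqn{H_0(t) = \sum_{s \le t} d_s / \sum_{j: t_j \ge s} e^{\eta_j}} over
#' distinct event times \eqn{s}; at \eqn{\beta = 0} this is the
#' Nelson--Aalen estimator. Predicted survival is
#' \eqn{S(t|x) = \exp(-H_0(t) e^{x^T\beta})}.
#'
#' @inheritParams partialLoglik
#' @return a right-continuous step function \code{H0(t)} with \code{H0(0)=0};
#'   attributes \code{time} and \code{hazard} hold the jump points.
#' @export
breslowBaseline <- function(data, beta) {
  stopifnot(is(data, "SurvivalData"))
  eta <- drop(data@covariates %*% as.numeric(beta))
  eta <- eta - mean(eta)
  w <- exp(eta)
  evt <- sort(unique(data@time[data@status == 1L]))
  d <- vapply(evt, function(s) sum(data@time == s & data@status == 1L), 0)
  riskmass <- vapply(evt, function(s) sum(w[data@time >= s]), 0)
  H <- cumsum(d / riskmass)
  f <- stats::stepfun(evt, c(0, H), right = FALSE)
  attr(f, "time") <- evt
  attr(f, "hazard") <- H
  attr(f, "etaCenter") <- mean(drop(data@covariates %*% as.numeric(beta)))
  f
}

#' Predicted survival curves for new subjects
#'
#' Combines a fitted coefficient vector and a Breslow baseline from the
#' training data into per-subject survival step functions
#' \eqn{S(t|x) = \exp(-H_0(t)\,e^{x^T\beta})} evaluated for new covariates.
#'
#' @param train a [SurvivalData-class] the model was fitted on.
#' @param beta fitted coefficients (original covariate scale).
#' @param newX covariate matrix of the subjects to predict for.
#' @return a [PredictedSurvival-class] step-function container.
#' @export
predictSurvival <- function(train, beta, newX) {
  H0 <- breslowBaseline(train, beta)
  newX <- as.matrix(newX)
  eta <- drop(newX %*% as.numeric(beta)) - attr(H0, "etaCenter")
  knots <- attr(H0, "time")
  S <- exp(-outer(exp(eta), attr(H0, "hazard")))
  new("PredictedSurvival", times = knots, surv = S)
}
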