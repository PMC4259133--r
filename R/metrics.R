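## Prediction-quality measures for censored survival data: the
## censoring-weighted (Graf) Brier score and its time integral, the
## concordance index, and the recovery-rate summary used in the
## variable-selection simulations.

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Fits a Kaplan-Meier curve with the roles of events and censorings
#' swapped, giving \eqn{\hat G(t) = P(\mathrm{censoring\ time} > t)}, the
#' inverse-probability-of-censoring weight function of the Brier score.
#'
#' @param data a [SurvivalData-class].
#' @return a right-continuous step function \code{G(t)} with
#'   \code{G(0) = 1}; attributes \code{time}/\code{surv} hold the steps.
#'   Evaluate left limits \eqn{\hat G(t-)} with \code{attr(G, "left")(t)}.
#' @export
kmCensoring <- function(data) {
  stopifnot(is(data, "SurvivalData"))
  sf <- survival::survfit(survival::Surv(data@time, 1L - data@status) ~ 1)
  tt <- sf$time
  ss <- sf$surv
  G <- stats::stepfun(tt, c(1, ss), right = FALSE)
  Gleft <- function(t) {
    i <- findInterval(t, tt, left.open = TRUE)
    c(1, ss)[i + 1L]
  }
  attr(G, "time") <- tt
  attr(G, "surv") <- ss
  attr(G, "left") <- Gleft
  G
}

#' Survival probabilities at a time point
#'
#' @param pred a [PredictedSurvival-class].
#' @param t single time point.
#' @return vector of \eqn{\hat S(t|x_i)} over subjects.
#' @export
survAt <- function(pred, t) {
  stopifnot(is(pred, "PredictedSurvival"))
  i <- findInterval(t, pred@times)
  if (i == 0L) rep(1, nrow(pred@surv)) else pred@surv[, i]
}

#' Censoring-weighted Brier score at a time point
#'
#' The Graf estimator
#' \deqn{BS(t) = \frac{1}{n}\sum_i \Big[\hat S(t|x_i)^2\,
#'   \frac{1(t_i \le t,\ \delta_i = 1)}{\hat G(t_i-)} +
#'   (1-\hat S(t|x_i))^2\, \frac{1(t_i > t)}{\hat G(t)}\Big],}
#' the inverse-censoring-weighted squared error of the predicted survival
#' probability; small values mean good predictions and \eqn{BS(t) \in
#' [0,1]}. Subjects whose weight denominator is zero are dropped and the
#' divisor reduced accordingly; the count is reported in attribute
#' \code{nExcluded}.
#'
#' @param data the [SurvivalData-class] being predicted (test set).
#' @param pred a [PredictedSurvival-class] for the same subjects.
#' @param t evaluation time, > 0.
#' @param G optional precomputed [kmCensoring()] function for \code{data}.
#' @return scalar Brier score with attribute \code{nExcluded}.
#' @export
brierScore <- function(data, pred, t, G = kmCensoring(data)) {
  stopifnot(is(data, "SurvivalData"), t > 0)
  if (nrow(pred@surv) != nSubjects(data))
    stop("pred must cover the same subjects as data", call. = FALSE)
  S <- survAt(pred, t)
  ti <- data@time
  di <- data@status
  Gleft <- attr(G, "left")
  contrib <- numeric(length(ti))
  keep <- rep(TRUE, length(ti))
  i1 <- which(ti <= t & di == 1L)   # failed by t: weight 1/G(t_i-)
  if (length(i1)) {
    w <- Gleft(ti[i1])
    bad <- w <= 0
    contrib[i1[!bad]] <- S[i1[!bad]]^2 / w[!bad]
    keep[i1[bad]] <- FALSE
  }
  i2 <- which(ti > t)               # still at risk: weight 1/G(t)
  if (length(i2)) {
    gt <- G(t)
    if (gt <= 0) keep[i2] <- FALSE
    else contrib[i2] <- (1 - S[i2])^2 / gt
  }
  nEff <- sum(keep)
  if (nEff == 0L) {
    out <- NA_real_
  } else {
    out <- sum(contrib[keep]) / nEff
  }
  attr(out, "nExcluded") <- sum(!keep)
  out
}

#' Integrated Brier score
#'
#' \eqn{IBS = \frac{1}{\max_i t_i}\int_0^{\max_i t_i} BS(t)\,dt}. Between
#' consecutive knots (observed test times and prediction step times) the
#' Brier score is constant, so the integral is computed exactly as a
#' weighted sum of right-continuous segment values; refining the grid does
#' not change the result.
#'
#' @inheritParams brierScore
#' @return scalar IBS in \[0, 1\], attribute \code{nExcluded} = maximum
#'   per-time exclusion count.
#' @export
integratedBrierScore <- function(data, pred) {
  stopifnot(is(data, "SurvivalData"))
  Tmax <- max(data@time)
  knots <- sort(unique(c(data@time, pred@times)))
  knots <- knots[knots > 0 & knots < Tmax]
  u <- c(0, knots, Tmax)
  G <- kmCensoring(data)
  widths <- diff(u)
  # BS is constant on each inter-knot segment; its midpoint value is the
  # segment value regardless of endpoint continuity conventions
  mids <- (u[-1] + u[-length(u)]) / 2
  excl <- 0L
  vals <- vapply(mids, function(tk) {
    b <- brierScore(data, pred, tk, G = G)
    excl <<- max(excl, attr(b, "nExcluded"))
    if (is.na(b)) 0 else as.numeric(b)
  }, 0)
  out <- sum(vals * widths) / Tmax
  attr(out, "nExcluded") <- excl
  out
}

#' Concordance index for censored survival data
#'
#' Fraction of orderable subject pairs whose predicted risks agree with
#' the observed ordering of survival times. A pair \eqn{(i, j)} is
#' orderable when \eqn{t_i < t_j} and \eqn{\delta_i = 1}; it is concordant
#' when the shorter-lived subject carries the higher predicted risk. Tied
#' risk scores count 1/2, so exchangeable random scores give 0.5 in
#' expectation and perfect ordering gives 1.
#'
#' @param data a [SurvivalData-class].
#' @param risk per-subject risk scores: higher = predicted shorter
#'   survival. For a fitted Cox model this is the linear predictor
#'   \eqn{x^T\hat\beta}.
#' @return concordance in \[0, 1\]; \code{NA} with a warning when no pair
#'   is orderable.
#' @export
concordanceIndex <- function(data, risk) {
  stopifnot(is(data, "SurvivalData"))
  risk <- as.numeric(risk)
  if (length(risk) != nSubjects(data))
    stop("need one risk score per subject", call. = FALSE)
  ti <- data@time
  orderable <- outer(ti, ti, "<") & (data@status == 1L)
  den <- sum(orderable)
  if (den == 0L) {
    warning("no orderable pairs; concordance undefined", call. = FALSE)
    return(NA_real_)
  }
  conc <- outer(risk, risk, ">")
  tied <- outer(risk, risk, "==")
  sum(orderable * (conc + 0.5 * tied)) / den
}

#' Recovery rate of a variable-selection experiment
#'
#' Ratio of the average number of selected true-signal variables to the
#' average number of selected variables, the averages taken across
#' replicates before forming the ratio.
#'
#' @param nRelevant per-replicate counts of selected true-signal variables.
#' @param nSelected per-replicate counts of all selected variables.
#' @return scalar in \[0, 1\]; \code{NA} with a warning when nothing was
#'   ever selected.
#' @export
recoveryRate <- function(nRelevant, nSelected) {
  if (length(nRelevant) != length(nSelected))
    stop("count vectors must have equal length", call. = FALSE)
  if (mean(nSelected) == 0) {
    warning("no variables selected in any replicate; recovery undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mean(nRelevant) / mean(nSelected)
}
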