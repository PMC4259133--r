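#' Construct a harmonic penalty
#'
#' @param a shrinkage parameter, strictly inside (1, 2). Values near 1 give
#'   near-lasso behaviour; values near 2 approach the L1/2 penalty.
#' @return a [HarmonicPenalty-class] object.
#' @examples
#' pen <- harmonicPenalty(1.5)
#' penaltyValue(c(0, 1, 4), pen)
#' @export
harmonicPenalty <- function(a) new("HarmonicPenalty", a = as.numeric(a))

#' @describeIn harmonicPenalty accessor for the shrinkage parameter.
#' @param object a \code{HarmonicPenalty}.
#' @export
shrinkageParam <- function(object) object@a

.check_a <- function(a) {
  if (length(a) != 1L || !is.finite(a) || a <= 1 || a >= 2)
    stop("shrinkage parameter 'a' must be a scalar strictly inside (1, 2)",
         call. = FALSE)
  a
}

.as_a <- function(a) {
  if (is(a, "HarmonicPenalty")) a@a else .check_a(as.numeric(a))
}

# q and c of P(b) = sqrt(q b + c^2) - c
.pen_const <- function(a) {
  list(q = 2 / (a * (a - 1)), c = (2 - a) / (a - 1))
}

#' Harmonic penalty value
#'
#' Evaluates \eqn{P(b) = \sqrt{q b + c^2} - c} with \eqn{q = 2/(a(a-1))},
#' \eqn{c = (2-a)/(a-1)}, on coefficient magnitudes \eqn{b \ge 0}. Computed
#' in the cancellation-free form \eqn{q b / (\sqrt{q b + c^2} + c)}, which
#' stays accurate as \eqn{a \to 1} where \eqn{c} grows without bound.
#' \eqn{P(b) \to |b|} as \eqn{a \to 1} and \eqn{P(b) \to \sqrt b} as
#' \eqn{a \to 2}.
#'
#' @param b numeric vector of coefficient magnitudes, all \eqn{\ge 0}.
#' @param a shrinkage parameter in (1, 2), or a [HarmonicPenalty-class].
#' @return numeric vector of penalty values, nonnegative, \code{P(0) = 0}.
#' @examples
#' penaltyValue(1, 1.999)   # ~ sqrt(1) = 1
#' penaltyValue(1, 1.001)   # ~ |1| = 1
#' @export
penaltyValue <- function(b, a) {
  a <- .as_a(a)
  if (any(!is.finite(b)) || any(b < 0))
    stop("coefficient magnitudes 'b' must be finite and nonnegative",
         call. = FALSE)
  k <- .pen_const(a)
  x <- k$q * b
  x / (sqrt(x + k$c^2) + k$c)
}

#' Harmonic penalty derivative
#'
#' Derivative of [penaltyValue()] with respect to the magnitude:
#' \eqn{P'(b) = q / (2\sqrt{q b + c^2})}. It is finite and positive
#' everywhere, equal to \eqn{1/(a(2-a))} at the origin, and strictly
#' decreasing in \eqn{b} (the penalty is concave). The finite slope at zero
#' is what lets the path-seeking ratio \eqn{\tau_j = g_j / P'(|\beta_j|)}
#' be formed for inactive coordinates.
#'
#' @inheritParams penaltyValue
#' @return numeric vector of strictly positive derivative values.
#' @examples
#' penaltyDerivative(0, 1.5)  # 1/(1.5 * 0.5) = 4/3
#' @export
penaltyDerivative <- function(b, a) {
  a <- .as_a(a)
  if (any(!is.finite(b)) || any(b < 0))
    stop("coefficient magnitudes 'b' must be finite and nonnegative",
         call. = FALSE)
  k <- .pen_const(a)
  k$q / (2 * sqrt(k$q * b + k$c^2))
}

setMethod("show", "HarmonicPenalty", function(object) {
  cat("HarmonicPenalty, a =", object@a, "\n")
  cat("  slope at origin:", format(penaltyDerivative(0, object@a)), "\n")
})
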