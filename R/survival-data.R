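#' Construct a SurvivalData object
#'
#' @param X numeric matrix or data.frame of covariates, subjects in rows.
#' @param time observed times, strictly positive.
#' @param status event indicators: 1 = event, 0 = right-censored (logical
#'   accepted).
#' @return a [SurvivalData-class] object.
#' @examples
#' d <- survivalData(matrix(rnorm(20), 10, 2), time = rexp(10) + 0.1,
#'                   status = rbinom(10, 1, 0.7))
#' d
#' @export
survivalData <- function(X, time, status) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  new("SurvivalData", covariates = X, time = as.numeric(time),
      status = as.integer(status))
}

#' @rdname survivalData
#' @param object a \code{SurvivalData}.
#' @export
covariates <- function(object) object@covariates

#' @rdname survivalData
#' @export
survTimes <- function(object) object@time

#' @rdname survivalData
#' @export
eventStatus <- function(object) object@status

#' @rdname survivalData
#' @export
nSubjects <- function(object) nrow(object@covariates)

#' @rdname survivalData
#' @export
nFeatures <- function(object) ncol(object@covariates)

setMethod("show", "SurvivalData", function(object) {
  cat("SurvivalData:", nSubjects(object), "subjects,",
      nFeatures(object), "covariates\n")
  cat(sprintf("  events: %d (%.1f%% censored)\n", sum(object@status),
              100 * mean(object@status == 0L)))
  cat("  time range: [", format(min(object@time)), ",",
      format(max(object@time)), "]\n")
})

#' Subset a SurvivalData by subjects
#'
#' @param x a \code{SurvivalData}.
#' @param i subject index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "SurvivalData", function(x, i, j, ..., drop = FALSE) {
  survivalData(x@covariates[i, , drop = FALSE], x@time[i], x@status[i])
})

#' Read survival data from a delimited text file
#'
#' Expects a header with columns \code{time}, \code{status} and one column
#' per covariate; any delimiter understood by [utils::read.table()].
#'
#' @param file path to the table.
#' @param sep field separator (default tab; use "," for CSV).
#' @return a [SurvivalData-class].
#' @export
readSurvivalData <- function(file, sep = "\t") {
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           check.names = FALSE)
  need <- c("time", "status")
  if (!all(need %in% names(tab)))
    stop("input table must contain 'time' and 'status' columns; found: ",
         paste(names(tab)[seq_len(min(5, ncol(tab)))], collapse = ", "),
         call. = FALSE)
  feat <- setdiff(names(tab), need)
  if (!length(feat)) stop("no covariate columns found", call. = FALSE)
  bad <- !vapply(tab[feat], is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric covariate column(s): ",
         paste(feat[bad], collapse = ", "), call. = FALSE)
  survivalData(as.matrix(tab[feat]), tab$time, tab$status)
}

#' Write survival data as a delimited text file
#'
#' @param object a [SurvivalData-class].
#' @param file output path.
#' @param sep field separator.
#' @export
writeSurvivalData <- function(object, file, sep = "\t") {
  tab <- data.frame(time = object@time, status = object@status,
                    object@covariates, check.names = FALSE)
  utils::write.table(tab, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write fitted coefficients as two-column delimited text
#'
#' @param beta named numeric vector of coefficients.
#' @param file output path.
#' @param all write zero coefficients too? Default keeps the sparse support.
#' @export
writeCoefficients <- function(beta, file, all = FALSE) {
  if (is.null(names(beta))) names(beta) <- paste0("x", seq_along(beta))
  if (!all) beta <- beta[beta != 0]
  utils::write.table(data.frame(name = names(beta), value = unname(beta)),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
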