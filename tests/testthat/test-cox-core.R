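test_that("SurvivalData validates its inputs", {
  expect_error(survivalData(matrix(1, 3, 2), c(1, -1, 2), c(1, 1, 0)),
               "strictly positive")
  expect_error(survivalData(matrix(1, 3, 2), c(1, 1, 2), c(1, 2, 0)),
               "status")
  expect_error(survivalData(matrix(1, 3, 2), c(1, 1, 2), c(0, 0, 0)),
               "at least one event")
  d <- survivalData(matrix(rnorm(6), 3, 2), c(1, 2, 3), c(1L, 0L, 1L))
  expect_identical(nSubjects(d), 3L)
  expect_identical(nFeatures(d), 2L)
  sub <- d[c(1, 3)]
  expect_identical(survTimes(sub), c(1, 3))
})

test_that("partial log-likelihood matches hand-computed worked cases", {
  # two subjects, both events, beta = 0: risk sets of size 2 and 1
  d2 <- survivalData(matrix(0, 2, 1), time = c(1, 2), status = c(1, 1))
  expect_equal(partialLoglik(d2, 0), -log(2), tolerance = 1e-12)
  # single covariate, event then censoring
  d3 <- survivalData(matrix(c(1, 0), 2, 1), time = c(1, 2), status = c(1, 0))
  expect_equal(partialLoglik(d3, 0.5), 0.5 - log(exp(0.5) + 1),
               tolerance = 1e-12)
  expect_equal(partialLoglik(d3, 0.5), -0.474077, tolerance = 1e-6)
  # at beta = 0 the likelihood depends only on risk-set sizes
  d <- rand_surv(25, 3, seed = 4)
  sizes <- vapply(which(eventStatus(d) == 1L),
                  function(i) sum(survTimes(d) >= survTimes(d)[i]), 0)
  expect_equal(partialLoglik(d, rep(0, 3)), -sum(log(sizes)),
               tolerance = 1e-10)
})

test_that("partial log-likelihood agrees with coxph and the brute-force oracle", {
  for (seed in 1:3) {
    d <- rand_surv(40, 4, seed = seed, beta = c(0.8, -0.5, 0, 0))
    beta <- withr::with_seed(seed + 10, rnorm(4, sd = 0.5))
    l <- partialLoglik(d, beta)
    expect_equal(l, oracle_loglik(survTimes(d), eventStatus(d),
                                  drop(covariates(d) %*% beta)),
                 tolerance = 1e-10)
    ref <- survival::coxph(
      survival::Surv(survTimes(d), eventStatus(d)) ~ covariates(d),
      init = beta, ties = "breslow",
      control = survival::coxph.control(iter.max = 0))
    expect_equal(l, ref$loglik[2], tolerance = 1e-8)
  }
  # shift invariance in eta: adding a constant to eta leaves l unchanged
  d <- rand_surv(15, 2, seed = 9)
  eta <- drop(covariates(d) %*% c(0.3, -0.2))
  expect_equal(
    harmonicCox:::.partial_loglik_eta(survTimes(d), eventStatus(d), eta),
    harmonicCox:::.partial_loglik_eta(survTimes(d), eventStatus(d), eta + 7),
    tolerance = 1e-9)
})

test_that("eta-space gradient and Hessian match finite differences", {
  d <- rand_surv(10, 2, seed = 11, beta = c(0.5, -0.5))
  beta <- c(0.4, 0.2)
  eta <- drop(covariates(d) %*% beta)
  gh <- etaGradHess(d, beta)
  h <- 1e-5
  fd <- vapply(seq_len(10), function(i) {
    ep <- eta; ep[i] <- ep[i] + h
    em <- eta; em[i] <- em[i] - h
    tt <- survTimes(d); st <- eventStatus(d)
    -(oracle_loglik(tt, st, ep) - oracle_loglik(tt, st, em)) / (2 * h)
  }, 0)
  expect_lt(max(abs(gh$mu - fd)), 1e-6)
  # Hessian: central second differences of the oracle likelihood,
  # symmetry, PSD, zero row sums
  h2 <- 1e-4
  tt <- survTimes(d); st <- eventStatus(d)
  fdH <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    pert <- function(si, sj) {
      e <- eta
      e[i] <- e[i] + si * h2
      e[j] <- e[j] + sj * h2
      oracle_loglik(tt, st, e)
    }
    fdH[i, j] <- -(pert(1, 1) - pert(1, -1) - pert(-1, 1) + pert(-1, -1)) /
      (4 * h2^2)
  }
  expect_lt(max(abs(gh$A - fdH)), 1e-5)
  expect_equal(gh$A, t(gh$A), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(gh$A))), 1e-12)
  expect_gte(min(eigen(gh$A, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  # diagonal mode returns the diagonal of the full Hessian
  ghd <- etaGradHess(d, beta, diagOnly = TRUE)
  expect_equal(ghd$A, diag(gh$A), tolerance = 1e-12)
  expect_equal(ghd$mu, gh$mu)
})

test_that("the working least-squares problem is a faithful expansion of -l", {
  d <- rand_surv(10, 3, seed = 21, beta = c(1, 0, -1))
  beta0 <- c(0.3, -0.1, 0.2)
  qa <- quadraticApprox(d, beta0)
  # gradient consistency: d/dbeta of the quadratic form Q/2 at the
  # expansion point equals -dl/dbeta
  gQ <- -drop(crossprod(qa@xhat, qa@yhat - qa@xhat %*% beta0))
  h <- 1e-5
  gl <- vapply(1:3, function(j) {
    bp <- beta0; bp[j] <- bp[j] + h
    bm <- beta0; bm[j] <- bm[j] - h
    -(partialLoglik(d, bp) - partialLoglik(d, bm)) / (2 * h)
  }, 0)
  expect_lt(max(abs(gQ - gl)), 1e-6)
  # curvature: Q/2 differences reproduce the Taylor value of -l
  db <- c(0.05, -0.04, 0.03)
  Q <- function(b) sum((qa@yhat - qa@xhat %*% b)^2)
  taylor <- sum(gl * db) + 0.5 * drop(t(db) %*% crossprod(qa@xhat) %*% db)
  expect_equal((Q(beta0 + db) - Q(beta0)) / 2, taylor, tolerance = 1e-8)
  # identity-curvature seam: yhat = z and xhat = x
  ls <- leastSquaresApprox(covariates(d), survTimes(d))
  expect_identical(ls@yhat, survTimes(d))
  expect_identical(ls@xhat, covariates(d))
})

test_that("iterating the expansion with no penalty reproduces the Cox MLE", {
  d <- rand_surv(50, 2, seed = 31, beta = c(1, -0.6))
  beta <- c(0, 0)
  for (i in 1:25) {
    qa <- quadraticApprox(d, beta)
    beta <- drop(solve(crossprod(qa@xhat), crossprod(qa@xhat, qa@yhat)))
  }
  ref <- survival::coxph(
    survival::Surv(survTimes(d), eventStatus(d)) ~ covariates(d),
    ties = "breslow")
  expect_lt(max(abs(beta - unname(coef(ref)))), 1e-4)
})

test_that("Breslow baseline reduces to Nelson-Aalen and yields valid curves", {
  d <- survivalData(matrix(rnorm(3), 3, 1), time = c(1, 2, 3),
                    status = c(1, 1, 1))
  H0 <- breslowBaseline(d, 0)
  expect_equal(H0(c(0.5, 1, 2, 3, 9)),
               c(0, 1/3, 1/3 + 1/2, 1/3 + 1/2 + 1, 1/3 + 1/2 + 1),
               tolerance = 1e-12)
  # predicted survival: starts at 1, nonincreasing, in [0, 1]
  dd <- rand_surv(30, 2, seed = 41, beta = c(0.7, 0))
  ps <- predictSurvival(dd, c(0.5, 0), covariates(dd)[1:5, ])
  expect_s4_class(ps, "PredictedSurvival")
  expect_equal(survAt(ps, 0), rep(1, 5))
  S <- ps@surv
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(S[, -1] <= S[, -ncol(S)] + 1e-12))
})

test_that("survival tables round-trip through delimited text", {
  d <- rand_surv(12, 3, seed = 51)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSurvivalData(d, f)
  d2 <- readSurvivalData(f)
  expect_equal(covariates(d2), covariates(d), tolerance = 1e-12)
  expect_equal(survTimes(d2), survTimes(d), tolerance = 1e-12)
  expect_identical(eventStatus(d2), eventStatus(d))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", bad)
  expect_error(readSurvivalData(bad), "time")
  cf <- withr::local_tempfile(fileext = ".tsv")
  writeCoefficients(c(x1 = 1.5, x2 = 0, x3 = -2), cf)
  tab <- read.delim(cf)
  expect_identical(tab$name, c("x1", "x3"))
})
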