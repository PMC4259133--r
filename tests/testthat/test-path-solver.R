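test_that("tau ratios match a straight-line evaluation", {
  withr::local_seed(61)
  n <- 20; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  approx <- leastSquaresApprox(X, y)
  beta <- c(0.4, 0, -0.2, 0, 0.1)
  a <- 1.6
  tau <- computeTau(approx, beta, a)
  # coordinate-by-coordinate re-derivation from the definitions
  q <- 2 / (a * (a - 1)); cc <- (2 - a) / (a - 1)
  for (j in seq_len(p)) {
    gj <- sum((y - X %*% beta) * X[, j]) / n
    pj <- q / (2 * sqrt(q * abs(beta[j]) + cc^2))
    expect_equal(tau[j], gj / pj, tolerance = 1e-12)
  }
  # at beta = 0 all penalty slopes are equal: argmax |tau| = argmax |g|
  tau0 <- computeTau(approx, rep(0, p), a)
  g0 <- drop(crossprod(X, y)) / n
  expect_identical(which.max(abs(tau0)), which.max(abs(g0)))
  # zero residual at the truth: tau vanishes (path terminus)
  Xo <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  bstar <- c(1, -2, 0, 0.5, 0, 0)
  expect_lt(max(abs(computeTau(leastSquaresApprox(Xo, drop(Xo %*% bstar)),
                               bstar, 1.4))), 1e-12)
})

test_that("inner path moves one coordinate per step and stands still at zero signal", {
  withr::local_seed(62)
  X <- matrix(rnorm(60), 20, 3)
  path0 <- gpsInnerPath(leastSquaresApprox(X, rep(0, 20)), a = 1.5)
  expect_length(path0@v, 0)
  expect_equal(unname(coef(path0)), rep(0, 3))
  expect_true(path0@converged)

  y <- drop(X %*% c(1, -0.5, 0)) + rnorm(20, sd = 0.1)
  ctl <- pathControl(maxInnerSteps = 500)
  path <- suppressWarnings(gpsInnerPath(leastSquaresApprox(X, y),
                                        a = 1.5, control = ctl))
  st <- pathStates(path)
  expect_true(all(diff(st$v) > 0))
  # single-coordinate moves of at most deltaV: replay and compare
  beta <- rep(0, 3)
  for (s in seq_len(nrow(st))) {
    expect_lte(abs(st$value[s] - beta[st$coord[s]]), ctl@deltaV + 1e-12)
    beta[st$coord[s]] <- st$value[s]
  }
})

test_that("near a = 1 the path matches the lasso on an orthogonal design", {
  withr::local_seed(63)
  n <- 40; p <- 6
  X <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)  # X'X/n = I
  bstar <- c(2, -1.5, 1, 0, 0, 0)
  y <- drop(X %*% bstar)
  approx <- leastSquaresApprox(X, y)
  path <- suppressWarnings(
    gpsInnerPath(approx, a = 1.001,
                 control = pathControl(maxInnerSteps = 5000)))
  st <- pathStates(path)
  # entry order follows descending |X'y|
  expected_order <- order(-abs(drop(crossprod(X, y)) / n))
  first_seen <- st$coord[!duplicated(st$coord)]
  expect_identical(first_seen[1:3], expected_order[1:3])
  # orthogonal-design lasso solution at penalty lambda is the
  # soft-threshold of the least-squares coefficients; match by L1 norm
  ols <- drop(crossprod(X, y)) / n
  for (vq in c(0.5, 1.5, 3)) {
    b <- drop(pathCoef(path, vq))
    L1 <- sum(abs(b))
    soft <- function(lam) sign(ols) * pmax(abs(ols) - lam, 0)
    lam <- uniroot(function(l) sum(abs(soft(l))) - L1, c(0, max(abs(ols))))$root
    expect_lt(max(abs(b - soft(lam))), 0.05)
  }
})

test_that("near a = 1 the path matches glmnet on a correlated design", {
  skip_if_not_installed("glmnet")
  withr::local_seed(64)
  n <- 80; p <- 8
  X <- matrix(rnorm(n * p), n, p) + 0.3 * rnorm(n)
  X <- scale(X) * sqrt(n / (n - 1))
  y <- drop(X %*% c(1.5, -1, 0.8, rep(0, 5))) + rnorm(n, sd = 0.3)
  y <- y - mean(y)
  path <- suppressWarnings(
    gpsInnerPath(leastSquaresApprox(X, y), a = 1.001,
                 control = pathControl(maxInnerSteps = 8000)))
  gn <- glmnet::glmnet(X, y, intercept = FALSE, standardize = FALSE,
                       thresh = 1e-12)
  B <- as.matrix(gn$beta)
  for (vq in c(1, 2, 3)) {
    b <- drop(pathCoef(path, vq))
    k <- which.min(abs(colSums(abs(B)) - sum(abs(b))))
    expect_lt(max(abs(b - B[, k])), 0.05)
  }
})

test_that("sign reversals are corrected before new variables enter", {
  # beta0 has a positive coordinate whose tau is negative: the
  # sign-mismatch set takes priority over the globally largest tau
  X <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0)) * 2
  y <- c(-1, 6, 0, 0)        # g = (X'y - X'X beta)/n
  approx <- leastSquaresApprox(X, y)
  beta0 <- c(1, 0)
  tau <- computeTau(approx, beta0, 1.5)
  expect_lt(tau[1], 0)       # mismatch with beta0[1] > 0
  expect_gt(abs(tau[2]), abs(tau[1]))  # coordinate 2 would win globally
  path <- suppressWarnings(
    gpsInnerPath(approx, beta0 = beta0, a = 1.5,
                 control = pathControl(maxInnerSteps = 5)))
  st <- pathStates(path)
  expect_identical(st$coord[1], 1L)
  expect_lt(st$value[1], beta0[1])
})

test_that("the working loss is monotone along the inner path at small steps", {
  withr::local_seed(65)
  X <- matrix(rnorm(200), 50, 4)
  y <- drop(X %*% c(1, -1, 0.5, 0)) + rnorm(50, sd = 0.2)
  approx <- leastSquaresApprox(X, y)
  path <- suppressWarnings(
    gpsInnerPath(approx, a = 1.5,
                 control = pathControl(deltaV = 1e-3,
                                       maxInnerSteps = 2000)))
  B <- pathCoef(path, path@v[seq(1, length(path@v), by = 25)])
  loss <- apply(B, 2, function(b) sum((y - X %*% b)^2))
  expect_true(all(diff(loss) <= 1e-10))
})

test_that("a converged path really has all tau ratios inside tolerance", {
  # orthonormal design with targets on the step lattice: the path can
  # land exactly on the optimum and terminate by the tau criterion
  withr::local_seed(69)
  n <- 16
  X <- qr.Q(qr(matrix(rnorm(n * n), n, n))) * sqrt(n)
  bstar <- c(0.5, -0.25, 0.1, rep(0, n - 3))
  approx <- leastSquaresApprox(X, drop(X %*% bstar))
  ctl <- pathControl(maxInnerSteps = 10000)
  path <- gpsInnerPath(approx, a = 1.5, control = ctl)
  expect_true(path@converged)
  bhat <- drop(pathCoef(path, max(path@v)))
  expect_lt(max(abs(computeTau(approx, bhat, 1.5))), ctl@tauTol)
  expect_equal(unname(bhat), bstar, tolerance = 1e-8)
})

test_that("zero-crossing moves clamp exactly onto zero", {
  withr::local_seed(66)
  X <- matrix(rnorm(120), 30, 4)
  y <- drop(X %*% c(1, 0.5, -0.5, 0)) + rnorm(30, sd = 0.3)
  beta0 <- c(-0.004, 0, 0, 0)  # |beta| < deltaV with the wrong sign
  path <- suppressWarnings(
    gpsInnerPath(leastSquaresApprox(X, y), beta0 = beta0, a = 1.5,
                 control = pathControl(maxInnerSteps = 300)))
  st <- pathStates(path)
  moved1 <- st$value[st$coord == 1L]
  expect_true(0 %in% moved1)  # passed through an exact zero, no overshoot
})

test_that("a one-covariate strong effect drives the path to the Cox MLE", {
  scn <- simScenario(n = 50, p = 1, rho = 0, sigma = 0, beta = 1.2,
                     theta = 0)
  d <- makeDataset(scn, seed = 67)
  path <- suppressWarnings(
    harmonicCoxPath(d, a = 1.5,
                    control = pathControl(maxInnerSteps = 3000,
                                          maxOuterIters = 8)))
  ref <- survival::coxph(
    survival::Surv(survTimes(d), eventStatus(d)) ~ covariates(d),
    ties = "breslow")
  expect_lt(abs(coef(path) - unname(coef(ref))), 0.05)
})

test_that("true signals enter the path first in a planted-signal design", {
  hits <- 0L
  for (seed in 1:5) {
    scn <- simScenario(n = 200, p = 30, rho = 0.1, sigma = 0.2,
                       beta = c(defaultSignal(5), rep(0, 25)))
    d <- makeDataset(scn, seed = 700 + seed)
    path <- suppressWarnings(
      harmonicCoxPath(d, a = 1.5,
                      control = pathControl(maxInnerSteps = 400,
                                            maxOuterIters = 2)))
    first5 <- unique(pathStates(path)$coord)[1:5]
    if (setequal(first5, 1:5)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("path export and control files round-trip", {
  withr::local_seed(68)
  X <- matrix(rnorm(100), 25, 4)
  y <- drop(X %*% c(1, -1, 0, 0)) + rnorm(25, sd = 0.2)
  path <- suppressWarnings(
    gpsInnerPath(leastSquaresApprox(X, y), a = 1.5,
                 control = pathControl(maxInnerSteps = 200)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writePath(path, f, every = 10L)
  lines <- readLines(f)
  expect_match(lines[1], "^v\tnnz\t")
  expect_gt(length(lines), 2)

  cfg <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# solver settings", "deltaV=0.005", "maxOuterIters=3",
               "hessian=diag"), cfg)
  ctl <- readPathControl(cfg)
  expect_equal(ctl@deltaV, 0.005)
  expect_identical(ctl@maxOuterIters, 3L)
  expect_identical(ctl@hessian, "diag")
  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("stepSize=1", bad)
  expect_error(readPathControl(bad), "unknown control key")
})
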