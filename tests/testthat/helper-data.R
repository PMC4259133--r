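# small random survival datasets built in code for unit tests
rand_surv <- function(n, p, seed, beta = rep(0, p), censor = 0.3) {
  withr::local_seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  lp <- drop(X %*% beta)
  tt <- rexp(n, rate = exp(lp))
  cc <- rexp(n, rate = censor * mean(exp(lp)) / max(1 - censor, 1e-6))
  st <- as.integer(tt <= cc)
  if (sum(st) == 0L) st[which.min(tt)] <- 1L
  survivalData(X, pmin(tt, cc) + 1e-9, st)
}

# straight-line partial log-likelihood oracle: literal double loop over
# Eq-style risk sets, no shared code with the package internals
oracle_loglik <- function(time, status, eta) {
  out <- 0
  for (i in seq_along(time)) {
    if (status[i] == 1L) {
      out <- out + eta[i] - log(sum(exp(eta[time >= time[i]])))
    }
  }
  out
}
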