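# Metropolis-within-Gibbs sampler: determinism, invariants, exactness
# against brute-force oracles, and the Geweke diagnostic.

test_that("same seed gives bit-identical chains; chain length follows thin", {
  dat <- standardizeCovariates(makeToyExperiment())
  ctl <- DMSamplerControl(nIterations = 300, thin = 3, seed = 4)
  ch1 <- fitDMRegression(dat, control = ctl)
  ch2 <- fitDMRegression(dat, control = ctl)
  expect_identical(alphaDraws(ch1), alphaDraws(ch2))
  expect_identical(betaDraws(ch1), betaDraws(ch2))
  expect_identical(xiDraws(ch1), xiDraws(ch2))
  expect_equal(nDraws(ch1), 100)
  # n_iterations == thin stores exactly one state
  ch3 <- fitDMRegression(dat, control = DMSamplerControl(nIterations = 10,
                                                         thin = 10, seed = 1))
  expect_equal(nDraws(ch3), 1)
})

test_that("stored draws always satisfy the spike-and-slab coupling", {
  dat <- standardizeCovariates(makeToyExperiment(seed = 3))
  ch <- fitDMRegression(dat, control = DMSamplerControl(nIterations = 500,
                                                        thin = 5, seed = 9))
  expect_true(all((xiDraws(ch) == 0) == (betaDraws(ch) == 0)))
  expect_equal(modelSizeTrace(ch),
               as.numeric(apply(xiDraws(ch), 1, sum)))
  expect_true(validObject(ch))
})

test_that("zero intercept step leaves the intercepts at their start", {
  dat <- standardizeCovariates(makeToyExperiment())
  ch <- fitDMRegression(dat, priorOnly = TRUE,
                        control = DMSamplerControl(nIterations = 100, thin = 5,
                                                   seed = 2, alphaStepSd = 0))
  expect_true(all(alphaDraws(ch) == 0))
  expect_equal(unname(acceptanceRates(ch)["alpha"]), 1)
})

test_that("all-zero count rows are rejected with the sample named", {
  Y <- rbind(good = c(5L, 3L), empty = c(0L, 0L))
  colnames(Y) <- c("t1", "t2")
  x <- DMExperiment(Y, matrix(rnorm(2), 2, 1))
  expect_error(suppressWarnings(fitDMRegression(x)), "empty")
})

test_that("prior-only chain recovers the marginalized spike-and-slab prior", {
  # with the likelihood disabled the chain targets the prior exactly:
  # every PPI has expectation m and alpha_j ~ N(0, s2). The add proposal is
  # matched to the slab (fixed variance = slab variance, adaptation not yet
  # started) so inclusion indicators mix at the Bernoulli(m) rate.
  dat <- standardizeCovariates(makeToyExperiment(n = 10, J = 6, P = 6))
  hyp <- DMHyperParams(slabVar = 1, interceptVar = 10, m = 0.01)
  ch <- fitDMRegression(dat, hyper = hyp, priorOnly = TRUE,
                        control = DMSamplerControl(nIterations = 40000,
                                                   thin = 5, seed = 21,
                                                   alphaStepSd = 2,
                                                   adaptFixedConst = 1,
                                                   adaptStart = 100000))
  keep <- seq.int(nDraws(ch) %/% 2 + 1, nDraws(ch))
  # mean inclusion fraction per stored draw, batch-means standard error
  frac <- modelSizeTrace(ch)[keep] / (6 * 6)
  nb <- floor(sqrt(length(frac)))
  bs <- length(frac) %/% nb
  bm <- vapply(seq_len(nb), function(b) mean(frac[((b - 1) * bs + 1):(b * bs)]),
               numeric(1))
  se <- sd(bm) / sqrt(nb)
  expect_lt(abs(mean(frac) - 0.01), 3 * se + 1e-4)
  a <- as.numeric(alphaDraws(ch)[keep, ])
  expect_lt(abs(mean(a)), 0.3)          # 0 within MC error (sd ~ 3.16)
  expect_equal(var(a), 10, tolerance = 0.15)
})

test_that("chain PPIs match a quadrature oracle on a tiny instance", {
  # P = 1, J = 2: enumerate the four indicator configurations and integrate
  # alpha_1, alpha_2 (and beta where included) on a dense grid
  set.seed(31)
  n <- 8
  X <- matrix(scale(rnorm(n)), n, 1)
  alpha_t <- c(0.3, -0.2)
  beta_t <- matrix(c(0.9, 0), 1, 2)
  gam <- computeGamma(alpha_t, beta_t, X)
  Y <- t(vapply(seq_len(n), function(i)
    as.integer(rmultinom(1, 60, gam[i, ] / sum(gam[i, ]))), integer(2)))
  colnames(Y) <- c("t1", "t2")
  rownames(Y) <- rownames(X) <- paste0("s", 1:n)
  hyp <- DMHyperParams(slabVar = 2, interceptVar = 2, m = 0.2)

  ag <- seq(-3, 3, length.out = 41)
  bg <- seq(-3, 3, length.out = 41)
  loglik_grid <- function(b1, b2) {
    # vectorized over the alpha grid for fixed betas
    ll <- matrix(0, length(ag), length(ag))
    z1 <- outer(X[, 1] * b1, rep(1, length(ag))) +
      matrix(ag, n, length(ag), byrow = TRUE)     # n x |ag| for taxon 1
    z2 <- outer(X[, 1] * b2, rep(1, length(ag))) +
      matrix(ag, n, length(ag), byrow = TRUE)
    g1 <- exp(z1); g2 <- exp(z2)
    t1 <- lgamma(Y[, 1] + g1) - lgamma(g1)        # n x |ag|
    t2 <- lgamma(Y[, 2] + g2) - lgamma(g2)
    yp <- rowSums(Y)
    for (i2 in seq_along(ag)) {
      gp <- g1 + matrix(g2[, i2], n, length(ag))
      ll[, i2] <- colSums(t1 + lgamma(gp) - lgamma(yp + gp)) + sum(t2[, i2])
    }
    ll
  }
  # grid-cell weights: the step size must enter because configurations
  # integrate over different numbers of coefficients
  prior_a <- dnorm(ag, 0, sqrt(2)) * (ag[2] - ag[1])
  prior_b <- dnorm(bg, 0, sqrt(2)) * (bg[2] - bg[1])
  marg <- function(xi1, xi2) {
    # marginal likelihood x prior mass of one indicator configuration
    b1s <- if (xi1) bg else 0
    b2s <- if (xi2) bg else 0
    tot <- 0
    for (k1 in seq_along(b1s)) for (k2 in seq_along(b2s)) {
      L <- exp(loglik_grid(b1s[k1], b2s[k2]))
      w <- sum(L * outer(prior_a, prior_a))
      if (xi1) w <- w * prior_b[k1]
      if (xi2) w <- w * prior_b[k2]
      tot <- tot + w
    }
    pm <- 0.2^(xi1 + xi2) * 0.8^(2 - xi1 - xi2)
    tot * pm
  }
  w00 <- marg(0, 0); w10 <- marg(1, 0); w01 <- marg(0, 1); w11 <- marg(1, 1)
  z <- w00 + w10 + w01 + w11
  oracle_ppi <- c((w10 + w11) / z, (w01 + w11) / z)

  dat <- DMExperiment(Y, X, standardized = TRUE)
  ch <- fitDMRegression(dat, hyper = hyp,
                        control = DMSamplerControl(nIterations = 300000,
                                                   thin = 10, seed = 32,
                                                   alphaStepSd = 0.8,
                                                   adaptFixedConst = 0.5))
  ppi <- computePPI(ch)
  expect_lt(abs(ppi[1, 1] - oracle_ppi[1]), 0.05)
  expect_lt(abs(ppi[1, 2] - oracle_ppi[2]), 0.05)
})

test_that("chains stay finite and adapted variances floored on degenerate data", {
  # one dominant taxon carrying ~99% of every sample
  set.seed(41)
  n <- 15
  Y <- cbind(dom = rpois(n, 500), a = rpois(n, 3), b = rpois(n, 2))
  Y[Y == 0] <- 1L
  storage.mode(Y) <- "integer"
  rownames(Y) <- paste0("s", 1:n)
  x <- standardizeCovariates(DMExperiment(Y, matrix(rnorm(2 * n), n, 2)))
  ch <- fitDMRegression(x, control = DMSamplerControl(nIterations = 20000,
                                                      thin = 20, seed = 5))
  expect_true(all(is.finite(alphaDraws(ch))))
  expect_true(all(is.finite(betaDraws(ch))))
  expect_true(all(is.finite(logPostTrace(ch))))
})

test_that("Geweke z behaves on stationary, symmetric and trending traces", {
  set.seed(51)
  zs <- replicate(20, gewekeZ(rnorm(10000)))
  expect_true(all(abs(zs) < 4))
  # a deterministic trend is flagged loudly
  expect_gt(abs(gewekeZ(seq_len(1000))), 10)
  # constant trace degenerates to zero with a warning
  expect_warning(z0 <- gewekeZ(rep(1, 100)), "constant")
  expect_equal(z0, 0)
  expect_error(gewekeZ(rnorm(10)), "at least 20")
})

test_that("Geweke z agrees qualitatively with the coda implementation", {
  skip_if_not_installed("coda")
  set.seed(52)
  x <- as.numeric(arima.sim(list(ar = 0.6), 5000))
  z_pkg <- gewekeZ(x)
  z_coda <- unname(coda::geweke.diag(coda::mcmc(x))$z)
  # different spectral estimators, same scale and verdict
  expect_lt(abs(z_pkg - z_coda), 1.5)
  expect_equal(abs(z_pkg) < 2, abs(z_coda) < 2)
})

test_that("convergenceSummary reports model-size and coefficient z-scores", {
  dat <- standardizeCovariates(makeToyExperiment(seed = 6))
  ch <- fitDMRegression(dat, control = DMSamplerControl(nIterations = 1000,
                                                        thin = 5, seed = 6))
  cs <- suppressWarnings(convergenceSummary(ch))
  expect_true(is.finite(cs$modelSizeZ))
})
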