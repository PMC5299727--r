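# Dirichlet-Multinomial likelihood, link and prior.

test_that("dmLogPmf matches closed forms on degenerate cases", {
  # single category: the outcome is certain
  expect_equal(dmLogPmf(5, 2.0), 0)
  # uniform DM over the two outcomes of a single draw
  expect_equal(dmLogPmf(c(1, 0), c(1, 1)), log(0.5))
  expect_equal(dmLogPmf(c(0, 1), c(1, 1)), log(0.5))
})

test_that("dmLogPmf validates its domain", {
  expect_error(dmLogPmf(c(1, 0), c(1, -1)), "positive")
  expect_error(dmLogPmf(c(1, 0), c(1, 0)), "positive")
  expect_error(dmLogPmf(c(1.5, 0), c(1, 1)), "integer")
  expect_error(dmLogPmf(c(-1, 2), c(1, 1)), "integer")
})

test_that("dmLogPmf normalizes over all compositions", {
  # the corrected product term Gamma(y_j + gamma_j) is the one that sums
  # to one; checked by enumeration for J up to 4 and totals up to 6
  set.seed(5)
  for (J in 2:4) {
    for (yp in c(2, 4, 6)) {
      gamma <- runif(J, 0.2, 3)
      comps <- compositionsOf(yp, J)
      total <- sum(exp(apply(comps, 1, dmLogPmf, gamma = gamma)))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
})

test_that("dmLogPmf agrees with an independent brute-force evaluation", {
  set.seed(8)
  for (rep in 1:5) {
    J <- sample(2:5, 1)
    y <- sample(0:6, J, replace = TRUE)
    gamma <- runif(J, 0.1, 4)
    expect_equal(dmLogPmf(y, gamma), oracleDmLogPmf(y, gamma),
                 tolerance = 1e-12)
  }
})

test_that("DM variance inflates the multinomial variance by (y+ + g+)/(1 + g+)", {
  # exact first/second moments by enumeration at J = 2
  gamma <- c(1.3, 2.2)
  N <- 6
  comps <- compositionsOf(N, 2)
  pr <- exp(apply(comps, 1, dmLogPmf, gamma = gamma))
  m1 <- sum(comps[, 1] * pr)
  v_dm <- sum(comps[, 1]^2 * pr) - m1^2
  p <- gamma[1] / sum(gamma)
  v_mult <- N * p * (1 - p)
  expect_equal(v_dm, v_mult * (N + sum(gamma)) / (1 + sum(gamma)),
               tolerance = 1e-10)
})

test_that("dmLogPmf approaches the multinomial log pmf for large gamma", {
  y <- c(3, 1, 2)
  p <- c(0.5, 0.2, 0.3)
  expect_equal(dmLogPmf(y, p * 1e6),
               dmultinom(y, prob = p, log = TRUE), tolerance = 1e-3)
})

test_that("computeGamma implements the log-linear link", {
  X <- matrix(rnorm(6), 3, 2)
  # null model: all concentrations 1
  expect_equal(computeGamma(c(0, 0), matrix(0, 2, 2), X),
               matrix(1, 3, 2))
  # intercept-only rows
  expect_equal(computeGamma(log(c(2, 3)), matrix(0, 2, 2), X),
               matrix(rep(c(2, 3), each = 3), 3, 2))
  # single covariate arithmetic
  expect_equal(computeGamma(0, matrix(0.5, 1, 1), matrix(1, 1, 1))[1, 1],
               exp(0.5))
  expect_error(computeGamma(c(0, 0), matrix(0, 2, 2), matrix(0, 3, 3)),
               "ncol")
})

test_that("computeGamma clips extreme linear predictors", {
  g <- computeGamma(1000, matrix(0, 1, 1), matrix(0, 1, 1))
  expect_equal(g[1, 1], exp(50))
  g <- computeGamma(-1000, matrix(0, 1, 1), matrix(0, 1, 1))
  expect_equal(g[1, 1], exp(-50))
})

test_that("log-likelihood is additive and matches dmLogPmf at n = 1", {
  set.seed(11)
  X <- matrix(rnorm(3), 1, 3)
  Y <- matrix(c(4L, 1L, 0L, 2L), 1, 4)
  alpha <- rnorm(4); beta <- matrix(rnorm(12, sd = 0.3), 3, 4)
  gam <- computeGamma(alpha, beta, X)
  expect_equal(dmLogLikelihood(alpha, beta, Y, X), dmLogPmf(Y[1, ], gam[1, ]))
  # stacking identical rows doubles the log-likelihood
  expect_equal(dmLogLikelihood(alpha, beta, rbind(Y, Y), rbind(X, X)),
               2 * dmLogLikelihood(alpha, beta, Y, X))
})

test_that("incremental column update agrees with full recomputation", {
  set.seed(12)
  n <- 5; J <- 4; P <- 3
  X <- matrix(rnorm(n * P), n, P)
  Y <- matrix(rpois(n * J, 8), n, J)
  alpha <- rnorm(J); beta <- matrix(rnorm(P * J, sd = 0.4), P, J)
  gam <- computeGamma(alpha, beta, X)
  for (j in 1:J) {
    beta2 <- beta
    beta2[2, j] <- beta2[2, j] + 0.7
    gam2 <- computeGamma(alpha, beta2, X)
    full <- dmLogLikelihood(alpha, beta2, Y, X) -
      dmLogLikelihood(alpha, beta, Y, X)
    inc <- dmLogLikelihoodDelta(Y[, j], rowSums(Y), rowSums(gam),
                                gam[, j], gam2[, j])
    expect_equal(inc, full, tolerance = 1e-8)
  }
})

test_that("log prior matches its closed form and enforces coupling", {
  hyp <- DMHyperParams(slabVar = 10, interceptVar = 10, m = 0.01)
  J <- 3; P <- 4
  alpha <- rep(0, J)
  beta <- matrix(0, P, J); xi <- matrix(0L, P, J)
  expect_equal(dmLogPrior(alpha, beta, xi, hyp),
               J * dnorm(0, 0, sqrt(10), log = TRUE) + P * J * log(0.99))
  # one included coefficient adds its slab density and the log-odds term
  beta[2, 1] <- 0.5; xi[2, 1] <- 1L
  expect_equal(dmLogPrior(alpha, beta, xi, hyp),
               J * dnorm(0, 0, sqrt(10), log = TRUE) +
                 dnorm(0.5, 0, sqrt(10), log = TRUE) +
                 log(0.01) + (P * J - 1) * log(0.99))
  xi[2, 1] <- 0L
  expect_error(dmLogPrior(alpha, beta, xi, hyp), "coupling")
})

test_that("posterior density is invariant to consistent taxon permutation", {
  set.seed(13)
  n <- 6; J <- 5; P <- 2
  X <- matrix(rnorm(n * P), n, P)
  Y <- matrix(rpois(n * J, 10), n, J)
  alpha <- rnorm(J)
  xi <- matrix(rbinom(P * J, 1, 0.3), P, J)
  beta <- matrix(rnorm(P * J), P, J) * xi
  hyp <- DMHyperParams()
  perm <- sample(J)
  f0 <- dmLogLikelihood(alpha, beta, Y, X) + dmLogPrior(alpha, beta, xi, hyp)
  f1 <- dmLogLikelihood(alpha[perm], beta[, perm], Y[, perm], X) +
    dmLogPrior(alpha[perm], beta[, perm], xi[, perm], hyp)
  expect_equal(f1, f0)
})

test_that("hyperparameter construction follows the a + b = 2 convention", {
  h <- DMHyperParams(m = 0.01)
  expect_equal(h@a, 0.02)
  expect_equal(h@b, 1.98)
  expect_equal(priorInclusion(h), 0.01)
  h2 <- DMHyperParams(a = 1, b = 3)
  expect_equal(priorInclusion(h2), 0.25)
  expect_error(DMHyperParams(m = 1.2), "m")
  expect_error(DMHyperParams(slabVar = -1), "slabVar")
})
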