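# Pure log-density computations of the Dirichlet-Multinomial regression
# model. These are the reference (vectorized R) implementations; the sampler
# re-implements the incremental forms in compiled code for speed and the two
# are held together by tests.

# linear predictors are clipped to +/- ZETA_MAX before exponentiation so
# gamma stays inside [exp(-50), exp(50)]; inactive for standardized
# covariates and effects of realistic size.
ZETA_MAX <- 50

#' Dirichlet-Multinomial log probability mass
#'
#' Log pmf of the Dirichlet-Multinomial (compound multinomial) distribution
#' for one count vector y with concentration vector gamma:
#' \deqn{\log f(y \mid \gamma) = \log\Gamma(y_+ + 1) + \log\Gamma(\gamma_+) -
#'   \log\Gamma(y_+ + \gamma_+) + \sum_j [\log\Gamma(y_j + \gamma_j) -
#'   \log\Gamma(\gamma_j) - \log\Gamma(y_j + 1)]}
#' computed entirely in log-gamma space. Relative to the multinomial with
#' the same mean, the DM inflates the variance by the factor
#' (y_+ + gamma_+)/(1 + gamma_+).
#'
#' Some presentations misprint the product term as Gamma(y_j + gamma_+);
#' the form above, with Gamma(y_j + gamma_j), is the one that normalizes to
#' one over the compositions of y_+ and is what this package implements
#' throughout.
#'
#' @param y non-negative integer count vector of length J.
#' @param gamma strictly positive concentration vector of length J.
#' @return the log pmf, a single number.
#' @examples
#' dmLogPmf(c(1, 0), c(1, 1))   # log(0.5): uniform over two outcomes
#' @export
dmLogPmf <- function(y, gamma) {
  if (length(y) != length(gamma))
    stop("'y' and 'gamma' must have the same length")
  if (any(!is.finite(gamma)) || any(gamma <= 0))
    stop("'gamma' must be strictly positive")
  if (any(y < 0) || any(y != round(y)))
    stop("'y' must contain non-negative integers")
  yp <- sum(y)
  gp <- sum(gamma)
  lgamma(yp + 1) + lgamma(gp) - lgamma(yp + gp) +
    sum(lgamma(y + gamma) - lgamma(gamma) - lgamma(y + 1))
}

#' Concentration parameters from the log-linear link
#'
#' Computes `gamma[i, j] = exp(alpha_j + sum_p beta_pj x_ip)`, the DM
#' concentration of taxon j in sample i. Linear predictors are clipped to
#' +/- 50 before exponentiation as an overflow guard.
#'
#' @param alpha length-J intercept vector (log baseline concentration).
#' @param beta P x J coefficient matrix.
#' @param X n x P covariate matrix.
#' @return n x J matrix of strictly positive concentrations.
#' @examples
#' X <- matrix(c(1, -1), 2, 1)
#' computeGamma(alpha = 0, beta = matrix(0.5, 1, 1), X = X)
#' @export
computeGamma <- function(alpha, beta, X) {
  X <- as.matrix(X)
  beta <- as.matrix(beta)
  if (ncol(X) != nrow(beta))
    stop("ncol(X) must equal nrow(beta): ", ncol(X), " vs ", nrow(beta))
  if (length(alpha) != ncol(beta))
    stop("length(alpha) must equal ncol(beta)")
  zeta <- sweep(X %*% beta, 2, alpha, "+")
  exp(pmin(pmax(zeta, -ZETA_MAX), ZETA_MAX))
}

#' Dirichlet-Multinomial regression log-likelihood
#'
#' Sum over samples of [dmLogPmf()] at the concentrations implied by the
#' log-linear link.
#'
#' @param alpha,beta regression state (length-J vector, P x J matrix).
#' @param Y n x J count matrix (or a [DMExperiment-class]).
#' @param X n x P covariate matrix; ignored when `Y` is a `DMExperiment`.
#' @return total log-likelihood.
#' @export
dmLogLikelihood <- function(alpha, beta, Y, X = NULL) {
  if (is(Y, "DMExperiment")) {
    X <- covariateMatrix(Y)
    Y <- countMatrix(Y)
  }
  Y <- as.matrix(Y)
  gam <- computeGamma(alpha, beta, X)
  if (!identical(dim(gam), dim(Y)))
    stop("count and covariate tables are not paired: gamma is ",
         nrow(gam), " x ", ncol(gam), ", Y is ", nrow(Y), " x ", ncol(Y))
  yp <- rowSums(Y)
  gp <- rowSums(gam)
  sum(lgamma(yp + 1) + lgamma(gp) - lgamma(yp + gp)) +
    sum(lgamma(Y + gam) - lgamma(gam) - lgamma(Y + 1))
}

#' Incremental log-likelihood change for one taxon column
#'
#' Change in the total log-likelihood when the concentration column of a
#' single taxon j moves from `gammaOldJ` to `gammaNewJ` while all other
#' columns stay fixed. Only the taxon-j terms and the row-total terms are
#' recomputed; this is the performance contract the sampler's inner loop
#' relies on, and it agrees with a full recomputation to floating-point
#' accuracy.
#'
#' @param yJ length-n counts of taxon j.
#' @param yPlus length-n row totals y_i+.
#' @param gammaPlus length-n current concentration row totals.
#' @param gammaOldJ,gammaNewJ length-n current and proposed concentrations
#'   of taxon j.
#' @return the log-likelihood difference (new minus old).
#' @export
dmLogLikelihoodDelta <- function(yJ, yPlus, gammaPlus, gammaOldJ, gammaNewJ) {
  gpNew <- gammaPlus - gammaOldJ + gammaNewJ
  sum(lgamma(gpNew) - lgamma(yPlus + gpNew) -
      lgamma(gammaPlus) + lgamma(yPlus + gammaPlus) +
      lgamma(yJ + gammaNewJ) - lgamma(gammaNewJ) -
      lgamma(yJ + gammaOldJ) + lgamma(gammaOldJ))
}

#' Joint log-prior of the regression state
#'
#' Log density of (alpha, beta, xi) under the spike-and-slab prior: normal
#' N(0, s^2) intercepts; for each association, Bernoulli(m) inclusion (the
#' Beta(a, b) hyperprior on the inclusion probability integrated out, with
#' m = a/(a+b)) and, when included, a N(0, r^2) slab on the coefficient.
#'
#' @param alpha length-J intercepts.
#' @param beta P x J coefficients.
#' @param xi P x J 0/1 inclusion indicators; must satisfy the coupling
#'   `xi == 0  <=>  beta == 0`.
#' @param hyper a [DMHyperParams-class].
#' @return the log prior density (Dirac spike mass counted as log(1 - m)).
#' @export
dmLogPrior <- function(alpha, beta, xi, hyper) {
  beta <- as.matrix(beta)
  xi <- as.matrix(xi)
  if (!identical(dim(beta), dim(xi)))
    stop("'beta' and 'xi' must have the same shape")
  if (any((xi == 0) != (beta == 0)))
    stop("spike-and-slab coupling violated: beta must be 0 exactly when xi is 0")
  J <- length(alpha)
  s2 <- rep_len(hyper@interceptVar, J)
  r2 <- rep_len(hyper@slabVar, J)
  m <- priorInclusion(hyper)
  inc <- xi == 1
  r2m <- matrix(r2, nrow(beta), J, byrow = TRUE)
  sum(dnorm(alpha, 0, sqrt(s2), log = TRUE)) +
    sum(dnorm(beta[inc], 0, sqrt(r2m[inc]), log = TRUE)) +
    sum(inc) * log(m) + sum(!inc) * log(1 - m)
}
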