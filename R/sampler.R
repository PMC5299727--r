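#' Fit the Dirichlet-Multinomial regression by stochastic-search MCMC
#'
#' Runs the Metropolis-within-Gibbs sampler: a symmetric random-walk
#' Metropolis update of each taxon intercept alpha_j, followed by a Gibbs
#' scan over every (covariate, taxon) pair that proposes delete moves for
#' included coefficients and add moves — with the coefficient drawn from a
#' component-wise adaptive two-component normal mixture — for excluded
#' ones. The proposal variance of each coefficient is adapted with a
#' recursive (Welford) estimate over all its previous post-scan values,
#' zeros included; a small fixed mixture component keeps the chain
#' irreducible regardless of the adapted estimate.
#'
#' The chain is initialized at the empty model (all `xi = 0`) with
#' data-informed intercepts `alpha_j = log(J * mean_i(y_ij) / mean_i(y_i+))`
#' (0 for all-zero taxa), which shortens burn-in relative to a cold start.
#' Runs are deterministic given `control@seed`.
#'
#' Only add/delete moves are made: an included coefficient's value changes
#' by being deleted and re-added. Covariates should be standardized
#' ([standardizeCovariates()]) so that the default intercept step and
#' effect-size priors are on the intended scale; a warning is emitted
#' otherwise.
#'
#' @param x a [DMExperiment-class] pairing counts with covariates.
#' @param hyper a [DMHyperParams-class]; default `DMHyperParams()`.
#' @param control a [DMSamplerControl-class]; default `DMSamplerControl()`.
#' @param priorOnly logical; if `TRUE` the likelihood term is dropped and
#'   the sampler targets the prior alone (used to validate the sampler
#'   against the known prior).
#' @param verbose print progress and acceptance rates.
#' @return a [DMChain-class].
#' @examples
#' sim <- simulateDMData(n = 30, P = 4, J = 5, nRelevantCovariates = 2,
#'                       nRelevantTaxa = 2, nAssoc = 3, seed = 7)
#' ch <- fitDMRegression(sim$data,
#'                       control = DMSamplerControl(nIterations = 200,
#'                                                  thin = 2, seed = 7))
#' ch
#' @export
fitDMRegression <- function(x, hyper = DMHyperParams(),
                            control = DMSamplerControl(),
                            priorOnly = FALSE, verbose = FALSE) {
  stopifnot(is(x, "DMExperiment"), is(hyper, "DMHyperParams"),
            is(control, "DMSamplerControl"))
  validObject(x); validObject(hyper); validObject(control)
  Y <- countMatrix(x)
  X <- covariateMatrix(x)
  if (ncol(X) < 1) stop("at least one covariate is required")
  zero_rows <- rowSums(Y) == 0
  if (any(zero_rows))
    stop("sample(s) with all-zero counts: ",
         paste(rownames(Y)[zero_rows], collapse = ", "))
  if (!isStandardized(x) && !priorOnly)
    warning("covariates are not flagged as standardized; ",
            "consider standardizeCovariates()")

  n <- nrow(Y); J <- ncol(Y); P <- ncol(X)
  s2 <- rep_len(hyper@interceptVar, J)
  r2 <- rep_len(hyper@slabVar, J)
  m <- priorInclusion(hyper)

  prop <- colMeans(Y) / mean(rowSums(Y))
  alpha_init <- ifelse(prop > 0, log(prop * J), 0)
  if (priorOnly) alpha_init <- rep(0, J)

  set.seed(control@seed)
  res <- .dm_mcmc_cpp(
    Y = Y, X = X, s2 = s2, r2 = r2, m = m, alpha_init = alpha_init,
    n_iter = control@nIterations, thin = control@thin,
    t_alpha = control@alphaStepSd,
    adapt_scale_const = control@adaptScaleConst,
    adapt_mix_weight = control@adaptMixWeight,
    adapt_fixed_const = control@adaptFixedConst,
    adapt_start = control@adaptStart, var_floor = control@varFloor,
    random_scan = control@randomScan, use_likelihood = !priorOnly,
    refresh_included = control@refreshIncluded)

  dimnames(res$alpha) <- list(NULL, colnames(Y))
  dimnames(res$beta) <- list(NULL, colnames(X), colnames(Y))
  dimnames(res$xi) <- dimnames(res$beta)
  acc <- c(alpha = res$acc_alpha, add = res$acc_add, delete = res$acc_delete)
  if (verbose)
    message(sprintf(
      "chain: %d stored draws; acceptance alpha=%.3f add=%.4f delete=%.3f",
      nrow(res$alpha), acc["alpha"], acc["add"], acc["delete"]))
  new("DMChain", alphaDraws = res$alpha, betaDraws = res$beta,
      xiDraws = res$xi, logPostTrace = as.numeric(res$log_post),
      modelSizeTrace = as.numeric(res$model_size), acceptance = acc,
      adaptedVar = res$adapted_var, control = control, hyper = hyper)
}

#' Geweke convergence z-score
#'
#' Compares the mean of an early chain segment with the mean of a late
#' segment: `z = (mean_first - mean_last) / sqrt(se1^2 + se2^2)`. Standard
#' errors account for autocorrelation through batch means with
#' `floor(sqrt(T))` batches per segment. |z| well above 2 flags a trend,
#' i.e. a chain that has not reached its stationary regime. Typically
#' applied to the model-size trace and to the traces of selected
#' coefficients.
#'
#' @param trace numeric vector of draws (length >= 20).
#' @param fracFirst,fracLast fractions of the chain forming the early and
#'   late segments (defaults 0.1 and 0.5).
#' @return a single z value; 0 with a warning for a constant trace.
#' @examples
#' set.seed(1)
#' gewekeZ(rnorm(5000))      # near 0 for a stationary trace
#' gewekeZ(seq_len(1000))    # very large for a trend
#' @export
gewekeZ <- function(trace, fracFirst = 0.1, fracLast = 0.5) {
  trace <- as.numeric(trace)
  T <- length(trace)
  if (T < 20) stop("trace must have at least 20 draws")
  if (sd(trace) == 0) {
    warning("constant trace; Geweke z defined as 0")
    return(0)
  }
  first <- trace[seq_len(max(1, floor(fracFirst * T)))]
  last <- trace[seq.int(T - max(1, floor(fracLast * T)) + 1, T)]
  bm_se <- function(x) {
    nb <- max(2L, floor(sqrt(length(x))))
    bs <- length(x) %/% nb
    bm <- vapply(seq_len(nb), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                 numeric(1))
    sd(bm) / sqrt(nb)
  }
  se1 <- bm_se(first); se2 <- bm_se(last)
  if (se1 == 0 && se2 == 0) {
    warning("zero batch-mean variance in both segments; Geweke z defined as 0")
    return(0)
  }
  (mean(first) - mean(last)) / sqrt(se1^2 + se2^2)
}

#' Convergence summary of a chain
#'
#' Geweke z for the model-size trace and the five-number summary of the
#' Geweke z-scores of the coefficient traces selected by the median model.
#'
#' @param chain a [DMChain-class].
#' @param burnIn stored draws to discard; default [defaultBurnIn()].
#' @return list with `modelSizeZ` and `betaZFiveNum` (named numeric vector,
#'   `NULL` when nothing is selected).
#' @export
convergenceSummary <- function(chain, burnIn = defaultBurnIn(chain)) {
  keep <- seq.int(burnIn + 1L, nDraws(chain))
  msz <- gewekeZ(modelSizeTrace(chain)[keep])
  ppi <- computePPI(chain, burnIn = burnIn)
  sel <- which(medianModel(ppi) == 1, arr.ind = TRUE)
  bz <- NULL
  if (nrow(sel) > 0) {
    zs <- apply(sel, 1, function(idx)
      suppressWarnings(gewekeZ(betaDraws(chain)[keep, idx[1], idx[2]])))
    bz <- setNames(quantile(zs, c(0, 0.25, 0.5, 0.75, 1)),
                   c("min", "q1", "median", "q3", "max"))
  }
  list(modelSizeZ = msz, betaZFiveNum = bz)
}
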