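#' @importFrom methods new validObject is setClass setGeneric setMethod
#'   setValidity slot callNextMethod as show
#' @importFrom stats dnorm rnorm runif var median sd quantile rmultinom
#'   rgamma cor hclust cutree as.dist setNames
#' @importFrom utils head read.delim write.table
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @useDynLib DMVarSel, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Taxa counts paired with sample covariates
#'
#' `DMExperiment` couples a taxa abundance count table with a sample-level
#' covariate matrix, the two inputs of the Dirichlet-Multinomial regression
#' model. It extends [SummarizedExperiment::SummarizedExperiment] with taxa
#' as rows (features) and samples as columns; covariates live in `colData`.
#'
#' Counts must be non-negative integers with at least two taxa and unique
#' taxon names; covariates must be numeric and finite, in the same sample
#' order as the count columns.
#'
#' @slot standardized logical flag; `TRUE` once covariate columns have been
#'   mean-centred and scaled to unit sample variance (see
#'   [standardizeCovariates()]).
#'
#' @seealso [DMExperiment()] the constructor, [covariateMatrix()],
#'   [countMatrix()]
#' @export
setClass("DMExperiment",
  contains = "SummarizedExperiment",
  slots = c(standardized = "logical"),
  prototype = prototype(standardized = FALSE)
)

setValidity("DMExperiment", function(object) {
  msg <- character()
  if (!("counts" %in% assayNames(object))) {
    msg <- c(msg, "assay 'counts' is required")
  } else {
    y <- assay(object, "counts")
    if (any(!is.finite(y))) msg <- c(msg, "counts must be finite")
    else {
      if (any(y < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(y != round(y))) msg <- c(msg, "counts must be integers")
    }
    if (nrow(y) < 2) msg <- c(msg, "at least two taxa are required")
    if (anyDuplicated(rownames(y))) msg <- c(msg, "taxon names must be unique")
  }
  cd <- colData(object)
  if (ncol(cd) > 0) {
    numeric_ok <- vapply(seq_len(ncol(cd)), function(k) {
      is.numeric(cd[[k]]) && all(is.finite(cd[[k]]))
    }, logical(1))
    if (!all(numeric_ok)) {
      msg <- c(msg, sprintf("covariates must be numeric and finite (check '%s')",
                            colnames(cd)[which(!numeric_ok)[1]]))
    }
  }
  if (length(object@standardized) != 1L) msg <- c(msg, "'standardized' must be a single flag")
  if (length(msg)) msg else TRUE
})

#' Construct a DMExperiment
#'
#' @param counts numeric matrix of non-negative integer counts, samples in
#'   rows and taxa in columns (the usual orientation of an OTU/taxa table on
#'   disk). Row names are sample IDs, column names taxon IDs.
#' @param covariates numeric matrix or data frame of sample-level covariates,
#'   samples in rows (same order as `counts`), covariates in columns.
#' @param standardized logical; set `TRUE` if `covariates` are already
#'   mean-centred with unit sample variance.
#'
#' @return a [DMExperiment-class] object (taxa x samples internally).
#' @examples
#' y <- matrix(rpois(20, 5), 4, 5,
#'             dimnames = list(paste0("s", 1:4), paste0("taxon", 1:5)))
#' x <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("age", "bmi")))
#' DMExperiment(y, x)
#' @export
DMExperiment <- function(counts, covariates, standardized = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(counts))
    stop("'counts' and 'covariates' must describe the same samples (",
         nrow(counts), " vs ", nrow(covariates), " rows)")
  if (ncol(covariates) > 0 && is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  se <- SummarizedExperiment(
    assays = list(counts = t(counts)),
    colData = DataFrame(covariates, row.names = rownames(counts))
  )
  new("DMExperiment", se, standardized = isTRUE(standardized))
}

#' Hyperparameters of the spike-and-slab DM regression prior
#'
#' Holds the slab variance r^2 of the non-zero regression coefficients, the
#' intercept prior variance s^2, and the Beta(a, b) hyperprior on the
#' per-association inclusion probabilities. Each inclusion probability
#' governs a single Bernoulli indicator, so the Beta hyperprior integrates
#' out analytically to independent Bernoulli(m) indicators with prior mean
#' inclusion m = a / (a + b); no inclusion probability is ever sampled.
#'
#' @slot slabVar numeric, slab variance r^2 (scalar, or one value per taxon).
#' @slot interceptVar numeric, intercept prior variance s^2 (scalar or per
#'   taxon).
#' @slot a,b numeric, Beta hyperprior parameters.
#' @seealso [DMHyperParams()], [priorInclusion()]
#' @export
setClass("DMHyperParams",
  slots = c(slabVar = "numeric", interceptVar = "numeric",
            a = "numeric", b = "numeric"))

setValidity("DMHyperParams", function(object) {
  msg <- character()
  if (any(object@slabVar <= 0)) msg <- c(msg, "slabVar must be > 0")
  if (any(object@interceptVar <= 0)) msg <- c(msg, "interceptVar must be > 0")
  if (object@a <= 0 || object@b <= 0) msg <- c(msg, "a and b must be > 0")
  m <- object@a / (object@a + object@b)
  if (m <= 0 || m >= 1) msg <- c(msg, "prior mean inclusion must lie in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Construct prior hyperparameters
#'
#' Defaults follow the vague specification used throughout: slab and
#' intercept variances of 10 and a sparse prior mean inclusion of 1%
#' (a = 0.02, b = 1.98, so a + b = 2). Supply either `m` (giving a = 2m,
#' b = 2(1 - m)) or `a` and `b` directly.
#'
#' @param slabVar slab variance r^2 for included coefficients; scalar or one
#'   value per taxon.
#' @param interceptVar prior variance s^2 of the taxon intercepts.
#' @param m prior mean inclusion probability in (0, 1); ignored when `a` and
#'   `b` are given.
#' @param a,b Beta hyperprior parameters (optional alternative to `m`).
#' @return a [DMHyperParams-class] object.
#' @examples
#' DMHyperParams()                 # r2 = s2 = 10, m = 0.01
#' DMHyperParams(slabVar = 1, m = 0.05)
#' DMHyperParams(a = 1, b = 9)     # m = 0.1 without the a + b = 2 convention
#' @export
DMHyperParams <- function(slabVar = 10, interceptVar = 10, m = 0.01,
                          a = NULL, b = NULL) {
  if (is.null(a) != is.null(b))
    stop("supply both 'a' and 'b', or neither")
  if (is.null(a)) {
    if (m <= 0 || m >= 1) stop("'m' must lie in (0, 1)")
    a <- 2 * m
    b <- 2 * (1 - m)
  }
  new("DMHyperParams", slabVar = slabVar, interceptVar = interceptVar,
      a = a, b = b)
}

#' @describeIn DMHyperParams prior mean inclusion probability m = a/(a+b).
#' @param object a `DMHyperParams` object.
#' @export
priorInclusion <- function(object) object@a / (object@a + object@b)

#' Sampler settings
#'
#' Settings of the Metropolis-within-Gibbs sampler: chain length, thinning,
#' burn-in (counted in post-thinning draws), the random-walk step for the
#' intercepts, and the constants of the component-wise adaptive proposal.
#' The adaptive proposal for a coefficient beta_pj is the two-component
#' normal mixture
#' `w N(beta, 2.38^2 sigma2_pj P/J) + (1 - w) N(beta, 0.01 P/J)`
#' with `w = adaptMixWeight` and `sigma2_pj` a recursively updated estimate
#' of the marginal posterior variance of beta_pj; the `P/J` factor (one for
#' square problems) comes from reading the scaling constants of the
#' component-wise mixture literally. Until `adaptStart` draws have
#' accumulated only the small fixed component is used.
#'
#' @slot nIterations total MCMC iterations.
#' @slot thin keep every `thin`-th state.
#' @slot burnIn number of stored (thinned) draws to discard; `NA` means half.
#' @slot seed integer seed for the run.
#' @slot alphaStepSd random-walk sd t_alpha for intercept proposals.
#' @slot adaptScaleConst scale constant of the adapted component (2.38^2).
#' @slot adaptMixWeight weight of the adapted component (0.95).
#' @slot adaptFixedConst numerator of the fixed component variance (0.01).
#' @slot adaptStart draws required before the adapted variance is used.
#' @slot varFloor lower bound on the adapted variance estimate.
#' @slot randomScan permute the (p, j) scan order each iteration instead of
#'   the fixed row-major order.
#' @slot refreshIncluded add a symmetric random-walk refresh move for
#'   included coefficients after each add/delete proposal (default `TRUE`).
#'   Without it included coefficients can only change value through
#'   delete-then-add cycles, which are essentially never accepted for
#'   well-supported coefficients; correlated null covariates then freeze in
#'   as false positives. Set `FALSE` for the plain add/delete scheme.
#' @seealso [DMSamplerControl()], [fitDMRegression()]
#' @export
setClass("DMSamplerControl",
  slots = c(nIterations = "integer", thin = "integer", burnIn = "integer",
            seed = "integer", alphaStepSd = "numeric",
            adaptScaleConst = "numeric", adaptMixWeight = "numeric",
            adaptFixedConst = "numeric", adaptStart = "integer",
            varFloor = "numeric", randomScan = "logical",
            refreshIncluded = "logical"))

setValidity("DMSamplerControl", function(object) {
  msg <- character()
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (object@thin < 1L || object@thin > object@nIterations)
    msg <- c(msg, "thin must lie in [1, nIterations]")
  if (!is.na(object@burnIn) &&
      object@burnIn >= object@nIterations %/% object@thin)
    msg <- c(msg, "burnIn must be smaller than the number of stored draws")
  if (object@alphaStepSd < 0) msg <- c(msg, "alphaStepSd must be >= 0")
  if (object@adaptMixWeight <= 0 || object@adaptMixWeight >= 1)
    msg <- c(msg, "adaptMixWeight must lie in (0,1)")
  if (object@varFloor <= 0) msg <- c(msg, "varFloor must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct sampler settings
#'
#' Defaults mirror the reference protocol: 10,000 iterations thinned to
#' every fifth, half the stored draws discarded as burn-in, and the
#' adaptive-mixture constants 2.38^2, 0.95/0.05 and 0.01.
#'
#' @param nIterations total iterations (default 10000).
#' @param thin thinning interval (default 5).
#' @param burnIn stored draws to discard; `NA` (default) discards the first
#'   half.
#' @param seed integer seed.
#' @param alphaStepSd random-walk sd for the intercept update (default 0.5,
#'   tuned for standardized covariates).
#' @param adaptScaleConst,adaptMixWeight,adaptFixedConst,adaptStart,varFloor
#'   adaptive-proposal constants; see [DMSamplerControl-class].
#' @param randomScan logical; permute the scan order each iteration.
#' @param refreshIncluded logical; within-model refresh move for included
#'   coefficients (default `TRUE`; see [DMSamplerControl-class]).
#' @return a [DMSamplerControl-class] object.
#' @examples
#' DMSamplerControl(nIterations = 5000, thin = 5, seed = 11)
#' @export
DMSamplerControl <- function(nIterations = 10000, thin = 5, burnIn = NA,
                             seed = 1, alphaStepSd = 0.5,
                             adaptScaleConst = 2.38^2, adaptMixWeight = 0.95,
                             adaptFixedConst = 0.01, adaptStart = 100,
                             varFloor = 1e-6, randomScan = FALSE,
                             refreshIncluded = TRUE) {
  new("DMSamplerControl",
      nIterations = as.integer(nIterations), thin = as.integer(thin),
      burnIn = as.integer(burnIn), seed = as.integer(seed),
      alphaStepSd = alphaStepSd, adaptScaleConst = adaptScaleConst,
      adaptMixWeight = adaptMixWeight, adaptFixedConst = adaptFixedConst,
      adaptStart = as.integer(adaptStart), varFloor = varFloor,
      randomScan = isTRUE(randomScan),
      refreshIncluded = isTRUE(refreshIncluded))
}

#' Posterior chain of the DM regression sampler
#'
#' Thinned draws of the intercepts alpha (T x J), coefficients beta and
#' inclusion indicators xi (T x P x J arrays), the joint log-posterior trace,
#' the model-size trace (number of included associations per stored draw),
#' acceptance rates, and the final adapted proposal variances. Every stored
#' state satisfies the spike-and-slab coupling `xi == 0  <=>  beta == 0`.
#'
#' @slot alphaDraws T x J matrix.
#' @slot betaDraws,xiDraws T x P x J arrays.
#' @slot logPostTrace,modelSizeTrace length-T numeric vectors.
#' @slot acceptance named numeric vector (alpha / add / delete rates).
#' @slot adaptedVar P x J matrix of final recursive variance estimates.
#' @slot control the [DMSamplerControl-class] used.
#' @slot hyper the [DMHyperParams-class] used.
#' @seealso [fitDMRegression()], [computePPI()], [gewekeZ()]
#' @export
setClass("DMChain",
  slots = c(alphaDraws = "matrix", betaDraws = "array", xiDraws = "array",
            logPostTrace = "numeric", modelSizeTrace = "numeric",
            acceptance = "numeric", adaptedVar = "matrix",
            control = "DMSamplerControl", hyper = "DMHyperParams"))

setValidity("DMChain", function(object) {
  msg <- character()
  dB <- dim(object@betaDraws)
  if (length(dB) != 3L) msg <- c(msg, "betaDraws must be a T x P x J array")
  if (!identical(dim(object@xiDraws), dB))
    msg <- c(msg, "xiDraws must match betaDraws in shape")
  else if (any((object@xiDraws == 0) != (object@betaDraws == 0)))
    msg <- c(msg, "spike-and-slab coupling violated: beta must be 0 exactly when xi is 0")
  if (length(object@logPostTrace) != dB[1] ||
      length(object@modelSizeTrace) != dB[1])
    msg <- c(msg, "traces must have one entry per stored draw")
  if (length(msg)) msg else TRUE
})

#' Selection summary from a posterior chain
#'
#' @slot ppi P x J matrix of marginal posterior probabilities of inclusion.
#' @slot threshold PPI threshold c used for selection.
#' @slot method `"median"` or `"fdr"`.
#' @slot selected P x J 0/1 matrix, 1 where `ppi > threshold`.
#' @slot fdrEstimate estimated Bayesian FDR of the selected set.
#' @slot betaCondMean,betaCondMedian P x J conditional (on inclusion)
#'   posterior mean / median of beta; 0 for never-included pairs.
#' @slot betaMargMean P x J marginal posterior mean (zeros included).
#' @seealso [selectAssociations()], [bayesianFDR()], [fdrThreshold()]
#' @export
setClass("DMSelection",
  slots = c(ppi = "matrix", threshold = "numeric", method = "character",
            selected = "matrix", fdrEstimate = "numeric",
            betaCondMean = "matrix", betaCondMedian = "matrix",
            betaMargMean = "matrix"))

#' Ground truth of a simulated dataset
#'
#' @slot alphaTrue length-J intercepts.
#' @slot betaTrue,xiTrue P x J coefficient and indicator matrices.
#' @slot piStar n x J matrix of realized Dirichlet probability rows.
#' @slot gammaStar n x J matrix of Dirichlet concentration parameters.
#' @slot depths length-n sequencing depths N_i.
#' @slot psi overdispersion parameter used.
#' @seealso [simulateDMData()]
#' @export
setClass("DMSimTruth",
  slots = c(alphaTrue = "numeric", betaTrue = "matrix", xiTrue = "matrix",
            piStar = "matrix", gammaStar = "matrix", depths = "integer",
            psi = "numeric"))
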