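#' Count matrix in samples-by-taxa orientation
#'
#' Returns the taxa count table as an n x J matrix (samples in rows), the
#' orientation used by the model formulas. The underlying assay stores taxa
#' as rows per SummarizedExperiment convention; this accessor transposes.
#'
#' @param object a [DMExperiment-class].
#' @return n x J integer matrix with sample and taxon dimnames.
#' @export
countMatrix <- function(object) {
  stopifnot(is(object, "DMExperiment"))
  t(assay(object, "counts"))
}

#' Covariate matrix
#'
#' @param object a [DMExperiment-class].
#' @return n x P numeric matrix of covariates (possibly empty with P = 0).
#' @export
covariateMatrix <- function(object) {
  stopifnot(is(object, "DMExperiment"))
  cd <- colData(object)
  m <- as.matrix(as.data.frame(cd))
  if (ncol(cd) == 0L)
    m <- matrix(numeric(0), nrow = ncol(object), ncol = 0)
  rownames(m) <- colnames(object)
  m
}

#' @describeIn countMatrix row totals y_i+ (per-sample sequencing depth).
#' @export
sampleDepths <- function(object) rowSums(countMatrix(object))

#' @describeIn countMatrix whether covariates are standardized.
#' @export
isStandardized <- function(object) object@standardized

setMethod("show", "DMExperiment", function(object) {
  callNextMethod()
  cat("covariates(", ncol(colData(object)), "): ",
      paste(head(colnames(colData(object)), 6), collapse = ", "),
      if (ncol(colData(object)) > 6) ", ..." else "", "\n",
      "standardized: ", object@standardized, "\n", sep = "")
})

setMethod("show", "DMHyperParams", function(object) {
  cat("DMHyperParams\n",
      "  slab variance r2: ", paste(unique(object@slabVar), collapse = ", "), "\n",
      "  intercept variance s2: ", paste(unique(object@interceptVar), collapse = ", "), "\n",
      "  Beta(a, b) on inclusion: a = ", object@a, ", b = ", object@b,
      "  (prior mean inclusion m = ", signif(priorInclusion(object), 4), ")\n",
      sep = "")
})

setMethod("show", "DMSamplerControl", function(object) {
  cat("DMSamplerControl: ", object@nIterations, " iterations, thin ",
      object@thin, ", burn-in ",
      if (is.na(object@burnIn)) "half of stored draws" else object@burnIn,
      ", seed ", object@seed, "\n",
      "  alpha step sd ", object@alphaStepSd, "; adaptive mixture ",
      object@adaptMixWeight, " x ", round(object@adaptScaleConst, 3),
      " sigma2/(JP) + ", signif(1 - object@adaptMixWeight, 3), " x ",
      object@adaptFixedConst, "/(JP), adapt start ", object@adaptStart, "\n",
      sep = "")
})

#' Number of stored draws in a chain
#' @param object a [DMChain-class].
#' @return integer count of thinned stored states.
#' @export
nDraws <- function(object) dim(object@betaDraws)[1]

#' Draw accessors
#'
#' Extract stored draws from a [DMChain-class]: `alphaDraws` (T x J),
#' `betaDraws` and `xiDraws` (T x P x J), `modelSizeTrace` and
#' `logPostTrace` (length T), and `acceptanceRates`.
#'
#' @param object a [DMChain-class].
#' @name chain-accessors
NULL

#' @rdname chain-accessors
#' @export
alphaDraws <- function(object) object@alphaDraws

#' @rdname chain-accessors
#' @export
betaDraws <- function(object) object@betaDraws

#' @rdname chain-accessors
#' @export
xiDraws <- function(object) object@xiDraws

#' @rdname chain-accessors
#' @export
modelSizeTrace <- function(object) object@modelSizeTrace

#' @rdname chain-accessors
#' @export
logPostTrace <- function(object) object@logPostTrace

#' @rdname chain-accessors
#' @export
acceptanceRates <- function(object) object@acceptance

#' Default burn-in of a chain
#'
#' Stored draws to discard before summarizing: the chain's `burnIn` setting,
#' or half the stored draws when that was `NA`.
#'
#' @param object a [DMChain-class].
#' @return integer number of leading stored draws to drop.
#' @export
defaultBurnIn <- function(object) {
  b <- object@control@burnIn
  if (is.na(b)) nDraws(object) %/% 2L else as.integer(b)
}

setMethod("show", "DMChain", function(object) {
  d <- dim(object@betaDraws)
  cat("DMChain: ", d[1], " stored draws (thin ", object@control@thin,
      "), P = ", d[2], " covariates x J = ", d[3], " taxa\n",
      "  model size: median ", median(object@modelSizeTrace),
      " [", min(object@modelSizeTrace), ", ", max(object@modelSizeTrace), "]\n",
      "  acceptance: alpha ", signif(object@acceptance["alpha"], 3),
      ", add ", signif(object@acceptance["add"], 3),
      ", delete ", signif(object@acceptance["delete"], 3), "\n", sep = "")
})

setMethod("show", "DMSelection", function(object) {
  cat("DMSelection (", object@method, " rule, threshold c = ",
      signif(object@threshold, 4), ")\n",
      "  selected associations: ", sum(object@selected),
      " of ", length(object@selected), "\n",
      "  estimated Bayesian FDR: ", signif(object@fdrEstimate, 4), "\n",
      sep = "")
})

setMethod("show", "DMSimTruth", function(object) {
  cat("DMSimTruth: ", length(object@alphaTrue), " taxa, ",
      nrow(object@betaTrue), " covariates, ",
      sum(object@xiTrue), " true associations, psi = ", object@psi, "\n",
      sep = "")
})
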