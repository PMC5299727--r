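# Posterior summaries: PPIs, median probability model, Bayesian FDR.

#' Marginal posterior probabilities of inclusion
#'
#' The PPI of association (p, j) is the proportion of retained draws in
#' which its indicator xi_pj equals 1.
#'
#' @param chain a [DMChain-class].
#' @param burnIn leading stored draws to discard (default [defaultBurnIn()]).
#' @return P x J matrix of PPIs in \[0, 1\].
#' @export
computePPI <- function(chain, burnIn = defaultBurnIn(chain)) {
  T <- nDraws(chain)
  if (burnIn < 0 || burnIn >= T)
    stop("burnIn must leave at least one retained draw (T = ", T, ")")
  keep <- seq.int(burnIn + 1L, T)
  ppi <- apply(xiDraws(chain)[keep, , , drop = FALSE], c(2, 3), mean)
  dimnames(ppi) <- dimnames(xiDraws(chain))[2:3]
  ppi
}

#' Median probability model
#'
#' Selects the associations whose PPI strictly exceeds 0.5. Ties at exactly
#' 0.5 are excluded (strict "greater than").
#'
#' @param ppi P x J matrix of PPIs.
#' @return P x J 0/1 matrix.
#' @export
medianModel <- function(ppi) {
  stopifnot(all(ppi >= 0 & ppi <= 1))
  (ppi > 0.5) + 0L
}

#' Bayesian false discovery rate of a PPI threshold
#'
#' For the selected set `D = 1(ppi > c)`, the estimated Bayesian FDR is
#' `sum((1 - ppi) * D) / sum(D)` — the average posterior probability of
#' exclusion among the selections.
#'
#' @param ppi P x J matrix of PPIs.
#' @param c threshold in \[0, 1).
#' @return the estimated FDR; 0 with attribute `empty = TRUE` when nothing
#'   exceeds the threshold.
#' @examples
#' bayesianFDR(c(0.9, 0.8, 0.1), c = 0.5)  # (0.1 + 0.2) / 2 = 0.15
#' @export
bayesianFDR <- function(ppi, c) {
  stopifnot(c >= 0, c < 1)
  D <- ppi > c
  if (!any(D)) return(structure(0, empty = TRUE))
  sum((1 - ppi[D])) / sum(D)
}

#' Optimal PPI threshold for a target Bayesian FDR
#'
#' Finds the smallest threshold c — and hence the largest selected set —
#' with estimated Bayesian FDR below `alphaLevel`. Because the FDR estimate
#' is piecewise constant in c, the search is exact over the grid of 0 and
#' the observed PPI values.
#'
#' @param ppi matrix (or vector) of PPIs.
#' @param alphaLevel target FDR level in (0, 1).
#' @return the threshold `c`, with attributes `fdr` (its estimated FDR),
#'   `nSelected`, and `attained` (`FALSE` when no threshold meets the level,
#'   in which case the maximum PPI is returned and nothing is selected).
#' @export
fdrThreshold <- function(ppi, alphaLevel) {
  stopifnot(alphaLevel > 0, alphaLevel < 1)
  grid <- sort(unique(c(0, as.numeric(ppi))))
  for (c in grid) {
    f <- bayesianFDR(ppi, c)
    if (!isTRUE(attr(f, "empty")) && f < alphaLevel) {
      return(structure(c, fdr = as.numeric(f), nSelected = sum(ppi > c),
                       attained = TRUE))
    }
  }
  structure(max(ppi), fdr = NA_real_, nSelected = 0L, attained = FALSE)
}

#' Posterior coefficient summaries
#'
#' Conditional summaries average the draws of beta_pj over the iterations
#' in which the association is included (0 when never included); marginal
#' summaries average over all retained draws, zeros included.
#'
#' @param chain a [DMChain-class].
#' @param burnIn leading stored draws to discard.
#' @param conditional logical; condition on inclusion (default) or not.
#' @return list of P x J matrices `mean` and `median`.
#' @export
betaSummaries <- function(chain, burnIn = defaultBurnIn(chain),
                          conditional = TRUE) {
  T <- nDraws(chain)
  if (burnIn < 0 || burnIn >= T) stop("burnIn must leave retained draws")
  keep <- seq.int(burnIn + 1L, T)
  b <- betaDraws(chain)[keep, , , drop = FALSE]
  if (conditional) {
    xi <- xiDraws(chain)[keep, , , drop = FALSE]
    stat <- function(f) {
      out <- matrix(0, dim(b)[2], dim(b)[3], dimnames = dimnames(b)[2:3])
      for (p in seq_len(dim(b)[2])) for (j in seq_len(dim(b)[3])) {
        inc <- xi[, p, j] == 1
        if (any(inc)) out[p, j] <- f(b[inc, p, j])
      }
      out
    }
    list(mean = stat(mean), median = stat(median))
  } else {
    list(mean = apply(b, c(2, 3), mean), median = apply(b, c(2, 3), median))
  }
}

#' Select associations from a fitted chain
#'
#' Applies the median probability model (`method = "median"`, PPI > 0.5) or
#' Bayesian FDR thresholding (`method = "fdr"`, the largest selection whose
#' estimated FDR stays below `alphaLevel`) and attaches coefficient
#' summaries.
#'
#' @param chain a [DMChain-class].
#' @param method `"median"` or `"fdr"`.
#' @param alphaLevel target Bayesian FDR for `method = "fdr"` (default 0.1).
#' @param burnIn leading stored draws to discard.
#' @return a [DMSelection-class].
#' @export
selectAssociations <- function(chain, method = c("median", "fdr"),
                               alphaLevel = 0.1,
                               burnIn = defaultBurnIn(chain)) {
  method <- match.arg(method)
  ppi <- computePPI(chain, burnIn = burnIn)
  if (method == "median") {
    thr <- 0.5
  } else {
    thr <- as.numeric(fdrThreshold(ppi, alphaLevel))
  }
  sel <- (ppi > thr) + 0L
  fdr <- bayesianFDR(ppi, min(thr, 1 - 1e-12))
  cond <- betaSummaries(chain, burnIn = burnIn, conditional = TRUE)
  marg <- betaSummaries(chain, burnIn = burnIn, conditional = FALSE)
  new("DMSelection", ppi = ppi, threshold = thr, method = method,
      selected = sel, fdrEstimate = as.numeric(fdr),
      betaCondMean = cond$mean, betaCondMedian = cond$median,
      betaMargMean = marg$mean)
}

#' Export a selection as a long-format table
#'
#' One row per (covariate, taxon) pair with its PPI, conditional
#' coefficient summaries, and selection flags under both rules.
#'
#' @param selection a [DMSelection-class].
#' @param alphaLevel Bayesian FDR level for the `selected_fdr` column.
#' @return data.frame with columns `covariate_id`, `taxon_id`, `ppi`,
#'   `beta_cond_mean`, `beta_cond_median`, `selected_median_model`,
#'   `selected_fdr`.
#' @export
selectionTable <- function(selection, alphaLevel = 0.1) {
  ppi <- selection@ppi
  cfdr <- fdrThreshold(ppi, alphaLevel)
  cov_ids <- if (is.null(rownames(ppi))) paste0("x", seq_len(nrow(ppi)))
             else rownames(ppi)
  taxon_ids <- if (is.null(colnames(ppi))) paste0("taxon", seq_len(ncol(ppi)))
               else colnames(ppi)
  df <- data.frame(
    covariate_id = rep(cov_ids, times = ncol(ppi)),
    taxon_id = rep(taxon_ids, each = nrow(ppi)),
    ppi = as.numeric(ppi),
    beta_cond_mean = as.numeric(selection@betaCondMean),
    beta_cond_median = as.numeric(selection@betaCondMedian),
    selected_median_model = as.integer(medianModel(ppi)),
    selected_fdr = as.integer(ppi > as.numeric(cfdr)),
    stringsAsFactors = FALSE)
  df[order(-df$ppi), ]
}
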