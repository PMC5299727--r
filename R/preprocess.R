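# Real-data preparation: prevalence filtering of taxa, correlation-based
# de-correlation of covariates, standardization.

#' Filter taxa by prevalence
#'
#' Keeps taxon j when it is present (count > 0) in at least
#' `minPrevalence` of the samples; column order is preserved. The common
#' microbiome default of 5% removes extremely low-abundance taxa whose
#' concentration parameters are barely informed by the data.
#'
#' @param x a [DMExperiment-class].
#' @param minPrevalence required fraction of samples in (0, 1), default
#'   0.05.
#' @return the filtered [DMExperiment-class].
#' @export
filterPrevalence <- function(x, minPrevalence = 0.05) {
  stopifnot(is(x, "DMExperiment"), minPrevalence > 0, minPrevalence < 1)
  Y <- countMatrix(x)
  prev <- colSums(Y > 0) / nrow(Y)
  keep <- prev >= minPrevalence
  if (sum(keep) < 2)
    stop("fewer than two taxa pass the prevalence filter")
  x[keep, ]
}

#' De-correlate covariates by average-linkage clustering
#'
#' Clusters covariates with average-linkage hierarchical clustering on the
#' dissimilarity 1 - Pearson correlation, cuts the tree at `cut`, and keeps
#' one representative per cluster — by default the covariate with the
#' largest variance, or a user-supplied list (one named covariate per
#' cluster it should represent).
#'
#' @param x a [DMExperiment-class] with P >= 2 covariates.
#' @param cut dissimilarity height at which to cut (default 0.5, i.e.
#'   covariates correlated above 0.5 on average merge).
#' @param representatives optional character vector of covariate names to
#'   prefer as representatives of their clusters.
#' @return list with `data` (the reduced [DMExperiment-class]) and
#'   `report` (data.frame mapping every covariate to its `cluster` and
#'   `representative`, and whether it was `kept`).
#' @export
decorrelateCovariates <- function(x, cut = 0.5, representatives = NULL) {
  stopifnot(is(x, "DMExperiment"))
  X <- covariateMatrix(x)
  if (ncol(X) < 2) stop("at least two covariates are required")
  v <- apply(X, 2, var)
  if (any(v == 0))
    stop("constant covariate(s) with undefined correlation: ",
         paste(colnames(X)[v == 0], collapse = ", "))
  d <- as.dist(1 - cor(X))
  cl <- cutree(hclust(d, method = "average"), h = cut)
  keep_of_cluster <- vapply(sort(unique(cl)), function(k) {
    members <- names(cl)[cl == k]
    pref <- intersect(representatives, members)
    if (length(pref)) pref[1] else members[which.max(v[members])]
  }, character(1))
  report <- data.frame(
    covariate_id = names(cl), cluster = as.integer(cl),
    representative = keep_of_cluster[cl],
    kept = names(cl) %in% keep_of_cluster,
    row.names = NULL, stringsAsFactors = FALSE)
  keep_idx <- match(keep_of_cluster[order(match(keep_of_cluster, colnames(X)))],
                    colnames(X))
  out <- x
  colData(out) <- colData(x)[, sort(keep_idx), drop = FALSE]
  list(data = out, report = report)
}

#' Standardize covariates
#'
#' Mean-centres each covariate column and scales it to unit sample
#' variance (denominator n - 1). Idempotent up to floating point.
#'
#' @param x a [DMExperiment-class].
#' @return the [DMExperiment-class] with standardized covariates and the
#'   `standardized` flag set.
#' @export
standardizeCovariates <- function(x) {
  stopifnot(is(x, "DMExperiment"))
  X <- covariateMatrix(x)
  if (ncol(X) == 0) stop("no covariates to standardize")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant covariate(s) cannot be standardized: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  Xs <- scale(X, center = TRUE, scale = sds)
  out <- x
  colData(out) <- DataFrame(as.data.frame(Xs), row.names = colnames(x))
  out@standardized <- TRUE
  validObject(out)
  out
}
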