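# Table I/O and run manifests. Tables are TSV: a header row of taxon (or
# covariate) names, first column of sample IDs.

#' Read a taxa count table from TSV
#'
#' Expects a header row of taxon names and a first column of sample IDs.
#' Every count must be a non-negative integer; violations are reported with
#' their row/column coordinates.
#'
#' @param path path to the TSV file.
#' @return integer matrix, samples in rows.
#' @export
readCountTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("non-numeric entries in count table ", path)
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "invalid count %s at sample '%s', taxon '%s' in %s (counts must be non-negative integers)",
      format(m[bad[1, , drop = FALSE]]), rownames(m)[bad[1, 1]],
      colnames(m)[bad[1, 2]], path))
  storage.mode(m) <- "integer"
  m
}

#' Read a covariate table from TSV
#'
#' Same layout as [readCountTable()] but real-valued.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, samples in rows.
#' @export
readCovariateTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("covariate table ", path, " must be numeric and finite")
  m
}

#' Read paired count and covariate tables into a DMExperiment
#'
#' @param countPath,covariatePath TSV paths; sample IDs must agree in
#'   content and order.
#' @return a [DMExperiment-class].
#' @export
readDMExperiment <- function(countPath, covariatePath) {
  Y <- readCountTable(countPath)
  X <- readCovariateTable(covariatePath)
  if (!identical(rownames(Y), rownames(X)))
    stop("sample IDs of ", countPath, " and ", covariatePath,
         " do not match")
  DMExperiment(Y, X)
}

#' Write a sample-by-feature table as TSV
#'
#' @param m matrix with sample row names and feature column names.
#' @param path output path.
#' @param idColumn name of the first (sample ID) column.
#' @export
writeTable <- function(m, path, idColumn = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a posterior chain to plain-text files
#'
#' Writes `alpha.tsv` (wide, one column per taxon), `beta.tsv` and `xi.tsv`
#' (long format: `iter`, `covariate_id`, `taxon_id`, `value`, with zero
#' coefficients omitted from `beta.tsv`), plus `manifest.json` with the
#' settings, hyperparameters, seed and acceptance rates.
#'
#' @param chain a [DMChain-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeChain <- function(chain, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- alphaDraws(chain)
  writeTable(`rownames<-`(a, seq_len(nrow(a))), file.path(dir, "alpha.tsv"),
             idColumn = "iter")
  b <- betaDraws(chain); xi <- xiDraws(chain)
  idx <- which(xi == 1, arr.ind = TRUE)
  long <- data.frame(
    iter = idx[, 1],
    covariate_id = dimnames(b)[[2]][idx[, 2]],
    taxon_id = dimnames(b)[[3]][idx[, 3]],
    value = b[idx])
  long <- long[order(long$iter, long$taxon_id, long$covariate_id), ]
  write.table(long, file.path(dir, "beta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  xi_long <- long[, 1:3]
  xi_long$value <- rep(1L, nrow(xi_long))
  write.table(xi_long, file.path(dir, "xi.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  trace <- data.frame(iter = seq_len(nDraws(chain)),
                      log_post = logPostTrace(chain),
                      model_size = modelSizeTrace(chain))
  write.table(trace, file.path(dir, "trace.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeManifest(chain, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Write the reproducibility manifest of a run
#'
#' JSON record of the sampler settings, hyperparameters, seed, acceptance
#' rates, and package version — together with the input tables this fully
#' determines re-execution.
#'
#' @param chain a [DMChain-class].
#' @param path output JSON path.
#' @param extra optional named list merged into the manifest (e.g. the
#'   selected FDR threshold).
#' @return the path, invisibly.
#' @export
writeManifest <- function(chain, path, extra = list()) {
  ctl <- chain@control
  hyp <- chain@hyper
  manifest <- c(list(
    package = "DMVarSel",
    version = as.character(utils::packageVersion("DMVarSel")),
    settings = list(
      nIterations = ctl@nIterations, thin = ctl@thin,
      burnIn = if (is.na(ctl@burnIn)) "half" else ctl@burnIn,
      seed = ctl@seed, alphaStepSd = ctl@alphaStepSd,
      adaptScaleConst = ctl@adaptScaleConst,
      adaptMixWeight = ctl@adaptMixWeight,
      adaptFixedConst = ctl@adaptFixedConst,
      adaptStart = ctl@adaptStart, varFloor = ctl@varFloor,
      randomScan = ctl@randomScan),
    hyperparameters = list(
      slabVar = hyp@slabVar, interceptVar = hyp@interceptVar,
      a = hyp@a, b = hyp@b, priorMeanInclusion = priorInclusion(hyp)),
    acceptance = as.list(acceptanceRates(chain))),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
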