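## Tabular input, configuration and result serialization.
##
## Input is delimited text (CSV/TSV, header row required, RFC-4180-style
## quoting as handled by read.csv). Blocks may carry a row-ID column used to
## align subjects across files; otherwise row order aligns them.

.readBlock <- function(path, sep = ",", idColumn = NULL) {
  df <- utils::read.csv(path, sep = sep, check.names = FALSE)
  ids <- NULL
  if (!is.null(idColumn)) {
    if (!idColumn %in% names(df))
      stop(sprintf("file '%s' has no ID column '%s'", path, idColumn),
           call. = FALSE)
    ids <- as.character(df[[idColumn]])
    if (anyDuplicated(ids))
      stop(sprintf("file '%s': duplicated IDs (e.g. '%s')", path,
                   ids[anyDuplicated(ids)]), call. = FALSE)
    df[[idColumn]] <- NULL
  }
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop(sprintf("file '%s': non-numeric column(s): %s", path,
                 paste(names(df)[bad], collapse = ", ")), call. = FALSE)
  m <- as.matrix(df)
  rownames(m) <- ids
  m
}

#' Read a mediation dataset from delimited text files
#'
#' @param yFile,mFile,xFile,zFile paths to the outcome, mediator, exposure
#'   and (optional) confounder tables; headers required.
#' @param sep field separator (default comma; use \code{"\t"} for TSV).
#' @param idColumn optional name of a row-ID column present in every file;
#'   rows are aligned on it (otherwise by position, with matching counts
#'   enforced).
#' @param standardize center every column to mean zero and scale to unit
#'   variance; the transform is recorded in the \code{"standardization"}
#'   attribute so estimates can be mapped back to the original scale.
#' @return A \linkS4class{MediationDataset}.
#' @export
readMediationCsv <- function(yFile, mFile, xFile, zFile = NULL, sep = ",",
                             idColumn = NULL, standardize = FALSE) {
  blocks <- list(Y = .readBlock(yFile, sep, idColumn),
                 M = .readBlock(mFile, sep, idColumn),
                 X = .readBlock(xFile, sep, idColumn))
  files <- c(Y = yFile, M = mFile, X = xFile)
  if (!is.null(zFile)) {
    blocks$Z <- .readBlock(zFile, sep, idColumn)
    files <- c(files, Z = zFile)
  }
  ns <- vapply(blocks, nrow, integer(1))
  if (length(unique(ns)) > 1L) {
    msg <- paste(sprintf("%s (%s): %d rows", names(files), files, ns),
                 collapse = "; ")
    stop("row-count mismatch across blocks: ", msg, call. = FALSE)
  }
  if (!is.null(idColumn)) {
    ref <- rownames(blocks$Y)
    for (b in names(blocks)[-1]) {
      if (!setequal(rownames(blocks[[b]]), ref))
        stop(sprintf("IDs in '%s' do not match '%s'", files[[b]], yFile),
             call. = FALSE)
      blocks[[b]] <- blocks[[b]][ref, , drop = FALSE]
    }
  }
  std <- NULL
  if (standardize) {
    std <- lapply(blocks, function(m) {
      if (!ncol(m)) return(list(center = numeric(0), scale = numeric(0)))
      ctr <- colMeans(m)
      scl <- apply(m, 2L, stats::sd)
      scl[scl == 0] <- 1
      list(center = ctr, scale = scl)
    })
    blocks <- mapply(function(m, s) {
      if (!ncol(m)) return(m)
      scale(m, center = s$center, scale = s$scale)[, , drop = FALSE]
    }, blocks, std, SIMPLIFY = FALSE)
  }
  out <- MediationDataset(blocks$Y, blocks$M, blocks$X, blocks$Z)
  attr(out, "standardization") <- std
  out
}

#' Run a full mediation analysis and serialize the results
#'
#' Executes the complete pipeline (moments, dimension selection if
#' requested, sparse envelope, closed-form estimates, causal effects,
#' Wald and optionally bootstrap inference) and returns -- and optionally
#' writes as JSON -- an effect table with one row per outcome column:
#' direct, indirect and total estimate with p-values, plus the selected
#' mediators by name and the full coefficient estimates.
#'
#' @param data a \linkS4class{MediationDataset}.
#' @param d integer envelope dimension or \code{"cv"}.
#' @param lambda penalty: number, 0 or \code{"auto"}.
#' @param contrast list with elements \code{x} and \code{xprime} (defaults
#'   to a unit change in the first exposure).
#' @param bootstrapB bootstrap replicates (0 disables the bootstrap).
#' @param seed integer seed recorded in the output.
#' @param outFile optional path; results are written as pretty JSON.
#' @return (invisibly) the results list.
#' @export
runMediationAnalysis <- function(data, d = "cv", lambda = "auto",
                                 contrast = NULL, bootstrapB = 0L,
                                 seed = 1L, outFile = NULL) {
  stopifnot(is(data, "MediationDataset"))
  k <- ncol(data@X); r <- ncol(data@Y)
  fit <- fitEsplsm(data, d = d, lambda = lambda, seed = seed)
  if (is.null(contrast)) {
    x1 <- rep(0, k); x1[1] <- 1
    contrast <- list(x = x1, xprime = rep(0, k))
  }
  eff <- causalEffects(fit, contrast$x, contrast$xprime)
  wald <- waldInference(fit)
  boot <- if (bootstrapB > 0L)
    bootstrapInference(data, d = fit@basis@d, B = bootstrapB, seed = seed,
                       lambda = if (identical(lambda, "auto")) "auto"
                                else lambda)
  else NULL

  outNames <- colnames(data@Y)
  if (is.null(outNames)) outNames <- paste0("Y", seq_len(r))
  medNames <- colnames(data@M)
  if (is.null(medNames)) medNames <- paste0("M", seq_len(nMediators(data)))
  wp <- function(w) as.vector(attr(w, "entryPValues"))[seq_len(r)]
  effectTable <- data.frame(
    outcome = outNames,
    direct = eff@ande, indirect = eff@acme, total = eff@total,
    pDirectWald = wp(wald$direct), pIndirectWald = wp(wald$indirect))
  if (!is.null(boot)) {
    effectTable$pDirectBoot <- as.vector(attr(boot$direct,
                                              "entryPValues"))[seq_len(r)]
    effectTable$pIndirectBoot <- as.vector(attr(boot$indirect,
                                                "entryPValues"))[seq_len(r)]
  }
  results <- list(
    package = as.character(utils::packageVersion("envmed")),
    seed = as.integer(seed),
    d = fit@basis@d,
    lambda = fit@config@lambda,
    nSelected = length(fit@pattern@selected),
    selectedMediators = medNames[fit@pattern@selected],
    effectTable = effectTable,
    estimates = list(betaX = fit@betaX, betaM = fit@betaM,
                     gammaX = fit@gammaX),
    converged = fit@basis@converged)
  if (!is.null(outFile)) {
    jsonlite::write_json(results, outFile, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(results)
}
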