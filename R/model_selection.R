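# Selecting the number of modules by MDL-penalized cross-validated test
# likelihood, and comparing candidate lineage topologies by mean data
# likelihood over repeated fits with Welch t-tests.

# Free parameter count: (k-1) root prior + k(k-1) per branch + 2km Gaussian
# parameters per cell type.
mdlFreeParams <- function(k, m, nCellTypes, nBranches) {
  (k - 1) + nBranches * k * (k - 1) + nCellTypes * 2 * k * m
}

#' MDL-penalized cross-validated score for one module count
#'
#' Loci are shuffled deterministically by `seed` and split into `folds`
#' folds. For each fold the model is fitted on the training loci and the
#' held-out data log-likelihood is computed on the full tree, minus an MDL
#' complexity penalty `(d / 2) * log(n_train)` where `d` is the number of
#' free parameters. The penalty constant is a package convention (the
#' classical two-part MDL/BIC term) and is recorded in the returned
#' attributes so reports can state it.
#'
#' @param mms a [MarkMatrixSet-class].
#' @param tree a [LineageTree-class].
#' @param k candidate module count.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed integer seed (shuffling and fits).
#' @param ... passed to [cmintFit()].
#' @return numeric vector of per-fold penalized test log-likelihoods, with
#'   attribute `penalty` (per-fold penalty applied).
#' @export
mdlCvScore <- function(mms, tree, k, folds = 5L, seed = 1L, ...) {
  if (folds < 2L) stop("at least two folds are required")
  n <- length(mms@loci)
  set.seed(seed)
  shuffled <- sample(mms@loci)
  foldId <- rep(seq_len(folds), length.out = n)
  m <- length(mms@marks)
  d <- mdlFreeParams(k, m, length(mms@cellTypes), length(mms@cellTypes) - 1L)
  scores <- numeric(folds); pens <- numeric(folds)
  for (f in seq_len(folds)) {
    testIds <- shuffled[foldId == f]
    trainIds <- setdiff(shuffled, testIds)
    if (length(trainIds) < k)
      stop("a training fold has fewer loci than modules")
    fit <- cmintFit(subsetLoci(mms, trainIds), tree, k,
                    seed = seed + f, ...)
    pens[f] <- d / 2 * log(length(trainIds))
    scores[f] <- dataLoglik(subsetLoci(mms, testIds), tree,
                            fittedParams(fit)) - pens[f]
  }
  attr(scores, "penalty") <- pens
  scores
}

#' Select the number of modules over a grid
#'
#' Runs [mdlCvScore()] for every candidate `k` and selects the one with the
#' highest mean penalized test log-likelihood.
#'
#' @inheritParams mdlCvScore
#' @param kGrid integer vector of candidate module counts.
#' @return a [SelectionReport-class] with one row of fold scores per
#'   candidate.
#' @export
selectK <- function(mms, tree, kGrid, folds = 5L, seed = 1L, ...) {
  stopifnot(length(kGrid) >= 1)
  scores <- t(vapply(kGrid, function(k)
    as.numeric(mdlCvScore(mms, tree, k, folds = folds, seed = seed, ...)),
    numeric(folds)))
  rownames(scores) <- as.character(kGrid)
  sel <- as.character(kGrid[which.max(rowMeans(scores))])
  new("SelectionReport", candidates = as.character(kGrid), scores = scores,
      selected = sel, pvalues = matrix(numeric(0), 0, 0), what = "k")
}

#' Compare candidate lineage topologies by data likelihood
#'
#' Fits the model `nRuns` times per topology (distinct seeds), ranks
#' topologies by mean final log-likelihood and reports pairwise Welch
#' two-sample t-test p-values on the per-run log-likelihoods.
#'
#' @param mms a [MarkMatrixSet-class].
#' @param topologies named list of [LineageTree-class] candidates over the
#'   same cell types (unnamed lists are labelled topology1, topology2, ...).
#' @param k module count used for every fit.
#' @param nRuns fits per topology.
#' @param seed base integer seed.
#' @param ... passed to [cmintFit()].
#' @return a [SelectionReport-class]; `selected` is the top-ranked topology.
#' @export
compareTopologies <- function(mms, topologies, k, nRuns = 5L, seed = 1L, ...) {
  stopifnot(length(topologies) >= 1)
  if (is.null(names(topologies)))
    names(topologies) <- paste0("topology", seq_along(topologies))
  nodes0 <- sort(topologies[[1]]@nodes)
  for (tp in topologies)
    if (!identical(sort(tp@nodes), nodes0))
      stop("all candidate topologies must cover the same cell types")
  scores <- t(vapply(seq_along(topologies), function(i) {
    vapply(seq_len(nRuns), function(r)
      totalLogLik(cmintFit(mms, topologies[[i]], k,
                       seed = seed + (r - 1L), ...)),
      0)
  }, numeric(nRuns)))
  rownames(scores) <- names(topologies)
  nt <- length(topologies)
  pv <- matrix(NA_real_, nt, nt, dimnames = list(names(topologies),
                                                 names(topologies)))
  if (nRuns >= 2L) {
    for (i in seq_len(nt)) for (j in seq_len(nt)) if (i != j) {
      if (sd(scores[i, ]) == 0 && sd(scores[j, ]) == 0)
        pv[i, j] <- if (all(scores[i, ] == scores[j, ])) 1 else 0
      else
        pv[i, j] <- t.test(scores[i, ], scores[j, ])$p.value
    }
  }
  sel <- names(topologies)[which.max(rowMeans(scores))]
  new("SelectionReport", candidates = names(topologies), scores = scores,
      selected = sel, pvalues = pv, what = "topology")
}

#' Write a SelectionReport as tab-delimited scores plus a summary
#' @param report a [SelectionReport-class].
#' @param path output file.
#' @export
writeSelectionReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# selection over %s; selected: %s", report@what,
                     report@selected), con)
  if (report@what == "k")
    writeLines("# score: MDL-penalized held-out log-likelihood, penalty (d/2) log(n_train)",
               con)
  d <- data.frame(candidate = report@candidates,
                  mean_score = rowMeans(report@scores),
                  report@scores, check.names = FALSE)
  write.table(format(d, digits = 6), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
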