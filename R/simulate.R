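# Simulator: draws complete lineage chromatin datasets from the generative
# model (module paths down the tree, then diagonal-Gaussian emissions) with
# ground-truth assignments and parameters, plus a benchmark harness that
# runs the tree-coupled model and the two baselines on one draw.

#' Simulation configuration
#'
#' Defaults describe the regime used throughout the package's benchmarks: a
#' three-cell-type chain, five modules, four marks, 5000 loci, module means
#' separated by three standard deviations, 80% of each transition row on
#' the diagonal with the remaining 20% spread uniformly, and no
#' missingness.
#'
#' @param tree a [LineageTree-class] (default chain A -> B -> C).
#' @param k modules.
#' @param m marks.
#' @param nLoci loci.
#' @param meanSep distance between adjacent module means, in SD units.
#' @param varScale emission variance.
#' @param diagMass transition-matrix diagonal mass in \[0, 1\].
#' @param offDiag `"uniform"` spreads the off-diagonal mass evenly;
#'   `"sparse"` concentrates it on the next two module indices (cyclically),
#'   giving strongly asymmetric transitions.
#' @param missingRate per-entry probability that a (locus, mark, cell type)
#'   measurement is masked.
#' @param seed mandatory integer seed.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(tree = NULL, k = 5L, m = 4L, nLoci = 5000L,
                      meanSep = 3, varScale = 1, diagMass = 0.8,
                      offDiag = c("uniform", "sparse"), missingRate = 0,
                      seed) {
  if (missing(seed)) stop("a seed is mandatory")
  offDiag <- match.arg(offDiag)
  if (is.null(tree)) tree <- LineageTree(c(B = "A", C = "B"))
  stopifnot(nLoci >= k, diagMass >= 0, diagMass <= 1,
            missingRate >= 0, missingRate <= 1)
  structure(list(tree = tree, k = as.integer(k), m = as.integer(m),
                 nLoci = as.integer(nLoci), meanSep = meanSep,
                 varScale = varScale, diagMass = diagMass, offDiag = offDiag,
                 missingRate = missingRate, seed = as.integer(seed)),
            class = "SimConfig")
}

# Transition matrix with the configured diagonal mass.
simTransition <- function(k, diagMass, offDiag) {
  Tm <- matrix(0, k, k)
  for (i in seq_len(k)) {
    if (offDiag == "uniform") {
      Tm[i, ] <- (1 - diagMass) / max(k - 1, 1)
    } else {
      targets <- (c(i, i + 1) %% k) + 1 # next two modules, cyclic
      targets <- setdiff(targets, i)
      Tm[i, targets] <- (1 - diagMass) / length(targets)
    }
    Tm[i, i] <- Tm[i, i] + diagMass
  }
  sweep(Tm, 1, rowSums(Tm), `/`)
}

# Module mean lattice: module j gets the base-B digit code of j across the
# m marks, scaled by meanSep * SD, plus a small per-cell-type jitter
# (10% of the separation) so cell types are related but not identical.
simMeans <- function(k, m, meanSep, varScale) {
  B <- max(2, ceiling(k^(1 / m)))
  sdv <- sqrt(varScale)
  codes <- t(matrix(vapply(seq_len(k) - 1L, function(j) {
    (j %/% B^(seq_len(m) - 1L)) %% B
  }, numeric(m)), nrow = m))
  codes * meanSep * sdv
}

#' Sample a dataset from the generative model
#'
#' Root module drawn from a uniform prior, each child's module from its
#' branch transition row, observations from the per-cell-type diagonal
#' Gaussians; mark-wise independent missingness masked at the configured
#' rate. Fully reproducible by the config seed.
#'
#' @param cfg a [simConfig()] object.
#' @return list with elements `mms` ([MarkMatrixSet-class]), `truth`
#'   (integer assignment matrix, 0-based), and `params` (the true
#'   [CmintParameters-class]).
#' @export
sampleDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  tree <- cfg$tree
  ord <- topoOrder(tree)
  k <- cfg$k; m <- cfg$m; n <- cfg$nLoci
  ids <- sprintf("locus%05d", seq_len(n))
  base <- simMeans(k, m, cfg$meanSep, cfg$varScale)
  means <- lapply(setNames(ord, ord), function(ct)
    base + matrix(rnorm(k * m, 0, 0.1 * cfg$meanSep * sqrt(cfg$varScale)),
                  k, m))
  variances <- lapply(setNames(ord, ord), function(ct)
    matrix(cfg$varScale, k, m))
  transitions <- lapply(setNames(setdiff(ord, tree@root),
                                 setdiff(ord, tree@root)),
                        function(ct) simTransition(k, cfg$diagMass,
                                                   cfg$offDiag))
  prior <- rep(1 / k, k)
  truth <- matrix(0L, n, length(ord), dimnames = list(ids, ord))
  truth[, tree@root] <- sample.int(k, n, replace = TRUE,
                                   prob = prior) - 1L
  for (v in ord[-1]) {
    p <- parentOf(tree, v)
    Tm <- transitions[[v]]
    truth[, v] <- vapply(truth[, p] + 1L, function(i)
      sample.int(k, 1, prob = Tm[i, ]), 0L) - 1L
  }
  vals <- lapply(setNames(ord, ord), function(ct) {
    mu <- means[[ct]][truth[, ct] + 1L, , drop = FALSE]
    X <- mu + matrix(rnorm(n * m, 0, sqrt(cfg$varScale)), n, m)
    dimnames(X) <- list(ids, paste0("mark", seq_len(m)))
    if (cfg$missingRate > 0)
      X[matrix(runif(n * m) < cfg$missingRate, n, m)] <- NA_real_
    X
  })
  attr(truth, "k") <- k
  list(mms = MarkMatrixSet(vals), truth = truth,
       params = CmintParameters(prior = prior, transitions = transitions,
                                means = means, variances = variances))
}

#' Benchmark the tree-coupled model against the baselines on one draw
#'
#' Samples one dataset from `cfg`, runs the requested methods, and returns
#' per-method cluster-quality (mean per-cell-type silhouette and coherence)
#' and transition-detection metrics against the simulated truth. A
#' `truth` control row (ground-truth labels scored as a prediction) is
#' always included.
#'
#' Cluster-quality metrics are evaluated on a deterministic subsample of at
#' most `qualityLoci` loci (silhouette is quadratic in the locus count;
#' transition metrics always use every locus).
#'
#' @param cfg a [simConfig()] object.
#' @param methods subset of `c("cmint", "merge_first", "cluster_first")`.
#' @param qualityLoci cap on loci used for silhouette/coherence.
#' @param ... passed to [cmintFit()] / the baseline fitters.
#' @return data.frame with columns method, silhouette, coherence,
#'   precision, recall, fscore.
#' @export
makeBenchmark <- function(cfg,
                          methods = c("cmint", "merge_first", "cluster_first"),
                          qualityLoci = 1000L, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  sim <- sampleDataset(cfg)
  tree <- cfg$tree
  qsub <- if (nrow(sim$truth) > qualityLoci)
    seq(1L, nrow(sim$truth), length.out = qualityLoci) else
    seq_len(nrow(sim$truth))
  qsub <- unique(as.integer(qsub))
  tables <- list(truth = sim$truth)
  for (meth in methods) {
    tables[[meth]] <- switch(meth,
      cmint = assignments(cmintFit(sim$mms, tree, cfg$k,
                                   seed = cfg$seed + 1000L, ...)),
      merge_first = mergeFirst(sim$mms, cfg$k, seed = cfg$seed + 2000L, ...),
      cluster_first = clusterFirst(sim$mms, tree, cfg$k,
                                   seed = cfg$seed + 3000L, ...))
  }
  rows <- lapply(names(tables), function(meth) {
    at <- tables[[meth]]
    sil <- mean(vapply(cellTypes(sim$mms), function(ct) {
      X <- markValues(sim$mms, ct)[qsub, , drop = FALSE]
      X[is.na(X)] <- 0
      labs <- at[qsub, ct]
      if (length(unique(labs)) < 2L) return(NA_real_)
      silhouetteIndex(X, labs)
    }, 0))
    coh <- mean(vapply(cellTypes(sim$mms), function(ct) {
      X <- markValues(sim$mms, ct)[qsub, , drop = FALSE]
      X[is.na(X)] <- 0
      labs <- at[qsub, ct]
      if (length(unique(labs)) < 2L) return(NA_real_)
      clusterCoherence(X, labs)
    }, 0))
    prf <- transitionPRF(at, sim$truth, tree)
    data.frame(method = meth, silhouette = sil, coherence = coh,
               precision = prf["precision"], recall = prf["recall"],
               fscore = prf["fscore"], row.names = NULL)
  })
  do.call(rbind, rows)
}
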