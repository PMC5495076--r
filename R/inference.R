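# Tree-coupled Gaussian mixture model: emission likelihoods, exact E-step by
# two-pass sum-product message passing over the lineage tree (all nodes
# observed), M-step updates, and the EM driver.
#
# All probability arithmetic is carried out in log space. Transition
# matrices are stored in linear space and entered into log-space message
# products through stabilized log(exp(B) %*% T) primitives, so underflow
# cannot occur for any locus.

# log(rowSums(exp(M))) computed stably row-wise.
rowLogSumExp <- function(M) {
  mx <- apply(M, 1, max)
  mx[!is.finite(mx)] <- 0 # all -Inf rows: log(0) = -Inf handled below
  r <- mx + log(rowSums(exp(M - mx)))
  r
}

# log( exp(B) %*% W ) for a log-matrix B (n x k) and non-negative W (k x k').
logMatProd <- function(B, W) {
  mx <- apply(B, 1, max)
  mx[!is.finite(mx)] <- 0
  log(pmax(exp(B - mx) %*% W, .Machine$double.xmin)) + mx
}

#' Per-module Gaussian emission log-likelihoods for one cell type
#'
#' For each module j, the log density of a locus profile under the
#' diagonal-covariance Gaussian of module j in the given cell type, summed
#' over non-missing mark dimensions only (missing dimensions are
#' marginalized out exactly, which the diagonal covariance makes trivial).
#' A fully missing profile yields 0 (log 1) for every module.
#'
#' @param x numeric vector of mark values for one locus (NA = missing).
#' @param params a [CmintParameters-class].
#' @param cellType cell type whose Gaussians to use.
#' @return length-k numeric vector of log densities.
#' @export
emissionLoglik <- function(x, params, cellType) {
  mu <- params@means[[cellType]]
  s2 <- params@variances[[cellType]]
  obs <- !is.na(x)
  if (!any(obs)) return(rep(0, params@k))
  xo <- matrix(x[obs], params@k, sum(obs), byrow = TRUE)
  ll <- -0.5 * rowSums(log(2 * pi * s2[, obs, drop = FALSE]) +
                         (xo - mu[, obs, drop = FALSE])^2 /
                           s2[, obs, drop = FALSE])
  as.numeric(ll)
}

# n x k matrix of emission log-likelihoods for every locus of one cell type.
emissionLoglikMatrix <- function(mms, params, cellType) {
  X <- mms@values[[cellType]]
  mu <- params@means[[cellType]]
  s2 <- params@variances[[cellType]]
  n <- nrow(X); k <- params@k
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    # per-dimension log density, 0 where missing
    D <- sweep(X, 2, mu[j, ], `-`)^2
    D <- sweep(D, 2, s2[j, ], `/`)
    D <- D + matrix(log(2 * pi * s2[j, ]), n, ncol(X), byrow = TRUE)
    D[mms@missing[[cellType]]] <- 0
    out[, j] <- -0.5 * rowSums(D)
  }
  out
}

#' Exact E-step on the lineage tree
#'
#' Two-pass sum-product (leafward collect, rootward distribute) over the
#' rooted tree computes, for every locus, the exact posterior marginal over
#' modules at every cell type and the exact pairwise posterior over (parent,
#' child) module pairs on every branch, together with the total data
#' log-likelihood. Because every node is observed, the messages combine the
#' node's own emission likelihood with its subtree evidence.
#'
#' @param mms a [MarkMatrixSet-class].
#' @param tree a [LineageTree-class] whose nodes match `cellTypes(mms)`.
#' @param params a [CmintParameters-class].
#' @return A [PosteriorSet-class].
#' @export
eStep <- function(mms, tree, params) {
  checkTreeData(mms, tree)
  n <- length(mms@loci); k <- params@k
  ord <- topoOrder(tree)
  L <- lapply(setNames(ord, ord), function(ct)
    emissionLoglikMatrix(mms, params, ct))
  if (any(vapply(L, function(x) any(is.na(x)), TRUE)))
    stop("NaN encountered in emission likelihoods")

  # Leafward: beta[v][l, j] = log P(data in subtree(v) | module(v) = j).
  # msg[c][l, i] = log sum_j T_c[i, j] exp(beta[c][l, j]) for branch to c.
  beta <- list(); msg <- list()
  for (v in rev(ord)) {
    b <- L[[v]]
    for (ch in childrenOf(tree, v)) b <- b + msg[[ch]]
    beta[[v]] <- b
    if (v != tree@root)
      msg[[v]] <- logMatProd(b, t(params@transitions[[v]]))
  }
  rootTerm <- sweep(beta[[tree@root]], 2, log(params@prior), `+`)
  perLocus <- rowLogSumExp(rootTerm)

  # Rootward: alpha[v][l, j] = log P(module(v) = j, data outside subtree(v)).
  alpha <- list()
  alpha[[tree@root]] <- matrix(log(params@prior), n, k, byrow = TRUE)
  gamma <- list(); xi <- list()
  for (v in ord) {
    gv <- alpha[[v]] + beta[[v]] - perLocus
    gamma[[v]] <- exp(gv)
    for (ch in childrenOf(tree, v)) {
      # evidence above ch, including v's emission and ch's siblings
      A <- alpha[[v]] + beta[[v]] - msg[[ch]]
      alpha[[ch]] <- logMatProd(A, params@transitions[[ch]])
      Tl <- log(pmax(params@transitions[[ch]], .Machine$double.xmin))
      x <- array(0, c(n, k, k))
      for (i in seq_len(k))
        x[, i, ] <- exp(A[, i] +
                          matrix(Tl[i, ], n, k, byrow = TRUE) +
                          beta[[ch]] - perLocus)
      xi[[ch]] <- x
    }
  }
  new("PosteriorSet", gamma = gamma[ord],
      xi = xi[setdiff(ord, tree@root)],
      loglik = sum(perLocus), perLocusLoglik = as.numeric(perLocus))
}

#' Total data log-likelihood under a parameter set
#'
#' Same quantity as the `loglik` slot of [eStep()]'s result, computed by the
#' leafward pass only (no posteriors retained). Used for held-out scoring
#' and topology comparison.
#'
#' @inheritParams eStep
#' @return scalar log-likelihood.
#' @export
dataLoglik <- function(mms, tree, params) {
  checkTreeData(mms, tree)
  ord <- topoOrder(tree)
  beta <- list()
  for (v in rev(ord)) {
    b <- emissionLoglikMatrix(mms, params, v)
    if (any(is.na(b))) stop("NaN encountered in emission likelihoods")
    for (ch in childrenOf(tree, v)) b <- b + beta[[ch]]
    if (v != tree@root)
      beta[[v]] <- logMatProd(b, t(params@transitions[[v]]))
    else
      beta[[v]] <- b
  }
  sum(rowLogSumExp(sweep(beta[[tree@root]], 2, log(params@prior), `+`)))
}

checkTreeData <- function(mms, tree) {
  if (!setequal(mms@cellTypes, tree@nodes))
    stop("tree nodes and MarkMatrixSet cell types differ")
  invisible(TRUE)
}

#' M-step: maximize expected complete-data log-likelihood
#'
#' Means are responsibility-weighted averages per cell type, module and mark
#' over non-missing entries; variances are weighted squared deviations,
#' floored; each branch's transition matrix is the row-normalized sum of
#' pairwise posteriors over loci; the root prior is the normalized root
#' marginal mass. A (module, mark) cell with no observed weight falls back
#' to the global mark mean/variance of that cell type.
#'
#' @inheritParams eStep
#' @param post a [PosteriorSet-class] from [eStep()].
#' @param varFloor lower bound applied to every variance.
#' @return a [CmintParameters-class].
#' @export
mStep <- function(mms, tree, post, varFloor = 1e-4) {
  k <- ncol(post@gamma[[1]])
  ord <- topoOrder(tree)
  prior <- colSums(post@gamma[[tree@root]])
  prior <- prior / sum(prior)
  transitions <- lapply(post@xi, function(x) {
    Tm <- apply(x, c(2, 3), sum)
    sweep(Tm, 1, pmax(rowSums(Tm), .Machine$double.xmin), `/`)
  })
  means <- list(); variances <- list()
  for (ct in ord) {
    X <- mms@values[[ct]]
    obs <- !mms@missing[[ct]]
    X0 <- ifelse(obs, X, 0)
    g <- post@gamma[[ct]]
    mu <- matrix(0, k, ncol(X)); s2 <- matrix(0, k, ncol(X))
    gmu <- colMeans(X, na.rm = TRUE)
    gs2 <- pmax(apply(X, 2, var, na.rm = TRUE), varFloor)
    gmu[is.nan(gmu)] <- 0; gs2[is.na(gs2)] <- varFloor
    for (j in seq_len(k)) {
      w <- g[, j] * obs            # n x m effective weights
      W <- colSums(w)
      ok <- W > 1e-12
      mu[j, ] <- ifelse(ok, colSums(w * X0) / pmax(W, 1e-300), gmu)
      dev2 <- (X0 - matrix(mu[j, ], nrow(X), ncol(X), byrow = TRUE))^2
      s2[j, ] <- ifelse(ok, colSums(w * dev2) / pmax(W, 1e-300), gs2)
    }
    means[[ct]] <- mu
    variances[[ct]] <- pmax(s2, varFloor)
  }
  CmintParameters(prior = prior, transitions = transitions,
                  means = means, variances = variances)
}

# k-means++-style seeding: first center uniform, then proportional to
# squared distance to the nearest chosen center. Returns k row indices.
kppSeed <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1, prob = p)
    nd <- rowSums((X - matrix(X[centers[j + 1L], ], n, ncol(X),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

# Initial parameters: k-means++ seeding of k shared centers on the pooled
# (row-stacked) data of all cell types, used as the initial means of every
# cell type so that module j starts at the same location throughout the
# tree and the positional module correspondence is fixed from iteration 0
# (independent per-cell-type seeding lets each cell type settle on a
# permuted labelling that the transition matrices silently absorb).
# Missing entries are imputed at the column mean for seeding only.
# Variances start at the global per-mark variance of each cell type, the
# prior uniform. Transitions start strongly diagonal (0.9 I + 0.1 uniform):
# together with the shared centers this anchors the positional module
# correspondence across cell types, without which EM can settle into
# likelihood-equivalent solutions whose labels are permuted differently in
# different cell types (the transition matrices absorb the permutation and
# MAP transition calls become meaningless). The M-step re-estimates the
# transitions freely from the first iteration, so the strong diagonal only
# selects the aligned basin, it does not bias the converged estimates.
initParams <- function(mms, tree, k, varFloor) {
  ord <- topoOrder(tree)
  imputed <- lapply(ord, function(ct) {
    X <- mms@values[[ct]]
    cm <- colMeans(X, na.rm = TRUE); cm[is.nan(cm)] <- 0
    for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- cm[j]
    X
  })
  names(imputed) <- ord
  pooled <- do.call(rbind, imputed)
  centers <- pooled[kppSeed(pooled, k), , drop = FALSE]
  rownames(centers) <- NULL
  means <- list(); variances <- list()
  for (ct in ord) {
    means[[ct]] <- centers
    variances[[ct]] <- matrix(pmax(apply(imputed[[ct]], 2, var), varFloor),
                              k, ncol(imputed[[ct]]), byrow = TRUE)
  }
  Tr <- 0.9 * diag(k) + 0.1 / k
  transitions <- lapply(setNames(setdiff(ord, tree@root),
                                 setdiff(ord, tree@root)),
                        function(ct) Tr)
  CmintParameters(prior = rep(1 / k, k), transitions = transitions,
                  means = means, variances = variances)
}

#' Fit the tree-coupled chromatin module model by EM
#'
#' Runs expectation-maximization from `nInit` random initializations and
#' returns the run with the highest final log-likelihood. Convergence is
#' declared when the relative log-likelihood improvement falls below `tol`.
#' A module whose total responsibility in some cell type drops below 1e-12
#' is re-seeded at the locus with the lowest likelihood under the current
#' model (a message records the event). Fully reproducible for a given
#' `seed`.
#'
#' @param mms a [MarkMatrixSet-class].
#' @param tree a [LineageTree-class] over the same cell types.
#' @param k number of modules (>= 2).
#' @param nInit random initializations.
#' @param maxIter maximum EM iterations per initialization.
#' @param tol relative log-likelihood improvement threshold.
#' @param seed integer seed driving all randomness.
#' @param varFloor variance floor.
#' @param initial optional [CmintParameters-class] to start from (then
#'   `nInit` is ignored and a single run is performed).
#' @return a [CmintFit-class].
#' @export
cmintFit <- function(mms, tree, k, nInit = 3L, maxIter = 300L, tol = 1e-6,
                     seed = 1L, varFloor = 1e-4, initial = NULL) {
  checkTreeData(mms, tree)
  if (is.null(initial)) {
    if (k < 2L) stop("k must be at least 2")
    if (k > length(mms@loci)) stop("more modules than loci")
  }
  runOne <- function(runSeed) {
    set.seed(runSeed)
    params <- if (is.null(initial)) initParams(mms, tree, k, varFloor)
              else initial
    trace <- numeric(0)
    post <- NULL
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      post <- eStep(mms, tree, params)
      trace <- c(trace, post@loglik)
      if (it > 1L) {
        rel <- (trace[it] - trace[it - 1L]) / max(abs(trace[it - 1L]), 1)
        if (abs(rel) < tol) { converged <- TRUE; break }
      }
      if (it == maxIter) break # keep params consistent with post
      params <- mStep(mms, tree, post, varFloor = varFloor)
      params <- reseedEmpty(mms, tree, params, post)
    }
    list(params = params, post = post, trace = trace,
         converged = converged, seed = runSeed)
  }
  seeds <- seed + seq_len(if (is.null(initial)) max(1L, nInit) else 1L) - 1L
  runs <- lapply(seeds, runOne)
  best <- runs[[which.max(vapply(runs, function(r) r$post@loglik, 0))]]
  at <- mapAssignments(best$post)
  rownames(at) <- mms@loci
  new("CmintFit", params = best$params, posteriors = best$post,
      assignments = at, loglikTrace = best$trace,
      seed = as.integer(best$seed), nIter = length(best$trace),
      converged = best$converged)
}

# Re-seed modules whose total responsibility collapsed: center the module
# at the locus with the lowest per-locus likelihood.
reseedEmpty <- function(mms, tree, params, post) {
  worst <- which.min(post@perLocusLoglik)
  for (ct in mms@cellTypes) {
    dead <- which(colSums(post@gamma[[ct]]) < 1e-12)
    for (j in dead) {
      message(sprintf("re-seeding empty module %d in cell type %s", j - 1L, ct))
      x <- mms@values[[ct]][worst, ]
      obs <- !is.na(x)
      params@means[[ct]][j, obs] <- x[obs]
    }
  }
  params
}

#' MAP module assignments from posteriors
#'
#' Per locus and cell type, the argmax of the posterior marginal; ties break
#' toward the lowest module index so outputs are deterministic.
#'
#' @param post a [PosteriorSet-class].
#' @return integer loci x cell-type matrix of 0-based module indices with a
#'   `k` attribute.
#' @export
mapAssignments <- function(post) {
  at <- vapply(post@gamma, function(g) max.col(g, ties.method = "first") - 1L,
               integer(nrow(post@gamma[[1]])))
  if (is.null(dim(at))) at <- matrix(at, nrow = 1,
                                     dimnames = list(NULL, names(post@gamma)))
  attr(at, "k") <- ncol(post@gamma[[1]])
  at
}
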