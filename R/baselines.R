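# Baseline clusterings used for benchmarking the tree-coupled model:
# MERGE-FIRST (one clustering of the concatenated matrix) and CLUSTER-FIRST
# (independent per-cell-type clusterings with Hungarian label matching along
# tree edges). Both reuse the same diagonal-Gaussian mixture machinery,
# initialization, variance floor and convergence settings as the main model
# so comparisons isolate the tree coupling itself.

# Fit a plain diagonal GMM by running the tree model on a single-node tree.
singleGmm <- function(X, k, seed, nInit = 1L, maxIter = 300L, tol = 1e-6,
                      varFloor = 1e-4) {
  mms <- MarkMatrixSet(list(only = X))
  tree <- new("LineageTree", nodes = "only", root = "only",
              parent = setNames(character(0), character(0)))
  cmintFit(mms, tree, k, nInit = nInit, maxIter = maxIter, tol = tol,
           seed = seed, varFloor = varFloor)
}

#' MERGE-FIRST baseline clustering
#'
#' Concatenates the per-cell-type matrices column-wise into one loci x
#' (cell types * marks) matrix, clusters it once with a diagonal-Gaussian
#' mixture, and projects the single labelling onto every cell type, so all
#' columns of the resulting assignment table are identical.
#'
#' @param mms a [MarkMatrixSet-class].
#' @param k number of clusters.
#' @param seed integer seed.
#' @param ... further arguments passed to [cmintFit()] (`nInit`, `maxIter`,
#'   `tol`, `varFloor`).
#' @return integer loci x cell-type assignment matrix (0-based) with a `k`
#'   attribute.
#' @export
mergeFirst <- function(mms, k, seed = 1L, ...) {
  mats <- lapply(mms@cellTypes, function(ct) {
    v <- mms@values[[ct]]
    colnames(v) <- paste(ct, colnames(v), sep = ".")
    v
  })
  merged <- do.call(cbind, mats)
  fit <- singleGmm(merged, k, seed, ...)
  lab <- assignments(fit)[, 1]
  at <- matrix(lab, nrow = length(lab), ncol = length(mms@cellTypes),
               dimnames = list(mms@loci, mms@cellTypes))
  storage.mode(at) <- "integer"
  attr(at, "k") <- as.integer(k)
  at
}

#' CLUSTER-FIRST baseline clustering with label matching
#'
#' Clusters each cell type independently with a diagonal-Gaussian mixture,
#' then walks the tree from the root outward and relabels each child's
#' clusters to its parent's by maximum-overlap assignment
#' ([hungarianMatch()] on the negative contingency-table overlap), so labels
#' propagate consistently over multi-branch trees.
#'
#' @inheritParams mergeFirst
#' @param tree a [LineageTree-class]; matching runs along its edges.
#' @return integer loci x cell-type assignment matrix (0-based, matched
#'   labels) with a `k` attribute.
#' @export
clusterFirst <- function(mms, tree, k, seed = 1L, ...) {
  checkTreeData(mms, tree)
  ord <- topoOrder(tree)
  raw <- lapply(seq_along(ord), function(i)
    assignments(singleGmm(mms@values[[ord[i]]], k, seed + i - 1L, ...))[, 1])
  names(raw) <- ord
  matched <- list()
  matched[[tree@root]] <- raw[[tree@root]]
  for (v in ord[-1]) {
    p <- parentOf(tree, v)
    overlap <- matrix(0, k, k)
    tab <- table(factor(matched[[p]], levels = 0:(k - 1)),
                 factor(raw[[v]], levels = 0:(k - 1)))
    overlap[] <- as.numeric(tab)
    perm <- hungarianMatch(-overlap) # perm[i] = child label matched to i-1
    relabel <- integer(k)
    relabel[perm] <- seq_len(k)      # child label j -> parent label
    matched[[v]] <- relabel[raw[[v]] + 1L] - 1L
  }
  at <- vapply(ord, function(v) matched[[v]], integer(length(mms@loci)))
  rownames(at) <- mms@loci
  attr(at, "k") <- as.integer(k)
  at
}

#' Hungarian algorithm for minimum-cost assignment
#'
#' Solves the square assignment problem exactly by the shortest augmenting
#' path method (O(k^3)). Ties between equal-cost assignments are broken
#' deterministically (columns scanned in increasing order), so repeated
#' calls always return the same permutation.
#'
#' @param cost square numeric matrix of finite costs.
#' @return integer permutation `p` with `p[i]` the column assigned to row
#'   `i`; `sum(cost[cbind(seq_len(k), p)])` is minimal.
#' @export
hungarianMatch <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost))
    stop("cost must be a square matrix")
  if (any(!is.finite(cost))) stop("cost entries must be finite")
  n <- nrow(cost)
  # Jonker-Volgenant style shortest augmenting path with dual potentials.
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1) # p[j+1] = row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) perm[p[j + 1]] <- j
  perm
}
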