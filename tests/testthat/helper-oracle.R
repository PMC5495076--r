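# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (exhaustive enumeration, direct
# summation, scalar loops) and independent of the package's message-passing
# and matrix code paths.

# Exhaustive-enumeration oracle for the tree-coupled model: sums over all
# k^(#nodes) joint module assignments per locus.
bruteOracle <- function(mms, tree, params) {
  ord <- cmint:::topoOrder(tree)
  k <- params@k
  n <- length(loci(mms))
  L <- lapply(setNames(ord, ord), function(ct)
    t(vapply(seq_len(n), function(l)
      emissionLoglik(markValues(mms, ct)[l, ], params, ct), numeric(k))))
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), length(ord))))
  colnames(combos) <- ord
  gam <- lapply(setNames(ord, ord), function(ct) matrix(0, n, k))
  nonroot <- setdiff(ord, rootOf(tree))
  xi <- lapply(setNames(nonroot, nonroot), function(ct) array(0, c(n, k, k)))
  ll <- numeric(n)
  for (l in seq_len(n)) {
    w <- numeric(nrow(combos))
    for (r in seq_len(nrow(combos))) {
      z <- combos[r, ]
      lp <- log(params@prior[z[rootOf(tree)]]) +
        L[[rootOf(tree)]][l, z[rootOf(tree)]]
      for (v in ord[-1]) {
        p <- parentOf(tree, v)
        lp <- lp + log(params@transitions[[v]][z[p], z[v]]) + L[[v]][l, z[v]]
      }
      w[r] <- lp
    }
    mx <- max(w); ev <- exp(w - mx); Z <- sum(ev)
    ll[l] <- mx + log(Z)
    pr <- ev / Z
    for (r in seq_len(nrow(combos))) {
      z <- combos[r, ]
      for (v in ord) gam[[v]][l, z[v]] <- gam[[v]][l, z[v]] + pr[r]
      for (v in ord[-1]) {
        p <- parentOf(tree, v)
        xi[[v]][l, z[p], z[v]] <- xi[[v]][l, z[p], z[v]] + pr[r]
      }
    }
  }
  list(gamma = gam, xi = xi, loglik = sum(ll))
}

# Random small instance (data + valid parameters) for oracle comparisons.
randomInstance <- function(seed, maxNodes = 4, maxK = 3, maxLoci = 20,
                           missingRate = 0.15) {
  set.seed(seed)
  trees <- list(
    LineageTree(c(B = "A")),
    LineageTree(c(B = "A", C = "B")),
    LineageTree(c(B = "A", C = "A")),
    LineageTree(c(B = "A", C = "B", D = "B")),
    LineageTree(c(B = "A", C = "A", D = "A"))
  )
  trees <- Filter(function(t) length(cellTypes(t)) <= maxNodes, trees)
  tree <- trees[[sample.int(length(trees), 1)]]
  ord <- cmint:::topoOrder(tree)
  k <- sample(2:maxK, 1)
  n <- sample(3:maxLoci, 1)
  m <- sample(1:3, 1)
  vals <- lapply(setNames(ord, ord), function(ct) {
    X <- matrix(rnorm(n * m), n, m,
                dimnames = list(paste0("g", seq_len(n)),
                                paste0("mk", seq_len(m))))
    X[matrix(runif(n * m) < missingRate, n, m)] <- NA
    X
  })
  rdir <- function(kk) { x <- runif(kk) + 0.1; x / sum(x) }
  params <- CmintParameters(
    prior = rdir(k),
    transitions = lapply(setNames(ord[-1], ord[-1]), function(v)
      t(vapply(seq_len(k), function(i) rdir(k), numeric(k)))),
    means = lapply(setNames(ord, ord), function(v) matrix(rnorm(k * m), k, m)),
    variances = lapply(setNames(ord, ord), function(v)
      matrix(runif(k * m, 0.3, 2), k, m)))
  list(mms = MarkMatrixSet(vals), tree = tree, params = params, k = k)
}

# Plain diagonal-Gaussian mixture EM, written directly from the standard
# responsibility/update formulas (no tree, no message passing). Reference
# for the single-node reduction of the tree model.
gmmEmRef <- function(X, prior, means, variances, maxIter = 300L,
                     tol = 1e-6, varFloor = 1e-4) {
  n <- nrow(X); k <- length(prior)
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    logd <- vapply(seq_len(k), function(j)
      log(prior[j]) + rowSums(dnorm(X, matrix(means[j, ], n, ncol(X),
                                              byrow = TRUE),
                                    matrix(sqrt(variances[j, ]), n, ncol(X),
                                           byrow = TRUE), log = TRUE)),
      numeric(n))
    mx <- apply(logd, 1, max)
    ll <- sum(mx + log(rowSums(exp(logd - mx))))
    trace <- c(trace, ll)
    if (it > 1 &&
        abs((trace[it] - trace[it - 1]) / max(abs(trace[it - 1]), 1)) < tol)
      break
    r <- exp(logd - mx - log(rowSums(exp(logd - mx))))
    Nk <- colSums(r)
    prior <- Nk / n
    for (j in seq_len(k)) {
      means[j, ] <- colSums(r[, j] * X) / Nk[j]
      variances[j, ] <- pmax(colSums(r[, j] *
        sweep(X, 2, means[j, ])^2) / Nk[j], varFloor)
    }
  }
  list(loglik = trace[length(trace)], trace = trace,
       prior = prior, means = means, variances = variances)
}

# A tiny MarkMatrixSet from explicit matrices.
toyMms <- function(...) MarkMatrixSet(list(...))

# All permutations of 1..n (for brute-force assignment matching).
allPerms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- allPerms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub), n - 1))
  }))
}

chainTree <- function() LineageTree(c(B = "A", C = "B"))
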