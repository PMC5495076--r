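# The tree-coupled mixture model: emissions, exact E-step vs enumeration,
# M-step updates, EM behaviour and determinism.

test_that("emission log-likelihood matches univariate closed forms", {
  params <- CmintParameters(
    prior = c(0.5, 0.5),
    transitions = list(),
    means = list(A = matrix(c(0, 2), 2, 1)),
    variances = list(A = matrix(1 / (2 * pi), 2, 1)))
  # x at the mean with var 1/(2pi): density 1, log density 0
  expect_equal(emissionLoglik(0, params, "A")[1], 0)
  # equidistant from both means with equal variances: symmetric entries
  expect_equal(emissionLoglik(1, params, "A")[1],
               emissionLoglik(1, params, "A")[2])
})

test_that("missing mark dimensions are marginalized, not imputed", {
  set.seed(1)
  k <- 2; m <- 3
  params <- CmintParameters(
    prior = c(0.4, 0.6), transitions = list(),
    means = list(A = matrix(rnorm(k * m), k, m)),
    variances = list(A = matrix(runif(k * m, 0.5, 2), k, m)))
  x <- c(0.3, NA, -0.7)
  got <- emissionLoglik(x, params, "A")
  # direct 2-D computation over the observed marks only
  want <- vapply(1:k, function(j)
    sum(dnorm(x[c(1, 3)], params@means$A[j, c(1, 3)],
              sqrt(params@variances$A[j, c(1, 3)]), log = TRUE)), 0)
  expect_equal(got, want)
  expect_equal(emissionLoglik(c(NA, NA, NA), params, "A"), c(0, 0))
})

test_that("single-node E-step reduces to plain mixture responsibilities", {
  set.seed(2)
  X <- matrix(rnorm(20), 10, 2,
              dimnames = list(paste0("g", 1:10), c("m1", "m2")))
  mms <- MarkMatrixSet(list(A = X))
  tree <- LineageTree(c(B = "A"))  # placeholder; build true single node below
  single <- new("LineageTree", nodes = "A", root = "A",
                parent = setNames(character(0), character(0)))
  params <- CmintParameters(
    prior = c(0.3, 0.7), transitions = list(),
    means = list(A = matrix(c(-1, 1, 0, 0), 2, 2)),
    variances = list(A = matrix(1, 2, 2)))
  post <- eStep(mms, single, params)
  logd <- vapply(1:2, function(j)
    log(params@prior[j]) +
      dnorm(X[, 1], params@means$A[j, 1], 1, log = TRUE) +
      dnorm(X[, 2], params@means$A[j, 2], 1, log = TRUE), numeric(10))
  resp <- exp(logd - apply(logd, 1, max))
  resp <- resp / rowSums(resp)
  expect_equal(post@gamma$A, unname(resp), tolerance = 1e-12)
  expect_equal(post@loglik,
               sum(log(rowSums(exp(logd)))), tolerance = 1e-10)
})

test_that("identity transitions force equal assignments along a chain", {
  X1 <- matrix(c(-1, 1), 2, 1, dimnames = list(c("g1", "g2"), "m1"))
  mms <- MarkMatrixSet(list(A = X1, B = X1))
  tree <- LineageTree(c(B = "A"))
  params <- CmintParameters(
    prior = c(0.5, 0.5),
    transitions = list(B = diag(2)),
    means = list(A = matrix(c(-1, 1), 2, 1), B = matrix(c(-1, 1), 2, 1)),
    variances = list(A = matrix(1, 2, 1), B = matrix(1, 2, 1)))
  post <- eStep(mms, tree, params)
  # gamma at both nodes proportional to prior_j N(x_A|j) N(x_B|j)
  for (l in 1:2) {
    w <- vapply(1:2, function(j)
      0.5 * dnorm(X1[l, 1], c(-1, 1)[j], 1)^2, 0)
    expect_equal(post@gamma$A[l, ], w / sum(w), tolerance = 1e-12)
    expect_equal(post@gamma$B[l, ], w / sum(w), tolerance = 1e-12)
  }
})

test_that("E-step matches exhaustive enumeration on random small instances", {
  for (s in 1:8) {
    inst <- randomInstance(100 + s)
    post <- eStep(inst$mms, inst$tree, inst$params)
    orc <- bruteOracle(inst$mms, inst$tree, inst$params)
    expect_equal(post@loglik, orc$loglik, tolerance = 1e-8)
    for (ct in names(orc$gamma))
      expect_equal(post@gamma[[ct]], orc$gamma[[ct]], tolerance = 1e-8)
    for (ct in names(orc$xi))
      expect_equal(post@xi[[ct]], orc$xi[[ct]], tolerance = 1e-8)
    expect_equal(dataLoglik(inst$mms, inst$tree, inst$params), orc$loglik,
                 tolerance = 1e-8)
  }
})

test_that("pairwise posteriors are consistent with node marginals", {
  for (s in 1:5) {
    inst <- randomInstance(200 + s)
    post <- eStep(inst$mms, inst$tree, inst$params)
    for (ct in cellTypes(inst$tree))
      expect_equal(rowSums(post@gamma[[ct]]),
                   rep(1, length(loci(inst$mms))), tolerance = 1e-8)
    for (v in names(post@xi)) {
      p <- parentOf(inst$tree, v)
      expect_equal(apply(post@xi[[v]], c(1, 2), sum), post@gamma[[p]],
                   tolerance = 1e-8)
      expect_equal(apply(post@xi[[v]], c(1, 3), sum), post@gamma[[v]],
                   tolerance = 1e-8)
    }
  }
})

test_that("M-step reproduces hand-computed weighted updates", {
  inst <- randomInstance(42, missingRate = 0)
  post <- eStep(inst$mms, inst$tree, inst$params)
  upd <- mStep(inst$mms, inst$tree, post, varFloor = 1e-6)
  n <- length(loci(inst$mms)); k <- inst$k
  # independent recomputation of every update formula
  expect_equal(upd@prior, colSums(post@gamma[[rootOf(inst$tree)]]) / n,
               tolerance = 1e-12)
  for (v in names(post@xi)) {
    num <- apply(post@xi[[v]], c(2, 3), sum)
    expect_equal(unname(upd@transitions[[v]]), num / rowSums(num),
                 tolerance = 1e-12)
  }
  for (ct in cellTypes(inst$mms)) {
    X <- markValues(inst$mms, ct)
    g <- post@gamma[[ct]]
    for (j in seq_len(k)) {
      mu <- colSums(g[, j] * X) / sum(g[, j])
      expect_equal(unname(upd@means[[ct]][j, ]), unname(mu),
                   tolerance = 1e-10)
      s2 <- colSums(g[, j] * sweep(X, 2, mu)^2) / sum(g[, j])
      expect_equal(unname(upd@variances[[ct]][j, ]),
                   unname(pmax(s2, 1e-6)), tolerance = 1e-10)
    }
  }
})

test_that("M-step limiting cases: hard and uniform responsibilities", {
  X <- matrix(c(0, 0, 10, 10, 1, 1, 9, 9), 4, 2,
              dimnames = list(paste0("g", 1:4), c("m1", "m2")))
  mms <- MarkMatrixSet(list(A = X))
  single <- new("LineageTree", nodes = "A", root = "A",
                parent = setNames(character(0), character(0)))
  hard <- new("PosteriorSet",
              gamma = list(A = cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))),
              xi = list(), loglik = 0, perLocusLoglik = numeric(4))
  upd <- mStep(mms, single, hard)
  expect_equal(unname(upd@means$A),
               unname(rbind(colMeans(X[1:2, ]), colMeans(X[3:4, ]))))
  unif <- new("PosteriorSet", gamma = list(A = matrix(0.5, 4, 2)),
              xi = list(), loglik = 0, perLocusLoglik = numeric(4))
  upd2 <- mStep(mms, single, unif)
  expect_equal(unname(upd2@means$A[1, ]), unname(colMeans(X)))
  expect_equal(unname(upd2@means$A[2, ]), unname(colMeans(X)))
})

test_that("EM trace is non-decreasing and fits are seed-deterministic", {
  cfg <- simConfig(nLoci = 300L, k = 3L, m = 3L, seed = 9L)
  sim <- sampleDataset(cfg)
  fit1 <- cmintFit(sim$mms, cfg$tree, 3L, nInit = 2L, seed = 5L)
  expect_true(all(diff(loglikTrace(fit1)) > -1e-6))
  fit2 <- cmintFit(sim$mms, cfg$tree, 3L, nInit = 2L, seed = 5L)
  expect_identical(loglikTrace(fit1), loglikTrace(fit2))
  expect_identical(assignments(fit1), assignments(fit2))
  expect_identical(fittedParams(fit1)@means, fittedParams(fit2)@means)
  expect_error(cmintFit(sim$mms, cfg$tree, 1000L, seed = 1L), "loci")
  expect_error(cmintFit(sim$mms, cfg$tree, 1L, seed = 1L), "at least 2")
})

test_that("single-node fit agrees with plain diagonal-GMM density (mclust)", {
  skip_if_not_installed("mclust")
  set.seed(7)
  X <- matrix(rnorm(400, rep(c(0, 4), each = 100)), 200, 2,
              dimnames = list(paste0("g", 1:200), c("m1", "m2")))
  single <- new("LineageTree", nodes = "A", root = "A",
                parent = setNames(character(0), character(0)))
  params <- CmintParameters(
    prior = c(0.45, 0.55), transitions = list(),
    means = list(A = rbind(c(0, 0), c(4, 4))),
    variances = list(A = rbind(c(1, 1.5), c(0.8, 1.2))))
  ours <- dataLoglik(MarkMatrixSet(list(A = X)), single, params)
  v <- params@variances$A
  scl <- apply(v, 1, function(r) prod(r)^(1 / length(r)))
  dens <- mclust::dens(data = X, modelName = "VVI", parameters = list(
    pro = params@prior,
    mean = t(params@means$A),
    variance = list(modelName = "VVI", d = 2, G = 2,
                    scale = scl, shape = t(v / scl))), logarithm = TRUE)
  expect_equal(ours, sum(dens), tolerance = 1e-8)
})

test_that("mapAssignments takes the argmax with lowest-index tie-break", {
  post <- new("PosteriorSet",
              gamma = list(A = rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))),
              xi = list(), loglik = 0, perLocusLoglik = numeric(3))
  at <- mapAssignments(post)
  expect_equal(unname(at[, "A"]), c(0L, 0L, 1L))
  # random posteriors: equals per-entry argmax recomputed independently
  set.seed(3)
  g <- matrix(runif(40), 10, 4); g <- g / rowSums(g)
  post2 <- new("PosteriorSet", gamma = list(Z = g), xi = list(),
               loglik = 0, perLocusLoglik = numeric(10))
  expect_equal(unname(mapAssignments(post2)[, "Z"]),
               apply(g, 1, which.max) - 1L)
})

test_that("log-likelihood is additive over loci", {
  inst <- randomInstance(77, missingRate = 0)
  mms <- inst$mms
  ll <- dataLoglik(mms, inst$tree, inst$params)
  first <- subsetLoci(mms, loci(mms)[1])
  llFirst <- dataLoglik(first, inst$tree, inst$params)
  # duplicating a locus adds exactly that locus's contribution
  dup <- MarkMatrixSet(lapply(cellTypes(mms), function(ct) {
    v <- markValues(mms, ct)
    v2 <- rbind(v, v[1, , drop = FALSE])
    rownames(v2) <- c(rownames(v), "dup")
    v2
  }) |> setNames(cellTypes(mms)))
  expect_equal(dataLoglik(dup, inst$tree, inst$params), ll + llFirst,
               tolerance = 1e-8)
})

test_that("fit recovers known parameters on well-separated simulated data", {
  cfg <- simConfig(nLoci = 2000L, k = 4L, m = 3L, meanSep = 3, seed = 31L)
  sim <- sampleDataset(cfg)
  fit <- cmintFit(sim$mms, cfg$tree, 4L, seed = 8L)
  est <- fittedParams(fit)
  # optimal global module relabeling via Hungarian on summed mean distance
  cost <- matrix(0, 4, 4)
  for (ct in cellTypes(sim$mms))
    cost <- cost + as.matrix(dist(rbind(sim$params@means[[ct]],
                                        est@means[[ct]])))[1:4, 5:8]^2
  perm <- hungarianMatch(cost)
  meanErr <- max(vapply(cellTypes(sim$mms), function(ct)
    max(abs(sim$params@means[[ct]] - est@means[[ct]][perm, ])), 0))
  expect_lt(meanErr, 0.15)
})
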