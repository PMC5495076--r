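# Cluster-quality metrics (silhouette, coherence), transition-detection
# precision/recall/F-score against a ground-truth assignment table, and the
# two module-similarity matrices (two-background hypergeometric and
# F-score).

#' Mean silhouette index of a clustering
#'
#' Mean over loci of `(b - a) / max(a, b)` with `a` the mean intra-cluster
#' Euclidean distance and `b` the smallest mean distance to another cluster
#' (computed through [cluster::silhouette()]); members of singleton clusters
#' contribute 0.
#'
#' @param data loci x features numeric matrix.
#' @param labels cluster label per row (any atomic type).
#' @return scalar in \[-1, 1\].
#' @export
silhouetteIndex <- function(data, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L)
    stop("silhouette needs at least two clusters")
  sil <- cluster::silhouette(labels, dist(data))
  mean(sil[, "sil_width"])
}

#' Mean cluster coherence
#'
#' Mean over clusters of the mean Pearson correlation between each member's
#' profile and its cluster's mean profile. Members with a constant profile
#' (zero variance) contribute a correlation of 0.
#'
#' @inheritParams silhouetteIndex
#' @return scalar in \[-1, 1\].
#' @export
clusterCoherence <- function(data, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L)
    stop("coherence needs at least two clusters")
  perCluster <- vapply(unique(labels), function(l) {
    X <- data[labels == l, , drop = FALSE]
    centroid <- colMeans(X)
    if (sd(centroid) == 0) return(0)
    cors <- apply(X, 1, function(r) {
      if (sd(r) == 0) 0 else cor(r, centroid)
    })
    mean(cors)
  }, 0)
  mean(perCluster)
}

# (locus, branch) pairs whose module changes parent -> child
transitionEvents <- function(at, tree) {
  ev <- character(0)
  for (ch in setdiff(colnames(at), rootOf(tree))) {
    p <- parentOf(tree, ch)
    moved <- which(at[, ch] != at[, p])
    if (length(moved)) ev <- c(ev, paste(rownames(at)[moved], ch, sep = "|"))
  }
  ev
}

#' Precision/recall/F-score of detected module transitions
#'
#' A transition event is a (locus, branch) pair whose MAP module differs
#' between parent and child cell type. Inferred labels are first matched to
#' the truth labels by maximum overlap ([hungarianMatch()] on the
#' contingency overlap summed over cell types); a single global permutation
#' is used so that the inferred table's own transition structure is
#' preserved. Events are then compared as sets. With no inferred events,
#' precision is 0 unless the truth has none either (then 1); recall
#' symmetrically.
#'
#' @param inferred,truth integer loci x cell-type assignment matrices over
#'   the same loci and cell types, with equal module counts.
#' @param tree the [LineageTree-class] defining the branches.
#' @return named numeric vector `c(precision, recall, fscore)`.
#' @export
transitionPRF <- function(inferred, truth, tree) {
  stopifnot(identical(dim(inferred), dim(truth)))
  ki <- max(attr(inferred, "k"), max(inferred) + 1L)
  kt <- max(attr(truth, "k"), max(truth) + 1L)
  if (ki != kt) stop("inferred and truth use different module counts")
  k <- kt
  overlap <- matrix(0, k, k)
  for (ct in colnames(inferred)) {
    tab <- table(factor(truth[, ct], levels = 0:(k - 1)),
                 factor(inferred[, ct], levels = 0:(k - 1)))
    overlap <- overlap + matrix(as.numeric(tab), k, k)
  }
  perm <- hungarianMatch(-overlap)     # perm[i] = inferred label for truth i-1
  relabel <- integer(k)
  relabel[perm] <- seq_len(k)
  matched <- inferred
  matched[] <- relabel[inferred + 1L] - 1L
  evI <- transitionEvents(matched, tree)
  evT <- transitionEvents(truth, tree)
  inter <- length(intersect(evI, evT))
  precision <- if (length(evI) == 0) as.numeric(length(evT) == 0)
               else inter / length(evI)
  recall <- if (length(evT) == 0) as.numeric(length(evI) == 0)
            else inter / length(evT)
  fscore <- if (precision + recall == 0) 0
            else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, fscore = fscore)
}

# upper-tail hypergeometric p including the observed overlap
hyperUpperP <- function(overlap, sizeA, sizeB, universe) {
  stats::phyper(overlap - 1, sizeA, universe - sizeA, sizeB,
                lower.tail = FALSE)
}

#' Two-background hypergeometric module-similarity matrix
#'
#' Entry (i, j) is the mean of the negative log10 of two upper-tail
#' hypergeometric p-values for the overlap between the loci in module i of
#' `a` and module j of `b`: one p-value uses the first cell type's locus
#' universe as background, the other the second's. P-values are floored at
#' 1e-300 before taking logs; a pairing involving an empty module scores 0.
#'
#' @param a,b integer assignment vectors (0-based) over the same loci; names
#'   are locus ids.
#' @param k module count; defaults to the largest label + 1.
#' @return k x k numeric matrix with attributes `metric` and
#'   `backgroundSizes`.
#' @export
moduleSimilarityHypergeom <- function(a, b, k = NULL) {
  stopifnot(length(a) == length(b))
  if (is.null(k)) k <- max(a, b, na.rm = TRUE) + 1L
  # each background universe = loci actually assigned in that cell type
  Na <- sum(!is.na(a)); Nb <- sum(!is.na(b))
  out <- matrix(0, k, k)
  for (i in seq_len(k) - 1L) {
    Ai <- which(a == i)
    if (!length(Ai)) next
    for (j in seq_len(k) - 1L) {
      Bj <- which(b == j)
      if (!length(Bj)) next
      ov <- length(intersect(Ai, Bj))
      p1 <- max(hyperUpperP(ov, length(Ai), length(Bj), Na), 1e-300)
      p2 <- max(hyperUpperP(ov, length(Ai), length(Bj), Nb), 1e-300)
      out[i + 1L, j + 1L] <- mean(c(-log10(p1), -log10(p2)))
    }
  }
  attr(out, "metric") <- "neglog_hypergeometric_mean"
  attr(out, "backgroundSizes") <- c(Na, Nb)
  out
}

#' F-score module-similarity matrix
#'
#' Entry (i, j) is `2 |A_i intersect B_j| / (|A_i| + |B_j|)`, the Dice
#' F-score of the two locus sets; 0 when both are empty. Swapping the two
#' assignment vectors transposes the matrix.
#'
#' @inheritParams moduleSimilarityHypergeom
#' @return k x k numeric matrix with entries in \[0, 1\] and a `metric`
#'   attribute.
#' @export
moduleSimilarityFscore <- function(a, b, k = NULL) {
  stopifnot(length(a) == length(b))
  if (is.null(k)) k <- max(a, b) + 1L
  out <- matrix(0, k, k)
  for (i in seq_len(k) - 1L) {
    Ai <- which(a == i)
    for (j in seq_len(k) - 1L) {
      Bj <- which(b == j)
      denom <- length(Ai) + length(Bj)
      out[i + 1L, j + 1L] <- if (denom == 0) 0
        else 2 * length(intersect(Ai, Bj)) / denom
    }
  }
  attr(out, "metric") <- "fscore"
  out
}

#' Write a module-similarity matrix with a metadata header
#' @param sim matrix from [moduleSimilarityHypergeom()] or
#'   [moduleSimilarityFscore()].
#' @param path output file.
#' @export
writeSimilarityMatrix <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metric: %s", attr(sim, "metric")), con)
  bg <- attr(sim, "backgroundSizes")
  if (!is.null(bg))
    writeLines(sprintf("# background sizes: %s", paste(bg, collapse = ", ")),
               con)
  write.table(sim, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
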