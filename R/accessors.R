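# Accessor generics and show() methods for the core classes.

#' Cell types of an object
#' @param x a MarkMatrixSet or LineageTree.
#' @return character vector of cell-type identifiers.
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "MarkMatrixSet", function(x) x@cellTypes)

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "LineageTree", function(x) x@nodes)

#' Mark names
#' @param x a MarkMatrixSet.
#' @return character vector of mark names.
#' @export
setGeneric("markNames", function(x) standardGeneric("markNames"))

#' @rdname markNames
#' @export
setMethod("markNames", "MarkMatrixSet", function(x) x@marks)

#' Locus identifiers
#' @param x a MarkMatrixSet.
#' @return character vector of locus ids.
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname loci
#' @export
setMethod("loci", "MarkMatrixSet", function(x) x@loci)

#' Signal matrix for one cell type
#'
#' @param x a MarkMatrixSet.
#' @param cellType cell-type identifier.
#' @return loci x marks numeric matrix; missing entries are `NA`.
#' @export
markValues <- function(x, cellType) {
  stopifnot(is(x, "MarkMatrixSet"), cellType %in% x@cellTypes)
  x@values[[cellType]]
}

#' Missingness mask for one cell type
#' @inheritParams markValues
#' @return loci x marks logical matrix, TRUE where unmeasured.
#' @export
missingMask <- function(x, cellType) {
  stopifnot(is(x, "MarkMatrixSet"), cellType %in% x@cellTypes)
  x@missing[[cellType]]
}

#' Root of a lineage tree
#' @param x a LineageTree.
#' @return the root cell type.
#' @export
rootOf <- function(x) {
  stopifnot(is(x, "LineageTree"))
  x@root
}

#' Parent of a node
#' @param x a LineageTree.
#' @param node a non-root node.
#' @return the parent cell type.
#' @export
parentOf <- function(x, node) {
  stopifnot(is(x, "LineageTree"))
  if (node == x@root) stop("the root has no parent")
  unname(x@parent[[node]])
}

#' Children of a node
#' @param x a LineageTree.
#' @param node a node.
#' @return character vector (possibly empty) of children.
#' @export
childrenOf <- function(x, node) {
  stopifnot(is(x, "LineageTree"))
  names(x@parent)[x@parent == node]
}

# Nodes ordered root-first so every parent precedes its children.
topoOrder <- function(tree) {
  ord <- tree@root
  frontier <- childrenOf(tree, tree@root)
  while (length(frontier)) {
    ord <- c(ord, frontier[1])
    frontier <- c(frontier[-1], childrenOf(tree, frontier[1]))
  }
  ord
}

#' Number of modules
#' @param x a CmintParameters or CmintFit.
#' @return integer module count k.
#' @export
setGeneric("nModules", function(x) standardGeneric("nModules"))

#' @rdname nModules
#' @export
setMethod("nModules", "CmintParameters", function(x) x@k)

#' @rdname nModules
#' @export
setMethod("nModules", "CmintFit", function(x) x@params@k)

#' Fitted parameters of a model fit
#' @param x a CmintFit.
#' @return the [CmintParameters-class] of the fit.
#' @export
fittedParams <- function(x) { stopifnot(is(x, "CmintFit")); x@params }

#' Posteriors of a model fit
#' @param x a CmintFit.
#' @return the [PosteriorSet-class] of the fit.
#' @export
posteriors <- function(x) { stopifnot(is(x, "CmintFit")); x@posteriors }

#' MAP assignment table of a fit
#' @param x a CmintFit.
#' @return integer loci x cell-type matrix of 0-based module indices, with a
#'   `k` attribute.
#' @export
assignments <- function(x) { stopifnot(is(x, "CmintFit")); x@assignments }

#' Log-likelihood trace of a fit
#' @param x a CmintFit.
#' @return numeric vector, one entry per EM iteration.
#' @export
loglikTrace <- function(x) { stopifnot(is(x, "CmintFit")); x@loglikTrace }

#' Total data log-likelihood
#' @param x a PosteriorSet or CmintFit.
#' @return scalar log-likelihood.
#' @export
setGeneric("totalLogLik", function(x) standardGeneric("totalLogLik"))

#' @rdname totalLogLik
#' @export
setMethod("totalLogLik", "PosteriorSet", function(x) x@loglik)

#' @rdname totalLogLik
#' @export
setMethod("totalLogLik", "CmintFit", function(x) x@posteriors@loglik)

setMethod("show", "MarkMatrixSet", function(object) {
  cat(sprintf("MarkMatrixSet: %d loci x %d marks in %d cell types\n",
              length(object@loci), length(object@marks),
              length(object@cellTypes)))
  cat("  cell types:", paste(object@cellTypes, collapse = ", "), "\n")
  cat("  marks:     ", paste(object@marks, collapse = ", "), "\n")
  nmiss <- sum(vapply(object@missing, sum, 0L))
  ntot <- length(object@loci) * length(object@marks) * length(object@cellTypes)
  cat(sprintf("  missing:    %d / %d entries (%.1f%%)\n", nmiss, ntot,
              100 * nmiss / ntot))
})

setMethod("show", "LineageTree", function(object) {
  cat(sprintf("LineageTree: %d cell types, root '%s'\n",
              length(object@nodes), object@root))
  for (ch in names(object@parent))
    cat(sprintf("  %s -> %s\n", object@parent[[ch]], ch))
})

setMethod("show", "CmintParameters", function(object) {
  m <- if (length(object@means)) ncol(object@means[[1]]) else 0L
  cat(sprintf("CmintParameters: k = %d modules, %d marks, %d cell types, %d branches\n",
              object@k, m, length(object@means), length(object@transitions)))
})

setMethod("show", "CmintFit", function(object) {
  cat(sprintf("CmintFit: k = %d, logLik = %.4f, %d iterations (%s), seed %d\n",
              object@params@k, object@posteriors@loglik, object@nIter,
              if (object@converged) "converged" else "not converged",
              object@seed))
})

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport (%s): selected '%s'\n", object@what,
              object@selected))
  mu <- rowMeans(object@scores)
  for (i in seq_along(object@candidates))
    cat(sprintf("  %-12s mean score %.4f\n", object@candidates[i], mu[i]))
})

setMethod("show", "TransitionRule", function(object) {
  if (object@type == "pattern") {
    pat <- ifelse(is.na(object@modules), "*", object@modules)
    cat("TransitionRule (pattern):", paste(pat, collapse = "-"), "\n")
  } else {
    cat("TransitionRule (threshold):",
        paste(sprintf("%s%s%d", object@cellTypes, object@ops, object@values),
              collapse = " AND "), "\n")
  }
})
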