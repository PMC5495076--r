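#' @import methods
#' @importFrom stats dist cor sd var setNames phyper p.adjust pt rnorm runif
#'   quantile median complete.cases t.test
#' @importFrom utils read.delim write.table head
NULL

#' MarkMatrixSet: per-cell-type chromatin mark signal on a shared locus universe
#'
#' Container for the observed data of the tree-coupled chromatin module model:
#' one loci x marks real matrix per cell type, all matrices sharing the same
#' row (locus) and column (mark) ordering. Entries with no measurement are
#' recorded in a parallel logical mask, never silently zero-filled; downstream
#' likelihood computations marginalize missing mark dimensions.
#'
#' @slot cellTypes character vector of cell-type identifiers (ordered).
#' @slot marks character vector of mark names, shared across cell types.
#' @slot loci character vector of unique locus identifiers.
#' @slot values named list (one per cell type) of loci x marks numeric
#'   matrices.
#' @slot missing named list of logical matrices of the same shape; TRUE flags
#'   an entry with no measurement.
#'
#' @seealso [MarkMatrixSet()] constructor, [readMarkMatrices()],
#'   [normalizeAndLog()], [filterLoci()]
#' @export
setClass("MarkMatrixSet",
  representation(
    cellTypes = "character",
    marks = "character",
    loci = "character",
    values = "list",
    missing = "list"
  )
)

setValidity("MarkMatrixSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@loci))
    msg <- c(msg, "locus identifiers must be unique")
  if (anyDuplicated(object@cellTypes))
    msg <- c(msg, "cell-type identifiers must be unique")
  if (!identical(names(object@values), object@cellTypes) ||
      !identical(names(object@missing), object@cellTypes))
    msg <- c(msg, "values/missing lists must be named by cellTypes, in order")
  for (ct in object@cellTypes) {
    v <- object@values[[ct]]
    mis <- object@missing[[ct]]
    if (!is.matrix(v) || !is.numeric(v) ||
        nrow(v) != length(object@loci) || ncol(v) != length(object@marks)) {
      msg <- c(msg, sprintf("matrix for '%s' has wrong shape or type", ct))
      next
    }
    if (!identical(dim(mis), dim(v)) || !is.logical(mis))
      msg <- c(msg, sprintf("missing mask for '%s' does not match values", ct))
    if (any(is.na(v[!mis])))
      msg <- c(msg, sprintf("non-missing entries of '%s' contain NA", ct))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MarkMatrixSet
#'
#' @param values named list of loci x marks numeric matrices, one per cell
#'   type. Matrices must share dimnames. `NA` entries are interpreted as
#'   missing measurements.
#' @param missing optional named list of logical masks; defaults to
#'   `is.na(values)`.
#' @return A [MarkMatrixSet-class] object.
#' @examples
#' x <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("m1", "m2")))
#' mms <- MarkMatrixSet(list(A = x, B = x + 1))
#' cellTypes(mms)
#' @export
MarkMatrixSet <- function(values, missing = NULL) {
  stopifnot(is.list(values), length(values) >= 1, !is.null(names(values)))
  cts <- names(values)
  ref <- values[[1]]
  loci <- rownames(ref)
  marks <- colnames(ref)
  if (is.null(loci) && nrow(ref) == 0L) loci <- character(0)
  if (is.null(loci) || is.null(marks))
    stop("matrices must carry locus rownames and mark colnames")
  values <- lapply(values, function(v) {
    storage.mode(v) <- "double"
    v[loci, marks, drop = FALSE]
  })
  if (is.null(missing)) {
    missing <- lapply(values, is.na)
  } else {
    missing <- lapply(missing, function(m) m[loci, marks, drop = FALSE])
  }
  names(missing) <- cts
  # masked entries are stored as NA so they can never leak into arithmetic
  values <- mapply(function(v, m) { v[m] <- NA_real_; v },
                   values, missing, SIMPLIFY = FALSE)
  new("MarkMatrixSet", cellTypes = cts, marks = marks, loci = loci,
      values = values, missing = missing)
}

#' LineageTree: rooted tree over cell types
#'
#' A rooted tree whose nodes are observed cell types. Edges carry the
#' module transition matrices of the model; the class itself stores only the
#' topology as a parent map. Arbitrary branching factors are allowed.
#'
#' @slot nodes character vector of cell-type identifiers.
#' @slot root the designated root cell type.
#' @slot parent named character vector mapping each non-root node to its
#'   parent.
#'
#' @seealso [LineageTree()], [readLineageTree()], [childrenOf()]
#' @export
setClass("LineageTree",
  representation(nodes = "character", root = "character", parent = "character")
)

setValidity("LineageTree", function(object) {
  msg <- character()
  if (length(object@root) != 1L || !(object@root %in% object@nodes))
    msg <- c(msg, "exactly one root, drawn from nodes, is required")
  nonroot <- setdiff(object@nodes, object@root)
  if (!setequal(names(object@parent), nonroot))
    msg <- c(msg, "every non-root node needs exactly one parent entry")
  if (!all(object@parent %in% object@nodes))
    msg <- c(msg, "parent entries must be nodes")
  # acyclicity: walking up from any node must reach the root
  for (v in nonroot) {
    seen <- character()
    while (v != object@root) {
      if (v %in% seen) return("tree contains a cycle")
      seen <- c(seen, v)
      v <- object@parent[[v]]
      if (is.null(v) || is.na(v)) return("broken parent chain")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LineageTree
#'
#' @param parent named character vector: `parent["child"] = "parent"` for
#'   every non-root node.
#' @param root the root cell type; inferred as the unique node that is a
#'   parent but never a child when omitted.
#' @return A [LineageTree-class].
#' @examples
#' chain <- LineageTree(c(B = "A", C = "B"))
#' rootOf(chain)
#' childrenOf(chain, "A")
#' @export
LineageTree <- function(parent, root = NULL) {
  nodes <- union(unname(parent), names(parent))
  if (is.null(root)) {
    cand <- setdiff(unname(parent), names(parent))
    if (length(cand) != 1L)
      stop("cannot infer a unique root; pass `root=`")
    root <- cand
  }
  new("LineageTree", nodes = nodes, root = root, parent = parent)
}

#' CmintParameters: full parameter set of the tree-coupled mixture model
#'
#' @slot k module count.
#' @slot prior length-k module prior at the root cell type.
#' @slot transitions named list (one per non-root cell type) of k x k
#'   row-stochastic matrices; entry `[i, j]` is the probability that a locus
#'   in module `i` of the parent is in module `j` of the child.
#' @slot means named list (per cell type) of k x m Gaussian mean matrices.
#' @slot variances named list (per cell type) of k x m per-dimension variance
#'   matrices, all entries at or above the variance floor used in fitting.
#' @export
setClass("CmintParameters",
  representation(k = "integer", prior = "numeric", transitions = "list",
                 means = "list", variances = "list")
)

setValidity("CmintParameters", function(object) {
  msg <- character()
  k <- object@k
  if (abs(sum(object@prior) - 1) > 1e-9 || length(object@prior) != k)
    msg <- c(msg, "prior must be a length-k probability vector")
  for (nm in names(object@transitions)) {
    T_ <- object@transitions[[nm]]
    if (!is.matrix(T_) || any(dim(T_) != k))
      msg <- c(msg, sprintf("transition matrix for '%s' is not k x k", nm))
    else if (any(abs(rowSums(T_) - 1) > 1e-9) || any(T_ < 0))
      msg <- c(msg, sprintf("transition rows for '%s' must sum to 1", nm))
  }
  for (nm in names(object@means)) {
    mu <- object@means[[nm]]; s2 <- object@variances[[nm]]
    if (!is.matrix(mu) || nrow(mu) != k)
      msg <- c(msg, sprintf("means for '%s' must be k x m", nm))
    if (!is.matrix(s2) || !identical(dim(s2), dim(mu)) || any(s2 <= 0))
      msg <- c(msg, sprintf("variances for '%s' must be positive k x m", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CmintParameters object
#'
#' @param prior length-k root module prior.
#' @param transitions named list of k x k row-stochastic matrices, one per
#'   non-root cell type.
#' @param means,variances named lists of k x m matrices per cell type.
#' @return A [CmintParameters-class].
#' @export
CmintParameters <- function(prior, transitions, means, variances) {
  new("CmintParameters", k = length(prior), prior = prior,
      transitions = transitions, means = means, variances = variances)
}

#' PosteriorSet: exact posteriors from one E-step
#'
#' @slot gamma named list (per cell type) of n x k node marginal matrices;
#'   rows sum to 1.
#' @slot xi named list (per non-root cell type) of n x k x k arrays of
#'   pairwise branch posteriors over (parent module, child module); each
#'   locus slice sums to 1, its row sums equal the parent's marginal and its
#'   column sums the child's.
#' @slot loglik total data log-likelihood.
#' @slot perLocusLoglik length-n vector of per-locus log evidence.
#' @export
setClass("PosteriorSet",
  representation(gamma = "list", xi = "list", loglik = "numeric",
                 perLocusLoglik = "numeric")
)

#' CmintFit: result of fitting the tree-coupled mixture model
#'
#' @slot params fitted [CmintParameters-class].
#' @slot posteriors [PosteriorSet-class] at the fitted parameters.
#' @slot assignments integer loci x cell-type matrix of MAP module indices
#'   (0-based).
#' @slot loglikTrace per-iteration log-likelihood of the selected run.
#' @slot seed integer seed the run used.
#' @slot nIter iterations run.
#' @slot converged logical.
#' @export
setClass("CmintFit",
  representation(params = "CmintParameters", posteriors = "PosteriorSet",
                 assignments = "matrix", loglikTrace = "numeric",
                 seed = "integer", nIter = "integer", converged = "logical")
)

#' TransitionRule: declarative locus-selection pattern over module assignments
#'
#' Either an exact per-cell-type module pattern with wildcards (e.g.
#' `"5-6-8"`, `"*-6-*"`) or a conjunction of per-cell-type threshold
#' comparisons on the module index (e.g. `"MEP>10,GMP<4"`).
#'
#' @slot type `"pattern"` or `"threshold"`.
#' @slot cellTypes cell types the clauses refer to, in clause order.
#' @slot modules integer pattern (NA = wildcard) for pattern rules.
#' @slot ops character comparison operators (`">"`, `"<"`, `">="`, `"<="`,
#'   `"=="`) for threshold rules.
#' @slot values integer comparison values for threshold rules.
#' @seealso [parseRule()], [applyRule()]
#' @export
setClass("TransitionRule",
  representation(type = "character", cellTypes = "character",
                 modules = "integer", ops = "character", values = "integer")
)

#' SelectionReport: scores from model or topology selection
#'
#' @slot candidates candidate labels (k values or topology names).
#' @slot scores candidates x (fold or run) numeric score matrix.
#' @slot selected the winning candidate label.
#' @slot pvalues pairwise Welch t-test p-value matrix (topology comparison)
#'   or a 0 x 0 matrix.
#' @slot what `"k"` or `"topology"`.
#' @export
setClass("SelectionReport",
  representation(candidates = "character", scores = "matrix",
                 selected = "character", pvalues = "matrix", what = "character")
)

setValidity("SelectionReport", function(object) {
  if (!(object@selected %in% object@candidates))
    return("selected candidate must be among candidates")
  if (nrow(object@scores) != length(object@candidates))
    return("scores must have one row per candidate")
  TRUE
})
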