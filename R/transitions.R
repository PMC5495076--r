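# Downstream analyses on assignment tables: declarative transition rules,
# cell-type-unique module regions, hypergeometric enrichment with BH FDR,
# and expression-level discretization.

#' Parse a transition rule string
#'
#' Two syntaxes are accepted. A pattern rule lists one module index (or `*`
#' wildcard) per cell type, dash-separated and in the order of `cellTypes`:
#' `"5-6-8"`, `"*-6-*"`. A threshold rule is a comma-separated conjunction
#' of comparisons on the module index: `"MEP>10,GMP<4"` (operators `>`,
#' `<`, `>=`, `<=`, `==`).
#'
#' @param text rule string.
#' @param cellTypes cell-type order for pattern rules (required for
#'   patterns, ignored for threshold rules).
#' @return a [TransitionRule-class].
#' @export
parseRule <- function(text, cellTypes = NULL) {
  text <- gsub("\\s", "", text)
  if (grepl("[<>=]", text)) {
    clauses <- strsplit(text, ",")[[1]]
    m <- regmatches(clauses,
                    regexec("^([^<>=]+)(>=|<=|==|>|<)([0-9]+)$", clauses))
    if (any(lengths(m) != 4L)) stop("malformed threshold clause")
    new("TransitionRule", type = "threshold",
        cellTypes = vapply(m, `[`, "", 2L),
        modules = NA_integer_,
        ops = vapply(m, `[`, "", 3L),
        values = as.integer(vapply(m, `[`, "", 4L)))
  } else {
    parts <- strsplit(text, "-")[[1]]
    if (is.null(cellTypes))
      stop("pattern rules need the cell-type order")
    if (length(parts) != length(cellTypes))
      stop("pattern length must equal the number of cell types")
    mods <- suppressWarnings(as.integer(parts))
    if (any(is.na(mods) & parts != "*")) stop("malformed pattern entry")
    new("TransitionRule", type = "pattern", cellTypes = cellTypes,
        modules = mods, ops = character(0), values = integer(0))
  }
}

#' Select loci matching a transition rule
#'
#' @param at integer loci x cell-type assignment matrix.
#' @param rule a [TransitionRule-class] or a rule string (parsed with the
#'   table's cell-type order).
#' @return character vector of matching locus ids, in table order.
#' @export
applyRule <- function(at, rule) {
  if (is.character(rule)) rule <- parseRule(rule, colnames(at))
  if (!all(rule@cellTypes %in% colnames(at)))
    stop("rule refers to cell types absent from the table")
  keep <- rep(TRUE, nrow(at))
  if (rule@type == "pattern") {
    for (i in seq_along(rule@cellTypes)) {
      if (!is.na(rule@modules[i]))
        keep <- keep & at[, rule@cellTypes[i]] == rule@modules[i]
    }
  } else {
    for (i in seq_along(rule@cellTypes)) {
      col <- at[, rule@cellTypes[i]]
      keep <- keep & switch(rule@ops[i],
        ">" = col > rule@values[i], "<" = col < rule@values[i],
        ">=" = col >= rule@values[i], "<=" = col <= rule@values[i],
        "==" = col == rule@values[i])
    }
  }
  rownames(at)[keep]
}

#' Loci uniquely in a module in one cell type
#'
#' Loci assigned to `moduleId` in `cellType` but to a different module in
#' every other cell type of the table.
#'
#' @param at integer loci x cell-type assignment matrix.
#' @param moduleId 0-based module index.
#' @param cellType the cell type of interest.
#' @return character vector of locus ids.
#' @export
uniqueModuleLoci <- function(at, moduleId, cellType) {
  stopifnot(cellType %in% colnames(at))
  others <- setdiff(colnames(at), cellType)
  keep <- at[, cellType] == moduleId &
    rowSums(at[, others, drop = FALSE] == moduleId) == 0
  rownames(at)[keep]
}

#' Hypergeometric enrichment of locus sets in annotation terms
#'
#' For every (query set, annotation term) pair, the upper-tail
#' hypergeometric p-value of the overlap against the universe, followed by
#' Benjamini-Hochberg adjustment across all terms *within each query set*
#' (independent query sets are corrected independently; output headers state
#' this scope).
#'
#' @param locusSets named list of character vectors (query sets, e.g. module
#'   memberships or rule matches), each a subset of `universe`.
#' @param annotations named list of character vectors (term -> locus ids).
#' @param universe character vector of all eligible loci.
#' @return data.frame with columns set, term, overlap, setSize, termSize,
#'   universe, p, q; sorted by q then p within each set.
#' @export
enrichLoci <- function(locusSets, annotations, universe) {
  stopifnot(is.list(locusSets), is.list(annotations))
  annotations <- lapply(annotations, intersect, universe)
  out <- do.call(rbind, lapply(names(locusSets), function(sn) {
    qset <- intersect(locusSets[[sn]], universe)
    if (length(setdiff(locusSets[[sn]], universe)))
      stop(sprintf("query set '%s' is not a subset of the universe", sn))
    rows <- do.call(rbind, lapply(names(annotations), function(tn) {
      tset <- annotations[[tn]]
      ov <- length(intersect(qset, tset))
      p <- hyperUpperP(ov, length(tset), length(qset), length(universe))
      data.frame(set = sn, term = tn, overlap = ov,
                 setSize = length(qset), termSize = length(tset),
                 universe = length(universe), p = p)
    }))
    rows$q <- p.adjust(rows$p, method = "BH")
    rows[order(rows$q, rows$p), ]
  }))
  rownames(out) <- NULL
  out
}

#' Map annotation regions to loci by genomic overlap
#'
#' An annotation region maps to a locus when their intervals overlap by at
#' least one base. Annotations arrive as BED with a term column (column 5,
#' after the id/name column).
#'
#' @param annotGr GRanges of annotation regions with a `term` metadata
#'   column.
#' @param lociGr GRanges of loci with an `id` column, as from
#'   [readRegions()].
#' @return named list term -> character vector of locus ids.
#' @export
annotationToLocusSets <- function(annotGr, lociGr) {
  hits <- GenomicRanges::findOverlaps(annotGr, lociGr)
  if (!length(hits)) return(list())
  d <- data.frame(term = annotGr$term[S4Vectors::queryHits(hits)],
                  id = lociGr$id[S4Vectors::subjectHits(hits)])
  lapply(split(d$id, d$term), unique)
}

#' Discretize log-scale expression into low/medium/high
#'
#' Three-way labelling of per-gene log expression at fixed thresholds
#' (defaults 5.92 and 9.2, the cutoffs obtained by fitting a 3-component
#' Gaussian mixture to log absolute expression in the reprogramming
#' system). Boundary values are assigned to the lower class.
#'
#' @param expr numeric vector of log-scale expression, names = gene ids.
#' @param low low/medium boundary.
#' @param high medium/high boundary.
#' @return factor with levels low, medium, high.
#' @export
discretizeExpression <- function(expr, low = 5.92, high = 9.2) {
  lab <- ifelse(expr <= low, "low", ifelse(expr <= high, "medium", "high"))
  factor(setNames(lab, names(expr)), levels = c("low", "medium", "high"))
}

#' Derive expression thresholds from a 1-D Gaussian mixture
#'
#' Fits a univariate 3-component Gaussian mixture to log expression (via
#' the package's own EM on a single-node tree) and returns the two posterior
#' crossover points between components ordered by mean. Useful when the
#' fixed default thresholds of [discretizeExpression()] do not suit a
#' dataset.
#'
#' @param expr numeric vector of log-scale expression.
#' @param seed integer seed for the mixture fit.
#' @return numeric `c(low, high)` crossover thresholds.
#' @export
expressionThresholds <- function(expr, seed = 1L) {
  X <- matrix(expr, ncol = 1, dimnames = list(paste0("g", seq_along(expr)),
                                              "expr"))
  fit <- singleGmm(X, 3L, seed, nInit = 3L)
  p <- fittedParams(fit)
  ordc <- order(p@means[["only"]][, 1])
  grid <- seq(min(expr), max(expr), length.out = 4096)
  dens <- vapply(ordc, function(j)
    log(p@prior[j]) + stats::dnorm(grid, p@means[["only"]][j, 1],
                                   sqrt(p@variances[["only"]][j, 1]),
                                   log = TRUE), numeric(length(grid)))
  cls <- max.col(dens, ties.method = "first")
  c(low = max(grid[cls == 1]), high = max(grid[cls != 3]))
}
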