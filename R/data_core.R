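# File I/O and preprocessing: tab-delimited mark matrices, lineage tree
# files, BED-like regions, window aggregation, depth normalization, locus
# filtering, assignment-table round trips.

#' Read per-cell-type mark matrices
#'
#' Each file is tab-delimited with a header row of mark names and a first
#' column of locus identifiers. Matrices are aligned to the intersection of
#' loci across files (default) or their union, in which case rows absent from
#' a file are flagged missing. Mark columns are harmonized to the order of
#' the first file; files whose mark set differs are an error. When several
#' files are supplied for one cell type they are treated as replicates and
#' collapsed entry-wise by the median.
#'
#' @param paths named character vector (or named list of character vectors,
#'   for replicates) of file paths; names are cell types.
#' @param tree optional [LineageTree-class]; when given, cell types are
#'   checked and ordered against it.
#' @param union if TRUE, keep the union of loci and flag absences as missing;
#'   default keeps the intersection.
#' @return A [MarkMatrixSet-class].
#' @export
readMarkMatrices <- function(paths, tree = NULL, union = FALSE) {
  if (!is.list(paths)) paths <- as.list(paths)
  cts <- names(paths)
  if (is.null(cts) || any(cts == ""))
    stop("paths must be named by cell type")
  if (!is.null(tree)) {
    if (!setequal(cts, tree@nodes))
      stop("cell types in paths do not match the tree's nodes")
    paths <- paths[topoOrder(tree)]
    cts <- names(paths)
  }
  readOne <- function(f) {
    d <- read.delim(f, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
    ids <- as.character(d[[1]])
    if (anyDuplicated(ids))
      stop(sprintf("duplicate locus id '%s' in %s",
                   ids[duplicated(ids)][1], f))
    m <- as.matrix(d[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  }
  mats <- lapply(cts, function(ct) {
    reps <- lapply(paths[[ct]], readOne)
    marks0 <- colnames(reps[[1]])
    for (i in seq_along(reps)) {
      if (!setequal(colnames(reps[[i]]), marks0))
        stop(sprintf("mark set of %s disagrees with its first replicate",
                     paths[[ct]][i]))
      reps[[i]] <- reps[[i]][, marks0, drop = FALSE]
    }
    if (length(reps) == 1L) return(reps[[1]])
    shared <- Reduce(intersect, lapply(reps, rownames))
    arr <- vapply(reps, function(r) r[shared, , drop = FALSE],
                  reps[[1]][shared, , drop = FALSE])
    med <- apply(arr, c(1, 2), median, na.rm = TRUE)
    med[is.nan(med)] <- NA_real_
    dimnames(med) <- list(shared, marks0)
    med
  })
  names(mats) <- cts
  marks <- colnames(mats[[1]])
  for (ct in cts) {
    if (!setequal(colnames(mats[[ct]]), marks))
      stop(sprintf("mark set for cell type '%s' (%s) does not match '%s'",
                   ct, paste(unlist(paths[[ct]]), collapse = ","), cts[1]))
    mats[[ct]] <- mats[[ct]][, marks, drop = FALSE]
  }
  lc <- lapply(mats, rownames)
  ids <- if (union) Reduce(base::union, lc) else Reduce(intersect, lc)
  if (!length(ids)) stop("no loci shared across files")
  full <- lapply(mats, function(m) {
    out <- matrix(NA_real_, length(ids), length(marks),
                  dimnames = list(ids, marks))
    keep <- intersect(ids, rownames(m))
    out[keep, ] <- m[keep, ]
    out
  })
  MarkMatrixSet(full)
}

#' Write one cell type's mark matrix
#'
#' Inverse of [readMarkMatrices()] for a single cell type: tab-delimited,
#' locus ids in the first column (`locus`), one column per mark. Missing
#' entries are written as `NA`.
#'
#' @param mms a [MarkMatrixSet-class].
#' @param cellType which cell type to write.
#' @param path output file.
#' @export
writeMarkMatrix <- function(mms, cellType, path) {
  v <- markValues(mms, cellType)
  d <- data.frame(locus = rownames(v), v, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a lineage tree file
#'
#' Accepts either a two-column tab-delimited parent-child edge list headed by
#' a `#root: <name>` comment line, or a single-line Newick string (parsed
#' with \pkg{ape}; the basal node of the Newick string becomes the root, so
#' every internal node must be labelled).
#'
#' @param path tree file.
#' @return A [LineageTree-class].
#' @export
readLineageTree <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 1L && grepl(";\\s*$", lines[1])) {
    phy <- ape::read.tree(text = lines[1])
    if (is.null(phy$node.label) || any(!nzchar(phy$node.label)))
      stop("Newick internal nodes must all be labelled (they are cell types)")
    labs <- c(phy$tip.label, phy$node.label)
    parent <- setNames(labs[phy$edge[, 1]], labs[phy$edge[, 2]])
    return(LineageTree(parent))
  }
  rootLine <- grep("^#root:", lines, value = TRUE)
  if (length(rootLine) != 1L)
    stop("edge-list tree file needs exactly one '#root: <name>' line")
  root <- trimws(sub("^#root:", "", rootLine))
  edges <- lines[!grepl("^#", lines)]
  parts <- strsplit(edges, "\t")
  if (any(lengths(parts) != 2L))
    stop("edge lines must be '<parent>\\t<child>'")
  parent <- setNames(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
  LineageTree(parent, root = root)
}

#' Write a lineage tree as an edge list
#' @param tree a [LineageTree-class].
#' @param path output file.
#' @export
writeLineageTree <- function(tree, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#root: %s", tree@root), con)
  for (ch in names(tree@parent))
    writeLines(sprintf("%s\t%s", tree@parent[[ch]], ch), con)
  invisible(path)
}

#' Read BED-like regions
#'
#' BED3+1: chrom, start, end (0-based half-open), locus id in column 4.
#' Strand, if present, is ignored.
#'
#' @param path BED file.
#' @return A [GenomicRanges::GRanges] with an `id` metadata column. Note the
#'   returned ranges are 1-based closed as usual for GRanges; the file is
#'   interpreted as 0-based half-open.
#' @export
readRegions <- function(path) {
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (ncol(d) < 4L) stop("region file must be BED3+1 (id in column 4)")
  if (any(d[[2]] < 0) || any(d[[2]] >= d[[3]]))
    stop("regions must satisfy 0 <= start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = d[[1]],
    ranges = IRanges::IRanges(start = d[[2]] + 1L, end = d[[3]]))
  gr$id <- as.character(d[[4]])
  gr
}

#' Write regions as BED3+1
#' @param gr GRanges with an `id` column.
#' @param path output file.
#' @export
writeRegions <- function(gr, path) {
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr),
                  id = gr$id)
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Aggregate probe-level signal into fixed regions
#'
#' Each region's value is the arithmetic mean of all probe (or bin) values
#' whose coordinates overlap it by at least one base; regions with no
#' overlapping probe are missing (`NA`). This is the windowing used to turn
#' probe- or bin-level coverage into one value per locus (e.g. averaging
#' across an 8-kb promoter region, or 2-kb genomic tiles).
#'
#' @param probes GRanges of probe positions with a numeric `score` column,
#'   or a data.frame with columns chrom, start, end (0-based half-open),
#'   value.
#' @param regions GRanges with an `id` column, as from [readRegions()].
#' @return named numeric vector, one entry per region id, `NA` where no
#'   probe overlaps.
#' @export
aggregateSignal <- function(probes, regions) {
  if (is.data.frame(probes)) {
    probes <- GenomicRanges::GRanges(
      seqnames = probes[[1]],
      ranges = IRanges::IRanges(start = probes[[2]] + 1L, end = probes[[3]]),
      score = probes[[4]])
  }
  hits <- GenomicRanges::findOverlaps(regions, probes)
  out <- rep(NA_real_, length(regions))
  if (length(hits)) {
    sums <- tapply(probes$score[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), mean)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  names(out) <- regions$id
  out
}

#' Depth-normalize and log-transform a MarkMatrixSet
#'
#' Scales each entry by `median(library sizes) / its library size` so that
#' cell types or marks sequenced more deeply are brought onto a common depth,
#' then applies `log2(x + 1)`. Missing entries stay missing.
#'
#' @param mms a [MarkMatrixSet-class] of raw (non-negative) signal.
#' @param librarySizes named list per cell type of named numeric vectors per
#'   mark (strictly positive), or a cell type x mark matrix. `NULL` skips
#'   scaling and only log-transforms.
#' @return A normalized, log2-scale [MarkMatrixSet-class].
#' @export
normalizeAndLog <- function(mms, librarySizes = NULL) {
  vals <- mms@values
  if (!is.null(librarySizes)) {
    if (is.matrix(librarySizes)) {
      librarySizes <- lapply(setNames(rownames(librarySizes),
                                      rownames(librarySizes)),
                             function(ct) librarySizes[ct, ])
    }
    sizes <- unlist(librarySizes)
    if (any(sizes <= 0)) stop("library sizes must be strictly positive")
    ref <- median(sizes)
    for (ct in mms@cellTypes) {
      ls <- librarySizes[[ct]][mms@marks]
      if (any(is.na(ls)))
        stop(sprintf("library sizes for '%s' must cover all marks", ct))
      vals[[ct]] <- sweep(vals[[ct]], 2, ref / ls, `*`)
    }
  }
  vals <- lapply(vals, function(v) log2(v + 1))
  MarkMatrixSet(vals, missing = mms@missing)
}

#' Filter loci of a MarkMatrixSet
#'
#' `any_nonmissing` keeps loci measured in at least one cell type for at
#' least one mark; `all_nonzero` keeps loci with a non-zero, non-missing
#' value for every mark in every cell type. Row order is preserved.
#'
#' @param mms a [MarkMatrixSet-class].
#' @param rule `"any_nonmissing"` or `"all_nonzero"`.
#' @return the filtered [MarkMatrixSet-class].
#' @export
filterLoci <- function(mms, rule = c("any_nonmissing", "all_nonzero")) {
  rule <- match.arg(rule)
  keep <- switch(rule,
    any_nonmissing = Reduce(`|`, lapply(mms@missing, function(m) rowSums(!m) > 0)),
    all_nonzero = Reduce(`&`, lapply(mms@cellTypes, function(ct) {
      v <- mms@values[[ct]]
      rowSums(mms@missing[[ct]]) == 0 & rowSums(v == 0, na.rm = TRUE) == 0
    }))
  )
  if (!any(keep)) warning("no loci satisfy the filtering rule")
  subsetLoci(mms, mms@loci[keep])
}

#' Subset a MarkMatrixSet to a set of loci
#' @param mms a [MarkMatrixSet-class].
#' @param ids locus identifiers to keep (order respected).
#' @return the row-subset [MarkMatrixSet-class].
#' @export
subsetLoci <- function(mms, ids) {
  stopifnot(all(ids %in% mms@loci))
  MarkMatrixSet(lapply(mms@values, function(v) v[ids, , drop = FALSE]),
                missing = lapply(mms@missing, function(m) m[ids, , drop = FALSE]))
}

#' Write a MAP assignment table
#'
#' Tab-delimited: header `locus` plus one column per cell type, one row per
#' locus, module indices 0-based. Round-trips losslessly with
#' [readAssignments()].
#'
#' @param at integer loci x cell-type matrix (0-based), as from
#'   [assignments()].
#' @param path output file.
#' @export
writeAssignments <- function(at, path) {
  d <- data.frame(locus = rownames(at), at, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MAP assignment table written by [writeAssignments()]
#' @param path file path.
#' @return integer matrix with locus rownames and cell-type colnames.
#' @export
readAssignments <- function(path) {
  d <- read.delim(path, header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(d[[1]])
  m
}

#' Write a parameter bundle as sectioned text
#'
#' Single structured text file with `>prior`, `>transition <cellType>`,
#' `>means <cellType>` and `>variances <cellType>` sections, each followed by
#' tab-delimited numbers. Round-trips with [readParameters()].
#'
#' @param params a [CmintParameters-class].
#' @param path output file.
#' @export
writeParameters <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wmat <- function(m) apply(format(m, digits = 17, trim = TRUE,
                                   scientific = TRUE), 1,
                            paste, collapse = "\t")
  writeLines(c(">prior", paste(format(params@prior, digits = 17,
                                      scientific = TRUE),
                               collapse = "\t")), con)
  for (nm in names(params@transitions))
    writeLines(c(sprintf(">transition %s", nm),
                 wmat(params@transitions[[nm]])), con)
  for (nm in names(params@means))
    writeLines(c(sprintf(">means %s", nm), wmat(params@means[[nm]])), con)
  for (nm in names(params@variances))
    writeLines(c(sprintf(">variances %s", nm),
                 wmat(params@variances[[nm]])), con)
  invisible(path)
}

#' Read a parameter bundle written by [writeParameters()]
#' @param path file path.
#' @return a [CmintParameters-class].
#' @export
readParameters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^>", lines)
  bounds <- c(heads, length(lines) + 1L)
  sections <- list()
  for (i in seq_along(heads)) {
    key <- sub("^>", "", lines[heads[i]])
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- lapply(strsplit(body, "\t"), as.numeric)
    sections[[key]] <- do.call(rbind, rows)
  }
  prior <- as.numeric(sections[["prior"]])
  pick <- function(prefix) {
    keys <- grep(paste0("^", prefix, " "), names(sections), value = TRUE)
    out <- lapply(keys, function(k) sections[[k]])
    names(out) <- sub(paste0("^", prefix, " "), "", keys)
    out
  }
  CmintParameters(prior = prior, transitions = pick("transition"),
                  means = pick("means"), variances = pick("variances"))
}
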