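# Domain containers, file round trips and preprocessing.

test_that("MarkMatrixSet enforces shared dimensions and flags NA as missing", {
  X <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("m1", "m2")))
  Y <- X + 1
  Y[2, 1] <- NA
  mms <- MarkMatrixSet(list(A = X, B = Y))
  expect_identical(cellTypes(mms), c("A", "B"))
  expect_identical(loci(mms), paste0("g", 1:3))
  expect_true(missingMask(mms, "B")[2, 1])
  expect_false(any(missingMask(mms, "A")))
  # rows are realigned to the first matrix's order
  mms2 <- MarkMatrixSet(list(A = X, B = Y[c(3, 1, 2), ]))
  expect_equal(markValues(mms2, "B"), markValues(mms, "B"))
  expect_error(MarkMatrixSet(list(A = unname(X))), "rownames")
})

test_that("readMarkMatrices aligns loci by intersection or union", {
  d1 <- data.frame(locus = c("g1", "g2"), m1 = c(1, 2), m2 = c(3, 4))
  d2 <- data.frame(locus = c("g2", "g3"), m1 = c(5, 6), m2 = c(7, 8))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(d1, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(d2, f2, sep = "\t", row.names = FALSE, quote = FALSE)

  ident <- readMarkMatrices(c(A = f1, B = f1))
  expect_identical(loci(ident), c("g1", "g2"))
  expect_identical(markNames(ident), c("m1", "m2"))
  expect_false(any(missingMask(ident, "A")))

  inter <- readMarkMatrices(c(A = f1, B = f2))
  expect_identical(loci(inter), "g2")

  uni <- readMarkMatrices(c(A = f1, B = f2), union = TRUE)
  expect_setequal(loci(uni), c("g1", "g2", "g3"))
  expect_true(all(missingMask(uni, "B")["g1", ]))
  expect_true(all(missingMask(uni, "A")["g3", ]))
  expect_false(any(missingMask(uni, "A")[c("g1", "g2"), ]))
})

test_that("readMarkMatrices rejects duplicate loci and mismatched marks", {
  dup <- data.frame(locus = c("g1", "g1"), m1 = c(1, 2), m2 = c(3, 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(dup, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readMarkMatrices(c(A = f)), "duplicate locus")

  d1 <- data.frame(locus = "g1", m1 = 1, m2 = 2)
  d3 <- data.frame(locus = "g1", m1 = 1, OTHER = 2)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(d1, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(d3, f3, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readMarkMatrices(c(A = f1, B = f3)), "B")
})

test_that("replicate files for one cell type collapse by entry-wise median", {
  mk <- function(vals) data.frame(locus = c("g1", "g2"), m1 = vals)
  fs <- replicate(3, tempfile(fileext = ".tsv"))
  for (i in 1:3)
    write.table(mk(c(i, 10 * i)), fs[i], sep = "\t", row.names = FALSE,
                quote = FALSE)
  mms <- readMarkMatrices(list(A = fs))
  expect_equal(unname(markValues(mms, "A")[, "m1"]), c(2, 20))
})

test_that("aggregateSignal averages overlapping probes and flags empty regions", {
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 10001, 20001), end = c(8000, 18000, 28000)))
  regions$id <- c("r1", "r2", "r3")
  # 16 probes of constant value 1.5 inside r1; two probes {1, 3} in r2
  probes <- data.frame(
    chrom = "chr1",
    start = c(seq(0, 7500, by = 500), 10100, 10600),
    end = c(seq(0, 7500, by = 500) + 400, 10500, 11000),
    value = c(rep(1.5, 16), 1, 3))
  agg <- aggregateSignal(probes, regions)
  expect_equal(unname(agg["r1"]), 1.5)
  expect_equal(unname(agg["r2"]), 2)
  expect_true(is.na(agg["r3"]))
  # invariant to probe ordering
  shuf <- probes[sample(nrow(probes)), ]
  expect_equal(aggregateSignal(shuf, regions), agg)
})

test_that("normalizeAndLog applies median-ratio scaling then log2(x + 1)", {
  X <- matrix(c(0, 3), 2, 1, dimnames = list(c("g1", "g2"), "m1"))
  mms <- MarkMatrixSet(list(A = X, B = X))
  eq <- normalizeAndLog(mms, list(A = c(m1 = 5), B = c(m1 = 5)))
  expect_equal(unname(markValues(eq, "A")[, 1]), c(0, 2)) # log2(0+1), log2(3+1)
  # library sizes 1e6 vs 2e6: pre-log values differ by factor 2
  X10 <- matrix(10, 1, 1, dimnames = list("g1", "m1"))
  mms2 <- MarkMatrixSet(list(A = X10, B = X10))
  out <- normalizeAndLog(mms2, list(A = c(m1 = 1e6), B = c(m1 = 2e6)))
  preA <- 2^markValues(out, "A")[1, 1] - 1
  preB <- 2^markValues(out, "B")[1, 1] - 1
  expect_equal(preA / preB, 2)
  expect_error(normalizeAndLog(mms2, list(A = c(m1 = 0), B = c(m1 = 1))),
               "positive")
  # monotone in the raw value for a fixed library size
  Xm <- matrix(sort(runif(10, 0, 50)), 10, 1,
               dimnames = list(paste0("g", 1:10), "m1"))
  mono <- normalizeAndLog(MarkMatrixSet(list(A = Xm)), list(A = c(m1 = 2)))
  expect_false(is.unsorted(markValues(mono, "A")[, 1]))
})

test_that("filterLoci implements both retention rules", {
  X <- matrix(c(1, NA, 2, 1, NA, 0), 3, 2,
              dimnames = list(paste0("g", 1:3), c("m1", "m2")))
  Y <- matrix(c(1, NA, 1, 2, NA, 2), 3, 2, dimnames = dimnames(X))
  mms <- MarkMatrixSet(list(A = X, B = Y))
  anym <- filterLoci(mms, "any_nonmissing")
  expect_identical(loci(anym), c("g1", "g3")) # g2 unmeasured everywhere
  allz <- filterLoci(mms, "all_nonzero")
  expect_identical(loci(allz), "g1")          # g3 has a zero in A
  # identity when everything passes
  ok <- MarkMatrixSet(list(A = X[1, , drop = FALSE], B = Y[1, , drop = FALSE]))
  expect_identical(loci(filterLoci(ok, "all_nonzero")), "g1")
  none <- MarkMatrixSet(list(A = matrix(0, 1, 1, dimnames = list("g1", "m1"))))
  expect_warning(filterLoci(none, "all_nonzero"), "no loci")
})

test_that("assignment tables and parameter bundles round-trip losslessly", {
  at <- matrix(sample(0L:15L, 30, replace = TRUE), 10, 3,
               dimnames = list(paste0("g", 1:10), c("A", "B", "C")))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAssignments(at, f)
  back <- readAssignments(f)
  expect_identical(back, at)
  expect_true(all(back >= 0 & back <= 15))
  # empty table gives a header-only file
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeAssignments(at[0, , drop = FALSE], f2)
  expect_length(readLines(f2), 1L)

  inst <- randomInstance(5)
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeParameters(inst$params, f3)
  p2 <- readParameters(f3)
  expect_equal(p2@prior, inst$params@prior)
  expect_equal(unname(p2@transitions[[1]]), unname(inst$params@transitions[[1]]))
  expect_equal(lapply(p2@means, unname), lapply(inst$params@means, unname))
})

test_that("lineage trees parse from edge lists and Newick, and round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#root: MEF", "MEF\tpreiPSC", "preiPSC\tiPSC"), f)
  tr <- readLineageTree(f)
  expect_identical(rootOf(tr), "MEF")
  expect_identical(parentOf(tr, "iPSC"), "preiPSC")
  expect_identical(childrenOf(tr, "MEF"), "preiPSC")
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLineageTree(tr, f2)
  tr2 <- readLineageTree(f2)
  expect_identical(tr2@parent[order(names(tr2@parent))],
                   tr@parent[order(names(tr@parent))])

  fn <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((EryA,EryB)MEP,GMP)CMP;", fn)
  trn <- readLineageTree(fn)
  expect_identical(rootOf(trn), "CMP")
  expect_setequal(childrenOf(trn, "MEP"), c("EryA", "EryB"))
  expect_error(readLineageTree({
    fb <- withr::local_tempfile(fileext = ".nwk")
    writeLines("((A,B),C);", fb); fb
  }), "labelled")
})

test_that("regions read/write as 0-based half-open BED3+1", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t2000\tr1", "chr1\t2000\t4000\tr2"), f)
  gr <- readRegions(f)
  expect_equal(GenomicRanges::start(gr), c(1L, 2001L))
  expect_equal(GenomicRanges::width(gr), c(2000L, 2000L))
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeRegions(gr, f2)
  expect_identical(readLines(f2), readLines(f))
  fbad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t100\tr1", fbad)
  expect_error(readRegions(fbad), "start < end")
})

test_that("LineageTree validity rejects cycles and double parents", {
  expect_error(LineageTree(c(B = "A", A = "B")), "root")
  expect_s4_class(LineageTree(c(B = "A", C = "A", D = "C")), "LineageTree")
})
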