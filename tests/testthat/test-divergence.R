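test_that("aligned FASTA reading validates shape and normalizes characters", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgu-n", ">b", "ACGTTN"), f)
  aln <- readAlignment(f)
  expect_equal(dim(aln), c(2L, 6L))
  expect_equal(aln["a", ], c("A", "C", "G", "T", "-", "N"))
  writeLines(c(">a", "ACGT", ">b", "ACG"), f)
  expect_error(readAlignment(f), "unequal")
  # round trip
  b <- fixtureBuild()
  sp <- smallSpec()
  co <- mutateCohort(b$genome, sp)
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeAlignment(co$alignment, f2)
  expect_identical(readAlignment(f2), co$alignment)
})

test_that("site classification equals the definition oracle on exhaustive small columns", {
  chars <- c("A", "T", "-")
  n_taxa <- 5
  grid <- expand.grid(rep(list(chars), n_taxa), stringsAsFactors = FALSE)
  mat <- t(as.matrix(grid))
  rownames(mat) <- paste0("t", 1:n_taxa)
  got <- as.character(classifySites(mat))
  exp <- apply(mat, 2, oracleClassifySite)
  expect_identical(got, unname(exp))
  # three-base columns exercise other_variable
  m2 <- matrix(c("A", "A", "C", "G",
                 "A", "C", "G", "T",
                 "A", "A", "C", "C"), nrow = 4)
  rownames(m2) <- paste0("t", 1:4)
  expect_identical(as.character(classifySites(m2)),
                   c("other_variable", "other_variable",
                     "parsimony_informative"))
})

test_that("windowed Pi matches hand computation and direct recomputation", {
  aln <- alignmentMatrix(c(a = "AAAA", b = "AAAT", c = "AATT"))
  w <- windowScan(aln, window = 4, step = 4)
  expect_equal(w$pi, 1 / 3)
  expect_equal(w$n_snp, 2L)
  # identical rows
  aln0 <- alignmentMatrix(c(a = strrep("ACGT", 50), b = strrep("ACGT", 50)))
  w0 <- windowScan(aln0, window = 100, step = 50)
  expect_true(all(w0$pi == 0) && all(w0$n_snp == 0L))
  # brute-force equivalence on random alignments with missing data
  set.seed(404)
  for (rep in 1:8) {
    n <- sample(3:6, 1); L <- sample(150:400, 1)
    m <- matrix(sample(c("A", "C", "G", "T", "N", "-"), n * L, TRUE,
                       prob = c(.3, .2, .2, .2, .05, .05)), nrow = n)
    rownames(m) <- paste0("t", 1:n)
    w <- windowScan(m, window = 60, step = 25)
    for (k in seq_len(nrow(w)))
      expect_equal(w$pi[k], oraclePi(m, w$start[k], w$end[k]),
                   tolerance = 1e-12)
    # permutation invariance
    perm <- m[sample(n), , drop = FALSE]
    expect_equal(windowScan(perm, 60, 25)$pi, w$pi)
    # class counts tile the alignment
    expect_equal(sum(table(classifySites(m))), L)
  }
})

test_that("terminal partial windows follow the half-window rule", {
  # 1100 columns: the partial window [600, 1100) covers 500 >= 300 -> kept
  aln <- alignmentMatrix(c(a = strrep("A", 1100), b = strrep("A", 1100)))
  w <- windowScan(aln, window = 600, step = 200)
  expect_equal(w$start, c(0L, 200L, 400L, 600L))
  expect_equal(w$end, c(600L, 800L, 1000L, 1100L))
  # non-overlapping windows: a 40-column tail < half a window is dropped
  aln2 <- alignmentMatrix(c(a = strrep("A", 140), b = strrep("A", 140)))
  w2 <- windowScan(aln2, window = 100, step = 100)
  expect_equal(w2$start, 0L)
  expect_equal(w2$end, 100L)
  # ... but a 60-column tail is kept
  aln3 <- alignmentMatrix(c(a = strrep("A", 160), b = strrep("A", 160)))
  w3 <- windowScan(aln3, window = 100, step = 100)
  expect_equal(w3$end, c(100L, 160L))
  expect_warning(windowScan(alignmentMatrix(c(a = "ACGT", b = "ACGT")),
                            600, 200), "shorter")
})

test_that("hypervariable merging groups adjacent selected windows", {
  aln <- alignmentMatrix(c(a = strrep("A", 50), b = strrep("A", 50)))
  win <- data.frame(start = seq(0L, 40L, 10L), end = seq(10L, 50L, 10L),
                    midpoint = seq(5L, 45L, 10L),
                    pi = c(.01, .9, .91, .01, .95),
                    n_snp = c(5L, 30L, 30L, 5L, 30L))
  reg <- suppressWarnings(
    mergeHypervariable(win, aln, pi_quantile = 0.5, snp_min = 25))
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start, c(10L, 40L))
  expect_equal(reg$end, c(30L, 50L))
  expect_equal(reg$length, reg$end - reg$start)
  # SNP filter dominates: uniform low-SNP windows yield nothing
  win2 <- win; win2$n_snp <- 10L
  expect_equal(nrow(suppressWarnings(
    mergeHypervariable(win2, aln, 0.5, 25))), 0)
  # monotone selection: loosening either filter never removes regions
  relax <- suppressWarnings(mergeHypervariable(win, aln, 0.3, 20))
  expect_gte(sum(relax$length), sum(reg$length))
})

test_that("region statistics are recomputed over the merged span", {
  sp <- smallSpec(hot_rate = 0.05)
  b <- buildPlastome(sp)
  co <- mutateCohort(b$genome, sp)
  w <- windowScan(co$alignment)
  reg <- mergeHypervariable(w, co$alignment)
  expect_gt(nrow(reg), 0)
  cls <- classifySites(co$alignment)
  for (k in seq_len(nrow(reg))) {
    colcls <- cls[(reg$start[k] + 1):reg$end[k]]
    expect_equal(reg$n_svs[k], sum(colcls == "singleton"))
    expect_equal(reg$n_pip[k], sum(colcls == "parsimony_informative"))
    expect_lte(reg$n_svs[k] + reg$n_pip[k], reg$n_snp[k])
    expect_equal(reg$mean_pi[k],
                 oraclePi(co$alignment, reg$start[k], reg$end[k]),
                 tolerance = 1e-12)
  }
})

test_that("region annotation projects through reference gaps correctly", {
  b <- fixtureBuild()
  ref <- as.character(plastomeSeq(b$genome))
  # insert gap columns into the reference row at known places
  gaps_at <- c(500L, 5000L, 20000L)   # reference coordinates
  chars <- strsplit(ref, "")[[1]]
  out_ref <- character(0); out_alt <- character(0)
  prev <- 0L
  for (gpos in c(gaps_at, length(chars))) {
    out_ref <- c(out_ref, chars[(prev + 1):gpos])
    out_alt <- c(out_alt, chars[(prev + 1):gpos])
    if (gpos < length(chars)) {
      out_ref <- c(out_ref, "-", "-")
      out_alt <- c(out_alt, "G", "C")
    }
    prev <- gpos
  }
  aln <- rbind(ref = out_ref, alt = out_alt)
  proj <- plastomics:::alignmentToRefCoords(aln, "ref")
  # brute force: count non-gap reference chars before each column
  set.seed(12)
  cols <- sample.int(ncol(aln), 50)
  brute <- vapply(cols, function(j)
    sum(aln["ref", seq_len(j - 1)] != "-"), integer(1))
  expect_equal(proj[cols], brute)
  # labels: inside a gene and in a spacer
  ft <- geneFeatures(b$genome)
  i <- which(ft$gene == "matK")
  mid_gene <- (min(ft$exon_starts[[i]]) + max(ft$exon_ends[[i]])) %/% 2L
  expect_equal(plastomics:::locusLabel(b$genome, mid_gene), "matK")
  regions <- data.frame(start = mid_gene, end = mid_gene + 100L,
                        length = 100L, n_snp = 0L, n_svs = 0L,
                        n_pip = 0L, mean_pi = 0)
  lab <- annotateRegions(regions, b$genome, aln, "ref")
  expect_equal(lab$label, "matK")
  expect_error(annotateRegions(regions, b$genome, aln, "nope"), "nope")
})
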