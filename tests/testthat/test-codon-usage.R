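test_that("extractCDS recovers generator truth and follows strand convention", {
  b <- fixtureBuild()
  cds <- suppressMessages(extractCDS(b$genome))
  for (g in names(b$manifest$cds))
    expect_identical(unname(cds[[g]]), b$manifest$cds[[g]])
  # minus-strand two-exon gene: spliced = revcomp of concatenated exons
  ft <- geneFeatures(b$genome)
  i <- which(ft$gene == "atpF")
  expect_length(ft$exon_starts[[i]], 2)
  expect_equal(ft$strand[i], "-")
  seq <- as.character(plastomeSeq(b$genome))
  ex <- vapply(seq_along(ft$exon_starts[[i]]), function(k)
    substring(seq, ft$exon_starts[[i]][k] + 1, ft$exon_ends[[i]][k]),
    character(1))
  expect_identical(unname(cds[["atpF"]]),
                   revcompChr(paste(ex, collapse = "")))
  # pseudogene-flagged features are excluded
  g <- tinyPlastome("px", paste0(randomCDS(40, seed = 2), randDNA(50)),
                    data.frame(gene = "z", category = "PCG", strand = "+",
                               start = 0L, end = 120L, pseudo = TRUE))
  expect_message(out <- extractCDS(g), "excluded")
  expect_length(out, 0)
})

test_that("codon counting matches a hand-readable frame and a recount oracle", {
  cc <- countCodons(c(g1 = "ATGTTATTACTGTAA"))
  expect_equal(unname(cc$counts[c("ATG", "TTA", "CTG")]), c(1L, 2L, 1L))
  expect_equal(sum(cc$stop_counts), 1L)
  expect_equal(sum(cc$counts), 4L)
  # brute-force recount on random CDS
  set.seed(42)
  cdss <- vapply(1:5, function(i) randomCDS(sample(50:150, 1)),
                 character(1))
  names(cdss) <- paste0("g", 1:5)
  cc <- countCodons(cdss)
  oracle <- table(unlist(lapply(cdss, function(s) {
    cods <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    cods[-length(cods)]   # drop terminal stop
  })))
  expect_equal(sum(cc$counts), sum(oracle))
  for (cod in names(oracle))
    expect_equal(unname(cc$counts[cod]), unname(as.integer(oracle[cod])))
  # frame error names the gene
  expect_error(countCodons(c(bad = "ATGAA")), "bad")
  # codons with ambiguity are skipped and tallied
  cc2 <- countCodons(c(g = "ATGANATAA"))
  expect_equal(cc2$n_ambiguous_skipped, 1L)
})

test_that("RSCU follows the k*n/sum definition and its invariants", {
  # leucine family: TTA x2, CTG x1 -> RSCU(TTA) = 2*6/3 = 4
  cc <- countCodons(c(g = "ATGTTATTACTGTAA"))
  r <- computeRSCU(cc)
  expect_equal(unname(r$rscu[["TTA"]]), 4)
  expect_equal(unname(r$rscu[["CTG"]]), 2)
  # uniform 4-codon family -> all 1
  cc2 <- countCodons(c(g = "ATGGGTGGCGGAGGGTAA"))
  r2 <- computeRSCU(cc2)
  expect_equal(unname(r2$rscu[c("GGT", "GGC", "GGA", "GGG")]),
               rep(1, 4))
  # family normalization: sum of RSCU over each observed family == size
  b <- fixtureBuild()
  cc3 <- countCodons(suppressMessages(extractCDS(b$genome)))
  r3 <- computeRSCU(cc3)
  fams <- plastomics:::codonFamilies("11")
  for (aa in setdiff(names(fams), r3$zero_families))
    expect_equal(sum(r3$rscu[fams[[aa]]]), length(fams[[aa]]),
                 tolerance = 1e-9)
  # scale invariance
  cc4 <- cc3
  cc4$counts <- cc3$counts * 7L
  expect_equal(computeRSCU(cc4)$rscu, r3$rscu)
  # zero-total families are flagged and all-zero
  expect_true(all(r$rscu[fams[["R"]]] == 0))
  expect_true("R" %in% r$zero_families)
})

test_that("bias summary cross-tabulates mean RSCU by third-base class", {
  b <- fixtureBuild()
  cds <- suppressMessages(extractCDS(b$genome))
  t1 <- computeRSCU(countCodons(cds))
  t2 <- computeRSCU(countCodons(cds[seq(1, length(cds), 2)]))
  bs <- rscuBiasSummary(list(t1, t2))
  m <- (t1$rscu + t2$rscu) / 2
  third <- substring(names(m), 3, 3)
  expect_equal(bs$n_gt1, sum(m > 1))
  expect_equal(bs$n_gt1_AU, sum(m > 1 & third %in% c("A", "T")))
  expect_equal(bs$n_le1_GC, sum(m <= 1 & third %in% c("G", "C")))
  expect_equal(bs$n_gt1 + bs$n_le1, 61L)
  expect_true(all(bs$mean_rscu$codon == chartr("T", "U",
                                               toupper(bs$mean_rscu$codon))))
  # boundary strictness: all-1 table yields zero codons above 1
  allone <- t1
  allone$rscu[] <- 1
  bs2 <- rscuBiasSummary(list(allone))
  expect_equal(bs2$n_gt1, 0L)
})
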