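test_that("synthetic GenBank round-trips through write/read exactly", {
  b <- fixtureBuild()
  f <- withr::local_tempfile(fileext = ".gb")
  writeGenBank(b$genome, f)
  g2 <- readGenBank(f)
  expect_identical(as.character(plastomeSeq(g2)),
                   as.character(plastomeSeq(b$genome)))
  expect_identical(as.data.frame(geneFeatures(g2)),
                   as.data.frame(geneFeatures(b$genome)))
  # generator truth table agrees with what was read back
  ft <- geneFeatures(g2)
  man <- b$manifest$genes
  expect_setequal(ft$gene, man$symbol)
  expect_equal(nrow(ft), nrow(man))
})

test_that("a gene spanning the circular origin round-trips as one feature", {
  gt <- defaultGeneTable()
  gt <- gt[gt$symbol %in% c("psbA", "rpl2", "ycf1"), ]
  gt$junction[gt$symbol == "psbA"] <- "JLA"
  gt$offset[gt$symbol == "psbA"] <- 200   # 200 bp in LSC, rest in IRa
  sp <- smallSpec(seed = 11, gene_table = gt)
  b <- buildPlastome(sp)
  ft <- geneFeatures(b$genome)
  psbA <- which(ft$gene == "psbA")
  expect_length(psbA, 1)
  expect_gt(max(ft$exon_ends[[psbA]]), genomeLength(b$genome))
  f <- withr::local_tempfile(fileext = ".gb")
  writeGenBank(b$genome, f)
  g2 <- readGenBank(f)
  expect_identical(as.data.frame(geneFeatures(g2)), as.data.frame(ft))
  expect_identical(as.character(plastomeSeq(g2)),
                   as.character(plastomeSeq(b$genome)))
})

test_that("malformed GenBank input raises informative parse errors", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       x 10 bp", "FEATURES",
               "     CDS             1..9", '                     /gene="g"'),
             f)
  expect_error(readGenBank(f), "ORIGIN")
  writeLines(c("LOCUS       x 10 bp", "FEATURES",
               "     CDS             5..xyz",
               '                     /gene="bad"',
               "ORIGIN", "        1 acgtacgtac", "//"), f)
  expect_error(readGenBank(f), "bad")
})

test_that("quadripartite detection recovers planted coordinates and is rotation invariant", {
  b <- fixtureBuild()
  part <- fixturePartition()
  man <- b$manifest$partition
  expect_equal(part@lsc_len, man$lsc_len)
  expect_equal(part@ssc_len, man$ssc_len)
  expect_equal(part@ir_len, man$ir_len)
  expect_equal(part@lsc_len + part@ssc_len + 2L * part@ir_len,
               genomeLength(b$genome))
  # IR identity, byte for byte
  rs <- plastomics:::regionSequences(b$genome, part)
  expect_identical(revcompChr(rs$ira), rs$irb)
  # rotation invariance of region lengths
  seq <- as.character(plastomeSeq(b$genome))
  for (r in c(1, 5000, 25000, 39000)) {
    rot <- paste0(substring(seq, r + 1), substring(seq, 1, r))
    p2 <- detectQuadripartite(rot)
    expect_equal(regionLengths(p2), regionLengths(part))
  }
})

test_that("sequences without a long inverted repeat yield no partition", {
  set.seed(3)
  expect_null(detectQuadripartite(randDNA(10000)))
})

test_that("genome summary reports planted GC and gene counts", {
  b <- fixtureBuild()
  s <- summarizeGenome(b$genome, fixturePartition())
  expect_equal(s$gc_lsc, b$manifest$gc_realized$lsc, tolerance = 1e-12)
  expect_equal(s$gc_ssc, b$manifest$gc_realized$ssc, tolerance = 1e-12)
  expect_equal(s$gc_ir, b$manifest$gc_realized$ir, tolerance = 1e-12)
  expect_equal(s$n_genes, s$n_pcg + s$n_trna + s$n_rrna)
  man <- b$manifest$genes
  expect_equal(s$n_pcg, sum(man$category == "PCG"))
  expect_equal(s$n_duplicated, length(unique(man$symbol[man$mirrored])))
  expect_equal(s$n_intron_genes,
               length(unique(man$symbol[man$n_exons > 1])))
  # saturation case
  g <- tinyPlastome("gc100", strrep("GC", 3000), data.frame(
    gene = "x", category = "PCG", strand = "+", start = 0L, end = 300L,
    pseudo = FALSE))
  expect_equal(plastomics:::gcPercent(as.character(plastomeSeq(g))), 100)
})

test_that("classifyPosition matches a linear-scan oracle", {
  part <- fixturePartition()
  j <- junctions(part)
  L <- part@genome_length
  oracle <- function(p) {
    if (p < j[["JLB"]]) "LSC" else if (p < j[["JSB"]]) "IRb"
    else if (p < j[["JSA"]]) "SSC" else "IRa"
  }
  set.seed(1)
  pos <- c(0L, j[["JLB"]], j[["JSB"]], j[["JSA"]], L - 1L,
           sample.int(L, 200) - 1L)
  expect_identical(classifyPosition(part, pos),
                   vapply(pos, oracle, character(1)))
  expect_error(classifyPosition(part, L), "out of range")
})

test_that("gene model validation flags frameshifts and honors deposited pseudo flags", {
  b <- fixtureBuild()
  v <- validateGeneModels(b$genome)
  expect_true(all(v$len_mod3 == 0))
  expect_true(all(v$start_codon == "ATG"))
  expect_true(all(!v$pseudo))
  # minimal valid CDS
  g <- tinyPlastome("mini", paste0("ATGAAATAA", randDNA(100)), data.frame(
    gene = "m", category = "PCG", strand = "+", start = 0L, end = 9L,
    pseudo = FALSE))
  vm <- validateGeneModels(g)
  expect_false(vm$pseudo_candidate[1])
  expect_equal(vm$stop_codon[1], "TAA")
  # frameshift: delete one base mid-CDS of a clean gene
  cds <- randomCDS(60, seed = 5)
  broken <- paste0(substring(cds, 1, 50), substring(cds, 52, nchar(cds)))
  g2 <- tinyPlastome("fs", paste0(broken, randDNA(60)), data.frame(
    gene = "f", category = "PCG", strand = "+", start = 0L,
    end = nchar(broken), pseudo = FALSE))
  v2 <- validateGeneModels(g2)
  expect_equal(v2$len_mod3[1], 2L)
  expect_true(v2$pseudo_candidate[1])
  # deposited /pseudo is merged by OR even when the model looks clean
  g3 <- tinyPlastome("dep", paste0(cds, randDNA(60)), data.frame(
    gene = "p", category = "PCG", strand = "+", start = 0L,
    end = nchar(cds), pseudo = TRUE))
  v3 <- validateGeneModels(g3)
  expect_false(v3$pseudo_candidate[1])
  expect_true(v3$pseudo[1])
})
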