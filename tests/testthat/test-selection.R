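test_that("NG86 handles zero-divergence and single-wobble pairs", {
  cods <- rep("AAA", 9)
  r0 <- ng86(c("ATG", cods), c("ATG", cods))
  expect_equal(r0$ka, 0)
  expect_equal(r0$ks, 0)
  expect_equal(r0$omega_flag, "undefined_ks0")
  # one K->K third-position wobble among ten codons
  r1 <- ng86(c("ATG", cods), c("ATG", cods[-1], "AAG"))
  expect_equal(r1$ka, 0)
  expect_gt(r1$ks, 0)
  expect_equal(r1$omega, 0)
  expect_equal(r1$omega_flag, "ok")
})

test_that("NG86 is symmetric and conserves site totals", {
  set.seed(88)
  for (rep in 1:10) {
    ca <- plastomics:::splitCodons(randomCDS(40))[1:30]
    cb <- plastomics:::splitCodons(randomCDS(40))[1:30]
    rab <- ng86(ca, cb); rba <- ng86(cb, ca)
    expect_equal(rab$ka, rba$ka)
    expect_equal(rab$ks, rba$ks)
    expect_equal(rab$Sd, rba$Sd)
    expect_equal(rab$S + rab$N, 3 * length(ca), tolerance = 1e-9)
  }
})

test_that("NG86 counts match the pathway-enumeration oracle on sampled codon pairs", {
  tb <- plastomics:::ngTables("11")
  sense <- tb$codons[tb$aa != "*"]
  set.seed(7)
  pairs <- cbind(sample(sense, 80, TRUE), sample(sense, 80, TRUE))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    o <- oracleNg86(a, b)
    r <- ng86(a, b)
    expect_equal(r$S, o$S, tolerance = 1e-9)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-9)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-9)
  }
})

test_that("codon alignment preserves frame and scores consistently", {
  a <- "ATGAAACCCGGGTATTTTTAA"
  r <- codonAlignPair(a, a)
  expect_equal(r$codons_a, r$codons_b)
  expect_equal(r$n_dropped, 0L)
  # internal codon insertion -> one 3-base gap, frame preserved
  b <- "ATGAAACCCTGGGGGTATTTTTAA"   # extra TGG codon
  r2 <- codonAlignPair(a, b)
  expect_equal(r2$codons_a, r2$codons_b)   # retained columns identical
  expect_equal(length(r2$codons_a), 6L)
  expect_equal(r2$n_dropped, 1L)
  # score consistency: recompute the protein alignment score by hand
  data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(21)
  for (rep in 1:5) {
    s1 <- randomCDS(sample(30:60, 1))
    s2 <- randomCDS(sample(30:60, 1))
    protOf <- function(s) {
      s <- substring(s, 1, nchar(s) - 3)   # drop terminal stop
      as.character(Biostrings::translate(
        Biostrings::DNAString(s),
        genetic.code = Biostrings::getGeneticCode("11")))
    }
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(protOf(s1)),
      Biostrings::AAString(protOf(s2)),
      type = "global", substitutionMatrix = get("BLOSUM62"),
      gapOpening = 10, gapExtension = 0.5)
    expect_equal(codonAlignPair(s1, s2)$protein_score,
                 Biostrings::score(aln))
  }
  # internal stops violate the precondition
  expect_error(codonAlignPair("ATGTAAAAATAA", a), "stop")
})

test_that("shared-PCG sets apply the pseudo-exclusion and duplicate-collapse rules", {
  mk <- function(id, pseudo_matk) {
    rbcl <- randomCDS(60, seed = 1)
    matk <- randomCDS(50, seed = 2)
    seq <- paste0(randDNA(50), rbcl, randDNA(50), matk, randDNA(50))
    tinyPlastome(id, seq, data.frame(
      gene = c("rbcL", "matK"), category = "PCG", strand = "+",
      start = c(50L, 50L + 180L + 50L),
      end = c(50L + 180L, 50L + 180L + 50L + 150L),
      pseudo = c(FALSE, pseudo_matk)))
  }
  shared <- suppressWarnings(sharedPCGs(list(mk("A", FALSE), mk("B", TRUE))))
  expect_equal(shared$genes, "rbcl")
  # intersection against a planted presence/absence design
  b <- fixtureBuild()
  g2 <- b$genome
  shared2 <- sharedPCGs(list(b$genome, g2))
  man <- b$manifest$genes
  expect_setequal(shared2$genes,
                  tolower(unique(man$symbol[man$category == "PCG"])))
  # IR duplicates collapse to one sequence per genome
  expect_true(all(vapply(shared2$seqs, length, 1L) == 2))
})

test_that("the omega matrix averages defined values per gene and taxon", {
  rec <- data.frame(gene = "g", taxon_a = "A", taxon_b = "B",
                    ka = 0.1, ks = 0.4, omega = 0.25, omega_flag = "ok",
                    n_codons = 100L)
  m <- omegaMatrix(rec)
  expect_equal(unname(m["g", c("A", "B")]), c(0.25, 0.25))
  rec2 <- rbind(rec, data.frame(gene = "g", taxon_a = "A", taxon_b = "C",
                                ka = 0.2, ks = 0.4, omega = 0.5,
                                omega_flag = "ok", n_codons = 100L),
                data.frame(gene = "g", taxon_a = "B", taxon_b = "C",
                           ka = 0, ks = 0, omega = NA,
                           omega_flag = "undefined_ks0", n_codons = 100L))
  m2 <- omegaMatrix(rec2)
  expect_equal(unname(m2["g", "A"]), mean(c(0.25, 0.5)))
  expect_equal(unname(m2["g", "B"]), 0.25)   # undefined pair excluded
  expect_equal(unname(m2["g", "C"]), 0.5)
})

test_that("evolved pairs recover the planted omega on average", {
  set.seed(33)
  anc <- randomCDS(300)
  om <- vapply(1:15, function(i) {
    ev <- evolveCdsPair(anc, 0.5, 0.25, seed = 5000 + i)
    ng86(plastomics:::splitCodons(ev$cds_a)[-1],
         plastomics:::splitCodons(ev$cds_b)[-1])$omega
  }, numeric(1))
  expect_gt(mean(om), 0.35)
  expect_lt(mean(om), 0.65)
})
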