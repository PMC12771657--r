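test_that("SSR detection honors threshold boundaries", {
  bg <- "GCTGCAGTCGACGGTACGCGTAGCATCGAT"
  expect_equal(nrow(findSSRs(paste0(bg, strrep("A", 9), bg))), 0)
  hit <- findSSRs(paste0(bg, strrep("A", 10), bg))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$repeats, 10L)
  expect_equal(hit$motif, "A")
  expect_equal(hit$end - hit$start, 10L)
})

test_that("SSR records match the exhaustive oracle on random AT-rich sequences", {
  set.seed(101)
  for (rep in 1:12) {
    s <- randDNA(sample(1000:3000, 1), at = 0.7)
    # plant a few runs so the comparison has substance
    s <- paste0(s, strrep("AT", 7), randDNA(300, 0.7), strrep("TTG", 6),
                randDNA(200, 0.7))
    got <- findSSRs(s)
    exp <- oracleSSRs(s)
    expect_equal(nrow(got), nrow(exp))
    expect_setequal(paste(got$start, got$end, got$motif),
                    paste(exp$start, exp$end, exp$motif))
  }
})

test_that("canonical motif classes collapse strand and phase", {
  expect_equal(canonicalMotifClass("T"), "A/T")
  expect_equal(canonicalMotifClass("TA"), "AT/AT")
  expect_equal(canonicalMotifClass("TTTCA"), "AAATG/ATTTC")
  expect_error(canonicalMotifClass("ATAT"), "primitive")
  # orbit closure over all primitive dinucleotides: members of one class
  # map to the same label
  dinucs <- c("AC", "AG", "AT", "CA", "CG", "CT", "GA", "GC", "GT",
              "TA", "TC", "TG")
  cls <- vapply(dinucs, canonicalMotifClass, character(1))
  orbit <- function(m) {
    rots <- c(m, paste0(substring(m, 2), substring(m, 1, 1)))
    rc <- revcompChr(m)
    unique(c(rots, rc, paste0(substring(rc, 2), substring(rc, 1, 1))))
  }
  for (m in dinucs)
    expect_true(all(cls[intersect(orbit(m), dinucs)] == cls[[m]]))
  expect_equal(length(unique(cls)), 4)  # AC/GT, AG/CT, AT/AT, CG/CG
})

test_that("SSR class histogram is reverse-complement symmetric and thresholds are monotone", {
  set.seed(77)
  s <- paste0(randDNA(2000, 0.7), strrep("A", 11), randDNA(500, 0.7),
              strrep("GAA", 6), randDNA(500, 0.7))
  h1 <- table(findSSRs(s)$motif_class)
  h2 <- table(findSSRs(revcompChr(s))$motif_class)
  expect_equal(as.list(h1), as.list(h2))
  lo <- findSSRs(s, c(9L, 5L, 4L, 3L, 3L, 3L))
  hi <- findSSRs(s, c(11L, 7L, 6L, 5L, 4L, 4L))
  expect_gte(nrow(findSSRs(s)), nrow(hi))
  expect_lte(nrow(findSSRs(s)), nrow(lo))
})

test_that("a constructed palindrome is found as a P repeat", {
  set.seed(5)
  s <- randDNA(40)
  seqfull <- paste0(randDNA(200), s, revcompChr(s), randDNA(200))
  got <- findLongRepeats(seqfull, min_len = 30)
  expect_true(any(got$rtype == "P" & got$length >= 40))
})

test_that("long-repeat records match the quadratic oracle, including maximality", {
  set.seed(202)
  for (rep in 1:6) {
    core <- randDNA(400)
    seg <- substring(randDNA(60), 1, sample(14:25, 1))
    s <- paste0(core, seg, randDNA(80), revcompChr(seg), randDNA(80),
                paste(rev(strsplit(seg, "")[[1]]), collapse = ""),
                randDNA(80), chartr("ACGT", "TGCA", seg), randDNA(80), seg)
    got <- findLongRepeats(s, min_len = 12)
    exp <- oracleLongRepeats(s, min_len = 12)
    expect_identical(sortedRepeatKey(got), sortedRepeatKey(exp))
    # maximality: one-base extension breaks the type-specific match
    # (self-symmetric halves are exempt: their extension folds onto the
    # same palindrome)
    ch <- strsplit(s, "")[[1]]; n <- length(ch)
    for (r in seq_len(min(nrow(got), 10))) {
      if (got$self_symmetric[r]) next
      ty <- got$rtype[r]; len <- got$length[r]
      p1 <- got$pos1[r]; p2 <- got$pos2[r]
      lhs <- function(i) ch[i + 1]
      ok_right <- switch(ty,
        F = p1 + len >= n || p2 + len >= n ||
          lhs(p1 + len) != lhs(p2 + len),
        C = p1 + len >= n || p2 + len >= n ||
          lhs(p1 + len) != chartr("ACGT", "TGCA", lhs(p2 + len)),
        P = p1 + len >= n || p2 < 1 ||
          lhs(p1 + len) != chartr("ACGT", "TGCA", lhs(p2 - 1)),
        R = p1 + len >= n || p2 < 1 || lhs(p1 + len) != lhs(p2 - 1))
      expect_true(ok_right)
    }
  }
})

test_that("repeat location classification follows the gene/intron/IGS overlap rule", {
  b <- fixtureBuild()
  part <- fixturePartition()
  g <- b$genome
  ft <- geneFeatures(g)
  i <- which(ft$gene == "atpF")   # two exons, so it has an intron
  ex_s <- ft$exon_starts[[i]]; ex_e <- ft$exon_ends[[i]]
  probe <- data.frame(
    start = c(ex_s[1] + 2L,                    # inside exon
              ex_e[1] + 5L,                    # inside the intron
              ex_e[1] - 3L),                   # spans exon/intron boundary
    end = c(ex_s[1] + 12L, ex_e[1] + 15L, ex_e[1] + 7L))
  out <- classifyRepeatLocation(probe$start, probe$end, g, part)
  expect_equal(out$context, c("gene", "intron", "gene"))
  # linear-scan oracle on random intervals
  spans <- plastomics:::featureSpans(ft)
  set.seed(9)
  st <- sample.int(genomeLength(g) - 60L, 150) - 1L
  en <- st + sample(5:50, 150, replace = TRUE)
  got <- classifyRepeatLocation(st, en, g, part)
  for (k in seq_along(st)) {
    in_exon <- FALSE; in_gene <- FALSE
    for (i in seq_len(nrow(ft))) {
      if (st[k] < spans$end[i] && spans$start[i] < en[k]) in_gene <- TRUE
      for (e in seq_along(ft$exon_starts[[i]]))
        if (st[k] < ft$exon_ends[[i]][e] && ft$exon_starts[[i]][e] < en[k])
          in_exon <- TRUE
    }
    expect_equal(got$context[k],
                 if (in_exon) "gene" else if (in_gene) "intron" else "IGS")
    expect_equal(got$region[k],
                 classifyPosition(part, ((st[k] + en[k]) %/% 2L)))
  }
})

test_that("the IR pair is reported as a flagged palindromic hit", {
  b <- fixtureBuild()
  part <- fixturePartition()
  lr <- findLongRepeats(b$genome, min_len = 30, partition = part)
  irhit <- lr[lr$ir_pair, ]
  expect_equal(nrow(irhit), 1)
  expect_equal(irhit$rtype, "P")
  expect_gte(irhit$length, part@ir_len)
})
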