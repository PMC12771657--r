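test_that("the generator is deterministic under its seed", {
  sp <- smallSpec(seed = 19)
  b1 <- buildPlastome(sp)
  b2 <- buildPlastome(sp)
  expect_identical(as.character(plastomeSeq(b1$genome)),
                   as.character(plastomeSeq(b2$genome)))
  expect_identical(b1$manifest$ssrs, b2$manifest$ssrs)
  c1 <- mutateCohort(b1$genome, sp)
  c2 <- mutateCohort(b2$genome, sp)
  expect_identical(c1$alignment, c2$alignment)
  e1 <- evolveCdsPair(b1$manifest$cds$matK, 0.3, 0.1, seed = 4)
  e2 <- evolveCdsPair(b1$manifest$cds$matK, 0.3, 0.1, seed = 4)
  expect_identical(e1, e2)
})

test_that("planted repeats are recovered exactly and negative controls are clean", {
  b <- fixtureBuild()
  part <- fixturePartition()
  sp <- smallSpec()
  got_ssr <- findSSRs(b$genome, sp$ssr_thresholds)
  man <- b$manifest$ssrs
  expect_equal(nrow(got_ssr), nrow(man))
  expect_setequal(paste(got_ssr$start, got_ssr$end, got_ssr$motif),
                  paste(man$start, man$end, man$motif))
  got_lr <- findLongRepeats(b$genome, 30, partition = part)
  got_lr <- got_lr[!got_lr$ir_pair, ]
  expect_identical(sortedRepeatKey(got_lr),
                   sortedRepeatKey(b$manifest$long_repeats))
  # background-only genome: nothing but the flagged IR hit
  sp0 <- smallSpec(seed = 23, planted_ssrs = NULL,
                   planted_long_repeats = NULL)
  b0 <- buildPlastome(sp0)
  p0 <- detectQuadripartite(b0$genome)
  expect_equal(nrow(findSSRs(b0$genome)), 0)
  lr0 <- findLongRepeats(b0$genome, 30, partition = p0)
  expect_true(all(lr0$ir_pair))
})

test_that("zero mutation rates give an invariant cohort; hot blocks elevate diversity", {
  sp <- smallSpec(seed = 29, background_rate = 0, hot_rate = 0)
  b <- buildPlastome(sp)
  co <- mutateCohort(b$genome, sp)
  expect_true(all(co$alignment == co$alignment[rep(1, nrow(co$alignment)), ]))
  w <- windowScan(co$alignment)
  expect_true(all(w$pi == 0))
  expect_equal(nrow(mergeHypervariable(w, co$alignment)), 0)
  # measured Pi tracks the closed-form expectation of pairwise difference
  sp2 <- smallSpec(seed = 29)
  co2 <- mutateCohort(b$genome, sp2)
  pdiff <- function(r) 2 * r * (1 - r) + (2 / 3) * r^2
  blocks <- co2$manifest$hot_blocks
  hot_cols <- unlist(lapply(seq_len(nrow(blocks)), function(i)
    (blocks$start[i] + 1):blocks$end[i]))
  bg_cols <- setdiff(seq_len(ncol(co2$alignment)), hot_cols)
  measured_bg <- oraclePi(co2$alignment[, bg_cols], 0,
                          length(bg_cols))
  measured_hot <- oraclePi(co2$alignment[, hot_cols], 0,
                           length(hot_cols))
  expect_equal(measured_bg, pdiff(sp2$background_rate), tolerance = 0.1)
  expect_equal(measured_hot, pdiff(sp2$hot_rate), tolerance = 0.1)
})

test_that("CDS pair evolution honors its boundary targets", {
  anc <- randomCDS(150, seed = 3)
  # ks_target 0 -> identical copies
  e0 <- evolveCdsPair(anc, 0.5, 0, seed = 1)
  expect_identical(e0$cds_a, e0$cds_b)
  # omega_target 0 -> no nonsynonymous change, ka exactly 0
  e1 <- evolveCdsPair(anc, 0, 0.2, seed = 2)
  expect_equal(e1$n_nonsyn, 0L)
  r <- ng86(plastomics:::splitCodons(e1$cds_a),
            plastomics:::splitCodons(e1$cds_b))
  expect_equal(r$ka, 0)
  expect_gt(r$ks, 0)
})

test_that("the emitted bundle is readable and matches the in-memory objects", {
  b <- fixtureBuild()
  sp <- smallSpec()
  co <- mutateCohort(b$genome, sp)
  dir <- withr::local_tempdir()
  writeSyntheticBundle(b, dir, cohort = co)
  id <- plastomeId(b$genome)
  g2 <- readGenBank(file.path(dir, paste0(id, ".gb")))
  expect_identical(as.character(plastomeSeq(g2)),
                   as.character(plastomeSeq(b$genome)))
  f <- readPlastomeFasta(file.path(dir, paste0(id, ".fasta")))
  expect_identical(as.character(plastomeSeq(f)),
                   as.character(plastomeSeq(b$genome)))
  aln <- readAlignment(file.path(dir, "cohort_aln.fasta"))
  expect_identical(aln, co$alignment)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$partition$ir_len, b$manifest$partition$ir_len)
})

test_that("infeasible gene packings are rejected", {
  gt <- defaultGeneTable()[1:6, ]
  expect_error(
    syntheticSpec(total_len = 10000, ir_len = 2000, ssc_len = 1200,
                  gene_table = gt, planted_ssrs = NULL,
                  planted_long_repeats = NULL) |> buildPlastome(),
    "infeasible")
  # planted SSRs below threshold are rejected up front
  expect_error(
    smallSpec(planted_ssrs = data.frame(motif = "A", repeats = 5L,
                                        region = "LSC")),
    "threshold")
})
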