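#' @importFrom stats runif
NULL

# run code under a seed, restoring the caller's RNG state afterwards
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.BASES <- c("A", "C", "G", "T")

drawBases <- function(n, gc) {
  sample(.BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

compBase <- function(b) chartr("ACGT", "TGCA", b)

pickBaseNot <- function(forbidden) sample(setdiff(.BASES, forbidden), 1)

# random in-frame CDS: ATG start, TAA stop, GC-weighted sense codons
drawCDS <- function(len, gc) {
  stopifnot(len %% 3 == 0, len >= 6)
  n_mid <- len / 3 - 2
  mid <- character(n_mid)
  stops <- c("TAA", "TAG", "TGA")
  i <- 1L
  while (i <= n_mid) {
    cod <- paste(drawBases(3, gc), collapse = "")
    if (!cod %in% stops) { mid[i] <- cod; i <- i + 1L }
  }
  paste0("ATG", paste(mid, collapse = ""), "TAA")
}

#' Default gene layout for the synthetic plastome
#'
#' A realistic reduced gene complement: LSC genes anchored near the JLA and
#' JLB junctions (a psbA-like gene 138 bp from JLA; an rps19-like gene
#' extending 104 bp into IRb), intron-containing genes, an IRb block that
#' is mirrored into IRa (hence duplicated), SSC genes, and a ycf1-like gene
#' straddling JSA.  Columns: \code{symbol}, \code{category}, \code{strand},
#' \code{exon_lens} (comma-separated), \code{intron_len}, \code{region},
#' \code{junction} (\code{NA} or junction name), \code{offset}
#' (bp of the gene inside the region downstream of the junction; negative
#' values mean the gene lies entirely downstream at that distance).
#'
#' @return a data.frame, one row per gene to place.
#' @export
defaultGeneTable <- function() {
  g <- function(symbol, category, strand, exon_lens, intron_len, region,
                junction = NA, offset = NA)
    data.frame(symbol = symbol, category = category, strand = strand,
               exon_lens = paste(exon_lens, collapse = ","),
               intron_len = intron_len, region = region,
               junction = junction, offset = offset,
               stringsAsFactors = FALSE)
  rbind(
    g("psbA",  "PCG",  "-", 1062, 0, "LSC", "JLA", -138),
    g("trnH",  "tRNA", "+", 75,   0, "LSC"),
    g("matK",  "PCG",  "+", 1530, 0, "LSC"),
    g("rps16", "PCG",  "-", c(40, 227), 860, "LSC"),
    g("trnQ",  "tRNA", "-", 72,   0, "LSC"),
    g("atpA",  "PCG",  "+", 1524, 0, "LSC"),
    g("atpF",  "PCG",  "-", c(145, 410), 700, "LSC"),
    g("rpoB",  "PCG",  "+", 3213, 0, "LSC"),
    g("rpoC1", "PCG",  "+", c(432, 1614), 750, "LSC"),
    g("trnC",  "tRNA", "+", 71,   0, "LSC"),
    g("psbD",  "PCG",  "+", 1062, 0, "LSC"),
    g("psbC",  "PCG",  "+", 1386, 0, "LSC"),
    g("trnT",  "tRNA", "+", 73,   0, "LSC"),
    g("rbcL",  "PCG",  "+", 1428, 0, "LSC"),
    g("petA",  "PCG",  "+", 963,  0, "LSC"),
    g("psbB",  "PCG",  "+", 1527, 0, "LSC"),
    g("rpl20", "PCG",  "-", 354,  0, "LSC"),
    g("trnF",  "tRNA", "+", 73,   0, "LSC"),
    g("rps19", "PCG",  "-", 279,  0, "LSC", "JLB", 104),
    g("rpl2",  "PCG",  "-", 1491, 0, "IRb"),
    g("ycf2",  "PCG",  "+", 2100, 0, "IRb"),
    g("trnL",  "tRNA", "+", 81,   0, "IRb"),
    g("ndhB",  "PCG",  "-", c(777, 756), 680, "IRb"),
    g("rrn16", "rRNA", "+", 1491, 0, "IRb"),
    g("trnA",  "tRNA", "+", 73,   0, "IRb"),
    g("rrn23", "rRNA", "+", 2810, 0, "IRb"),
    g("rrn5",  "rRNA", "+", 121,  0, "IRb"),
    g("ndhF",  "PCG",  "-", 2241, 0, "SSC", "JSB", -10),
    g("rpl32", "PCG",  "+", 174,  0, "SSC"),
    g("ccsA",  "PCG",  "+", 960,  0, "SSC"),
    g("ndhD",  "PCG",  "-", 1503, 0, "SSC"),
    g("ndhE",  "PCG",  "-", 306,  0, "SSC"),
    g("ndhG",  "PCG",  "-", 531,  0, "SSC"),
    g("ndhA",  "PCG",  "-", c(553, 539), 1100, "SSC"),
    g("ycf1",  "PCG",  "+", 1800, 0, "SSC", "JSA", 950))
}

defaultPlantedSSRs <- function() {
  data.frame(
    motif = c("A", "T", "AT", "TA", "AAT", "TTTCA", "AAAT", "A", "AT", "A"),
    repeats = c(12L, 10L, 6L, 7L, 5L, 3L, 4L, 11L, 8L, 10L),
    region = c("LSC", "LSC", "LSC", "LSC", "LSC", "LSC", "LSC",
               "SSC", "SSC", "IRb"),
    stringsAsFactors = FALSE)
}

defaultPlantedLongRepeats <- function() {
  data.frame(rtype = c("F", "P", "R", "C", "P", "F"),
             length = c(41L, 48L, 32L, 31L, 36L, 30L),
             region = c("LSC", "LSC", "SSC", "LSC", "SSC", "LSC"),
             stringsAsFactors = FALSE)
}

#' Specification for a synthetic plastome study
#'
#' Bundles every tunable of the generator; the defaults emulate an East
#' Asian \emph{Aletris}-like chloroplast genome cohort: a ~154.5 kb
#' quadripartite circle (IR 26.6 kb, SSC 18.1 kb), per-region GC of
#' 35.3/31.2/42.8\%, a reduced but structurally faithful gene complement
#' (see [defaultGeneTable()]), planted A/T-rich microsatellites and long
#' repeats, a 14-taxon cohort with background per-site substitution
#' probability 0.002 and hot blocks at 0.012 (giving background Pi near
#' 0.004 and hot-region Pi near 0.02).
#'
#' @param seed integer seed; every generator output is reproducible
#'   bit-for-bit from (spec, seed).
#' @param total_len,ir_len,ssc_len genome and region sizes in bp (LSC is
#'   the remainder and must stay longer than SSC).
#' @param gc named numeric: GC fraction targets for \code{lsc}, \code{ssc},
#'   \code{ir} backgrounds.
#' @param gene_table data.frame as returned by [defaultGeneTable()].
#' @param planted_ssrs data.frame(motif, repeats, region).
#' @param planted_long_repeats data.frame(rtype, length, region); copies
#'   are placed in single-copy regions only.
#' @param n_taxa cohort size for [mutateCohort()].
#' @param background_rate,hot_rate per-site substitution probabilities.
#' @param n_hot_blocks,hot_block_len number and size of elevated-diversity
#'   blocks (placed deterministically in LSC/SSC background);
#'   alternatively supply \code{hot_blocks} as data.frame(start, end,
#'   rate) in genome coordinates.
#' @param hot_blocks optional explicit hot-block table (overrides the
#'   automatic layout).
#' @param ssr_thresholds minimum repeat counts per motif length 1-6 used
#'   for background screening.
#' @param min_repeat_len long repeats at or above this length are screened
#'   out of the background (default 30).
#' @return a validated list of class \code{SyntheticSpec}.
#' @export
syntheticSpec <- function(seed = 1L,
                          total_len = 154500L, ir_len = 26600L,
                          ssc_len = 18100L,
                          gc = c(lsc = 0.353, ssc = 0.312, ir = 0.428),
                          gene_table = defaultGeneTable(),
                          planted_ssrs = defaultPlantedSSRs(),
                          planted_long_repeats = defaultPlantedLongRepeats(),
                          n_taxa = 14L,
                          background_rate = 0.002, hot_rate = 0.012,
                          n_hot_blocks = 8L, hot_block_len = 1500L,
                          hot_blocks = NULL,
                          ssr_thresholds = .defaultSSRThresholds,
                          min_repeat_len = 30L) {
  lsc <- total_len - ssc_len - 2L * ir_len
  if (ir_len + ssc_len >= total_len || lsc <= ssc_len)
    stop("invalid sizes: need ir_len + ssc_len < total_len and LSC > SSC")
  stopifnot(all(c("lsc", "ssc", "ir") %in% names(gc)),
            all(gc >= 0 & gc <= 1),
            background_rate >= 0, background_rate <= 1,
            hot_rate >= 0, hot_rate <= 1, n_taxa >= 2)
  if (!is.null(planted_ssrs) && nrow(planted_ssrs)) {
    u <- nchar(planted_ssrs$motif)
    if (any(planted_ssrs$repeats < ssr_thresholds[u]))
      stop("planted SSRs must meet the detection thresholds")
    if (!all(vapply(planted_ssrs$motif, isPrimitiveMotif, logical(1))))
      stop("planted SSR motifs must be primitive")
  }
  if (!is.null(planted_long_repeats) && nrow(planted_long_repeats)) {
    if (any(planted_long_repeats$region == "IRb"))
      stop("planted long repeats must lie in single-copy regions")
  }
  spec <- list(seed = as.integer(seed), total_len = as.integer(total_len),
               ir_len = as.integer(ir_len), ssc_len = as.integer(ssc_len),
               lsc_len = as.integer(lsc), gc = gc, gene_table = gene_table,
               planted_ssrs = planted_ssrs,
               planted_long_repeats = planted_long_repeats,
               n_taxa = as.integer(n_taxa),
               background_rate = background_rate, hot_rate = hot_rate,
               n_hot_blocks = as.integer(n_hot_blocks),
               hot_block_len = as.integer(hot_block_len),
               hot_blocks = hot_blocks,
               ssr_thresholds = as.integer(ssr_thresholds),
               min_repeat_len = as.integer(min_repeat_len))
  class(spec) <- "SyntheticSpec"
  spec
}

# ---- gene layout ------------------------------------------------------------

# resolve the gene table into full-genome spans/exon layouts
resolveGeneLayout <- function(spec) {
  lsc <- spec$lsc_len; ir <- spec$ir_len; ssc <- spec$ssc_len
  L <- spec$total_len
  core_len <- lsc + ir + ssc
  jpos <- c(JLB = lsc, JSB = lsc + ir, JSA = core_len, JLA = 0L)
  gt <- spec$gene_table
  gt$len <- vapply(strsplit(gt$exon_lens, ","), function(x)
    sum(as.integer(x)), integer(1)) +
    ifelse(vapply(strsplit(gt$exon_lens, ","), length, integer(1)) > 1,
           gt$intron_len, 0L)
  gt$cds_len <- vapply(strsplit(gt$exon_lens, ","), function(x)
    sum(as.integer(x)), integer(1))
  gt$start <- NA_integer_
  # junction-anchored genes first
  for (i in which(!is.na(gt$junction))) {
    p <- jpos[[gt$junction[i]]]
    if (gt$junction[i] == "JLA" && gt$offset[i] >= 0) p <- L
    gt$start[i] <- if (gt$offset[i] >= 0) p - (gt$len[i] - gt$offset[i])
                   else p - gt$offset[i]
  }
  # mirror zone in IRb claimed by genes extending into IRa across JSA
  mirror_zone <- 0L
  for (i in which(!is.na(gt$junction) & gt$junction == "JSA")) {
    if (gt$offset[i] > 0) mirror_zone <- max(mirror_zone, gt$offset[i])
  }
  margin <- 60L
  region_bounds <- list(
    LSC = c(0L, lsc), IRb = c(lsc, lsc + ir), SSC = c(lsc + ir, core_len))
  for (reg in names(region_bounds)) {
    idx <- which(gt$region == reg & is.na(gt$start))
    if (!length(idx)) next
    lo <- region_bounds[[reg]][1]; hi <- region_bounds[[reg]][2]
    if (reg == "IRb") hi <- hi - mirror_zone
    anchored <- which(!is.na(gt$start))
    for (a in anchored) {
      s <- gt$start[a]; e <- s + gt$len[a]
      if (e > lo && s < hi) {  # keep the larger side of the free interval
        if ((s - lo) >= (hi - e)) hi <- min(hi, s) else lo <- max(lo, e)
      }
    }
    lo <- lo + margin; hi <- hi - margin
    need <- sum(gt$len[idx])
    slack <- (hi - lo) - need - 30L * length(idx)
    if (slack < 0)
      stop("infeasible packing: genes of region ", reg,
           " exceed available space by ", -slack, " bp")
    gaps <- runif(length(idx))
    gaps <- floor(gaps / sum(gaps) * slack) + 30L
    cur <- lo
    for (k in seq_along(idx)) {
      cur <- cur + gaps[k]
      gt$start[idx[k]] <- cur
      cur <- cur + gt$len[idx[k]]
    }
  }
  # exon coordinates (genomic ascending within the span)
  gt$exon_starts <- vector("list", nrow(gt))
  gt$exon_ends <- vector("list", nrow(gt))
  for (i in seq_len(nrow(gt))) {
    el <- as.integer(strsplit(gt$exon_lens[i], ",")[[1]])
    if (gt$strand[i] == "-") el <- rev(el)   # genomic order
    s <- gt$start[i]
    starts <- integer(0); ends <- integer(0); cur <- s
    for (k in seq_along(el)) {
      starts <- c(starts, cur); ends <- c(ends, cur + el[k])
      cur <- cur + el[k] + if (k < length(el)) gt$intron_len[i] else 0L
    }
    gt$exon_starts[[i]] <- starts
    gt$exon_ends[[i]] <- ends
  }
  gt
}

# ---- sequence assembly ------------------------------------------------------

# write characters to full-genome coordinates, redirecting positions that
# fall in IRa (or wrap) into the IRb mirror of the core vector
writeFull <- function(core, pos, chars, lsc, ir, L) {
  core_len <- length(core)
  pos <- pos %% L
  in_core <- pos < core_len
  core[pos[in_core] + 1L] <- chars[in_core]
  if (any(!in_core)) {
    u <- pos[!in_core] - core_len
    core[lsc + ir - u] <- compBase(chars[!in_core])
  }
  core
}

assembleFull <- function(core, lsc, ir) {
  irb <- core[(lsc + 1L):(lsc + ir)]
  c(core, rev(compBase(irb)))
}

#' Build a synthetic annotated plastome with a ground-truth manifest
#'
#' Generates a quadripartite circular genome in canonical rotation: random
#' per-region background (screened so that no microsatellite reaches the
#' detection thresholds and no repeat pair of any of the four types reaches
#' \code{min_repeat_len}), an exact inverted-repeat pair (IRa is the
#' reverse complement of IRb, byte for byte), genes placed per the gene
#' table (including junction-straddling genes and IRb genes mirrored into
#' IRa), and the requested SSRs and long repeats planted into otherwise
#' repeat-free background with flanks fixed so every planted repeat is
#' maximal and recovered exactly.  Deterministic under \code{spec$seed}.
#'
#' @param spec a \code{SyntheticSpec} from [syntheticSpec()].
#' @return list with \code{genome} (an \linkS4class{AnnotatedPlastome}) and
#'   \code{manifest}: realized partition lengths, gene table (with mirrored
#'   IR copies), CDS truth sequences, realized SSR records (including the
#'   IRa images of IRb-planted SSRs), long-repeat records, and realized
#'   per-region GC.
#' @export
buildPlastome <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(spec$seed, buildPlastomeImpl(spec))
}

buildPlastomeImpl <- function(spec) {
  lsc <- spec$lsc_len; ir <- spec$ir_len; ssc <- spec$ssc_len
  L <- spec$total_len
  core_len <- lsc + ir + ssc

  core <- c(drawBases(lsc, spec$gc[["lsc"]]),
            drawBases(ir, spec$gc[["ir"]]),
            drawBases(ssc, spec$gc[["ssc"]]))

  gt <- resolveGeneLayout(spec)

  # protectedMask keeps the placement allocator away from genes and planted
  # features; plantedMask marks planted repeats, the only content the
  # repair loop must never redraw (gene content is repaired codon-wise,
  # introns as background)
  protectedMask <- rep(FALSE, core_len)
  plantedMask <- rep(FALSE, core_len)
  protect <- function(mask, from, to) {  # [from, to) in full coords
    p <- (from:(to - 1L)) %% L
    u <- p[p >= core_len] - core_len
    p <- p[p < core_len]
    if (length(p)) mask[p + 1L] <- TRUE
    if (length(u)) mask[lsc + ir - u] <- TRUE
    mask
  }

  # gene content; cds_pos[[i]][t+1] is the full-genome position carrying
  # coding-strand offset t of gene i (used by the codon-level repair below)
  cds_pos <- vector("list", nrow(gt))
  toCoreIdx <- function(q) {        # full 0-based -> core 1-based index
    q <- q %% L
    ifelse(q < core_len, q + 1L, lsc + ir - (q - core_len))
  }
  gene_of <- rep(NA_integer_, core_len)
  cds_off <- rep(NA_integer_, core_len)
  for (i in seq_len(nrow(gt))) {
    clen <- gt$cds_len[i]
    content <- if (gt$category[i] == "PCG") drawCDS(clen, 0.40)
               else paste(drawBases(clen, 0.50), collapse = "")
    chars <- strsplit(content, "")[[1]]
    # genomic positions of concatenated-exon offsets, ascending
    gpos <- unlist(lapply(seq_along(gt$exon_starts[[i]]), function(k)
      gt$exon_starts[[i]][k]:(gt$exon_ends[[i]][k] - 1L)))
    fp <- if (gt$strand[i] == "+") gpos else rev(gpos)
    cds_pos[[i]] <- fp
    gchars <- if (gt$strand[i] == "+") chars else compBase(chars)
    core <- writeFull(core, fp, gchars, lsc, ir, L)
    ci <- toCoreIdx(fp)
    clash <- !is.na(gene_of[ci])
    if (any(clash))
      stop("infeasible packing: '", gt$symbol[i], "' overlaps '",
           gt$symbol[gene_of[ci][clash][1]],
           "' (directly or through the IR mirror)")
    gene_of[ci] <- i
    cds_off[ci] <- seq_along(fp) - 1L
    protectedMask <- protect(protectedMask, gt$start[i],
                             gt$start[i] + gt$len[i])
  }
  # redraw the sense codon (or raw base for RNA genes) covering core index
  # ci; never touches the start/stop codon of a PCG
  redrawGeneContent <- function(core, ci) {
    i <- gene_of[ci]; t <- cds_off[ci]
    if (gt$category[i] != "PCG") {
      q <- cds_pos[[i]][t + 1L]
      ch <- drawBases(1L, 0.5)
      if (gt$strand[i] == "-") ch <- compBase(ch)
      return(writeFull(core, q, ch, lsc, ir, L))
    }
    cidx <- t %/% 3L
    n_cod <- gt$cds_len[i] %/% 3L
    if (cidx == 0L || cidx == n_cod - 1L) return(core)
    cod <- "TAA"
    while (cod %in% c("TAA", "TAG", "TGA"))
      cod <- paste(drawBases(3, 0.40), collapse = "")
    for (k in 0:2) {
      q <- cds_pos[[i]][3L * cidx + k + 1L]
      ch <- substring(cod, k + 1, k + 1)
      if (gt$strand[i] == "-") ch <- compBase(ch)
      core <- writeFull(core, q, ch, lsc, ir, L)
    }
    core
  }

  regionBounds <- list(LSC = c(0L, lsc), IRb = c(lsc, lsc + ir),
                       SSC = c(lsc + ir, core_len))
  freeSlot <- function(len, region) {
    b <- regionBounds[[region]]
    free <- !protectedMask[(b[1] + 1L):b[2]]
    r <- rle(free)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= len + 8L)
    if (!length(ok)) stop("infeasible packing: no room for a ", len,
                          " bp feature in ", region)
    pick <- ok[sample.int(length(ok), 1)]
    off <- sample.int(r$lengths[pick] - len - 7L, 1) + 3L
    b[1] + starts[pick] - 1L + off   # 0-based start in full coords
  }

  # ---- plant SSRs
  ssr_manifest <- NULL
  ps <- spec$planted_ssrs
  if (!is.null(ps) && nrow(ps)) {
    for (i in seq_len(nrow(ps))) {
      motif <- toupper(ps$motif[i]); u <- nchar(motif); k <- ps$repeats[i]
      run <- strrep(motif, k); m <- u * k
      st <- freeSlot(m, ps$region[i])
      core <- writeFull(core, st:(st + m - 1L), strsplit(run, "")[[1]],
                        lsc, ir, L)
      mfirst <- substring(motif, 1, 1); mlast <- substring(motif, u, u)
      core <- writeFull(core, st - 1L, pickBaseNot(mlast), lsc, ir, L)
      core <- writeFull(core, st + m, pickBaseNot(mfirst), lsc, ir, L)
      protectedMask <- protect(protectedMask, st - 2L, st + m + 2L)
      plantedMask <- protect(plantedMask, st - 2L, st + m + 2L)
      ssr_manifest <- rbind(ssr_manifest, data.frame(
        start = st, end = st + m, motif = motif, unit_len = u,
        repeats = k, region = ps$region[i], stringsAsFactors = FALSE))
    }
    # IRb-planted SSRs are mirrored into IRa
    irb_rows <- which(ssr_manifest$region == "IRb")
    for (i in irb_rows) {
      s <- ssr_manifest$start[i]; e <- ssr_manifest$end[i]
      jsb <- lsc + ir; jsa <- core_len
      rc <- as.character(reverseComplement(DNAString(ssr_manifest$motif[i])))
      ssr_manifest <- rbind(ssr_manifest, data.frame(
        start = jsa + (jsb - e), end = jsa + (jsb - s), motif = rc,
        unit_len = ssr_manifest$unit_len[i],
        repeats = ssr_manifest$repeats[i], region = "IRa",
        stringsAsFactors = FALSE))
    }
  }

  # ---- plant long repeats (single-copy regions only)
  lr_manifest <- NULL
  pl <- spec$planted_long_repeats
  if (!is.null(pl) && nrow(pl)) {
    for (i in seq_len(nrow(pl))) {
      len <- pl$length[i]; ty <- pl$rtype[i]
      seg <- drawBases(len, 0.40)
      copy2 <- switch(ty, F = seg, P = rev(compBase(seg)),
                      R = rev(seg), C = compBase(seg))
      p1 <- freeSlot(len, pl$region[i])
      core <- writeFull(core, p1:(p1 + len - 1L), seg, lsc, ir, L)
      protectedMask <- protect(protectedMask, p1 - 2L, p1 + len + 2L)
      plantedMask <- protect(plantedMask, p1 - 2L, p1 + len + 2L)
      p2 <- freeSlot(len, pl$region[i])
      core <- writeFull(core, p2:(p2 + len - 1L), copy2, lsc, ir, L)
      protectedMask <- protect(protectedMask, p2 - 2L, p2 + len + 2L)
      plantedMask <- protect(plantedMask, p2 - 2L, p2 + len + 2L)
      # fix flanks so the pair is maximal for its type
      lo <- min(p1, p2); hi <- max(p1, p2)
      fixFlank <- function(core, posA, posB, transform) {
        a <- core[posA %% L + 1L]
        bpos <- posB %% L
        b <- core[bpos + 1L]
        if (transform(a) == b)
          core <- writeFull(core, bpos, pickBaseNot(transform(a)), lsc, ir, L)
        core
      }
      id <- function(x) x
      if (ty == "F") {
        core <- fixFlank(core, p1 - 1L, p2 - 1L, id)
        core <- fixFlank(core, p1 + len, p2 + len, id)
      } else if (ty == "C") {
        core <- fixFlank(core, p1 - 1L, p2 - 1L, compBase)
        core <- fixFlank(core, p1 + len, p2 + len, compBase)
      } else if (ty == "P") {
        core <- fixFlank(core, p1 - 1L, p2 + len, compBase)
        core <- fixFlank(core, p1 + len, p2 - 1L, compBase)
      } else if (ty == "R") {
        core <- fixFlank(core, p1 - 1L, p2 + len, id)
        core <- fixFlank(core, p1 + len, p2 - 1L, id)
      }
      lr_manifest <- rbind(lr_manifest, data.frame(
        rtype = ty, length = len, pos1 = lo, pos2 = hi,
        region = pl$region[i], stringsAsFactors = FALSE))
    }
  }

  # junction break: the IR pair must not extend by chance across junctions;
  # the extension partners are (s[lsc-1], s[0]) and (s[lsc+ir], s[core_len-1])
  breakPair <- function(core, ciA, ciB) {
    if (core[ciA] != compBase(core[ciB])) return(core)
    for (ci in c(ciB, ciA)) {
      other <- if (ci == ciB) ciA else ciB
      if (is.na(gene_of[ci]) && !plantedMask[ci]) {
        core[ci] <- pickBaseNot(compBase(core[other]))
        return(core)
      }
    }
    for (ci in c(ciA, ciB))
      if (!is.na(gene_of[ci])) return(redrawGeneContent(core, ci))
    core
  }
  enforceJunctionBreaks <- function(core) {
    core <- breakPair(core, lsc, 1L)
    breakPair(core, lsc + ir + 1L, core_len)
  }
  junctionBreaksOk <- function(core) {
    core[lsc] != compBase(core[1]) &&
      core[lsc + ir + 1L] != compBase(core[core_len])
  }
  core <- enforceJunctionBreaks(core)

  # ---- verification & repair loop
  expected_ssr <- if (is.null(ssr_manifest)) {
    data.frame(start = integer(), end = integer(), motif = character())
  } else ssr_manifest[order(ssr_manifest$start), c("start", "end", "motif")]
  expected_lr <- if (is.null(lr_manifest)) {
    data.frame(rtype = character(), length = integer(), pos1 = integer(),
               pos2 = integer())
  } else lr_manifest[order(lr_manifest$pos1),
                     c("rtype", "length", "pos1", "pos2")]
  partition <- new("RegionPartition", genome_length = L,
                   lsc_len = lsc, ssc_len = ssc, ir_len = ir,
                   rotation = 0L)

  repairPositions <- function(core, pos0) {   # full coords, 0-based
    pos0 <- pos0 %% L
    for (q in pos0) {
      ci <- if (q < core_len) q + 1L else lsc + ir - (q - core_len)
      if (!is.na(gene_of[ci])) {
        core <- redrawGeneContent(core, ci)
        next
      }
      if (plantedMask[ci]) next   # planted repeat: leave untouched
      reg <- if (ci - 1L < lsc) "lsc" else if (ci - 1L < lsc + ir) "ir"
             else "ssc"
      core[ci] <- drawBases(1L, spec$gc[[reg]])
    }
    core
  }

  ok <- FALSE
  for (iter in seq_len(40)) {
    full <- paste(assembleFull(core, lsc, ir), collapse = "")
    bad <- integer(0)
    found_ssr <- findSSRs(full, spec$ssr_thresholds)
    extra_s <- !paste(found_ssr$start, found_ssr$end, found_ssr$motif) %in%
      paste(expected_ssr$start, expected_ssr$end, expected_ssr$motif)
    miss_s <- !paste(expected_ssr$start, expected_ssr$end,
                     expected_ssr$motif) %in%
      paste(found_ssr$start, found_ssr$end, found_ssr$motif)
    if (any(miss_s))
      stop("internal error: planted SSR lost during screening")
    for (r in which(extra_s))
      bad <- c(bad, found_ssr$start[r]:(found_ssr$end[r] - 1L))
    found_lr <- findLongRepeats(full, spec$min_repeat_len,
                                partition = partition)
    found_lr <- found_lr[!found_lr$ir_pair, , drop = FALSE]
    key_f <- paste(found_lr$rtype, found_lr$length, found_lr$pos1,
                   found_lr$pos2)
    key_e <- paste(expected_lr$rtype, expected_lr$length, expected_lr$pos1,
                   expected_lr$pos2)
    if (!all(key_e %in% key_f))
      stop("internal error: planted long repeat lost during screening")
    for (r in which(!key_f %in% key_e)) {
      bad <- c(bad, found_lr$pos1[r]:(found_lr$pos1[r] + found_lr$length[r]
                                      - 1L))
      bad <- c(bad, found_lr$pos2[r]:(found_lr$pos2[r] + found_lr$length[r]
                                      - 1L))
    }
    if (!length(bad) && junctionBreaksOk(core)) { ok <- TRUE; break }
    core <- repairPositions(core, unique(bad))
    core <- enforceJunctionBreaks(core)
  }
  if (!ok) {
    full <- paste(assembleFull(core, lsc, ir), collapse = "")
    fs <- findSSRs(full, spec$ssr_thresholds)
    fl <- findLongRepeats(full, spec$min_repeat_len, partition = partition)
    fl <- fl[!fl$ir_pair, , drop = FALSE]
    ks_f <- paste(fs$start, fs$end, fs$motif)
    ks_e <- paste(expected_ssr$start, expected_ssr$end, expected_ssr$motif)
    kl_f <- paste(fl$rtype, fl$length, fl$pos1, fl$pos2)
    kl_e <- paste(expected_lr$rtype, expected_lr$length, expected_lr$pos1,
                  expected_lr$pos2)
    stop("background screening did not converge; extra SSRs: ",
         paste(setdiff(ks_f, ks_e), collapse = "; "),
         " | extra repeats: ", paste(setdiff(kl_f, kl_e), collapse = "; "),
         " | junction breaks ok: ", junctionBreaksOk(core))
  }

  # sanity: the detected quadripartite structure must equal the plan
  det <- detectQuadripartite(paste(assembleFull(core, lsc, ir),
                                   collapse = ""))
  if (is.null(det) || det@ir_len != ir || det@lsc_len != lsc)
    stop("internal error: planted IR not recovered (got ",
         if (is.null(det)) "none" else det@ir_len, ")")

  # ---- feature table with IRa mirrors of IRb genes
  sym <- gt$symbol; cat_ <- gt$category; str_ <- gt$strand
  exs <- gt$exon_starts; exe <- gt$exon_ends
  jsb <- lsc + ir; jsa <- core_len
  for (i in seq_len(nrow(gt))) {
    s <- gt$start[i]; e <- s + gt$len[i]
    if (s >= lsc && e <= jsb) {   # wholly inside IRb: mirror into IRa
      sym <- c(sym, gt$symbol[i]); cat_ <- c(cat_, gt$category[i])
      str_ <- c(str_, if (gt$strand[i] == "+") "-" else "+")
      exs <- c(exs, list(rev(jsa + (jsb - gt$exon_ends[[i]]))))
      exe <- c(exe, list(rev(jsa + (jsb - gt$exon_starts[[i]]))))
    }
  }
  mirrored <- c(rep(FALSE, nrow(gt)), rep(TRUE, length(sym) - nrow(gt)))
  ft <- newFeatureTable(sym, cat_, str_, rep(FALSE, length(sym)), exs, exe)

  full <- paste(assembleFull(core, lsc, ir), collapse = "")
  genome <- AnnotatedPlastome(id = sprintf("synth%04d", spec$seed),
                              sequence = full, features = ft)
  # CDS truth, extracted from the final (repaired) sequence
  cds_truth <- list()
  for (i in which(gt$category == "PCG"))
    cds_truth[[gt$symbol[i]]] <-
      splicedSequence(full, gt$exon_starts[[i]], gt$exon_ends[[i]],
                      gt$strand[i], L)
  gc_real <- vapply(regionSequences(genome, partition), gcPercent,
                    numeric(1))
  manifest <- list(
    seed = spec$seed,
    partition = list(total_len = L, lsc_len = lsc, ssc_len = ssc,
                     ir_len = ir),
    genes = data.frame(symbol = sym, category = cat_, strand = str_,
                       start = vapply(exs, min, numeric(1)),
                       end = vapply(exe, max, numeric(1)),
                       n_exons = vapply(exs, length, integer(1)),
                       mirrored = mirrored, stringsAsFactors = FALSE),
    cds = cds_truth,
    ssrs = if (is.null(ssr_manifest)) data.frame() else
      ssr_manifest[order(ssr_manifest$start), ],
    long_repeats = if (is.null(lr_manifest)) data.frame() else
      lr_manifest[order(lr_manifest$pos1), ],
    gc_realized = list(lsc = gc_real[["lsc"]],
                       ssc = gc_real[["ssc"]],
                       ir = gcPercent(paste0(
                         regionSequences(genome, partition)$irb,
                         regionSequences(genome, partition)$ira))))
  list(genome = genome, manifest = manifest)
}

# ---- cohort mutation --------------------------------------------------------

resolveHotBlocks <- function(spec) {
  if (!is.null(spec$hot_blocks)) return(spec$hot_blocks)
  lsc <- spec$lsc_len; ir <- spec$ir_len; ssc <- spec$ssc_len
  n <- spec$n_hot_blocks; len <- spec$hot_block_len
  n_lsc <- max(1L, round(n * 0.75)); n_ssc <- n - n_lsc
  mk <- function(lo, hi, k) {
    if (k < 1) return(NULL)
    anchors <- round(seq(lo + (hi - lo) * 0.08, hi - (hi - lo) * 0.08 - len,
                         length.out = k))
    data.frame(start = as.integer(anchors),
               end = as.integer(anchors + len), rate = spec$hot_rate)
  }
  rbind(mk(0L, lsc, n_lsc), mk(lsc + ir, lsc + ir + ssc, n_ssc))
}

#' Mutate a base plastome into an aligned cohort
#'
#' Applies independent per-taxon, per-site substitutions to the base
#' sequence: probability \code{background_rate} outside the hot blocks and
#' the block rate inside.  No indels are introduced, so the returned
#' matrix is a gap-free alignment in genome coordinates.
#'
#' @param base the \code{genome} from [buildPlastome()] (or any
#'   \linkS4class{AnnotatedPlastome}).
#' @param spec the \code{SyntheticSpec}; uses \code{n_taxa},
#'   \code{background_rate}, \code{hot_rate} and the hot-block layout.
#' @param seed optional seed (defaults to \code{spec$seed + 1}).
#' @return list with \code{alignment} (character matrix, taxa x columns)
#'   and \code{manifest}: hot-block
#'   table, per-block and background realized substitution counts, and the
#'   variable-column coordinates.
#' @export
mutateCohort <- function(base, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(seed, {
    chars <- strsplit(toupper(as.character(plastomeSeq(base))), "")[[1]]
    L <- length(chars)
    blocks <- resolveHotBlocks(spec)
    rate <- rep(spec$background_rate, L)
    if (!is.null(blocks) && nrow(blocks)) {
      for (i in seq_len(nrow(blocks))) {
        idx <- (blocks$start[i] + 1L):blocks$end[i]
        idx <- idx[idx >= 1 & idx <= L]
        rate[idx] <- blocks$rate[i]
      }
    }
    n <- spec$n_taxa
    mat <- matrix(rep(chars, each = n), nrow = n)
    n_sub <- integer(n)
    for (t in seq_len(n)) {
      hit <- which(runif(L) < rate)
      n_sub[t] <- length(hit)
      for (h in hit)
        mat[t, h] <- pickBaseNot(mat[t, h])
    }
    rownames(mat) <- sprintf("%s_t%02d", plastomeId(base), seq_len(n))
    variable <- which(vapply(seq_len(L), function(j)
      length(unique(mat[, j])) > 1, logical(1)))
    per_block <- if (!is.null(blocks) && nrow(blocks))
      vapply(seq_len(nrow(blocks)), function(i)
        sum(variable > blocks$start[i] & variable <= blocks$end[i]),
        integer(1)) else integer(0)
    list(alignment = mat,
         manifest = list(hot_blocks = blocks, n_substitutions = n_sub,
                         variable_columns = variable - 1L,
                         n_variable_in_block = per_block))
  })
}

# ---- CDS pair evolution -----------------------------------------------------

#' Evolve a coding-sequence pair under a target omega
#'
#' Proposes single-base codon changes uniformly at random (alternating
#' between the two copies), rejecting stop-creating changes, accepting
#' synonymous changes with probability 1 and nonsynonymous changes with
#' probability \code{omega_target}, until the number of accepted synonymous
#' events reaches the count implied by \code{ks_target} on the ancestral
#' synonymous site total (Jukes-Cantor inverted).  With
#' \code{omega_target = 0} the two copies differ only synonymously; with
#' \code{ks_target = 0} they are identical.
#'
#' @param cds in-frame coding sequence (>= 300 bp recommended).
#' @param omega_target desired Ka/Ks ratio (>= 0).
#' @param ks_target desired synonymous divergence (substitutions per
#'   synonymous site).
#' @param seed integer seed.
#' @param genetic_code NCBI genetic code id.
#' @return list with \code{cds_a}, \code{cds_b} and the realized counts
#'   \code{n_syn}, \code{n_nonsyn}.
#' @export
evolveCdsPair <- function(cds, omega_target, ks_target, seed,
                          genetic_code = "11") {
  stopifnot(nchar(cds) %% 3 == 0, omega_target >= 0, ks_target >= 0)
  withSeed(seed, {
    tb <- ngTables(genetic_code)
    code <- tb$aa
    cods <- splitCodons(toupper(cds))
    if (code[cods[length(cods)]] == "*") cods <- cods[-length(cods)]
    if (any(code[cods] == "*")) stop("internal stop codon in input CDS")
    S0 <- sum(tb$syn_sites[cods])
    ps_target <- 0.75 * (1 - exp(-4 * ks_target / 3))
    target_events <- round(S0 * ps_target)
    a <- cods; b <- cods
    n_syn <- 0L; n_nonsyn <- 0L
    guard <- 0L
    while (n_syn < target_events) {
      guard <- guard + 1L
      if (guard > 2e6) stop("evolveCdsPair did not reach ks_target")
      onA <- (guard %% 2L) == 0L
      cur <- if (onA) a else b
      i <- sample.int(length(cur), 1)
      pos <- sample.int(3L, 1)
      newb <- sample(setdiff(.BASES, substring(cur[i], pos, pos)), 1)
      cand <- cur[i]
      substring(cand, pos, pos) <- newb
      if (code[cand] == "*") next
      syn <- code[cand] == code[cur[i]]
      if (!syn && runif(1) > omega_target) next
      cur[i] <- cand
      if (onA) a <- cur else b <- cur
      if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
    }
    list(cds_a = paste(a, collapse = ""), cds_b = paste(b, collapse = ""),
         n_syn = n_syn, n_nonsyn = n_nonsyn)
  })
}

#' Write a synthetic bundle to disk
#'
#' Emits the genome as GenBank and FASTA, the truth manifest as JSON and,
#' when a cohort is supplied, the alignment as aligned FASTA.
#'
#' @param built result of [buildPlastome()].
#' @param dir output directory (created if needed).
#' @param cohort optional result of [mutateCohort()].
#' @return the directory, invisibly.
#' @export
writeSyntheticBundle <- function(built, dir, cohort = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- plastomeId(built$genome)
  writeGenBank(built$genome, file.path(dir, paste0(id, ".gb")))
  writePlastomeFasta(built$genome, file.path(dir, paste0(id, ".fasta")))
  man <- built$manifest
  man$cds <- as.list(man$cds)
  write_json(man, file.path(dir, "manifest.json"), auto_unbox = TRUE,
             digits = NA, dataframe = "rows")
  if (!is.null(cohort)) {
    writeAlignment(cohort$alignment, file.path(dir, "cohort_aln.fasta"))
    write_json(cohort$manifest, file.path(dir, "cohort_manifest.json"),
               auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(dir)
}
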