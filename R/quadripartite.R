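#' @importFrom Biostrings reverseComplement letterFrequency subseq
#' @importFrom utils write.table
#' @importFrom jsonlite write_json
NULL

#' Detect the quadripartite LSC-IRb-SSC-IRa structure
#'
#' Finds the longest pair of disjoint, exact reverse-complement repeats of at
#' least \code{min_ir_len} bp on the circular sequence (the inverted
#' repeats), and partitions the circle into LSC, IRb, SSC and IRa.  The
#' longer single-copy region is labeled LSC.  The partition is reported in
#' the canonical rotation: position 0 is the first LSC base and the regions
#' follow in the order LSC, IRb, SSC, IRa.  Detection works on any rotation
#' of the input; the \code{rotation} slot of the result records where the
#' canonical origin sits on the input sequence.
#'
#' Matching is exact (no mismatches); among equally long candidate pairs the
#' one whose IRb starts leftmost (canonically) wins, which makes the result
#' deterministic.
#'
#' @param genome an \linkS4class{AnnotatedPlastome} (or \code{DNAString} /
#'   character sequence).
#' @param min_ir_len minimum IR length in bp (default 1000; plastid IRs are
#'   typically >10 kb, and the floor excludes short dispersed repeats).
#' @return a \linkS4class{RegionPartition}, or \code{NULL} when no inverted
#'   repeat of the required size exists ("no quadripartite structure").
#' @examples
#' sp <- syntheticSpec(total_len = 40000, ir_len = 6000, ssc_len = 5000,
#'                     seed = 1)
#' g <- buildPlastome(sp)$genome
#' detectQuadripartite(g)
#' @export
detectQuadripartite <- function(genome, min_ir_len = 1000L) {
  stopifnot(min_ir_len >= 1)
  seq <- if (is(genome, "AnnotatedPlastome"))
    as.character(plastomeSeq(genome)) else as.character(genome)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 2L * min_ir_len + 2L) return(NULL)

  ss <- paste0(seq, seq)
  rc <- as.character(reverseComplement(DNAString(ss)))
  mem <- .cpp_find_mems(ss, rc, as.integer(min_ir_len))
  if (nrow(mem) == 0) return(NULL)

  # a match ss[i..i+len) == rc[j..j+len) means the partner copy starts at
  # 2L - j - len on ss; map both copies back onto the circle
  p <- 2L * L - mem$j - mem$len
  cand <- data.frame(s1 = mem$i %% L, s2 = p %% L,
                     len = pmin(mem$len, L %/% 2L))
  # canonical unordered pair
  a <- pmin(cand$s1, cand$s2); b <- pmax(cand$s1, cand$s2)
  cand$s1 <- a; cand$s2 <- b
  cand <- unique(cand)
  # the two copies must be disjoint arcs on the circle
  gap1 <- cand$s2 - (cand$s1 + cand$len)            # arc between copy1 -> copy2
  gap2 <- L - cand$s2 - cand$len + cand$s1          # arc between copy2 -> copy1
  cand <- cand[gap1 >= 0 & gap2 >= 0 & cand$len >= min_ir_len, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(-cand$len, cand$s1), , drop = FALSE]
  hit <- cand[1, ]

  ir <- hit$len
  # single-copy arcs between the two IR copies
  arcA <- list(start = (hit$s1 + ir) %% L, len = hit$s2 - (hit$s1 + ir))
  arcB <- list(start = (hit$s2 + ir) %% L, len = L - hit$s2 - ir + hit$s1)
  if (arcA$len <= 0 || arcB$len <= 0 || arcA$len == arcB$len)
    return(NULL)  # degenerate or no unambiguous LSC/SSC labeling
  lsc <- if (arcA$len > arcB$len) arcA else arcB
  ssc <- if (arcA$len > arcB$len) arcB else arcA
  new("RegionPartition",
      genome_length = as.integer(L),
      lsc_len = as.integer(lsc$len),
      ssc_len = as.integer(ssc$len),
      ir_len = as.integer(ir),
      rotation = as.integer(lsc$start))
}

#' Rotate a plastome into its canonical frame
#'
#' Shifts the sequence and all feature coordinates so that position 0 is the
#' first LSC base of \code{partition} (the frame in which
#' \linkS4class{RegionPartition} coordinates and [junctionReport()] are
#' expressed).  The SSC strand is kept as deposited.
#'
#' @param genome an \linkS4class{AnnotatedPlastome}.
#' @param partition the \linkS4class{RegionPartition} from
#'   [detectQuadripartite()] on this genome.
#' @return a list with elements \code{genome} (rotated plastome) and
#'   \code{partition} (same partition with \code{rotation} reset to 0).
#' @export
canonicalizePlastome <- function(genome, partition) {
  L <- genomeLength(genome)
  if (L != partition@genome_length)
    stop("partition and genome disagree on genome length")
  r <- partition@rotation %% L
  if (r == 0L) return(list(genome = genome, partition = partition))
  seq <- as.character(plastomeSeq(genome))
  rotated <- paste0(substring(seq, r + 1L, L), substring(seq, 1L, r))
  ft <- geneFeatures(genome)
  starts <- as.list(ft$exon_starts); ends <- as.list(ft$exon_ends)
  for (i in seq_along(starts)) {
    anchor <- min(starts[[i]])
    shift <- ((anchor - r) %% L) - anchor
    starts[[i]] <- starts[[i]] + shift
    ends[[i]] <- ends[[i]] + shift
  }
  ft2 <- if (nrow(ft)) newFeatureTable(ft$gene, ft$category, ft$strand,
                                       ft$pseudo, starts, ends)
         else ft
  part2 <- partition
  part2@rotation <- 0L
  list(genome = AnnotatedPlastome(plastomeId(genome), rotated, ft2,
                                  source = genome@source),
       partition = part2)
}

#' Classify a position into its quadripartite region
#'
#' @param partition a \linkS4class{RegionPartition}.
#' @param pos integer position(s), 0-based, in the canonical rotation.
#' @return character vector of labels in \code{LSC}, \code{IRb}, \code{SSC},
#'   \code{IRa}.
#' @export
classifyPosition <- function(partition, pos) {
  L <- partition@genome_length
  if (any(pos < 0 | pos >= L))
    stop("position out of range [0, ", L, ")")
  j <- junctions(partition)
  ifelse(pos < j[["JLB"]], "LSC",
    ifelse(pos < j[["JSB"]], "IRb",
      ifelse(pos < j[["JSA"]], "SSC", "IRa")))
}

gcPercent <- function(seqchar) {
  x <- DNAString(seqchar)
  f <- letterFrequency(x, c("G", "C", "A", "T"))
  denom <- sum(f)
  if (denom == 0) return(NA_real_)
  100 * (f[["G"]] + f[["C"]]) / denom
}

regionSequences <- function(genome, partition) {
  cg <- canonicalizePlastome(genome, partition)
  seq <- as.character(plastomeSeq(cg$genome))
  j <- junctions(cg$partition)
  L <- partition@genome_length
  list(lsc = substring(seq, 1, j[["JLB"]]),
       irb = substring(seq, j[["JLB"]] + 1, j[["JSB"]]),
       ssc = substring(seq, j[["JSB"]] + 1, j[["JSA"]]),
       ira = substring(seq, j[["JSA"]] + 1, L))
}

#' Summarize a plastome (lengths, GC, gene counts)
#'
#' Computes the standard comparative-table statistics: total and per-region
#' lengths, GC content overall and per region (ambiguous bases are excluded
#' from both numerator and denominator), gene counts by category, duplicated
#' gene symbols (present in two or more copies, typically IR duplicates),
#' intron-containing genes (unique symbols with more than one exon) and
#' pseudogene symbols.
#'
#' @param genome an \linkS4class{AnnotatedPlastome}.
#' @param partition matching \linkS4class{RegionPartition}.
#' @return a list of class \code{GenomeSummary} with fields
#'   \code{total_len}, \code{lsc_len}, \code{ssc_len}, \code{ir_len},
#'   \code{gc_total}, \code{gc_lsc}, \code{gc_ssc}, \code{gc_ir},
#'   \code{n_genes}, \code{n_pcg}, \code{n_trna}, \code{n_rrna},
#'   \code{n_duplicated}, \code{n_intron_genes}, \code{pseudo_genes}.
#' @export
summarizeGenome <- function(genome, partition) {
  if (genomeLength(genome) != partition@genome_length)
    stop("partition is inconsistent with genome length")
  rs <- regionSequences(genome, partition)
  ft <- geneFeatures(genome)
  dup <- table(ft$gene)
  n_exons <- vapply(ft$exon_starts, length, integer(1))
  out <- list(
    id = plastomeId(genome),
    total_len = partition@genome_length,
    lsc_len = partition@lsc_len,
    ssc_len = partition@ssc_len,
    ir_len = partition@ir_len,
    gc_total = gcPercent(as.character(plastomeSeq(genome))),
    gc_lsc = gcPercent(rs$lsc),
    gc_ssc = gcPercent(rs$ssc),
    gc_ir = gcPercent(paste0(rs$irb, rs$ira)),
    n_genes = nrow(ft),
    n_pcg = sum(ft$category == "PCG"),
    n_trna = sum(ft$category == "tRNA"),
    n_rrna = sum(ft$category == "rRNA"),
    n_duplicated = sum(dup >= 2),
    n_intron_genes = length(unique(ft$gene[n_exons > 1])),
    pseudo_genes = unique(ft$gene[ft$pseudo]))
  class(out) <- "GenomeSummary"
  out
}

#' @export
print.GenomeSummary <- function(x, ...) {
  cat(sprintf(
    "GenomeSummary %s: %d bp (LSC %d / SSC %d / IR %d)\n", x$id,
    x$total_len, x$lsc_len, x$ssc_len, x$ir_len))
  cat(sprintf("  GC %% total %.2f (LSC %.2f / SSC %.2f / IR %.2f)\n",
              x$gc_total, x$gc_lsc, x$gc_ssc, x$gc_ir))
  cat(sprintf("  genes %d (%d PCG / %d tRNA / %d rRNA), %d duplicated, %d with introns\n",
              x$n_genes, x$n_pcg, x$n_trna, x$n_rrna, x$n_duplicated,
              x$n_intron_genes))
  if (length(x$pseudo_genes))
    cat("  pseudogenes:", paste(x$pseudo_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Write genome summaries as TSV or JSON
#'
#' @param summaries a \code{GenomeSummary} or list of them.
#' @param path output path.
#' @param format \code{"tsv"} (one row per genome) or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
writeGenomeSummary <- function(summaries, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(summaries, "GenomeSummary")) summaries <- list(summaries)
  if (format == "json") {
    write_json(lapply(summaries, unclass), path, auto_unbox = TRUE,
               digits = NA)
    return(invisible(path))
  }
  rows <- lapply(summaries, function(s) {
    s <- unclass(s)
    s$pseudo_genes <- paste(s$pseudo_genes, collapse = ",")
    as.data.frame(s, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  for (col in c("gc_total", "gc_lsc", "gc_ssc", "gc_ir"))
    df[[col]] <- sprintf("%.2f", df[[col]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a region partition as BED
#'
#' Four records (LSC, IRb, SSC, IRa) in 0-based half-open canonical
#' coordinates.
#'
#' @param partition a \linkS4class{RegionPartition}.
#' @param path output path.
#' @param chrom sequence name to use in column 1.
#' @return \code{path}, invisibly.
#' @export
writePartitionBed <- function(partition, path, chrom = "plastome") {
  j <- junctions(partition)
  L <- partition@genome_length
  df <- data.frame(chrom = chrom,
                   start = c(0L, j[["JLB"]], j[["JSB"]], j[["JSA"]]),
                   end = c(j[["JLB"]], j[["JSB"]], j[["JSA"]], L),
                   name = c("LSC", "IRb", "SSC", "IRa"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
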