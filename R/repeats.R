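#' @importFrom Biostrings complement reverse
NULL

.defaultSSRThresholds <- c(10L, 6L, 5L, 4L, 3L, 3L)

asSeqChar <- function(x) {
  if (is(x, "AnnotatedPlastome")) toupper(as.character(plastomeSeq(x)))
  else toupper(as.character(x))
}

#' Find simple sequence repeats (microsatellites)
#'
#' Scans for maximal perfect tandem runs of 1-6 bp motifs, MISA-style.  A
#' run is reported once, with its primitive motif at the leftmost phase;
#' the default thresholds are 10 repeat units for mononucleotides, 6 for
#' di-, 5 for tri-, 4 for tetra- and 3 for penta- and hexanucleotides.
#' Compound/interrupted runs are not merged: each perfect run stands alone.
#'
#' @param x sequence (character/\code{DNAString}) or
#'   \linkS4class{AnnotatedPlastome}.
#' @param thresholds integer vector of length 6: minimum repeat count per
#'   unit length 1..6.
#' @return data.frame with columns \code{start}, \code{end} (0-based
#'   half-open, \code{end - start == unit_len * repeats}), \code{motif},
#'   \code{unit_len}, \code{repeats}, \code{motif_class} (strand-collapsed
#'   canonical class, see [canonicalMotifClass()]).
#' @export
findSSRs <- function(x, thresholds = .defaultSSRThresholds) {
  stopifnot(length(thresholds) == 6, all(thresholds >= 1))
  seq <- asSeqChar(x)
  df <- .cpp_find_ssrs(seq, as.integer(thresholds))
  df$end <- df$start + df$unit_len * df$repeats
  df$motif_class <- vapply(df$motif, canonicalMotifClass, character(1),
                           USE.NAMES = FALSE)
  df[, c("start", "end", "motif", "unit_len", "repeats", "motif_class")]
}

cyclicRotations <- function(m) {
  n <- nchar(m)
  vapply(seq_len(n) - 1L, function(k)
    paste0(substring(m, k + 1L, n), substring(m, 1L, k)), character(1))
}

isPrimitiveMotif <- function(m) {
  n <- nchar(m)
  for (d in seq_len(n - 1)) {
    if (n %% d != 0) next
    if (identical(strrep(substring(m, 1, d), n %/% d), m)) return(FALSE)
  }
  TRUE
}

#' Canonical strand-collapsed motif class
#'
#' Groups SSR motifs that describe the same locus on either strand and in
#' any phase: the class of a motif is \code{"X/Y"} where X is the
#' lexicographically smallest cyclic rotation of the motif, Y the smallest
#' rotation of its reverse complement, and the two are printed in sorted
#' order (so \code{"T"} maps to \code{"A/T"} and \code{"TA"} to
#' \code{"AT/AT"}).
#'
#' @param motif primitive motif of length 1-6.
#' @return the class label.
#' @export
canonicalMotifClass <- function(motif) {
  motif <- toupper(motif)
  if (!isPrimitiveMotif(motif))
    stop("motif '", motif, "' is not primitive")
  x <- min(cyclicRotations(motif))
  rc <- as.character(reverseComplement(DNAString(motif)))
  y <- min(cyclicRotations(rc))
  paste(sort(c(x, y))[1], sort(c(x, y))[2], sep = "/")
}

strandTransforms <- function(seq) {
  d <- DNAString(seq)
  list(F = seq,
       P = as.character(reverseComplement(d)),
       R = as.character(reverse(d)),
       C = as.character(complement(d)))
}

#' Find maximal long repeats (forward / palindromic / reverse / complement)
#'
#' Enumerates all maximal exact repeat pairs of length >= \code{min_len},
#' REPuter-style.  The second copy equals the first copy unchanged (F),
#' reverse-complemented (P), reversed (R) or complemented without reversal
#' (C).  Pairs are maximal (extending either copy by one base breaks the
#' type-specific match), may self-overlap, and are reported with
#' \code{pos1 < pos2}; both copies of P/R pairs are given as forward-strand
#' start coordinates.  A contiguous DNA palindrome (a segment equal to its
#' own reverse complement, or its own reversal for R) matches itself; such
#' hits are reported as their two halves with \code{self_symmetric = TRUE}.
#' When a \linkS4class{RegionPartition} is supplied, the
#' trivial palindromic hit of the full IRa/IRb pair is reported but flagged
#' in the \code{ir_pair} column.
#'
#' @param x sequence or \linkS4class{AnnotatedPlastome} (canonical rotation
#'   when \code{partition} is given).
#' @param min_len minimum repeat length in bp (>= 8; default 30).
#' @param max_reported keep at most this many records, by descending length
#'   (default 5000).
#' @param types subset of \code{c("F","P","R","C")}.
#' @param partition optional \linkS4class{RegionPartition} used only to flag
#'   the IR-vs-IR hit.
#' @return data.frame with columns \code{rtype}, \code{length}, \code{pos1},
#'   \code{pos2} (0-based starts of the two copies),
#'   \code{self_symmetric}, \code{ir_pair}.
#' @export
findLongRepeats <- function(x, min_len = 30L, max_reported = 5000L,
                            types = c("F", "P", "R", "C"),
                            partition = NULL) {
  stopifnot(min_len >= 8)
  seq <- asSeqChar(x)
  n <- nchar(seq)
  tr <- strandTransforms(seq)
  out <- list()
  for (ty in types) {
    mem <- .cpp_find_mems(seq, tr[[ty]], as.integer(min_len),
                          same_string = (ty == "F"))
    if (nrow(mem) == 0) next
    if (ty %in% c("P", "R")) {
      p2 <- n - mem$j - mem$len
      keep <- mem$i != p2
      df <- data.frame(pos1 = pmin(mem$i, p2)[keep],
                       pos2 = pmax(mem$i, p2)[keep],
                       length = mem$len[keep],
                       self_symmetric = rep(FALSE, sum(keep)))
      # a contiguous palindrome matches itself (i == p2); report its two
      # halves as the repeat pair, REPuter-style
      self <- which(!keep)
      if (length(self)) {
        h <- mem$len[self] %/% 2L
        df <- rbind(df, data.frame(
          pos1 = mem$i[self], pos2 = mem$i[self] + mem$len[self] - h,
          length = h, self_symmetric = TRUE))
        df <- df[df$length >= min_len, , drop = FALSE]
      }
    } else {
      keep <- mem$i != mem$j
      df <- data.frame(pos1 = pmin(mem$i, mem$j)[keep],
                       pos2 = pmax(mem$i, mem$j)[keep],
                       length = mem$len[keep],
                       self_symmetric = rep(FALSE, sum(keep)))
    }
    df <- unique(df)
    if (nrow(df)) {
      df$rtype <- ty
      out[[ty]] <- df
    }
  }
  if (!length(out))
    return(data.frame(rtype = character(), length = integer(),
                      pos1 = integer(), pos2 = integer(),
                      self_symmetric = logical(), ir_pair = logical()))
  res <- do.call(rbind, out)
  res <- res[order(-res$length, res$pos1, res$pos2), ]
  res$ir_pair <- FALSE
  if (!is.null(partition)) {
    j <- junctions(partition)
    irb <- c(j[["JLB"]], j[["JSB"]]); ira <- c(j[["JSA"]],
                                               partition@genome_length)
    ov <- function(s, len, reg)
      pmax(0, pmin(s + len, reg[2]) - pmax(s, reg[1])) / len
    res$ir_pair <- res$rtype == "P" &
      ov(res$pos1, res$length, irb) >= 0.9 &
      ov(res$pos2, res$length, ira) >= 0.9
  }
  if (nrow(res) > max_reported) res <- res[seq_len(max_reported), ]
  rownames(res) <- NULL
  res[, c("rtype", "length", "pos1", "pos2", "self_symmetric", "ir_pair")]
}

# does interval [s, e) overlap exon [a, b) on a circle of length L?
circOverlaps <- function(s, e, a, b, L) {
  (s < b & a < e) | (s < b - L & a - L < e) | (s < b + L & a + L < e)
}

#' Classify repeat loci by region and genomic context
#'
#' Context is \code{"gene"} if the interval overlaps any exon,
#' \code{"intron"} if it lies within a gene's span without touching an
#' exon, and \code{"IGS"} otherwise; intervals spanning an exon boundary
#' count as \code{"gene"} (overlap rule).  The quadripartite region is
#' assigned from the interval midpoint.
#'
#' @param start,end integer vectors of 0-based half-open intervals
#'   (canonical rotation).
#' @param genome an \linkS4class{AnnotatedPlastome} in canonical rotation.
#' @param partition matching \linkS4class{RegionPartition}.
#' @return data.frame with columns \code{region} and \code{context}.
#' @export
classifyRepeatLocation <- function(start, end, genome, partition) {
  L <- genomeLength(genome)
  stopifnot(all(start >= 0), all(end > start), all(start < L))
  ft <- geneFeatures(genome)
  spans <- featureSpans(ft)
  ctx <- rep("IGS", length(start))
  for (k in seq_along(start)) {
    in_gene <- FALSE; in_exon <- FALSE
    for (i in seq_len(nrow(ft))) {
      if (circOverlaps(start[k], end[k], spans$start[i], spans$end[i], L)) {
        in_gene <- TRUE
        es <- as.integer(ft$exon_starts[[i]]); ee <- as.integer(ft$exon_ends[[i]])
        if (any(circOverlaps(start[k], end[k], es, ee, L))) in_exon <- TRUE
      }
      if (in_exon) break
    }
    ctx[k] <- if (in_exon) "gene" else if (in_gene) "intron" else "IGS"
  }
  mid <- ((start + end) %/% 2L) %% L
  data.frame(region = classifyPosition(partition, mid), context = ctx)
}

#' Write SSR or long-repeat records as TSV or BED
#'
#' @param records data.frame from [findSSRs()] or [findLongRepeats()].
#' @param path output path.
#' @param format \code{"tsv"} or \code{"bed"} (BED name field encodes
#'   motif/class for SSRs, type/length for long repeats; long-repeat BED
#'   emits one record per copy).
#' @param chrom BED chromosome name.
#' @return \code{path}, invisibly.
#' @export
writeRepeats <- function(records, path, format = c("tsv", "bed"),
                         chrom = "plastome") {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if ("motif" %in% colnames(records)) {
    bed <- data.frame(chrom = chrom, start = records$start,
                      end = records$end,
                      name = paste0("SSR:", records$motif_class, ":x",
                                    records$repeats))
  } else {
    bed <- data.frame(
      chrom = chrom,
      start = c(records$pos1, records$pos2),
      end = c(records$pos1, records$pos2) + rep(records$length, 2),
      name = rep(paste0("LSR:", records$rtype, ":", records$length), 2))
    bed <- bed[order(bed$start), ]
  }
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
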