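#' @importFrom stats quantile
NULL

#' Read a multiple sequence alignment from aligned FASTA
#'
#' Rows are validated to have equal length, case-folded to upper case and U
#' is mapped to T.
#'
#' @param path aligned FASTA file.
#' @return character matrix (taxa x columns) with taxon labels as rownames;
#'   the representation used by all divergence-scan functions.
#' @export
readAlignment <- function(path) {
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("alignment format error: ",
                                          conditionMessage(e)))
  if (length(ss) == 0) stop("alignment format error: empty file ", path)
  if (length(unique(Biostrings::width(ss))) != 1)
    stop("alignment format error: rows have unequal lengths (",
         paste(Biostrings::width(ss), collapse = ", "), ")")
  alignmentMatrix(stats::setNames(chartr("U", "T",
                                         toupper(as.character(ss))),
                                  sub("\\s.*$", "", names(ss))))
}

#' Build an alignment matrix from named sequences
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return character matrix (taxa x columns).
#' @export
alignmentMatrix <- function(seqs) {
  stopifnot(length(seqs) >= 2, length(unique(nchar(seqs))) == 1)
  mat <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  rownames(mat) <- names(seqs)
  mat
}

#' Write an alignment matrix as aligned FASTA
#'
#' @param aln character matrix from [alignmentMatrix()]/[readAlignment()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  ss <- DNAStringSet(apply(aln, 1, paste, collapse = ""))
  writeXStringSet(ss, path)
  invisible(path)
}

# integer encoding: A=1 C=2 G=3 T=4, anything else (N, gaps) = 0 = missing
encodeAlignment <- function(aln) {
  m <- match(aln, c("A", "C", "G", "T"))
  m[is.na(m)] <- 0L
  matrix(m, nrow = nrow(aln), dimnames = dimnames(aln))
}

#' Classify alignment columns
#'
#' Characters outside A/C/G/T are treated as missing.  A column with fewer
#' than two informative characters is \code{excluded}.  Otherwise it is
#' \code{invariant} (one distinct base), \code{parsimony_informative} (at
#' least two bases each carried by at least two sequences),
#' \code{singleton} (exactly one sequence carries a minority base while all
#' others share one base), or \code{other_variable}.
#'
#' @param aln character matrix (taxa x columns).
#' @return factor of length \code{ncol(aln)} with the five levels above.
#' @export
classifySites <- function(aln) {
  enc <- encodeAlignment(aln)
  lv <- c("invariant", "singleton", "parsimony_informative",
          "other_variable", "excluded")
  counts <- vapply(1:4, function(b) colSums(enc == b), numeric(ncol(enc)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  informative <- rowSums(counts)
  n_bases <- rowSums(counts > 0)
  n_ge2 <- rowSums(counts >= 2)
  n_eq1 <- rowSums(counts == 1)
  cls <- rep("other_variable", ncol(enc))
  cls[informative < 2] <- "excluded"
  cls[informative >= 2 & n_bases == 1] <- "invariant"
  cls[informative >= 2 & n_bases >= 2 & n_ge2 >= 2] <- "parsimony_informative"
  cls[informative >= 2 & n_bases == 2 & n_eq1 == 1 &
        cls == "other_variable"] <- "singleton"
  factor(cls, levels = lv)
}

# per-pair cumulative difference and coverage counts; the O(1)-per-window
# backbone for the sliding scan
pairCumstats <- function(enc) {
  n <- nrow(enc); Lc <- ncol(enc)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  cs_diff <- matrix(0, np, Lc + 1L)
  cs_val <- matrix(0, np, Lc + 1L)
  for (p in seq_len(np)) {
    xi <- enc[pairs[1, p], ]; xj <- enc[pairs[2, p], ]
    valid <- xi > 0L & xj > 0L
    diff <- valid & (xi != xj)
    cs_diff[p, ] <- c(0, cumsum(diff))
    cs_val[p, ] <- c(0, cumsum(valid))
  }
  list(diff = cs_diff, valid = cs_val)
}

# mean over pairs of d_ij / L_eff_ij for columns [start, end) (0-based)
piFromCum <- function(cum, start, end) {
  d <- cum$diff[, end + 1L] - cum$diff[, start + 1L]
  l <- cum$valid[, end + 1L] - cum$valid[, start + 1L]
  ok <- l > 0
  if (!any(ok)) return(0)
  mean(d[ok] / l[ok])
}

#' Sliding-window nucleotide diversity
#'
#' For each window, Pi is the average over all sequence pairs of the number
#' of sites at which the two sequences hold different unambiguous bases,
#' divided by the number of sites at which both hold unambiguous bases
#' (pairwise deletion; per-pair effective length).  \code{n_snp} counts the
#' non-excluded variable columns in the window (see [classifySites()]).
#' Windows start every \code{step} columns; after the last full window one
#' terminal partial window is kept iff it covers at least half a window
#' length.  An alignment shorter than one window yields a single
#' whole-length window with a warning.
#'
#' @param aln character matrix (taxa x columns).
#' @param window window length in columns (default 600).
#' @param step step size in columns (default 200).
#' @return data.frame with columns \code{start}, \code{end} (0-based
#'   half-open alignment coordinates), \code{midpoint}, \code{pi},
#'   \code{n_snp}.
#' @export
windowScan <- function(aln, window = 600L, step = 200L) {
  stopifnot(window >= step, step >= 1)
  Lc <- ncol(aln)
  if (Lc < window) {
    warning("alignment (", Lc, " columns) shorter than one window (",
            window, "); returning a single whole-length window")
    starts <- 0L; ends <- Lc
  } else {
    starts <- seq(0L, Lc - window, by = step)
    ends <- starts + window
    nxt <- starts[length(starts)] + step
    if (nxt < Lc && (Lc - nxt) >= window / 2) {
      starts <- c(starts, nxt); ends <- c(ends, Lc)
    }
  }
  enc <- encodeAlignment(aln)
  cum <- pairCumstats(enc)
  cls <- classifySites(aln)
  variable <- cls %in% c("singleton", "parsimony_informative",
                         "other_variable")
  cs_var <- c(0L, cumsum(variable))
  pi <- vapply(seq_along(starts), function(k)
    piFromCum(cum, starts[k], ends[k]), numeric(1))
  n_snp <- cs_var[ends + 1L] - cs_var[starts + 1L]
  data.frame(start = starts, end = ends,
             midpoint = (starts + ends) %/% 2L, pi = pi,
             n_snp = as.integer(n_snp))
}

#' Merge high-diversity windows into hypervariable regions
#'
#' Selects windows whose Pi is at or above the empirical
#' \code{pi_quantile} quantile (ties included) AND whose SNP count exceeds
#' \code{snp_min}, then concatenates maximal runs of selected windows that
#' are adjacent (consecutive window indices) or overlapping into contiguous
#' regions.  Per region, SNP/SVS/PIP counts and the mean Pi are recomputed
#' over the merged column span from the alignment.
#'
#' @param windows data.frame from [windowScan()] on the same alignment.
#' @param aln the alignment matrix the windows were computed from.
#' @param pi_quantile quantile defining "top" windows (default 0.95).
#' @param snp_min windows must have \code{n_snp > snp_min} (default 25).
#' @return data.frame with columns \code{start}, \code{end}, \code{length},
#'   \code{n_snp}, \code{n_svs}, \code{n_pip}, \code{mean_pi}.
#' @export
mergeHypervariable <- function(windows, aln, pi_quantile = 0.95,
                               snp_min = 25L) {
  if (nrow(windows) < 20)
    warning("fewer than 20 windows; the Pi quantile threshold is unstable")
  thr <- quantile(windows$pi, pi_quantile, names = FALSE, type = 7)
  sel <- which(windows$pi >= thr & windows$n_snp > snp_min)
  empty <- data.frame(start = integer(), end = integer(),
                      length = integer(), n_snp = integer(),
                      n_svs = integer(), n_pip = integer(),
                      mean_pi = numeric())
  if (!length(sel)) return(empty)
  # group runs: consecutive selected window indices, or window overlap
  brk <- c(TRUE, diff(sel) > 1 &
             windows$start[sel[-1]] > windows$end[sel[-length(sel)]])
  grp <- cumsum(brk)
  enc <- encodeAlignment(aln)
  cum <- pairCumstats(enc)
  cls <- classifySites(aln)
  out <- lapply(split(sel, grp), function(idx) {
    s <- min(windows$start[idx]); e <- max(windows$end[idx])
    colcls <- cls[(s + 1L):e]
    data.frame(start = s, end = e, length = e - s,
               n_snp = sum(colcls %in% c("singleton",
                                         "parsimony_informative",
                                         "other_variable")),
               n_svs = sum(colcls == "singleton"),
               n_pip = sum(colcls == "parsimony_informative"),
               mean_pi = piFromCum(cum, s, e))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# map alignment columns to ungapped coordinates of a reference row:
# position of a column = number of non-gap reference characters before it
alignmentToRefCoords <- function(aln, ref_row) {
  if (!ref_row %in% rownames(aln))
    stop("reference taxon '", ref_row, "' is not a row of the alignment")
  ref <- aln[ref_row, ]
  cumsum(ref != "-") - as.integer(ref != "-")
}

#' Label hypervariable regions with gene or spacer names
#'
#' Maps region coordinates from the alignment to the ungapped coordinates
#' of a reference row, then labels each region with the gene symbol its
#' midpoint falls in, or, for intergenic midpoints, with the
#' \code{"left-right"} spacer name built from the flanking genes.
#'
#' @param regions data.frame from [mergeHypervariable()].
#' @param reference \linkS4class{AnnotatedPlastome} for the reference taxon.
#' @param aln alignment matrix containing the reference row.
#' @param ref_row taxon label of the reference row.
#' @return \code{regions} with added columns \code{ref_start},
#'   \code{ref_end} (ungapped reference coordinates) and \code{label}.
#' @export
annotateRegions <- function(regions, reference, aln, ref_row) {
  proj <- alignmentToRefCoords(aln, ref_row)
  Lr <- sum(aln[ref_row, ] != "-")
  Lc <- ncol(aln)
  if (nrow(regions) == 0) {
    regions$ref_start <- integer(0); regions$ref_end <- integer(0)
    regions$label <- character(0)
    return(regions)
  }
  regions$ref_start <- proj[pmin(regions$start + 1L, Lc)]
  regions$ref_end <- pmin(proj[regions$end] + 1L, Lr)
  mids <- (regions$ref_start + regions$ref_end) %/% 2L
  regions$label <- vapply(mids, function(m)
    locusLabel(reference, m), character(1))
  regions
}

# gene symbol at position, or "left-right" spacer label
locusLabel <- function(genome, pos) {
  ft <- geneFeatures(genome)
  if (nrow(ft) == 0) return("NA")
  L <- genomeLength(genome)
  spans <- featureSpans(ft)
  inside <- which(circOverlaps(pos, pos + 1L, spans$start, spans$end, L))
  if (length(inside)) return(ft$gene[inside[1]])
  d_left <- (pos - (spans$end %% L)) %% L
  d_right <- ((spans$start %% L) - pos) %% L
  paste0(ft$gene[which.min(d_left)], "-", ft$gene[which.min(d_right)])
}

#' Write window statistics or hypervariable-region tables as TSV
#'
#' @param x data.frame from [windowScan()], [mergeHypervariable()] or
#'   [annotateRegions()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDivergenceTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
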