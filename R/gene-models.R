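#' @importFrom Biostrings getGeneticCode
NULL

# substring on the circle: exon coordinates may exceed L (origin wrap)
circSubstring <- function(seq, start0, end0, L) {
  stopifnot(end0 - start0 <= L)
  ss <- paste0(seq, seq)
  substring(ss, start0 + 1L, end0)
}

splicedSequence <- function(seq, starts, ends, strand, L) {
  parts <- vapply(seq_along(starts), function(k)
    circSubstring(seq, starts[k], ends[k], L), character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-")
    s <- as.character(reverseComplement(DNAString(s)))
  s
}

splitCodons <- function(s) {
  n <- nchar(s) %/% 3L
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Validate protein-coding gene models
#'
#' For every PCG feature, reports the spliced CDS length, length modulo 3,
#' start and stop codon, and the positions (codon index, 1-based) of any
#' internal stop codons.  A gene is flagged as a pseudogene candidate iff
#' its length is not a multiple of 3, or it contains an internal stop, or
#' its start codon is not one of ATG/GTG/ACG.  The deposited \code{/pseudo}
#' flag is merged with this predicate by OR into the \code{pseudo} column.
#' PCGs shorter than 6 bp are marked \code{degenerate} instead of being
#' scored.
#'
#' @param genome an \linkS4class{AnnotatedPlastome}.
#' @param genetic_code NCBI genetic code id (default \code{"11"},
#'   bacterial/plastid).
#' @param start_codons accepted initiator codons.
#' @return a \code{DataFrame} with one row per PCG: \code{gene},
#'   \code{spliced_len}, \code{len_mod3}, \code{start_codon},
#'   \code{stop_codon}, \code{n_internal_stops}, \code{internal_stop_at}
#'   (first internal stop codon index or NA), \code{degenerate},
#'   \code{pseudo_deposited}, \code{pseudo_candidate}, \code{pseudo}.
#' @export
validateGeneModels <- function(genome, genetic_code = "11",
                               start_codons = c("ATG", "GTG", "ACG")) {
  code <- getGeneticCode(genetic_code)
  stops <- names(code)[code == "*"]
  ft <- geneFeatures(genome)
  pcg <- ft[ft$category == "PCG", , drop = FALSE]
  L <- genomeLength(genome)
  seq <- as.character(plastomeSeq(genome))
  n <- nrow(pcg)
  rec <- DataFrame(gene = pcg$gene, spliced_len = integer(n),
                   len_mod3 = integer(n), start_codon = character(n),
                   stop_codon = character(n), n_internal_stops = integer(n),
                   internal_stop_at = NA_integer_, degenerate = logical(n),
                   pseudo_deposited = pcg$pseudo,
                   pseudo_candidate = logical(n), pseudo = logical(n))
  for (i in seq_len(n)) {
    s <- splicedSequence(seq, as.integer(pcg$exon_starts[[i]]),
                         as.integer(pcg$exon_ends[[i]]), pcg$strand[i], L)
    len <- nchar(s)
    rec$spliced_len[i] <- len
    rec$len_mod3[i] <- len %% 3L
    if (len < 6L) {
      rec$degenerate[i] <- TRUE
      warning("degenerate PCG '", pcg$gene[i], "': spliced length ", len,
              " < 6 bp", call. = FALSE)
      rec$pseudo[i] <- rec$pseudo_deposited[i]
      next
    }
    codons <- splitCodons(s)
    rec$start_codon[i] <- codons[1]
    rec$stop_codon[i] <- codons[length(codons)]
    internal <- which(codons[-length(codons)] %in% stops)
    rec$n_internal_stops[i] <- length(internal)
    if (length(internal)) rec$internal_stop_at[i] <- internal[1]
    rec$pseudo_candidate[i] <- (rec$len_mod3[i] != 0L) ||
      length(internal) > 0L || !(codons[1] %in% start_codons)
    rec$pseudo[i] <- rec$pseudo_deposited[i] || rec$pseudo_candidate[i]
  }
  rec
}

#' Extract spliced coding sequences
#'
#' Joins exons in genomic order (reverse-complementing minus-strand genes)
#' for every PCG feature.  Features whose merged pseudogene flag (deposited
#' OR validation predicate, see [validateGeneModels()]) is set are excluded,
#' as are sequences whose length is not a multiple of 3; exclusions are
#' reported via \code{message()} and returned in the \code{"excluded"}
#' attribute.
#'
#' @param genome an \linkS4class{AnnotatedPlastome}.
#' @param exclude_pseudo drop pseudogene-flagged features (default TRUE).
#' @param genetic_code NCBI genetic code id used for validation.
#' @return named character vector of CDS sequences (names are gene symbols;
#'   IR-duplicated genes contribute one entry per copy, suffixed
#'   \code{.1}, \code{.2}, ... after the first).
#' @export
extractCDS <- function(genome, exclude_pseudo = TRUE, genetic_code = "11") {
  ft <- geneFeatures(genome)
  pcg_idx <- which(ft$category == "PCG")
  if (!length(pcg_idx))
    return(structure(character(0), excluded = character(0)))
  val <- validateGeneModels(genome, genetic_code)
  L <- genomeLength(genome)
  seq <- as.character(plastomeSeq(genome))
  out <- character(0); excluded <- character(0)
  for (k in seq_along(pcg_idx)) {
    i <- pcg_idx[k]
    if (exclude_pseudo && val$pseudo[k]) {
      excluded <- c(excluded, paste0(ft$gene[i], " (pseudogene flag)"))
      next
    }
    s <- splicedSequence(seq, as.integer(ft$exon_starts[[i]]),
                         as.integer(ft$exon_ends[[i]]), ft$strand[i], L)
    if (nchar(s) %% 3L != 0L) {
      excluded <- c(excluded, paste0(ft$gene[i], " (length not multiple of 3)"))
      next
    }
    out <- c(out, stats::setNames(s, ft$gene[i]))
  }
  if (length(excluded))
    message("extractCDS: excluded ", length(excluded), " feature(s): ",
            paste(excluded, collapse = "; "))
  # disambiguate duplicate symbols (IR copies)
  dup <- ave(seq_along(out), names(out), FUN = seq_along)
  names(out) <- ifelse(dup > 1, paste0(names(out), ".", dup), names(out))
  attr(out, "excluded") <- excluded
  out
}
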