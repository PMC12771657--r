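#' @importFrom stats setNames ave
NULL

allCodons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

codonFamilies <- function(genetic_code = "11") {
  code <- getGeneticCode(genetic_code)
  sense <- code[code != "*"]
  split(names(sense), unname(sense))
}

dnaToRna <- function(x) chartr("T", "U", x)

#' Count codons across a set of coding sequences
#'
#' Codons are read in frame 0.  Codons containing ambiguous bases are
#' skipped and counted separately; a terminal stop codon is tallied apart
#' from the sense counts.
#'
#' @param cds_list named character vector (or list) of in-frame coding
#'   sequences, e.g. from [extractCDS()].
#' @param genetic_code NCBI genetic code id.
#' @return an object of class \code{CodonCountTable}: list with
#'   \code{counts} (named integer over the 64 codons, sense occurrences
#'   only), \code{stop_counts} (terminal stops by codon),
#'   \code{aa_totals} (named integer per amino acid),
#'   \code{n_ambiguous_skipped}, \code{n_cds}, \code{n_codons_total}.
#' @export
countCodons <- function(cds_list, genetic_code = "11") {
  cds_list <- unlist(as.list(cds_list))
  code <- getGeneticCode(genetic_code)
  stops <- names(code)[code == "*"]
  counts <- setNames(integer(64), allCodons())
  stop_counts <- setNames(integer(length(stops)), stops)
  n_amb <- 0L
  for (g in seq_along(cds_list)) {
    s <- toupper(cds_list[[g]])
    if (nchar(s) %% 3L != 0L)
      stop("out-of-frame CDS for gene '",
           if (!is.null(names(cds_list))) names(cds_list)[g] else g,
           "': length ", nchar(s), " is not a multiple of 3")
    codons <- splitCodons(s)
    known <- codons %in% names(counts)
    n_amb <- n_amb + sum(!known)
    codons <- codons[known]
    if (!length(codons)) next
    last <- codons[length(codons)]
    if (last %in% stops) {
      stop_counts[last] <- stop_counts[last] + 1L
      codons <- codons[-length(codons)]
    }
    t <- table(codons)
    counts[names(t)] <- counts[names(t)] + as.integer(t)
  }
  aa <- code[names(counts)]
  aa_totals <- tapply(counts[aa != "*"], aa[aa != "*"], sum)
  out <- list(counts = counts, stop_counts = stop_counts,
              aa_totals = setNames(as.integer(aa_totals), names(aa_totals)),
              n_ambiguous_skipped = n_amb, n_cds = length(cds_list),
              n_codons_total = sum(counts) + sum(stop_counts),
              genetic_code = genetic_code)
  class(out) <- "CodonCountTable"
  out
}

#' Relative synonymous codon usage
#'
#' For each sense codon c in an amino-acid family of size k,
#' \eqn{RSCU(c) = k \cdot n_c / \sum_{c'} n_{c'}} where the sum runs over
#' the family.  RSCU is computed over the 61 sense codons; stop codons are
#' reported separately by [countCodons()].  Families with zero total yield
#' RSCU 0 for all members and are flagged.
#'
#' @param counts a \code{CodonCountTable}.
#' @return object of class \code{RSCUTable}: list with \code{rscu} (named
#'   numeric over sense codons, DNA alphabet), \code{zero_families}
#'   (character vector of unobserved amino acids) and \code{genetic_code}.
#' @export
computeRSCU <- function(counts) {
  stopifnot(inherits(counts, "CodonCountTable"))
  fam <- codonFamilies(counts$genetic_code)
  rscu <- setNames(numeric(0), character(0))
  zero <- character(0)
  for (aa in names(fam)) {
    cods <- fam[[aa]]
    tot <- sum(counts$counts[cods])
    if (tot == 0) {
      rscu[cods] <- 0
      zero <- c(zero, aa)
    } else {
      rscu[cods] <- counts$counts[cods] * length(cods) / tot
    }
  }
  rscu <- rscu[sort(names(rscu))]
  out <- list(rscu = rscu, zero_families = zero,
              genetic_code = counts$genetic_code)
  class(out) <- "RSCUTable"
  out
}

#' Codon-usage bias summary across genomes
#'
#' Averages RSCU per codon across a set of per-genome tables and
#' cross-tabulates codons with mean RSCU above 1 (preferred) versus at or
#' below 1 against the third-base class (A/U-ending vs G/C-ending), the
#' standard summary of chloroplast codon bias.
#'
#' @param rscu_tables list of \code{RSCUTable} objects (length >= 1).
#' @return list with \code{mean_rscu} (data.frame: codon in RNA alphabet,
#'   amino acid, mean RSCU, third-base class), \code{n_gt1},
#'   \code{n_gt1_AU}, \code{n_gt1_GC}, \code{n_le1}, \code{n_le1_AU},
#'   \code{n_le1_GC}.
#' @export
rscuBiasSummary <- function(rscu_tables) {
  if (inherits(rscu_tables, "RSCUTable")) rscu_tables <- list(rscu_tables)
  stopifnot(length(rscu_tables) >= 1)
  mat <- vapply(rscu_tables, function(t) t$rscu, rscu_tables[[1]]$rscu)
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
  m <- rowMeans(mat)
  code <- getGeneticCode(rscu_tables[[1]]$genetic_code)
  third <- substring(names(m), 3, 3)
  cls <- ifelse(third %in% c("A", "T"), "A/U", "G/C")
  gt1 <- m > 1
  df <- data.frame(codon = dnaToRna(names(m)), aa = unname(code[names(m)]),
                   mean_rscu = unname(m), third_base_class = cls,
                   stringsAsFactors = FALSE)
  df <- df[order(df$aa, df$codon), ]
  rownames(df) <- NULL
  list(mean_rscu = df,
       n_gt1 = sum(gt1), n_gt1_AU = sum(gt1 & cls == "A/U"),
       n_gt1_GC = sum(gt1 & cls == "G/C"),
       n_le1 = sum(!gt1), n_le1_AU = sum(!gt1 & cls == "A/U"),
       n_le1_GC = sum(!gt1 & cls == "G/C"))
}

#' Write per-genome codon counts and RSCU as TSV
#'
#' @param counts a \code{CodonCountTable}.
#' @param rscu matching \code{RSCUTable}.
#' @param path output path.
#' @return \code{path}, invisibly.  Codons are reported in the RNA alphabet.
#' @export
writeCodonUsage <- function(counts, rscu, path) {
  code <- getGeneticCode(counts$genetic_code)
  cods <- names(rscu$rscu)
  df <- data.frame(codon = dnaToRna(cods), aa = unname(code[cods]),
                   count = unname(counts$counts[cods]),
                   rscu = unname(rscu$rscu[cods]))
  df <- df[order(df$aa, df$codon), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a codon x genome mean-RSCU matrix as TSV
#'
#' @param rscu_tables named list of \code{RSCUTable} objects (names are
#'   genome labels).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRSCUMatrix <- function(rscu_tables, path) {
  mat <- vapply(rscu_tables, function(t) t$rscu, rscu_tables[[1]]$rscu)
  df <- data.frame(codon = dnaToRna(rownames(mat)), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
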