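#' @importFrom Biostrings pairwiseAlignment translate AAString pattern subject score
#' @importFrom utils combn data
NULL

.ngCache <- new.env(parent = emptyenv())

permutationsOf <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in permutationsOf(k - 1L)) {
      v <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, v[rest])
    }
  }
  out
}

# Precomputed NG86 machinery for one genetic code:
#  - syn_sites[codon]: sum over the 3 positions of the fraction of
#    synonymous changes among the non-stop single-base changes
#  - sd[a, b], nd[a, b]: synonymous/nonsynonymous differences between two
#    sense codons, averaged over all minimal substitution pathways after
#    excluding (and renormalizing away) pathways through stop codons
ngTables <- function(genetic_code = "11") {
  key <- paste0("code", genetic_code)
  if (!is.null(.ngCache[[key]])) return(.ngCache[[key]])
  code <- getGeneticCode(genetic_code)
  cods <- allCodons()
  aa <- code[cods]
  bases <- c("A", "C", "G", "T")
  nc <- length(cods)
  syn_sites <- setNames(numeric(nc), cods)
  for (c1 in cods) {
    if (aa[c1] == "*") { syn_sites[c1] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      alts <- vapply(setdiff(bases, substring(c1, pos, pos)), function(b) {
        x <- c1; substring(x, pos, pos) <- b; x
      }, character(1))
      alts <- alts[aa[alts] != "*"]
      if (length(alts)) s <- s + sum(aa[alts] == aa[c1]) / length(alts)
    }
    syn_sites[c1] <- s
  }
  sd <- matrix(NA_real_, nc, nc, dimnames = list(cods, cods))
  nd <- sd
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      a <- cods[i]; b <- cods[j]
      if (aa[a] == "*" || aa[b] == "*") next
      dpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      k <- length(dpos)
      if (k == 0) { sd[i, j] <- 0; nd[i, j] <- 0; next }
      paths <- permutationsOf(k)
      acc <- matrix(NA_real_, length(paths), 2)
      for (p in seq_along(paths)) {
        cur <- a; s_steps <- 0; n_steps <- 0; valid <- TRUE
        for (pos in dpos[paths[[p]]]) {
          nxt <- cur
          substring(nxt, pos, pos) <- substring(b, pos, pos)
          if (aa[nxt] == "*") { valid <- FALSE; break }
          if (aa[nxt] == aa[cur]) s_steps <- s_steps + 1
          else n_steps <- n_steps + 1
          cur <- nxt
        }
        if (valid) acc[p, ] <- c(s_steps, n_steps)
      }
      ok <- !is.na(acc[, 1])
      if (!any(ok)) {
        # no stop-free pathway (does not occur for sense pairs under the
        # standard/plastid code, kept as a safeguard): use all pathways,
        # counting steps into stops as nonsynonymous
        acc2 <- t(vapply(paths, function(pp) {
          cur <- a; s_steps <- 0; n_steps <- 0
          for (pos in dpos[pp]) {
            nxt <- cur
            substring(nxt, pos, pos) <- substring(b, pos, pos)
            if (aa[nxt] != "*" && aa[nxt] == aa[cur]) s_steps <- s_steps + 1
            else n_steps <- n_steps + 1
            cur <- nxt
          }
          c(s_steps, n_steps)
        }, numeric(2)))
        sd[i, j] <- mean(acc2[, 1]); nd[i, j] <- mean(acc2[, 2])
      } else {
        sd[i, j] <- mean(acc[ok, 1]); nd[i, j] <- mean(acc[ok, 2])
      }
    }
  }
  res <- list(codons = cods, aa = aa, syn_sites = syn_sites, sd = sd,
              nd = nd)
  .ngCache[[key]] <- res
  res
}

jukesCantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' NG86 Ka/Ks for an aligned codon pair
#'
#' Nei-Gojobori (1986) counting with Jukes-Cantor correction.  Synonymous
#' and nonsynonymous site counts per codon come from single-mutation
#' neighborhoods with mutations to stop codons excluded from the
#' opportunity, averaged between the two sequences.  Differences per codon
#' are partitioned by averaging over all minimal substitution pathways,
#' excluding pathways through stop codons.  Proportions are corrected by
#' \eqn{d = -3/4 \log(1 - 4p/3)}; a proportion at or above 3/4 yields an
#' undefined (NA) rate.  \eqn{\omega = Ka/Ks} is defined iff \eqn{Ks > 0};
#' a pair with \eqn{Ka > 0} and \eqn{Ks = 0} is flagged rather than
#' reported as infinite.
#'
#' @param codons_a,codons_b equal-length character vectors of aligned sense
#'   codons (no gaps, no ambiguity), e.g. from [codonAlignPair()].
#' @param genetic_code NCBI genetic code id.
#' @return list with \code{ka}, \code{ks}, \code{omega}, \code{omega_flag}
#'   (\code{"ok"}, \code{"undefined_ks0"}, \code{"undefined_ks0_ka_pos"} or
#'   \code{"saturated"}), site counts \code{S}, \code{N}, difference counts
#'   \code{Sd}, \code{Nd}, and \code{n_codons}.
#' @export
ng86 <- function(codons_a, codons_b, genetic_code = "11") {
  stopifnot(length(codons_a) == length(codons_b), length(codons_a) >= 1)
  tb <- ngTables(genetic_code)
  ia <- match(codons_a, tb$codons)
  ib <- match(codons_b, tb$codons)
  if (anyNA(ia) || anyNA(ib))
    stop("non-ACGT codon in input; drop ambiguous columns first")
  if (any(tb$aa[ia] == "*") || any(tb$aa[ib] == "*"))
    stop("stop codon inside aligned codon sequence")
  n_cod <- length(ia)
  S <- (sum(tb$syn_sites[ia]) + sum(tb$syn_sites[ib])) / 2
  N <- 3 * n_cod - S
  Sd <- sum(tb$sd[cbind(ia, ib)])
  Nd <- sum(tb$nd[cbind(ia, ib)])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- jukesCantor(ps)
  ka <- jukesCantor(pn)
  if (is.na(ka) || is.na(ks)) {
    omega <- NA_real_; flag <- "saturated"
  } else if (ks > 0) {
    omega <- ka / ks; flag <- "ok"
  } else {
    omega <- NA_real_
    flag <- if (ka > 0) "undefined_ks0_ka_pos" else "undefined_ks0"
  }
  list(ka = ka, ks = ks, omega = omega, omega_flag = flag, S = S, N = N,
       Sd = Sd, Nd = Nd, n_codons = n_cod)
}

#' Codon-aware pairwise alignment of two coding sequences
#'
#' Globally aligns the translated proteins (BLOSUM62, affine gaps) with
#' \code{\link[Biostrings]{pairwiseAlignment}} and back-translates the
#' alignment so that gaps occur only in multiples of 3.  Codon columns
#' containing a gap or an ambiguous base are dropped from downstream
#' counting.  Terminal stop codons are removed before alignment; internal
#' stops violate the precondition and raise an error.
#'
#' @param seq_a,seq_b in-frame coding sequences (character).
#' @param genetic_code NCBI genetic code id.
#' @param gap_opening,gap_extension affine gap penalties for the protein
#'   alignment.
#' @return list with \code{codons_a}, \code{codons_b} (retained aligned
#'   codon columns), \code{n_dropped} (gapped/ambiguous columns removed)
#'   and \code{protein_score}.
#' @export
codonAlignPair <- function(seq_a, seq_b, genetic_code = "11",
                           gap_opening = 10, gap_extension = 0.5) {
  code <- getGeneticCode(genetic_code)
  stops <- names(code)[code == "*"]
  prep <- function(s, who) {
    s <- toupper(s)
    if (nchar(s) %% 3L != 0L)
      stop("sequence ", who, " length is not a multiple of 3")
    cod <- splitCodons(s)
    if (cod[length(cod)] %in% stops) cod <- cod[-length(cod)]
    known <- cod %in% names(code)
    if (any(code[cod[known]] == "*"))
      stop("internal stop codon in sequence ", who)
    cod
  }
  ca <- prep(seq_a, "a"); cb <- prep(seq_b, "b")
  pa <- paste(ifelse(ca %in% names(code), unname(code[ca]), "X"),
              collapse = "")
  pb <- paste(ifelse(cb %in% names(code), unname(code[cb]), "X"),
              collapse = "")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- pairwiseAlignment(AAString(pa), AAString(pb), type = "global",
                           substitutionMatrix = get("BLOSUM62"),
                           gapOpening = gap_opening,
                           gapExtension = gap_extension)
  sa <- strsplit(as.character(pattern(aln)), "")[[1]]
  sb <- strsplit(as.character(subject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  keep_a <- character(0); keep_b <- character(0); dropped <- 0L
  for (k in seq_along(sa)) {
    ga <- sa[k] == "-"; gb <- sb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (ga || gb) { dropped <- dropped + 1L; next }
    coda <- ca[ia]; codb <- cb[ib]
    if (grepl("[^ACGT]", coda) || grepl("[^ACGT]", codb)) {
      dropped <- dropped + 1L; next
    }
    keep_a <- c(keep_a, coda); keep_b <- c(keep_b, codb)
  }
  if (!length(keep_a))
    stop("degenerate pair: no codon columns left after filtering")
  list(codons_a = keep_a, codons_b = keep_b, n_dropped = dropped,
       protein_score = score(aln))
}

#' Protein-coding genes shared by a set of genomes
#'
#' Intersects the PCG symbol sets of the input genomes after case
#' normalization.  Pseudogene-flagged copies (deposited flag OR validation
#' predicate) are excluded; IR-duplicated genes are collapsed to one
#' representative per genome (the copy with fewer validation flags, ties
#' broken by leftmost position).
#'
#' @param genomes list of \linkS4class{AnnotatedPlastome} objects (>= 2).
#' @param genetic_code NCBI genetic code id.
#' @return object of class \code{SharedGeneSet}: list with \code{genes}
#'   (sorted symbols present everywhere) and \code{seqs} (per gene, a named
#'   character vector of one CDS per genome).  An empty intersection
#'   triggers a warning and an empty set.
#' @export
sharedPCGs <- function(genomes, genetic_code = "11") {
  stopifnot(length(genomes) >= 2)
  per_genome <- lapply(genomes, function(g) {
    ft <- geneFeatures(g)
    idx <- which(ft$category == "PCG")
    if (!length(idx)) return(character(0))
    val <- validateGeneModels(g, genetic_code)
    flags <- val$len_mod3 != 0 | val$n_internal_stops > 0 | val$degenerate
    keep <- !val$pseudo
    sym <- tolower(ft$gene[idx])
    starts <- vapply(ft$exon_starts[idx], min, integer(1))
    chosen <- integer(0)
    for (s in unique(sym[keep])) {
      cand <- which(sym == s & keep)
      cand <- cand[order(flags[cand], starts[cand])]
      chosen <- c(chosen, cand[1])
    }
    L <- genomeLength(g)
    seq <- as.character(plastomeSeq(g))
    cds <- vapply(chosen, function(k) {
      i <- idx[k]
      splicedSequence(seq, as.integer(ft$exon_starts[[i]]),
                      as.integer(ft$exon_ends[[i]]), ft$strand[i], L)
    }, character(1))
    setNames(cds, sym[chosen])
  })
  ids <- vapply(genomes, plastomeId, character(1))
  names(per_genome) <- ids
  shared <- Reduce(intersect, lapply(per_genome, names))
  if (!length(shared))
    warning("no protein-coding genes shared by all genomes")
  shared <- sort(shared)
  seqs <- lapply(shared, function(g)
    vapply(per_genome, function(pg) pg[[g]], character(1)))
  names(seqs) <- shared
  out <- list(genes = shared, seqs = seqs, taxa = ids)
  class(out) <- "SharedGeneSet"
  out
}

#' Pairwise Ka/Ks records for a shared gene set
#'
#' Runs [codonAlignPair()] and [ng86()] for every shared gene over every
#' unordered pair of taxa.
#'
#' @param shared a \code{SharedGeneSet} from [sharedPCGs()].
#' @param genetic_code NCBI genetic code id.
#' @return data.frame with columns \code{gene}, \code{taxon_a},
#'   \code{taxon_b}, \code{ka}, \code{ks}, \code{omega}, \code{omega_flag},
#'   \code{n_codons}.
#' @export
kaksPairwise <- function(shared, genetic_code = "11") {
  stopifnot(inherits(shared, "SharedGeneSet"))
  taxa <- shared$taxa
  prs <- combn(length(taxa), 2)
  rows <- list()
  for (g in shared$genes) {
    sq <- shared$seqs[[g]]
    for (p in seq_len(ncol(prs))) {
      a <- taxa[prs[1, p]]; b <- taxa[prs[2, p]]
      rec <- tryCatch({
        al <- codonAlignPair(sq[[a]], sq[[b]], genetic_code)
        ng86(al$codons_a, al$codons_b, genetic_code)
      }, error = function(e) NULL)
      if (is.null(rec)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, taxon_a = a, taxon_b = b, ka = rec$ka, ks = rec$ks,
        omega = rec$omega, omega_flag = rec$omega_flag,
        n_codons = rec$n_codons)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(), taxon_a = character(),
                      taxon_b = character(), ka = numeric(), ks = numeric(),
                      omega = numeric(), omega_flag = character(),
                      n_codons = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene x taxon mean-omega matrix
#'
#' \code{cell(gene, taxon)} is the mean of the defined \eqn{\omega} values
#' over all pairs involving that taxon for that gene; undefined
#' \eqn{\omega} (Ks = 0 or saturation) is excluded from the mean, and cells
#' with no defined value are NA.
#'
#' @param records data.frame from [kaksPairwise()].
#' @return numeric matrix (genes x taxa).
#' @export
omegaMatrix <- function(records) {
  genes <- sort(unique(records$gene))
  taxa <- sort(unique(c(records$taxon_a, records$taxon_b)))
  m <- matrix(NA_real_, length(genes), length(taxa),
              dimnames = list(genes, taxa))
  def <- records[!is.na(records$omega), , drop = FALSE]
  for (gi in seq_along(genes)) {
    sub <- def[def$gene == genes[gi], , drop = FALSE]
    for (ti in seq_along(taxa)) {
      vals <- sub$omega[sub$taxon_a == taxa[ti] | sub$taxon_b == taxa[ti]]
      if (length(vals)) m[gi, ti] <- mean(vals)
    }
  }
  m
}

#' Write pairwise Ka/Ks records or the mean-omega matrix as TSV
#'
#' @param x data.frame from [kaksPairwise()] or matrix from
#'   [omegaMatrix()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeKaKs <- function(x, path) {
  if (is.matrix(x))
    x <- data.frame(gene = rownames(x), x, check.names = FALSE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
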