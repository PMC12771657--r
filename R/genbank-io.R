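#' @importFrom Biostrings readDNAStringSet writeXStringSet
NULL

# ---- location strings -------------------------------------------------------

# Parse a GenBank location string into exon intervals (0-based half-open,
# unwrapped across the origin) and a strand.  Supports n, a..b, join(...),
# order(...), complement(...) and complement() nested inside join().
parseLocation <- function(loc, genome_len, feature = "?") {
  loc <- gsub("[[:space:]<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  starts <- integer(0); ends <- integer(0)
  for (p in parts) {
    if (grepl("^complement\\(", p)) {
      strand <- "-"
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      ab <- rep(as.integer(p), 2)
    } else {
      stop("malformed location for feature '", feature, "': ", p)
    }
    if (any(is.na(ab)) || ab[2] < ab[1] || ab[1] < 1)
      stop("malformed location for feature '", feature, "': ", p)
    starts <- c(starts, ab[1] - 1L); ends <- c(ends, ab[2])
  }
  # unwrap exons that continue past the circular origin
  if (length(starts) > 1) {
    for (k in 2:length(starts)) {
      while (starts[k] < starts[k - 1]) {
        starts[k] <- starts[k] + genome_len
        ends[k] <- ends[k] + genome_len
      }
    }
    # re-merge segments that are contiguous after unwrapping (an exon
    # split in two only because it crosses the origin)
    keep <- c(TRUE, starts[-1] != ends[-length(ends)])
    grp <- cumsum(keep)
    starts <- as.integer(tapply(starts, grp, min))
    ends <- as.integer(tapply(ends, grp, max))
  }
  list(starts = starts, ends = ends, strand = strand)
}

# Format exon intervals back into a GenBank location string (1-based
# inclusive), re-wrapping intervals that extend past the origin.
formatLocation <- function(starts, ends, strand, genome_len) {
  segs <- character(0)
  for (k in seq_along(starts)) {
    s <- starts[k] %% genome_len
    e <- ends[k] - (starts[k] - s)
    if (e <= genome_len) {
      segs <- c(segs, paste0(s + 1L, "..", e))
    } else {  # wraps the origin: split in two
      segs <- c(segs, paste0(s + 1L, "..", genome_len),
                paste0(1L, "..", e - genome_len))
    }
  }
  loc <- if (length(segs) > 1) paste0("join(", paste(segs, collapse = ","), ")")
         else segs
  if (strand == "-") loc <- paste0("complement(", loc, ")")
  loc
}

# ---- reading ----------------------------------------------------------------

#' Read an annotated plastome from a GenBank flat file
#'
#' Parses a single (circular) GenBank record.  Gene models are taken from the
#' typed \code{CDS}, \code{tRNA} and \code{rRNA} features (CDS features
#' become category \code{"PCG"}); \code{gene} features that have no typed
#' counterpart (typically deposited pseudogenes) are kept as PCG features.
#' \code{/pseudo} and \code{/pseudogene} qualifiers are honored on either
#' record.  Compound (\code{join}) locations become multi-exon features, and
#' locations that continue past the circular origin are stored unwrapped
#' (end coordinates beyond the genome length).
#'
#' @param path path to a GenBank flat file with one record.
#' @return an \linkS4class{AnnotatedPlastome}.
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  toks <- strsplit(trimws(lines[locus[1]]), "[[:space:]]+")[[1]]
  id <- if (length(toks) >= 2) toks[2] else basename(path)

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank parse error: no ORIGIN sequence block")
  end <- grep("^//", lines)
  end <- if (length(end)) end[1] else length(lines) + 1L
  seqlines <- lines[(ori[1] + 1L):(end - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (!nzchar(seq)) stop("GenBank parse error: empty sequence after ORIGIN")
  L <- nchar(seq)

  featstart <- grep("^FEATURES", lines)
  if (!length(featstart)) stop("GenBank parse error: no FEATURES table")
  flines <- lines[(featstart[1] + 1L):(ori[1] - 1L)]

  # split the feature table into (key, text) blocks
  keys <- character(0); texts <- character(0)
  cur_key <- NULL; cur_txt <- NULL
  for (ln in flines) {
    if (grepl("^ {5}\\S", ln)) {
      if (!is.null(cur_key)) { keys <- c(keys, cur_key)
                               texts <- c(texts, paste(cur_txt, collapse = "\n")) }
      m <- regmatches(ln, regexec("^ {5}(\\S+)\\s+(.*)$", ln))[[1]]
      cur_key <- m[2]; cur_txt <- m[3]
    } else if (!is.null(cur_key) && grepl("^ +\\S", ln)) {
      cur_txt <- c(cur_txt, trimws(ln))
    }
  }
  if (!is.null(cur_key)) { keys <- c(keys, cur_key)
                           texts <- c(texts, paste(cur_txt, collapse = "\n")) }

  wanted <- keys %in% c("gene", "CDS", "tRNA", "rRNA")
  keys <- keys[wanted]; texts <- texts[wanted]
  if (!length(keys)) stop("GenBank parse error: record has no gene features")

  recs <- vector("list", length(keys))
  for (k in seq_along(keys)) {
    txt <- strsplit(texts[k], "\n", fixed = TRUE)[[1]]
    qual_at <- grep("^/", txt)
    loc <- paste(txt[seq_len(if (length(qual_at)) qual_at[1] - 1L
                             else length(txt))], collapse = "")
    quals <- txt[qual_at]
    gene <- sub('^/gene="?([^"]*)"?$', "\\1",
                grep("^/gene=", quals, value = TRUE))
    gene <- if (length(gene)) gene[1] else NA_character_
    pseudo <- any(grepl("^/pseudo", quals))
    pl <- parseLocation(loc, L, feature = if (is.na(gene)) keys[k] else gene)
    recs[[k]] <- list(key = keys[k], gene = gene, pseudo = pseudo,
                      starts = pl$starts, ends = pl$ends, strand = pl$strand)
  }

  typed <- recs[keys != "gene"]
  genes <- recs[keys == "gene"]
  # merge /pseudo from gene records onto overlapping typed records of the
  # same symbol; keep unmatched gene records as PCG features
  spanOf <- function(r) c(min(r$starts), max(r$ends))
  used <- logical(length(genes))
  for (tr in seq_along(typed)) {
    ts <- spanOf(typed[[tr]])
    for (g in seq_along(genes)) {
      if (used[g]) next
      if (identical(genes[[g]]$gene, typed[[tr]]$gene)) {
        gs <- spanOf(genes[[g]])
        if (gs[1] < ts[2] && ts[1] < gs[2]) {
          typed[[tr]]$pseudo <- typed[[tr]]$pseudo || genes[[g]]$pseudo
          used[g] <- TRUE
          break
        }
      }
    }
  }
  keep <- c(typed, genes[!used])
  cat_of <- function(key) switch(key, CDS = "PCG", tRNA = "tRNA",
                                 rRNA = "rRNA", gene = "PCG")
  ft <- newFeatureTable(
    gene = vapply(keep, function(r)
      if (is.na(r$gene)) "unknown" else r$gene, character(1)),
    category = vapply(keep, function(r) cat_of(r$key), character(1)),
    strand = vapply(keep, function(r) r$strand, character(1)),
    pseudo = vapply(keep, function(r) r$pseudo, logical(1)),
    exon_starts = lapply(keep, function(r) r$starts),
    exon_ends = lapply(keep, function(r) r$ends))
  AnnotatedPlastome(id = id, sequence = seq, features = ft, source = path)
}

#' Read a plastome from a FASTA file (sequence only)
#'
#' @param path FASTA file with a single sequence.
#' @return an \linkS4class{AnnotatedPlastome} with an empty feature table.
#' @export
readPlastomeFasta <- function(path) {
  ss <- readDNAStringSet(path)
  if (length(ss) < 1) stop("FASTA file contains no sequence: ", path)
  AnnotatedPlastome(id = sub("\\s.*$", "", names(ss)[1]),
                    sequence = ss[[1]], source = path)
}

# ---- writing ----------------------------------------------------------------

#' Write an annotated plastome as a GenBank flat file
#'
#' Emits one circular record.  Each feature is written as a \code{gene}
#' record plus its typed record (\code{CDS}/\code{tRNA}/\code{rRNA}), with
#' \code{/pseudo} on both when flagged, so that [readGenBank()] round-trips
#' the feature table exactly.
#'
#' @param genome an \linkS4class{AnnotatedPlastome}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenBank <- function(genome, path) {
  L <- genomeLength(genome)
  seq <- as.character(plastomeSeq(genome))
  con <- file(path, "w"); on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl(sprintf("LOCUS       %-16s %d bp    DNA     circular PLN 01-JAN-2026",
             plastomeId(genome), L))
  wl("DEFINITION  ", plastomeId(genome), " chloroplast, complete genome.")
  wl("FEATURES             Location/Qualifiers")
  wl(sprintf("     source          1..%d", L))
  wl(sprintf('                     /organism="%s"', plastomeId(genome)))
  ft <- geneFeatures(genome)
  key_of <- function(cat) switch(cat, PCG = "CDS", cat)
  for (i in seq_len(nrow(ft))) {
    loc <- formatLocation(as.integer(ft$exon_starts[[i]]),
                          as.integer(ft$exon_ends[[i]]), ft$strand[i], L)
    for (key in c("gene", key_of(ft$category[i]))) {
      wl(sprintf("     %-15s %s", key, loc))
      wl(sprintf('                     /gene="%s"', ft$gene[i]))
      if (ft$pseudo[i]) wl("                     /pseudo")
      if (key == "CDS") wl("                     /transl_table=11")
    }
  }
  wl("ORIGIN")
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    starts <- seq(p, min(p + 59L, L), by = 10L)
    chunk <- substring(seq, starts, pmin(starts + 9L, L))
    wl(sprintf("%9d %s", p, tolower(paste(chunk, collapse = " "))))
  }
  wl("//")
  invisible(path)
}

#' Write a plastome sequence as FASTA
#'
#' @param genome an \linkS4class{AnnotatedPlastome}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePlastomeFasta <- function(genome, path) {
  ss <- DNAStringSet(plastomeSeq(genome))
  names(ss) <- plastomeId(genome)
  writeXStringSet(ss, path)
  invisible(path)
}
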