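#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges IntegerList
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

#' Annotated plastid genome
#'
#' Container for one circular plastid genome: the sequence, a typed feature
#' table (protein-coding genes, tRNAs, rRNAs) and a record of where it came
#' from.  All coordinates are 0-based half-open; exons of features that
#' straddle the circular origin are stored unwrapped, i.e. with end
#' coordinates that may exceed the genome length.
#'
#' The feature table is a \code{\link[S4Vectors]{DataFrame}} with columns
#' \code{gene} (symbol), \code{category} (one of \code{"PCG"}, \code{"tRNA"},
#' \code{"rRNA"}), \code{strand} (\code{"+"}/\code{"-"}), \code{pseudo}
#' (logical), and the exon layout as two parallel
#' \code{\link[IRanges]{IntegerList}} columns \code{exon_starts} and
#' \code{exon_ends}.  Rows are sorted by first exon start.
#'
#' @slot id accession or label.
#' @slot sequence a \code{\link[Biostrings]{DNAString}} (circular by
#'   convention).
#' @slot features the feature \code{DataFrame} described above.
#' @slot source path of the file the genome was read from ("" if in-memory).
#'
#' @seealso [readGenBank()], [detectQuadripartite()], [summarizeGenome()]
#' @exportClass AnnotatedPlastome
setClass("AnnotatedPlastome",
  representation(id = "character", sequence = "DNAString",
                 features = "DataFrame", source = "character"))

setValidity("AnnotatedPlastome", function(object) {
  msgs <- character()
  L <- length(object@sequence)
  if (L < 1L) msgs <- c(msgs, "sequence must be non-empty")
  ft <- object@features
  req <- c("gene", "category", "strand", "pseudo", "exon_starts", "exon_ends")
  if (!all(req %in% colnames(ft)))
    msgs <- c(msgs, paste("feature table must have columns:",
                          paste(req, collapse = ", ")))
  if (nrow(ft) > 0 && all(req %in% colnames(ft))) {
    if (!all(ft$category %in% c("PCG", "tRNA", "rRNA")))
      msgs <- c(msgs, "category must be PCG, tRNA or rRNA")
    if (!all(ft$strand %in% c("+", "-")))
      msgs <- c(msgs, "strand must be '+' or '-'")
    st <- unlist(ft$exon_starts); en <- unlist(ft$exon_ends)
    if (length(st) != length(en) || any(en <= st))
      msgs <- c(msgs, "exon intervals must be non-empty [start, end)")
    if (length(st) && (any(st < 0) || any(st >= L)))
      msgs <- c(msgs, "exon starts must lie within [0, genome length)")
    fs <- vapply(ft$exon_starts, min, integer(1))
    if (is.unsorted(fs))
      msgs <- c(msgs, "features must be sorted by start coordinate")
  }
  if (length(msgs)) msgs else TRUE
})

#' Quadripartite region partition
#'
#' The LSC-IRb-SSC-IRa tiling of a plastid genome in its canonical rotation
#' (position 0 is the first LSC base, regions in the order LSC, IRb, SSC,
#' IRa).  The four junctions are, in 0-based coordinates of the first base
#' after each boundary: JLB = LSC length (first IRb base), JSB (first SSC
#' base), JSA (first IRa base) and JLA = 0 (first LSC base, wrapping).
#'
#' @slot genome_length total length in bp.
#' @slot lsc_len,ssc_len,ir_len region lengths in bp (the two IRs are equal
#'   by construction).
#' @slot rotation offset such that canonical position 0 corresponds to
#'   position \code{rotation} of the genome as supplied to
#'   [detectQuadripartite()].
#'
#' @exportClass RegionPartition
setClass("RegionPartition",
  representation(genome_length = "integer", lsc_len = "integer",
                 ssc_len = "integer", ir_len = "integer",
                 rotation = "integer"))

setValidity("RegionPartition", function(object) {
  msgs <- character()
  if (object@lsc_len + object@ssc_len + 2L * object@ir_len !=
      object@genome_length)
    msgs <- c(msgs, "regions must tile the genome: lsc + ssc + 2*ir == total")
  if (object@lsc_len <= object@ssc_len)
    msgs <- c(msgs, "LSC must be longer than SSC")
  if (any(c(object@lsc_len, object@ssc_len, object@ir_len) <= 0L))
    msgs <- c(msgs, "all region lengths must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn AnnotatedPlastome-class display a short summary.
#' @param object an \code{AnnotatedPlastome}.
#' @export
setMethod("show", "AnnotatedPlastome", function(object) {
  ft <- object@features
  cat("AnnotatedPlastome:", object@id, "\n")
  cat("  sequence:", length(object@sequence), "bp\n")
  cat(sprintf("  features: %d (%d PCG / %d tRNA / %d rRNA; %d pseudo)\n",
              nrow(ft), sum(ft$category == "PCG"),
              sum(ft$category == "tRNA"), sum(ft$category == "rRNA"),
              sum(ft$pseudo)))
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

#' @describeIn RegionPartition-class display region lengths and junctions.
#' @param object a \code{RegionPartition}.
#' @export
setMethod("show", "RegionPartition", function(object) {
  j <- junctions(object)
  cat("RegionPartition (canonical rotation, 0-based)\n")
  cat(sprintf("  LSC %d bp | IRb %d bp | SSC %d bp | IRa %d bp (total %d)\n",
              object@lsc_len, object@ir_len, object@ssc_len, object@ir_len,
              object@genome_length))
  cat(sprintf("  junctions: JLB=%d JSB=%d JSA=%d JLA=%d\n",
              j[["JLB"]], j[["JSB"]], j[["JSA"]], j[["JLA"]]))
})

# ---- accessors --------------------------------------------------------------

#' @rdname AnnotatedPlastome-class
#' @param x an \code{AnnotatedPlastome}.
#' @export
plastomeId <- function(x) x@id

#' @rdname AnnotatedPlastome-class
#' @export
plastomeSeq <- function(x) x@sequence

#' @rdname AnnotatedPlastome-class
#' @export
genomeLength <- function(x) length(x@sequence)

#' Feature table accessor
#' @param x an \code{AnnotatedPlastome}.
#' @return the feature \code{DataFrame} (see
#'   \linkS4class{AnnotatedPlastome}).
#' @export
geneFeatures <- function(x) x@features

#' @rdname RegionPartition-class
#' @param x a \code{RegionPartition}.
#' @export
regionLengths <- function(x) {
  c(lsc = x@lsc_len, irb = x@ir_len, ssc = x@ssc_len, ira = x@ir_len)
}

#' Junction positions of a partition
#'
#' @param x a \code{RegionPartition}.
#' @return named integer vector with the canonical 0-based position of the
#'   first base after each boundary: JLB, JSB, JSA, JLA.
#' @export
junctions <- function(x) {
  c(JLB = x@lsc_len,
    JSB = x@lsc_len + x@ir_len,
    JSA = x@lsc_len + x@ir_len + x@ssc_len,
    JLA = 0L)
}

# internal constructor: builds and sorts a feature DataFrame
newFeatureTable <- function(gene = character(), category = character(),
                            strand = character(), pseudo = logical(),
                            exon_starts = list(), exon_ends = list()) {
  ft <- DataFrame(gene = as.character(gene),
                  category = as.character(category),
                  strand = as.character(strand),
                  pseudo = as.logical(pseudo),
                  exon_starts = IntegerList(lapply(exon_starts, as.integer)),
                  exon_ends = IntegerList(lapply(exon_ends, as.integer)))
  if (nrow(ft) > 0) {
    ft <- ft[order(vapply(ft$exon_starts, min, integer(1))), , drop = FALSE]
    rownames(ft) <- NULL
  }
  ft
}

#' Construct an annotated plastome in memory
#'
#' @param id accession or label.
#' @param sequence character string or \code{DNAString}.
#' @param features a \code{DataFrame} as described in
#'   \linkS4class{AnnotatedPlastome}, or \code{NULL} for none.
#' @param source provenance string.
#' @return an \code{AnnotatedPlastome}.
#' @export
AnnotatedPlastome <- function(id, sequence, features = NULL, source = "") {
  if (is.character(sequence)) sequence <- DNAString(sequence)
  if (is.null(features)) features <- newFeatureTable()
  new("AnnotatedPlastome", id = id, sequence = sequence,
      features = features, source = source)
}

# feature spans (unwrapped): first exon start, last exon end
featureSpans <- function(ft) {
  if (nrow(ft) == 0)
    return(data.frame(start = integer(), end = integer()))
  data.frame(start = vapply(ft$exon_starts, min, integer(1)),
             end = vapply(ft$exon_ends, max, integer(1)))
}
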