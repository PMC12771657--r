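#' Report genes at the quadripartite junctions
#'
#' IRscope-style boundary report.  For each of the four junctions (JLB =
#' LSC/IRb, JSB = IRb/SSC, JSA = SSC/IRa, JLA = IRa/LSC) the report lists
#' (a) any gene whose total span (introns included) crosses the boundary,
#' with the number of bases lying in each flanking region, and (b)
#' otherwise the nearest gene on each side with its distance in bp.
#' Distances are measured on the circle in the canonical rotation, from the
#' junction to the nearest coordinate of the gene span.  A gene that starts
#' or ends exactly on a boundary is reported as \code{"abuts"} (0 bp).
#'
#' @param genome an \linkS4class{AnnotatedPlastome} in the canonical
#'   rotation (see [canonicalizePlastome()]).
#' @param partition matching \linkS4class{RegionPartition}.
#' @param max_dist only genes within this many bp of a junction are
#'   considered for the nearest-gene report (default 1000, mirroring the
#'   gene set usually drawn in junction figures).
#' @param categories feature categories to report (default protein-coding
#'   and tRNA genes).
#' @return data.frame with columns \code{genome}, \code{junction},
#'   \code{gene}, \code{relation} (\code{spans} / \code{abuts} /
#'   \code{nearest}), \code{region} (the flank the \code{bp} value refers
#'   to) and \code{bp}.  Spanning genes produce one row per flank, and the
#'   two \code{bp} values sum to the gene span length.
#' @export
junctionReport <- function(genome, partition, max_dist = 1000L,
                           categories = c("PCG", "tRNA")) {
  if (is.null(partition)) stop("no region partition available for ",
                               plastomeId(genome))
  if (genomeLength(genome) != partition@genome_length)
    stop("partition is inconsistent with genome length")
  L <- partition@genome_length
  j <- junctions(partition)
  flanks <- list(JLB = c("LSC", "IRb"), JSB = c("IRb", "SSC"),
                 JSA = c("SSC", "IRa"), JLA = c("IRa", "LSC"))
  ft <- geneFeatures(genome)
  ft <- ft[ft$category %in% categories, , drop = FALSE]
  spans <- featureSpans(ft)
  rows <- list()
  add <- function(junc, gene, relation, region, bp)
    rows[[length(rows) + 1L]] <<- data.frame(
      genome = plastomeId(genome), junction = junc, gene = gene,
      relation = relation, region = region, bp = as.integer(bp))
  for (junc in names(flanks)) {
    jpos <- if (junc == "JLA") L else j[[junc]]
    jmod <- jpos %% L
    up <- flanks[[junc]][1]; down <- flanks[[junc]][2]
    spanning <- FALSE
    for (i in seq_len(nrow(ft))) {
      s <- spans$start[i]; e <- spans$end[i]
      d <- (jmod - s) %% L
      if (d > 0 && d < (e - s)) {
        add(junc, ft$gene[i], "spans", up, d)
        add(junc, ft$gene[i], "spans", down, (e - s) - d)
        spanning <- TRUE
      }
    }
    if (spanning) next
    # nearest gene on each side (upstream: ends before the boundary;
    # downstream: starts after it)
    d_up <- (jmod - (spans$end %% L)) %% L
    d_down <- ((spans$start %% L) - jmod) %% L
    if (nrow(ft)) {
      iu <- which.min(d_up)
      if (d_up[iu] <= max_dist)
        add(junc, ft$gene[iu], if (d_up[iu] == 0) "abuts" else "nearest",
            up, d_up[iu])
      idn <- which.min(d_down)
      if (d_down[idn] <= max_dist)
        add(junc, ft$gene[idn], if (d_down[idn] == 0) "abuts" else "nearest",
            down, d_down[idn])
    }
  }
  if (!length(rows))
    return(data.frame(genome = character(), junction = character(),
                      gene = character(), relation = character(),
                      region = character(), bp = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write junction reports for one or more genomes as long-format TSV
#'
#' @param reports a data.frame from [junctionReport()] or a list of them
#'   (rows are concatenated).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeJunctionReport <- function(reports, path) {
  if (is.data.frame(reports)) reports <- list(reports)
  write.table(do.call(rbind, reports), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
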