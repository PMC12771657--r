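# shared fixtures: a small (40 kb) synthetic plastome reused across files

smallGeneTable <- function() {
  gt <- defaultGeneTable()
  gt[gt$symbol %in% c("psbA", "trnH", "matK", "atpF", "rps19",
                      "rpl2", "rrn16", "ndhF", "rpl32", "ccsA", "ycf1"), ]
}

smallSpec <- function(seed = 7, gene_table = smallGeneTable(),
                      n_taxa = 6, ...) {
  syntheticSpec(seed = seed, total_len = 40000, ir_len = 6000,
                ssc_len = 5000, gene_table = gene_table,
                n_taxa = n_taxa, ...)
}

.fixtures <- new.env()

fixtureBuild <- function() {
  if (is.null(.fixtures$b)) .fixtures$b <- buildPlastome(smallSpec())
  .fixtures$b
}

fixturePartition <- function() {
  if (is.null(.fixtures$p))
    .fixtures$p <- detectQuadripartite(fixtureBuild()$genome)
  .fixtures$p
}

# a spec with a probe gene straddling JSB by k bases (k bases inside SSC)
junctionSpec <- function(k, seed = 31) {
  gt <- defaultGeneTable()
  gt <- gt[gt$symbol %in% c("psbA", "matK", "rps19", "rpl2", "rrn16",
                            "rpl32", "ccsA"), ]
  probe <- gt[gt$symbol == "ccsA", ]
  probe$symbol <- "probe"
  probe$junction <- "JSB"
  probe$offset <- k
  syntheticSpec(seed = seed, total_len = 40000, ir_len = 6000,
                ssc_len = 5000, gene_table = rbind(gt, probe), n_taxa = 4)
}

randDNA <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

revcompChr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# minimal in-memory plastome with single-exon features, for tests that do
# not need the generator
tinyPlastome <- function(id, seq, genes) {
  # genes: data.frame(gene, category, strand, start, end, pseudo)
  ft <- plastomics:::newFeatureTable(
    gene = genes$gene, category = genes$category, strand = genes$strand,
    pseudo = genes$pseudo,
    exon_starts = as.list(genes$start), exon_ends = as.list(genes$end))
  AnnotatedPlastome(id, seq, ft)
}
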