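# plastomics

Comparative analysis of annotated chloroplast (plastid) genomes in R.

When a new plant species is described from plastome data, the supporting
genomic evidence follows a standard recipe: confirm the quadripartite
LSC–IRb–SSC–IRa architecture and summarize genome statistics, profile
codon-usage bias, catalogue microsatellites and long repeats, compare
inverted-repeat junction positions across taxa, scan a whole-genome
alignment for hypervariable regions usable as molecular markers, and test
protein-coding genes for selection.  `plastomics` implements that pipeline
as a set of tested, composable functions for people who want the analyses
reproducible rather than spread across half a dozen web tools — and ships a
synthetic plastome generator with a ground-truth manifest so the whole
pipeline can be validated end to end without downloading a single record.

## The methods at its core

* **Structure** — the IRs are found as the longest pair of disjoint exact
  reverse-complement repeats on the circle (seed-and-extend maximal-match
  enumeration in C++); genomes are rotated to the canonical frame with the
  four junctions JLB/JSB/JSA/JLA at known positions.
* **Codon usage** — relative synonymous codon usage per sense codon,
  RSCU(c) = k·n_c / Σ_family n, with A/U- vs G/C-ending bias summaries.
* **Repeats** — MISA-style maximal perfect tandem repeats (thresholds
  10/6/5/4/3/3 for unit lengths 1–6) and REPuter-style maximal exact
  forward/palindromic/reverse/complement pairs ≥ 30 bp, both validated
  against brute-force oracles.
* **Diversity** — sliding-window nucleotide diversity
  π = mean over pairs of d_ij / L_ij (pairwise deletion), 600 bp windows
  at 200 bp steps; windows in the top 5% of π with > 25 SNPs are merged
  into hypervariable regions characterized by SNP/SVS/PIP counts.
* **Selection** — Nei–Gojobori (1986) Ka/Ks with Jukes–Cantor correction
  over codon-aligned shared genes (protein alignment via BLOSUM62,
  back-translated), ω = Ka/Ks with undefined cases flagged, and gene ×
  taxon mean-ω matrices.

## Worked example

Build a fully ground-truthed synthetic plastome (the defaults emulate a
~154.5 kb *Aletris*-like genome), detect its structure, and run the marker
scan on a simulated 14-taxon cohort:

```r
library(plastomics)

spec  <- syntheticSpec(seed = 1)
built <- buildPlastome(spec)
part  <- detectQuadripartite(built$genome)
part
#> RegionPartition (canonical rotation, 0-based)
#>   LSC 83200 bp | IRb 26600 bp | SSC 18100 bp | IRa 26600 bp (total 154500)
#>   junctions: JLB=83200 JSB=109800 JSA=127900 JLA=0

summarizeGenome(built$genome, part)
#> GenomeSummary synth0001: 154500 bp (LSC 83200 / SSC 18100 / IR 26600)
#>   GC % total 38.71 (LSC 36.57 / SSC 35.31 / IR 43.20)
#>   genes 43 (28 PCG / 9 tRNA / 6 rRNA), 8 duplicated, 5 with introns

head(junctionReport(built$genome, part), 4)
#>      genome junction  gene relation region  bp
#> 1 synth0001      JLB rps19    spans    LSC 175
#> 2 synth0001      JLB rps19    spans    IRb 104
#> 3 synth0001      JSB  ndhF  nearest    SSC  10
#> 4 synth0001      JSA  ycf1    spans    SSC 850
```

The rps19-like gene extends 104 bp into IRb and the ycf1-like gene is cut
by JSA — the junction architecture the generator plants, recovered by the
report.  Now the diversity scan:

```r
cohort <- mutateCohort(built$genome, spec)
win <- windowScan(cohort$alignment)                   # 600/200 defaults
reg <- mergeHypervariable(win, cohort$alignment)      # top 5% pi, SNP > 25
reg <- annotateRegions(reg, built$genome, cohort$alignment,
                       rownames(cohort$alignment)[1])
reg[, c("start", "end", "length", "n_snp", "n_pip", "mean_pi", "label")]
#>    start    end length n_snp n_pip    mean_pi      label
#> 1   7000   8200   1200   179     3 0.02279304  trnH-matK
#> 2  20400  22000   1600   249     7 0.02391484       atpA
#> 3  34000  35600   1600   237     5 0.02260989 rpoB-rpoC1
#> 4  47800  49200   1400   214    11 0.02410518  psbD-psbC
#> 5  61400  62600   1200   175     6 0.02260989  rbcL-petA
#> 6  75000  76600   1600   238    11 0.02313874       psbB
#> 7 111400 112800   1400   209     3 0.02308477 ndhF-rpl32
#> 8 125000 126400   1400   234     8 0.02559655       ndhA
```

All eight hypervariable regions coincide with the generator's planted
high-substitution blocks (mean π ≈ 0.023 against a genome-wide background
near 0.004) and are labeled with the gene or intergenic spacer they fall
in.  Real annotated genomes enter the same way via `readGenBank()`, and
`runPipeline()`/`inst/scripts/plastomics-cli.R` orchestrate all stages
from a YAML config whose defaults are the standard comparative settings.

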