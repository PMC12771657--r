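---
title: "Methods: comparative plastome analysis with plastomics"
author: "plastomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis with plastomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

# Scope

`plastomics` re-implements, as a tested and reusable pipeline, the standard
comparative analyses applied to annotated chloroplast genomes when a new
plant species is described from plastome data: quadripartite structure
detection and genome summary statistics, codon-usage bias (RSCU),
microsatellite (SSR) and long-repeat scanning, inverted-repeat (IR)
junction reports, sliding-window nucleotide diversity with
hypervariable-region calling, and pairwise Ka/Ks selection analysis.  A
synthetic plastome generator with a full ground-truth manifest makes every
stage testable without downloading records.

# The data model

An `AnnotatedPlastome` holds one circular genome: a `DNAString`, and a
feature table (gene symbol, category PCG/tRNA/rRNA, strand, pseudogene
flag, exon layout).  All internal coordinates are 0-based half-open;
GenBank I/O converts to and from the 1-based inclusive convention, and
features that cross the circular origin are stored unwrapped (end
coordinates past the genome length).  This makes junction arithmetic exact:
a boundary position is simply an integer, and a gene spans it iff
`start < j < end` on the circle.

A `RegionPartition` is the LSC–IRb–SSC–IRa tiling in the *canonical
rotation*: position 0 is the first LSC base, regions follow in that order,
and the four junctions are JLB (first IRb base), JSB (first SSC base), JSA
(first IRa base) and JLA (position 0).  Genomes are rotated to this frame
(`canonicalizePlastome()`); the SSC strand is kept as deposited — no isomer
flipping — because comparative tables are built from records as deposited.

# Quadripartite detection

`detectQuadripartite()` finds the longest pair of disjoint, exact
reverse-complement repeats on the circle.  Matching is exact (Hamming
distance 0): published *Aletris*-type IRs are exact repeats, and exactness
keeps "longest" and "maximal" well defined and checkable against an
enumeration oracle.  Candidate matches are enumerated as maximal exact
matches between the doubled sequence and its reverse complement (packed
31-mer seeds, left-maximal extension, in C++), which makes the detector
invariant under rotation of the input.  Ties are broken by the leftmost IRb
start.  The default minimum IR length is 1000 bp — plastid IRs are
typically above 10 kb, and the floor excludes short dispersed repeats — and
a sequence without a qualifying repeat pair yields `NULL` ("no
quadripartite structure"), not an error.

# Gene models, CDS extraction and codon usage

`validateGeneModels()` reports, for every protein-coding gene, the spliced
length, length mod 3, start/stop codon and internal stop positions
(genetic code 11).  A gene is a *pseudogene candidate* iff its length is
not a multiple of 3, it contains an internal stop, or its start codon is
not one of ATG/GTG/ACG; the deposited `/pseudo` qualifier is merged with
this predicate by OR.  The three-codon start set is a documented choice:
plastid annotation pipelines accept ACG and GTG initiators (C-to-U editing
and alternative initiation), and the predicate must not flag such genes.

RSCU is computed over the 61 sense codons
(`RSCU(c) = k · n_c / Σ n_family`); stop codons are tallied separately.
IR-duplicated genes contribute both copies to genome-level codon totals,
matching how comparative tables pool annotated CDS as deposited; the
`extractCDS()` exclusion log makes the accounting auditable.  Reports use
the RNA alphabet (UUA, not TTA), the convention of published RSCU heatmaps;
DNA is used internally.

# Repeat scanning

`findSSRs()` reports maximal perfect tandem runs of 1–6 bp motifs with the
MISA-style thresholds 10/6/5/4/3/3 (mono- through hexanucleotide).  Each
locus is reported once, with its primitive motif at the leftmost phase;
compound or interrupted runs are not merged (no interruption parameter is
part of the study settings, and unmerged perfect runs are the simplest
auditable rule).  Motif classes collapse strand and phase:
`"X/Y"` with X the smallest rotation of the motif and Y the smallest
rotation of its reverse complement, printed in sorted order (so T → `A/T`,
TA → `AT/AT`).

`findLongRepeats()` enumerates maximal exact repeat pairs of the four
REPuter types — forward (F), palindromic (P), reverse (R), complement (C) —
at a 30 bp floor, truncated to the 5000 longest.  Pairs may self-overlap
and are reported with `pos1 < pos2` on the forward strand.  Two
representational details deserve note.  First, a contiguous DNA palindrome
(a segment equal to its own reverse complement) is a single self-symmetric
maximal match; it is reported as its two halves with
`self_symmetric = TRUE`, since "pair maximality" does not apply to the
halves of a palindrome.  Second, the IRa/IRb pair itself is, by
construction, a huge palindromic repeat; it is reported but flagged
(`ir_pair`) so tallies can include or exclude it — published counts do not
state which convention was used.

Both scanners run on exact-match seed-and-extend C++ cores and are
validated, record for record, against brute-force oracles (per-position
tandem counting; diagonal run-length enumeration) on random sequences with
planted repeats.

# Junction reports

`junctionReport()` lists, for each junction, any gene whose total span
(introns included) crosses it — with the bases falling in each flanking
region, which sum to the span length — and otherwise the nearest gene on
each side with its distance, measured on the circle from the junction to
the nearest span coordinate.  Spans rather than exon structures are used
because junction figures (IRscope-style) plot gene boxes.  By default only
protein-coding and tRNA genes within 1000 bp are reported, mirroring the
gene set such figures show; both the distance cap and the categories are
arguments.  Genes duplicated in the IR appear with equal offsets at the
two corresponding junctions, a property the tests assert.

# Sliding-window diversity and hypervariable regions

`windowScan()` computes, per window (600 bp, step 200 bp by default),
nucleotide diversity as the mean over sequence pairs of
`differences / sites where both hold unambiguous bases` — i.e. pairwise
deletion with a per-pair effective length.  Complete deletion would
discard most columns in whole-plastome alignments of a dozen taxa, so
pairwise deletion is the default.  Windows advance by the step; after the
last full window one terminal partial window is kept iff it covers at
least half a window, so region ends can fall off the window grid only
through the clipped terminal window.  Site classes follow the standard
definitions: a column with fewer than two unambiguous bases is excluded;
variable columns are parsimony-informative (at least two bases each in at
least two sequences), singleton (exactly one sequence carries a minority
base against an otherwise uniform column), or other-variable.

`mergeHypervariable()` selects windows with Pi at or above the empirical
95th percentile (ties included) AND more than 25 SNPs, then concatenates
maximal runs of adjacent (consecutive-index) or overlapping selected
windows.  The two filters are combined with AND: the OR reading would
select far more windows than is consistent with a short list of
hypervariable regions over a 150 kb genome.  Region SNP/SVS/PIP counts and
the region Pi are recomputed over the merged column span rather than
averaged over member windows, because a single Pi is reported per region
of non-uniform length; window-averaging is the documented alternative.
Note that the quantile-based cut caps the selectable fraction of windows
at about 5%: hypervariable regions can only be fully recovered when the
truly elevated fraction of the genome is below that capacity, which is how
the recovery experiments are dimensioned.

`annotateRegions()` maps alignment coordinates to ungapped reference
coordinates by cumulative gap counting and labels each region with the
gene at its midpoint or the `left-right` spacer name from the flanking
genes.

# Ka/Ks (NG86)

Shared protein-coding genes are the intersection of per-genome symbol sets
after case normalization, excluding pseudogene-flagged copies and
collapsing IR duplicates to the copy with fewer validation flags (ties:
leftmost).  Pairs are codon-aligned by aligning the translated proteins
(Needleman–Wunsch, BLOSUM62, gap opening 10 / extension 0.5 via
`Biostrings::pairwiseAlignment`) and back-translating, so gaps come only
in multiples of 3; codon columns containing a gap or ambiguity are dropped.

The estimator is Nei–Gojobori (1986) with Jukes–Cantor correction — the
software named in comparative studies does not pin down a method, and NG86
is closed-form, conventional, and checkable against an exhaustive
pathway-enumeration oracle.  Site counts come from single-mutation
neighborhoods with mutations to stop codons excluded from the opportunity
(each codon position contributes `syn/(non-stop neighbors)`, so synonymous
plus nonsynonymous sites always total 3 per codon); differences are
averaged over all minimal substitution pathways, excluding pathways
through stop codons and renormalizing (for multi-hit codons, over the
remaining orderings).  A proportion at or above 3/4 leaves that rate
undefined (saturation).  ω = Ka/Ks is defined iff Ks > 0; Ks = 0 with
Ka > 0 is flagged (`undefined_ks0_ka_pos`) rather than reported as
infinity, and undefined ω is excluded from the gene × taxon mean matrix,
whose cell (g, t) averages defined ω over all pairs involving taxon t.

# The synthetic-data generator

`buildPlastome()` emits a genome whose every analyzable property is known:

* region sizes and per-region GC default to an East Asian *Aletris*-like
  plastome (154.5 kb; IR 26.6 kb; SSC 18.1 kb; GC 35.3/31.2/42.8%);
* IRa is written as the exact reverse complement of IRb, with the four
  bases adjacent to the junctions constrained so the repeat cannot extend
  by chance — planted IR coordinates are therefore recovered exactly;
* genes are placed from a table that reproduces the canonical junction
  architecture (a psbA-like gene 138 bp inside the LSC at JLA; an
  rps19-like gene extending 104 bp into IRb; a ycf1-like gene cut by JSA;
  an IRb block mirrored into IRa, giving the duplicated gene set;
  intron-containing genes); protein-coding content is random sense codons
  between an ATG and a TAA;
* the background is screened: any microsatellite reaching the detection
  thresholds or repeat pair of any type reaching 30 bp that is not
  deliberately planted is removed by an iterative repair loop (background
  bases are redrawn; offending content inside coding genes is redrawn one
  sense codon at a time, so CDS validity is preserved);
* requested SSRs and long repeats are planted into free intergenic
  background with flanking bases fixed so each planted repeat is maximal,
  and the manifest lists their realized coordinates (including the IRa
  images of anything planted in IRb).

`mutateCohort()` applies independent per-taxon, per-site substitutions
(default 14 taxa; 0.002 background, 0.012 inside eight 1.5 kb hot blocks,
chosen so background diversity sits near Pi ≈ 0.004 and hot regions near
Pi ≈ 0.02, the magnitudes typical of congeneric plastome comparisons).
There are no indels, so the cohort is its own alignment.  Substitutions
are i.i.d. per site with uniform base choice — sufficient for diversity
and region-recovery testing, but deliberately simpler than real data: no
rate matrix, no indels, no alignment error, and hot blocks with hard
edges.  Passing tests therefore validate the statistics and the merging
rule, not robustness to alignment artifacts.

`evolveCdsPair()` diverges two copies of a CDS by proposing uniform
single-base codon changes, rejecting stop-creating ones, and accepting
synonymous changes with probability 1 and nonsynonymous ones with
probability ω, until the accepted synonymous events reach the count
implied by the target Ks (Jukes–Cantor inverted).  Because proposals are
uniform over the same single-mutation neighborhoods NG86 uses for its site
counts, the NG86 estimate of ω is consistent for the acceptance ratio, and
the estimator-recovery experiment (ω ∈ {0.1, 0.5, 1.0}, 500 codons, 100
replicates, Ks 0.2) recovers the target within 20%.

Every generator output is reproducible bit-for-bit from the spec and seed;
the RNG state of the caller is saved and restored.

# Pipeline and configuration

`validateConfig()` fills the standard defaults (600/200 window, top-5%
with SNP > 25, SSR thresholds 10/6/5/4/3/3, 30 bp repeat floor, 1000 bp IR
floor, genetic code 11), rejects unknown keys, and reports every problem
at once.  `runPipeline()` executes stages in dependency order, isolates
per-stage failures, and stamps every output TSV with the package version
and stage parameters.  A thin command-line wrapper
(`inst/scripts/plastomics-cli.R`) exposes the stages and the simulator as
subcommands; the R functions are the primary interface.

# Numerical and degenerate-input choices

* GC percentages exclude ambiguous bases from numerator and denominator.
* Codons containing N are skipped and counted separately; terminal stops
  are tallied apart from sense counts.
* Alignment columns with any non-ACGT character are missing data for both
  Pi (per-pair deletion) and site classification.
* PCGs shorter than 6 bp produce a degenerate-feature warning record, not
  an error; an empty shared-gene intersection warns and returns an empty
  set; an alignment shorter than one window yields a single whole-length
  window with a warning; fewer than 20 windows make the Pi quantile
  unstable and warn.
* Quantile thresholds use R's default empirical quantile (type 7) with
  ties included on the selection side.

# Problem sizes used by the test suite

The suite validates on desk-scale data chosen to finish in a few minutes:
40 kb plastomes (6 kb IR, 5 kb SSC) with an 11-gene complement for
structural fixtures, 1–3 kb sequences for SSR oracle comparisons and
400–800 bp for the quadratic long-repeat oracle (at a 12 bp floor so
random sequences still contain informative hits), 14-taxon cohorts for
recovery experiments with 20 replicate mutation draws, and the full
3721-pair sense-codon grid for the NG86 oracle.  The acceptance script
(`scripts/acceptance.R`) runs the generator at its full default scale
(154.5 kb, 14 taxa).

# Known limitations

* IR detection assumes exact IRs; genomes whose IRs differ by even one
  substitution are reported by their longest exact core.
* GenBank parsing covers the feature subset the pipeline consumes
  (gene/CDS/tRNA/rRNA, join/complement locations, /gene and /pseudo
  qualifiers); exotic location operators are rejected with an error naming
  the feature.  Trans-spliced genes annotated as separate fragments are
  treated as separate features, and junction distances list fragments
  independently.
* Alignment construction is out of scope: the diversity stage ingests an
  externally computed multiple alignment.
* NG86 assumes equal base frequencies and no transition/transversion bias;
  branch- or site-model likelihood methods are out of scope.
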