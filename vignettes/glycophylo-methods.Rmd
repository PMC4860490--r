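---
title: "Glycolysis-marker phylogenetics: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycolysis-marker phylogenetics: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Placing a new *Bifidobacterium* genome on the genus phylogeny is usually
done either with the 16S rRNA gene — cheap but poorly resolved within this
genus — or with a core-genome analysis, which is accurate but requires
assembling and aligning hundreds of shared genes. `glycophylo` implements a
middle road: multilocus sequence analysis (MLSA) on the nine canonical
glycolysis enzymes (phosphoglucomutase `pgm`, glucose-6-phosphate isomerase
`pgi`, fructose-bisphosphate aldolase `fba`, triose-phosphate isomerase
`tpi`, glyceraldehyde-3-phosphate dehydrogenase `gap`, phosphoglycerate
kinase `pgk`, phosphoglycerate mutase `gpm`, enolase `eno`, pyruvate kinase
`pyk`). 6-phosphofructokinase, the canonical third step, is absent in
bifidobacteria (the genus runs the bifid shunt instead), so the marker
scheme has nine genes, not ten. Because glycolysis is the biochemical spine
of the cell, these housekeeping genes are present in essentially every
genome, conserved enough to align across the genus, and variable enough —
more variable than ribosomal RNA — to resolve species groups.

The package covers the full workflow: mining annotated assemblies for the
marker genes, concatenating the translated proteins in pathway order,
aligning them with a parameter ensemble and selecting a consistent
alignment, inferring bootstrapped distance trees and majority-rule
consensus trees, quantifying congruence between trees, and analysing GC
composition at the genome and per-gene level. A synthetic-genome generator
provides ground-truth cohorts so every stage is testable without
downloading assemblies.

## Marker mining

Orthologs are located among a genome's *annotated CDS features* (the
package does not call genes): every CDS is globally aligned at the
nucleotide level against each reference sequence of a marker, and the CDS
qualifies when its best identity reaches `min_similarity` (default
**0.40**, the classical nucleotide cut-off for annotating orthologs across
a genus). Among qualifying CDSs the best *alignment score* wins — the
analogue of disambiguating multiple annotation hits with BLAST. "Identity"
is defined conservatively as matches divided by the full alignment length,
gap columns included; this is reproducible and errs toward rejecting
marginal hits. Ties resolve to the longer CDS, then the lexicographically
smaller locus tag, so mining is deterministic and repeated runs are
byte-identical.

The 16S rRNA gene is not a CDS, so it is found by a seed-and-extend scan:
exact 15-mers from the 16S references anchor candidate windows on both
strands, each window is aligned globally (free end gaps) against the
reference set, and the best-scoring locus above the identity cut-off is
kept, untranslated. When a genome carries several rRNA-like loci (real
genomes typically do), the highest-scoring alignment decides — mirroring
the manual BLAST disambiguation step of the original protocol.

Translation uses the bacterial genetic code (NCBI table 11) with `GTG` and
`TTG` accepted as initiators (translated as Met); an internal stop codon is
treated as a pseudogene-like defect and is an error, not a silent skip.
Concatenation orders the nine proteins by their pathway position
(pgm, pgi, fba, tpi, gap, pgk, gpm, eno, pyk) and records a partition
table so per-gene coordinates remain recoverable after alignment and
trimming. In strict mode (default) a genome missing any marker fails
loudly: on the real genus cohort all nine genes occur in every genome, so
a missing marker almost always means a broken input.

## Alignment ensemble and consistency selection

Instead of wrapping five external alignment programs, the package runs one
progressive aligner under five documented parameter sets and treats the
results as an ensemble. The aligner builds a neighbor-joining guide tree
from pairwise alignment distances and merges profiles in guide-tree
postorder under sum-of-pairs mean-profile scoring (no iterative
refinement). The ensemble members vary:

* substitution matrix — BLOSUM62 vs BLOSUM80 for proteins; the +5/−4
  scheme for nucleotides;
* gap costs — the protocol's protein costs (opening −10, extension −0.1
  per element) and a stiffer variant (−12/−2); for 16S, opening −15 and
  extension −6.66;
* end-gap policy — global with free end gaps vs penalized end gaps;
* guide distances — raw identity distance vs corrected distance;
* alignment polarity — two members align the *reversed* sequences and
  mirror the result back. Dynamic programming breaks ties in a fixed
  direction, so reversal relocates degenerate gaps to the other end of
  repeat regions; this reproduces the kind of disagreement real aligner
  ensembles show and guarantees the ensemble is informative even when the
  other knobs coincide.

Externally produced alignments can replace the built-in members via
`build_ensemble(member_files = ...)`; they are validated (same label set,
rows degap to the inputs) and then flow through the same machinery.

Each member is scored against the rest: for a column of the focal
alignment, every aligned residue pair (two rows, both ungapped) is checked
in each other member, and the column score is the mean fraction of members
that align the same two residues. The member with the highest mean column
score is selected (ties to the earliest member). Trimming then removes
columns whose gap fraction exceeds **0.9** or whose consistency score
falls below **0.5** — an explicit, documented stand-in for the automated
heuristics of alignment-trimming tools. The chosen alignment is recorded
both untrimmed and trimmed; trimming is idempotent at fixed thresholds.

## Tree inference

Point estimates and bootstrap replicates use corrected-distance neighbor
joining: the mismatch fraction $p$ over shared ungapped columns is
corrected by Kimura's protein formula $d = -\ln(1 - p - 0.2\,p^2)$, or by
Jukes–Cantor $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$ for nucleotides.
This replaces a maximum-likelihood search deliberately: NJ on corrected
distances is deterministic, fast enough for desk-scale validation, and
every downstream statistic (branch-length sums, support audits, consensus,
Robinson–Foulds, monophyly) is inference-agnostic — externally computed ML
trees can be dropped in as Newick at any point. Consequences of this
choice: branch-length sums are on a corrected-distance scale, not an ML
substitution-rate scale, and published ML-specific numbers (branch-length
sum tables, exact high-support node counts) are treated as
characterization, not as reproduction targets.

Numerical conventions, all chosen for determinism:

* saturated pairs ($p$ beyond the correction's domain) are set to twice
  the largest finite corrected distance, with a warning;
* NJ processes leaves in label-sorted order and breaks Q-matrix ties by
  the smallest index pair; negative intermediate branch lengths are
  clamped to zero with the deficit shifted to the sister edge, preserving
  the joined pair's path length;
* bootstrap resamples columns with replacement to the original column
  count; the whole replicate set is reproducible from one integer seed
  (default **1**, with **100** replicates);
* consensus is strict majority rule: a bipartition must occur in strictly
  more than `threshold` (default 0.5) of the replicate trees, so at
  exactly 50% with an even replicate count it is excluded; supports are
  `round(100 × frequency)` with half-up rounding (integer node labels);
  consensus branch lengths are the mean of the bipartition's edge lengths
  over the trees containing it;
* Robinson–Foulds distances count the symmetric difference of nontrivial
  bipartitions, normalized by the total nontrivial bipartitions of both
  trees; a group is monophyletic when a single bipartition separates
  exactly its members (unrooted sense), with singleton and
  all-but-at-most-one groups flagged as trivially monophyletic.

Support audits (`count_supports_ge`, default threshold **70**) report how
many internal nodes reach the threshold plus the support range; on both
synthetic and real cohorts the concatenated ~3,300-residue alignment is
expected to yield more well-supported nodes than the ~1.5 kb 16S gene —
roughly twice the information content — and that qualitative contract is
what the package asserts, not any exact count.

## GC analysis

GC content is (G+C)/(A+C+G+T) with `N` excluded from numerator and
denominator; other ambiguity codes are rejected at parse time so the
denominator is never fuzzy. Genomes are classified into the genus's three
compositional bands — low [0.52, 0.567), medium [0.567, 0.613), high
[0.613, 0.66] — half-open on the right except the last; values outside the
band range clamp to the extreme classes with a warning, since the bands
only span the range observed in the genus. The per-gene trend analysis
counts, for each marker, the genomes whose marker GC lies below their
genome-wide GC; the expected picture in this genus is that most glycolysis
genes sit above the genome-wide value while `tpi` and 16S sit below it.
Median comparisons use the standard McGill notched-boxplot rule, median
± 1.57·IQR/√n with linear-interpolation quantiles, and call two medians
different when the notches are disjoint; this is strong-evidence
heuristics, not a formal test, and the package deliberately stops there.
Marker GC is computed on the whole CDS; codon-position GC (GC3) is out of
scope.

## The synthetic-data generator

`simulate_tree` draws a Yule (pure-birth) phylogeny: exponential waiting
times at total rate *k*·rate with *k* extant lineages, one further
exponential interval after the last speciation so pendant edges are
positive, leaves labelled in order of origin. `evolve_genomes` then

1. samples ancestral marker CDSs codon-wise at each marker's GC target,
   rejecting stop codons (start fixed `ATG`, stop `TAA`). Rejecting the
   AT-rich stops biases realized GC upward, so the per-base sampling
   composition is first calibrated by solving
   `expected_codon_gc(g) = target` — without this, low-GC markers like
   `tpi` drift to the genome-wide value and the compositional trend the
   analysis is designed to detect would vanish from the fixture;
2. evolves each gene along every branch with per-site substitution
   probability $1 - e^{-\mu b}$, replacement bases drawn from the marker's
   calibrated composition; substitutions creating internal stops are
   rejected and start/stop codons are frozen, so every leaf CDS remains
   translatable and both the nucleotide mining rule and the protein trees
   are exercised by one fixture;
3. assembles each leaf genome by shuffling the nine CDSs and the 16S gene
   onto random strands, separated by random intergenic segments whose
   base composition is solved exactly (integer GC counts) so the
   genome-wide GC hits its target within ±0.005.

Default conditions mirror the study system at desk scale: ten genomes;
marker lengths summing to 3,350 aa (real concatenations span roughly
3,200–3,500 aa); a 1,550 nt 16S gene at one fifth of the protein-gene
substitution rate (ribosomal conservation); substitution rate 0.05 per
site per unit branch length on a Yule(1) tree, giving within-genus-like
nucleotide identities around 0.8–0.95; genome-wide GC 0.60 (the genus
average) with marker targets 0.62 except `tpi` (0.57) and 16S (0.58); and
230 kb genomes — one tenth of the genus's ~2.3 Mb average — so a full
ten-genome study runs in about two minutes. The parameter-recovery checks
in the test suite evolve the full-length markers on a fixed, well-resolved
eight-taxon tree (internal edges 0.06–0.10) rather than a random Yule
draw, because recovery is only a meaningful contract when the true tree's
edges carry signal; the Yule generator itself is validated separately
(leaf counts, determinism, rate scaling of total length).

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: there is no indel evolution (alignment-
ensemble divergence is exercised by dedicated repeat-region fixtures
instead), no rate heterogeneity across sites or lineages, no horizontal
transfer or recombination, no annotation errors, and single-contig
genomes only. Mining on real draft assemblies (frameshifted or truncated
annotations, multiple rRNA operons) will be messier than on these
fixtures; the strict-mode errors and per-genome reports are designed to
surface exactly those cases for manual review rather than resolve them
silently. Likewise the package reports annotation conflicts and bootstrap
supports but does not arbitrate group reassignment of border taxa; that
judgement is left to the user.

## Degenerate inputs and edge policies

Empty sequences, alphabet violations, unannotated genomes (zero CDS),
length-not-divisible-by-3 CDSs, pairs with no shared ungapped columns,
trimming that would remove every column, and leaf-set mismatches between
compared trees are all hard errors with messages naming the offending
object. A tree without numeric supports audits to a count of zero with a
warning. GenBank compound (`join`) locations are supported by
concatenating exon spans in feature order; internal coordinates are
0-based half-open, GenBank I/O 1-based inclusive, and the conversion is an
involution.

## Problem sizes used in validation

The shipped test suite runs a six-genome, short-gene cohort for the
mining/alignment unit tests and one full-scale eight-genome cohort
(3,350 aa concatenation, 100 bootstrap replicates) for the end-to-end
parameter-recovery and support-audit contracts; the whole suite completes
in about three minutes on one CPU. `scripts/acceptance.R` re-runs the
ten-genome default study from a single seed and writes every headline
quantity it computes as JSON.
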