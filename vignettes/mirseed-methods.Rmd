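---
title: "Methods: rule-based miRNA discovery from small-RNA sequencing"
author: "mirseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based miRNA discovery from small-RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseed)
```

## Overview

`mirseed` re-implements, as a reusable and fully testable R pipeline,
the standard bioinformatics workflow used to discover and characterize
microRNAs in a non-model organism from a small-RNA sequencing library:

1. clean-read filtering with per-category accounting;
2. exact genome mapping and annotation triage of unique tags;
3. rule-based novel miRNA calling from hairpin precursor geometry,
   driven by an internal RNA secondary-structure MFE folding engine;
4. conserved miRNA identification from EST homology;
5. miRNA family clustering and neighbor-joining trees with bootstrap
   support;
6. positional-rule target prediction with cleavage versus
   translational-inhibition classification;
7. hypergeometric GO/KEGG term enrichment; and
8. bipartite miRNA-target network construction and export.

Every stage is exercisable without external data through the bundled
synthetic-data generator, which plants known ground truth.

## Clean-read filtering

Raw reads are assigned to exactly one category, tested in a fixed
order: low quality, 3' adapter null, insert null, 5' adapter
contaminant, shorter than 18 nt, poly(A); survivors are adapter-trimmed
clean reads. The accounting identity `clean = high_quality - sum of the
five removal categories` holds on every input, and percentages are
reported against the high-quality count, rounded half-up to two
decimals, matching the conventions of published accounting tables.

Published pipelines rarely define "low quality" precisely; here it
means any base below Phred 10 or more than one ambiguous base, and both
knobs are arguments. The 3' adapter is located by the best ungapped
suffix-prefix overlap of at least 6 nt with at most one mismatch; no
overlap is an adapter null, an overlap at the first position (an empty
insert) an insert null. A read starting with at least 8 nt of the 5'
adapter is a contaminant; at least 80% A after trimming is poly(A).
These are explicit, testable operationalizations of category names that
tools usually leave implicit.

## Mapping and annotation triage

Mapping is exact substring matching of each tag on both genome strands
(Biostrings dictionary matching), the strictest reading of short-read
alignment with no mismatch ambiguity, which also keeps the test oracle
(a sliding-window scan) trivial. A tag counts once in unique-read
totals no matter how many loci it hits; all loci are retained for
discovery.

Tags are given a single annotation label by fixed priority: known
miRNA, rRNA, tRNA, snRNA, snoRNA, repeat, then genomic context (exon
sense, exon antisense, intron, intergenic), else unannotated. Putting
known miRNAs first means they are counted before ncRNA removal; the
remaining order is conventional and overridable. Genomic intervals are
held as `GenomicRanges` objects (1-based closed coordinates, the
GFF3/Bioconductor convention) rather than a bespoke interval type.

## The folding engine

The MFE folder is a Zuker-style dynamic program over nested structures
with Watson-Crick and G:U pairs, written in C++ for speed. The energy
model is deliberately simple and fully declared, because a threshold
such as "MFE no more than -18 kcal/mol" is only meaningful relative to
a stated model:

* stacking: a 6x6 nearest-neighbor table over pair types AU, UA, CG,
  GC, GU, UG (Turner-style magnitudes), shipped as a TSV asset
  (`inst/extdata/stack_energies.tsv`) and replaceable by the user;
* hairpin loops: `5.0 + 0.3 (len - 3)` kcal/mol, minimum loop 3 nt;
* bulges: `3.0 + 0.5 len`; internal loops: `2.0 + 0.4 len`, capped at
  30 unpaired nt;
* multibranch loops: `4.6 + 0.9 per branch + 0.1 per unpaired nt`;
* lone pairs disallowed (minimum helix length 2).

The whole model travels as a plain list, so any parameterization can be
plugged into every structure-dependent rule. A degenerate "unit" model
(-1 per pair, all penalties zero, lone pairs allowed) reduces the DP to
Nussinov base-pair maximization, which the test suite cross-checks
against an independent Nussinov implementation; the full model is
cross-checked against exhaustive enumeration of all valid structures of
short sequences. Ties between equal-energy structures are broken by a
fixed, documented traceback order (helix options before unpaired
extensions, 5'-most first), so folding is deterministic; we do not
additionally guarantee the maximum-pair structure among ties.

Hybridization energy of an ungapped miRNA:target duplex sums the same
stack table over adjacent paired columns (G:U pairs); unpaired columns
contribute nothing, so an all-mismatch duplex scores zero. Loop
penalties are intentionally omitted from this duplex score: it is a
complementarity-weighted score, not a full two-strand partition
function.

## Novel miRNA calls

A candidate is an unannotated tag of 18-25 nt, expressed at or above 5
copies (configurable; the floor suppresses degradation noise), mapped
to exon-antisense, intronic or intergenic space. At each locus,
precursor windows extending the tag by every pair of flanks from
{20, 60, 100, 150} nt are excised on the tag strand and folded. A
window passes when

1. the MFE structure is a single stem-loop (exactly one terminal
   hairpin loop, no multibranch loop);
2. the mature/star duplex has at most 2 nt of terminal overhang at
   either end;
3. no loop or bulge larger than 4 nt lies inside the duplex; and
4. the fold MFE is at most -18 kcal/mol (inclusive).

The star arm is derived computationally as the pairing-partner range of
the mature positions; an observed star read is not required, since star
strands are usually degraded. The lowest-MFE passing window is
reported. The flank sweep is a documented design choice: precursor
excision policies differ between published tools and are rarely stated;
a small sweep with a best-window rule is explicit and reproducible.

G:U wobble is treated context-dependently: inside folded structures it
pairs (thermodynamics), while in sequence-identity rules (EST homology,
target complementarity) it counts as a mismatch. This follows the
strict "complementarity" wording of the positional rules while keeping
folding realistic; a configuration switch offers the half-mismatch
alternative for target scanning.

## Conserved miRNAs from ESTs

Each EST is scanned on both strands against every reference mature
(18-25 nt) for ungapped windows with at most 3 sequence mismatches.
The EST context of a matching window is folded over the same flank
sweep; the candidate is accepted when the context forms a single
stem-loop whose star arm leaves at most 3 mature positions unpaired,
and the window is not a substring of any exclusion reference
(rRNA/tRNA and other non-miRNA sets). The ungapped mismatch scan is our
operationalization of a BLAST-based homology search whose word size and
E-value were not part of the published rule set; the acceptance rule
itself (mismatch count, length, exclusion, stem-loop) is implemented as
stated. Known miRNAs, by contrast, are counted by database identity
alone, without re-folding.

## Families and trees

Two miRNAs are linked when their best ungapped end-free alignment
(identity maximized over all offsets) reaches 98% identity with at most
2 mismatching columns; families are connected components of this
relation. Single linkage is the simplest closure of a pairwise
criterion; with 98% identity on 18-25 nt sequences the identity
threshold, not the mismatch count, is binding (2 mismatches on 21 nt is
only about 90%), but both are enforced as stated. Identity is taken
over aligned columns of the best offset; pairwise rather than
multiple-alignment-column identity is a documented choice.

Trees are canonical neighbor joining (via `ape::nj`) on p-distances
(1 - identity). Bootstrap support resamples columns of a right-padded
alignment with replacement, rebuilds the NJ tree, and tallies splits of
the reference topology; the default is 1,000 replicates, and tests use
fewer for speed. The padded alignment is a deliberate simplification:
family members under the 98% rule are nearly identical, so a full
multiple aligner would change little; topology, not branch length, is
the supported output.

## Target prediction

An ungapped antiparallel scan slides each miRNA over each transcript
(sense orientation). A window of miRNA length passes the strict rules
when: at most 4 mismatches overall with at most 1 in positions 1-9 and
none at 10-11 (positions numbered from the miRNA 5' end); a perfect
duplex across positions 8-12; no indels (guaranteed by the gap-free
scan); terminal overhangs of at most 1 nt (zero by construction, since
the window is flush with the miRNA); and duplex energy strictly below
-18 kcal/mol.

The strict rule set forbids central mismatches, yet translational
inhibition is classically diagnosed by a mismatch in the central region
(positions 9-11). We resolve this tension explicitly: a relaxed scan
drops only the central-perfection rule, and sites are classified as
translational inhibition when positions 9-11 contain a non-Watson-Crick
column (in practice position 9, since 10-11 remain constrained). Both
strict and relaxed site tables are returned, labeled; summaries use the
strict set and the network uses the relaxed set so that inhibition
edges are represented.

## Enrichment

For each term with at least one candidate gene, the upper-tail
hypergeometric probability P(X >= m) is computed from (N, M, n, m),
where N is the number of annotated background genes, n the annotated
candidates, M the genes carrying the term and m the candidates carrying
it. The inclusive tail boundary (>= m) is the canonical choice for
these variable definitions. GO uses Bonferroni control, KEGG uses
Benjamini-Hochberg FDR, both at 0.05 by default and both via
`p.adjust`. Terms with m = 0 are untestable and excluded from the
correction count. Annotations are counted as given; no GO-hierarchy
propagation is performed.

## Network

One directed edge per distinct (miRNA, gene) pair; an edge is
translational-inhibition when any supporting site is. Bipartiteness is
asserted on every build. "Most enriched network" notions are
operationalized as maximum miRNA degree and largest weakly connected
component. Export formats are SIF and GraphML (igraph), both
re-importable.

## The synthetic-data generator

The generator emulates the statistical shape of a small-RNA study so
the pipeline can be validated against planted truth:

* a random genome (default two 25-kb contigs) with regularly spaced
  two-exon gene models on alternating strands, the rest intergenic;
* 28 planted hairpins (20 "novel", 8 "known", the latter also present
  in the known-miRNA reference set), built constructively as
  mature + A/C loop + reverse complement so criteria satisfaction is by
  design, then re-verified in genomic context (flanks included) at
  generation time, redrawing on failure;
* mature lengths drawn from {20..23} nt peaking at 21-22;
* log-normal expression (meanlog 6.5, sdlog 1) scaled so mature reads
  are half of the default 50,000-read library, with 30% decoy
  t/r/sn/snoRNA fragments and 20% uniform degradation fragments;
* adapter-defect reads at configured rates exercising every filter
  category; every insert is screened so adapter trimming recovers it
  exactly, making the generator's category ledger an exact oracle for
  the filter report;
* ESTs embedding near-copies (1 mismatch) of unexpressed reference
  matures inside hairpin contexts; transcripts carrying planted
  perfect-complement target sites plus a few single-mismatch
  (position 9) sites in translational-inhibition geometry;
* gene-to-GO/KO maps in which one designated term is assigned to
  target genes at 90% and to background genes at 5%, so enrichment
  should rank it first.

Everything is fixed by one seed; the same configuration reproduces
byte-identical outputs. What the generator does *not* emulate: sequence
composition bias, realistic transcriptome structure, isomiR
heterogeneity, sequencing error beyond the planted defect classes, and
multi-mapping repeat structure. Passing the planted-truth tests
therefore demonstrates correctness of the pipeline's logic under its
stated rules, not discovery performance on real libraries.

## Numerical and scale choices

* Percentages in report tables round half away from zero (base R
  `round` is half-to-even) to match the published accounting style.
* Folding tolerance in oracle comparisons is 1e-6 kcal/mol.
* The acceptance script and tests run the default study (50-kb genome,
  28 hairpins, ~52,000 raw reads), which completes in about two
  minutes on one core; oracle-equivalence suites use 10-18 nt
  sequences for exhaustive enumeration and 30-mers for the Nussinov
  cross-check, sizes at which enumeration is exact yet fast.
* Degenerate inputs: empty read sets yield all-zero reports; empty
  site tables yield empty networks; transcripts shorter than a miRNA
  yield no sites; fewer than 3 taxa is an error for neighbor joining.

## Known limitations

The energy model is simplified (no dangles, no terminal-AU penalties,
no tetraloop bonuses, no temperature dependence), so absolute MFE
values differ from full Turner-model folders; the -18 kcal/mol
thresholds apply to this declared model. The EST scanner is ungapped;
true homologs with indels would be missed. No probabilistic scoring of
precursors (miRDeep-style) is attempted, and degradome support for
target sites is out of scope.
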