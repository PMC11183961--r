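---
title: "Methods: taxonomy, normalization and siderophore pathway calling in ironmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxonomy, normalization and siderophore pathway calling in ironmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ironmeta profiles iron-acquisition genes in assembled metagenomes sampled
over time. This vignette explains the statistical procedures the package
implements, the choices behind their defaults, and what the bundled
synthetic study can and cannot demonstrate.

## Thresholded LCA classification of ORFs

Each predicted ORF arrives with a table of protein-homology hits (the
12-column tabular alignment layout), each hit carrying a percent identity,
bitscore, e-value and, via a lookup, a subject taxon. Classification
proceeds in three steps.

**Valid-hit selection.** Hits with e-value above `evalue_cutoff` (default
1e-3) are discarded. The best remaining hit is the one with maximal
bitscore; ties break by lower e-value, then higher identity, then input
order, so output is deterministic. Valid hits must reach at least 80% of
the best hit's bitscore and sit inside an identity window around the best
hit's identity. The window is applied *relatively* by default (identity at
least 10% of the best hit's identity), which is a deliberately weak filter;
because that wording is ambiguous in common usage, `lca_params(identity_mode
= "absolute")` switches to the stricter reading (within 10 percentage
points of the best identity). The default stays with the literal relative
rule.

**Support.** Walking ranks from species up to superkingdom, the classifier
looks for a taxon at each rank claimed by at least 90% of the valid hits
(`support_fraction`). The comparison is `count >= fraction * n` with a tiny
epsilon, so the natural boundary case — 9 agreeing hits out of 10 — passes.
Hits whose subjects carry no taxon label stay in the denominator: they are
bona fide valid hits that support nothing, which conservatively prevents a
single labeled hit among many unlabeled ones from forcing a deep
assignment. The candidate assignment is the deepest supported rank.

**Identity floors.** A minimum best-hit identity is required to *report* an
assignment at each rank: 85, 60, 55, 50, 46, 42 and 40 percent for species,
genus, family, order, class, phylum and superkingdom. If the candidate rank
fails its floor, the call moves up the candidate's lineage to the deepest
rank whose floor the identity meets; below 40% the ORF is unclassified.
The identity compared is the best valid hit's (configurable to the median
of valid-hit identities via `floor_identity = "median"`).

## Consensus contig taxonomy and read fractions

A contig inherits a taxonomy from its ORFs by a top-down walk with parent
consistency: at each rank, a taxon qualifies when it is claimed by at least
50% of *all* the contig's ORFs (annotated or not) and at least 70% of the
ORFs annotated at that rank, and its parent is the taxon chosen at the
previous rank. The consensus is the deepest rank reached before the rule
first fails; failing already at superkingdom leaves the contig
unclassified. Unclassified ORFs count toward the total but never toward
the annotated denominator. Community composition is then the fraction of
mapped reads per taxon, rolling each contig's consensus up to the target
rank, with an explicit unclassified bucket so fractions always sum to one.

Contig taxonomy drives *global* abundances; per-ORF taxonomy drives the
taxonomic breakdown of particular gene categories. This mirrors the
two-level design of assembly-based profiling: contigs integrate evidence
over genes, but a function's host is best read off the gene itself.

## Copy numbers per genome

Coverages (mean aligned depth per base, taken as input; the mapping stage
is out of scope) are normalized by the median aggregate coverage of ten
universal single-copy marker genes. Since these housekeeping genes occur
once per genome in essentially all prokaryotes, their median coverage
estimates "genomes sequenced", and `coverage / marker_median` is the
average copy number of a feature per genome in the community. The marker
aggregate per COG is the *sum* of its ORFs' coverages (configurable to the
mean); markers with no detected ORF contribute an aggregate of zero, and a
profile whose marker median is zero cannot be normalized and errors. Copy
numbers are exactly invariant under global rescaling of a sample's
coverages, and a category's copy number is the sum over its member COGs.
The identity of the ten marker COGs is a configuration input; the bundled
study uses ten placeholder identifiers (`COG5501`–`COG5510`).

## Iron-function categories and pathway calls

A small closed vocabulary groups iron-related COGs: ferrous iron ABC
transporters, TonB-dependent outer-membrane ferric-siderophore receptors,
cell-membrane ferric-siderophore ABC transporters, divalent-cation ABC
transporters, dicitrate and heme transport, storage, regulators, and
siderophore synthesis. Each ORF gets the COG of its best qualifying hit;
ORFs outside the catalog form an implicit non-iron pool, so the category
sizes partition the input.

Siderophore biosynthesis pathways are held as a pathway–gene–COG multi-map:
a gene may carry several COG signatures (a dhbE-like ligase sits in both an
AMP-dependent-synthetase COG and a dedicated ligase COG) and a COG may
serve many pathways (a promiscuous NRPS family). Presence calling uses
three rules: a pathway *may be* present when every gene has at least one
detected signature; it *is* present when, additionally, at least one
detected signature is unique to that pathway (and not flagged ambiguous);
and it is absent as soon as any gene is missing. Uniqueness is derived
from the network, never read from the file. "Unique to this pathway" is
operationalized at COG level because detection is COG-based — the
gene-level reading cannot be evaluated from COG profiles. A gene with
several COGs counts as present if any of them is detected, treating
multi-COG membership as alternative signatures of one gene. The detection
floor defaults to any nonzero coverage, as no abundance threshold for
presence is defensible a priori.

Ambiguous COGs — families conflating siderophore enzymes with unrelated
ones, flagged as a curation input since the underlying database curation is
not recomputable here — still satisfy gene presence, but are excluded from
the quantitation of synthesis copy numbers. The reported synthesis copy
number is therefore a deliberate underestimate. Study-level pathway status
is the best status across samples (PRESENT > MAYBE > ABSENT), which covers
both the per-sample and the pooled reading of presence; both tables are
reported.

## The synthetic study

The simulator generates a ground-truthed mock study at desk scale. The
default scenario runs thirteen chronological samples in which a
Bacteroidetes flavobacterium blooms from a 9% to a 55% read fraction along
a logistic trajectory while an alphaproteobacterium recedes (36% to 21%),
a gammaproteobacterial clade stays near one fifth, a thaumarchaeon all but
disappears (12% to 0.5%) and two minor phyla decline — the qualitative arc
of a polar spring-to-summer transition. Sequencing effort defaults to 1e5
mapped reads per sample and per-ORF coverage noise to a lognormal with
coefficient of variation 0.1 (mean-preserving; strictly positive with a
heavy-ish tail, controlled by a single parameter); both are scenario
defaults a desk-scale benchmark can afford while keeping multinomial error
well below the recovery tolerances. `base_depth` (100) sets the coverage
scale and cancels out of every copy number.

Genomes realize a producer/cheater split: the gammaproteobacterium carries
the full signature set of eight recoverable pathways (plus all but one
gene of an amphibactin-like pathway, so that pathway is called absent for
the right reason), while the blooming Bacteroidetes carries transport
genes only, including a single-copy fhuA-like receptor whose recovered
per-genome copy number should be 1. Hit tables are constructed to be
recoverable by design: true hits point at the species under the ORF's true
genus with identities drawn uniformly between the genus and species floors
(61–84%), so the classifier lands exactly at genus; decoys point at a
sister genus with bitscores below the 80% window, exercising valid-hit
selection without corrupting the answer. With `noise_cv = 0` and
`reads_per_sample = Inf` every estimate equals truth exactly, which the
tests use as a fidelity check.

What the simulator does *not* emulate: sequence-level error, assembly
fragmentation and chimerism, classification error from incomplete
reference databases, strain-level variation, and compositional artifacts
of real mapping pipelines. Passing recovery tests therefore demonstrates
the correctness of the downstream statistics, not the robustness of
upstream annotation on real data.

## Numerical choices and degenerate inputs

Threshold comparisons use `>=` with an epsilon of 1e-9 so exact rational
boundaries (9/10 support, bitscore exactly 80% of best, identity exactly
at a floor) behave as stated regardless of binary floating-point
representation. All tie-breaks (best hits, supported taxa, consensus
candidates) resolve by count, then lexicographically, making every output
deterministic. Empty hit files parse to empty tables; malformed rows fail
with their line number; taxonomy cycles, duplicate roots and missing
parents are structural errors; an empty pathway table is rejected; zero
mapped reads and an all-zero marker profile are errors rather than NaNs.

## Problem sizes used in verification

The test suite checks the LCA classifier against a brute-force
node-by-node oracle on ~10,000 generated hit tables (up to 6 hits over a
29-node tree, identities on a grid at every rank floor ±1), the consensus
rule against direct evaluation on all ~3,000 compositions of up to 10 ORFs
over five assignment options, and the pathway classifier against full
enumeration of present-COG subsets on three toy networks. Parameter
recovery runs the default scenario across 100 seeds and requires phylum
fractions within ±2 percentage points of truth in at least 95% of
replicates, the single-copy receptor's mean recovered copy number within
±10% of 1, at least 95% of unambiguous synthesis coverage attributed to
the producer clade, and the cheater's share of the ferric-siderophore
receptor category within ±5 points of its simulated share. These sizes
were chosen as the smallest that exercise every rule exhaustively or tie
down the estimators' sampling error well below the tolerances.

## Known limitations

The LCA support rule is evaluated per rank independently; pipelines
differing in whether support is required only at the reported rank can
disagree on contrived inputs. Whether unlabeled-subject hits belong in the
support denominator is a genuine ambiguity; the conservative inclusion
used here can only make calls shallower. The marker aggregate uses the
coverage sum over ORFs of a marker COG, which assumes fragmented marker
genes rather than paralogs; `agg = "mean"` is available where that
assumption fails. Pathway presence is qualitative: a pathway split across
strains, or present below the detection floor, is invisible by
construction.
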