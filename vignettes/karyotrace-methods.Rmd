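---
title: "KaryoTrace: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KaryoTrace: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KaryoTrace)
```

## The problem

Crucifer genomes descend from an inferred eight-chromosome ancestral
karyotype whose chromosomes are partitioned into 22 conserved genomic
blocks, labelled with letters A through X. Because the blocks are defined
by ordered reference gene sets, a descendant genome can be interpreted
against the ancestor purely from gene order: syntenic gene pairs are
chained into syntenic fragments, the fragments are projected onto blocks,
and the resulting block copy numbers, block adjacencies ("associations")
and per-chromosome block composition diagnose whole-genome duplications,
chromosome fusions and rearrangements. KaryoTrace implements that chain
of inference, together with the companion analyses typically run beside
it in a polyploid genome study: subgenome partitioning with gene
retention and homoeolog expression dominance, synonymous-rate (Ks)
dating of the duplication, and a glycosyltransferase candidate screen
combining a PSPG-motif scan with expression–metabolite correlation.

All analyses run end-to-end on a bundled forward simulator of karyotype
evolution, which produces every input with ground truth attached, so the
whole pipeline is testable as a parameter-recovery exercise.

## Synteny detection and fragment chaining

A homolog pair (a, b) counts as *syntenic* when at least `minSupport`
(default 2) other homolog pairs lie within `flankWindow` (default 20)
gene ranks of *a* and of *b* on the same chromosome combination —
collinear flanking support. Surviving pairs are deduplicated to the
best-supported pair per gene *within each chromosome combination* (ties:
similarity, then gene id). Deduplicating per chromosome combination
rather than globally is deliberate: in a tetraploid each ancestral gene
must keep one syntenic partner per subgenome copy, which live on
different chromosomes; a global best-pair rule would erase one copy and
halve every block copy number.

Fragment chaining applies the consolidation rule: two pairs are merged
when, **in both genomes**, they are separated by *fewer than 50*
intervening genes (strict) *or by at most 300 kb* (inclusive, measured
between the nearest ends of the boundary gene models). Candidate links
are adjacencies in the gene order of either genome, and fragments are
the closure of the link relation (union–find). Defining links over both
gene orders makes the relation — and therefore the fragment membership —
exactly symmetric under swapping the two genomes; on collinear data it
coincides with chaining along one genome. The one-genome variant of the
rule (`bothGenomes = FALSE`) is available because the published wording
does not say in which genome the separation was measured; requiring both
is the conservative default.

Fragment orientation is called `same`/`inverted` when at least 90% of
consecutive member pairs agree in rank direction, else `mixed`. Strand
is carried through but ignored by the chaining rule, which is stated in
terms of gene counts and distance only.

## Block projection, copy number and events

Within a fragment, member genes are ordered along the descendant
chromosome and labelled with their ancestral partner's block; maximal
runs of one label become candidate projections. Runs below
`minGenesPerCall` (default 5) are dropped — the minimum evidence for a
block copy is not stated in the source analyses, and 5 genes suppresses
single-gene artefacts while staying far below any realistic block size.
Same-label projections on one chromosome separated by less than the
chaining gap are merged, which reunites a block split across fragments.
Purity is the fraction of the fragment's genes carrying the projected
label; unlabelled partners lower purity but never fail a call.

Copy number is simply the number of surviving projections per label
(absent labels are reported at 0). Associations are unordered adjacent
label pairs along each chromosome, compared with the ancestral adjacency
list as a plain intersection fraction. Chromosome events: ancestral
chromosomes contributing at least `minFraction` (default 10%) of a
descendant chromosome's projected span are its contributors — one
contributor is an intact inheritance, two or more a fusion. The 10%
floor keeps small translocations from being mistaken for fusions. A
rearrangement flag is raised when a contributor's blocks are not
monotone in ancestral order or not contiguous along the chromosome; an
inversion confined to the interior of a single block is invisible to
this order-based flag, a known limitation.

One behaviour worth knowing: a long inversion whose breakpoint falls
mid-block can strand the two halves of that block further apart than the
chaining gap, in which case the label legitimately projects twice. With
the simulator's default random inversion (10–30% of the fused
chromosome) this happens for a minority of seeds; it is a property of
the method under mid-block breakpoints, not an artefact.

## Subgenomes, retention, dominance

Homoeologous chromosomes are paired by shared syntenic-pair counts using
greedy heaviest-edge matching — with at most 14 chromosomes and
homoeolog weights far above background, the greedy matching is the
maximum-weight one in practice. Within each pair the chromosome with
higher gene density (genes/Mb) is assigned to subgenome DsA, the partner
to DsB; exact ties fall back to name order with a warning, and an
optional linkage-group majority vote can override per-pair assignments.

Retention is the fraction of ancestral genes with at least one syntenic
partner in a subgenome, reported globally and in sliding windows
(default 100 genes, step 50) along each ancestral chromosome.

Expression dominance uses the linear TPM ratio
`(tpmA + c) / (tpmB + c)` with pseudocount `c = 0.1` (stabilizes
near-zero expression; the source analyses do not state one), replicates
averaged before the ratio. At each fold threshold f in 1..8 a pair is
A-dominant when the ratio exceeds f (strict, so f = 1 already excludes
exactly balanced pairs) and B-dominant symmetrically; "greater than 1-
to 8-fold" is read as linear thresholds, with a log2 mode available
because the published phrasing is ambiguous. Subgenome bias is probed
with a two-sided binomial sign test (null 0.5 over dominant pairs) — the
source states the absence of a significant imbalance without naming a
test, and the sign test is its most direct operationalization.

## Ks estimation and peak detection

Synonymous divergence uses the Nei–Gojobori (1986) codon-counting
method: per-position synonymous site fractions from the standard genetic
code (changes to stops count as nonsynonymous), site counts averaged
over the two sequences, and per-codon differences averaged with equal
weight over all minimal mutational pathways, excluding pathways through
stop codons (falling back to all pathways in the degenerate case where
every pathway crosses a stop). Multiple hits are corrected with
Jukes–Cantor, `Ks = -(3/4) log(1 - (4/3) ps)`; `ps >= 3/4` is a
saturation error for a single pair and an NA in batch mode. NG86 is the
concrete estimator because the source names only a Ka/Ks toolbox, not a
model; codons containing alignment gaps are dropped pairwise, ambiguity
codes are rejected.

The Ks distribution is summarized by a Gaussian kernel density on a
fixed grid (0 to 3, step 0.005) after discarding estimates above 3
(saturated tail). Bandwidth defaults to Silverman's rule with a fixed
numeric override for reproducibility. The main peak is the grid argmax;
secondary peaks must be local maxima at least 0.1 Ks from a higher peak
and at least 10% of the maximal density.

## Candidate screen

The PSPG scan slides a 44-residue window and scores the five anchor
residues of the plant secondary product glycosyltransferase box (W1, Q4,
H19, S24, E27); windows with at least 4 of 5 anchors are reported, with
overlapping windows collapsed to the best per protein. The anchored scan
is the self-contained stand-in for a profile-HMM search: it exercises
exactly the residues reported as catalytically critical, and external
HMM/BLAST hit tables can be substituted where available. Motif start
positions are reported 1-based, the R/Bioconductor convention.

The correlation screen computes Pearson r between each candidate's
expression and the target metabolite total (by default the sum of the
two monoglucosides), with the exact two-sided t-transform probability
`t = r sqrt((n-2)/(1-r^2))` on n−2 degrees of freedom, and passes genes
with `r > 0.75` and `p < 1e-05`. With few samples that probability
threshold is extremely stringent; it is applied as configured rather
than rationalized. Fold statistics report mean ratios with
nearest-integer rounding (halves away from zero) and flag compounds
whose ratio exceeds 4 or falls below 1/4 (the one-fourth rule); a zero
denominator yields an infinite-fold sentinel, flagged but not an error.

## The simulator: what it emulates, what it does not

`buildAncestralKaryotype()` lays 22 blocks over 8 chromosomes following
a bundled layout table. The published analyses state the number of
blocks and chromosomes but not the letter-to-chromosome layout, so the
bundled table is a synthetic stand-in: the classical 24-letter layout
with the adjacent pairs M+N and O+P merged (letters N and P unused).
Every downstream quantity depends only on block membership and order,
never on which letter sits where.

Gene coordinates live on a uniform grid — 10 kb per gene slot, 2 kb gene
length by default — because the chaining rule mixes gene counts and
physical distance; the grid makes both halves exercisable and lets gene
loss open real physical gaps. Events (fusion, inversion, translocation,
whole-genome duplication, per-gene loss) each draw from an RNG stream
derived from the scenario seed and event index, so appending an event
never perturbs earlier ones. Duplication is autotetraploid-style whole
doubling, and "rearranged after fusion" defaults to one inversion over a
random 10–30% of the fused chromosome — the published account says only
"rearranged", so the operation is a modelling choice exposed in the
scenario.

Expression draws a log-normal family baseline, a per-family tissue
effect, and a per-homoeolog-pair log2 ratio from N(biasMean, biasSd);
bias mean 0 encodes the no-dominance null. Planted screen genes override
this with an affine function of a metabolite total plus Gaussian noise.
Codon alignments are built from codons with fourfold-degenerate third
positions and mutated under Jukes–Cantor at rate `trueKs` on third
positions and `trueKa` (default `trueKs/5`) on the first two, redrawing
mutations that would create an in-frame stop; the expected corrected
synonymous distance equals `trueKs` by construction.

What the simulator does not model: nucleotide-level assembly, repeats
and TEs, read-level noise, tandem duplication, segmental (non-whole)
duplication, expression count noise (TPM values are treated as given,
as they are inputs to the real analyses), codon usage bias, and
selection heterogeneity along sequences. Passing recovery tests
therefore shows the inference machinery is correct under clean,
grid-coordinate, family-labelled homology — not that the pipeline is
robust to annotation error, fragmented assemblies or homology
mis-assignment in real data.

## Problem sizes and tolerances used by the test suite

The packaged tests run the karyotype recovery at 22 blocks × 50 genes
(1100 ancestral genes; tetraploid 4400), retention and dominance at 100
genes per block with 5% per-subgenome loss, dominance null calibration
over 25 expression seeds (requiring at least 60% of seeds
non-significant at every threshold — the joint probability of eight
correlated null tests all exceeding 0.05 is well below the per-test
95%), and Ks recovery on 2000 pairs of 300 codons at true Ks 0.12 with
the peak required inside 0.11–0.13. Oracle-equivalence properties
(chaining vs an independent transitive closure, NG86 vs an exhaustive
pathway enumerator) run on instances of up to 200 genes and 50 codons,
where exhaustive enumeration is exact and fast.
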