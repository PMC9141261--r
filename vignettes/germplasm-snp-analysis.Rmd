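---
title: "Methods: SNP-array diversity and functional-allele analysis of germplasm collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-array diversity and functional-allele analysis of germplasm collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpkit)
```

This vignette is the package's account of the methods it implements and of
the design choices that were genuinely open. The setting is a germplasm
collection of inbred crop varieties — the motivating case is a highland
rice panel of ~150 landraces, a few wild *Oryza* accessions and a control
variety — genotyped on a dense biallelic SNP array (~44k markers over 12
chromosomes; the package's synthetic profile works at ~1/20 of that scale).

## Genotype model

A genotype is an **unordered diploid call**: two allele characters from
`{A,C,G,T,I,D}` in alphabetical order, or `"NN"` for missing. Phase is
never observed on an array and never used by any analysis here, so `"GA"`
and `"AG"` are the same call and are canonicalized on ingest. The `I`/`D`
symbols encode indel markers (insertion/deletion relative to the
reference), which lets a single comparison engine handle SNP and indel
functional markers alike. Multi-allelic behavior is treated as a defect:
the array is biallelic by design, and markers with more than two observed
alleles are flagged and fail the MAF filter.

## Marker QC

Per-marker statistics are computed once on the full sample set:

* `missing_rate` = missing calls / samples;
* `het_rate` = heterozygous calls / non-missing calls;
* `maf` = lesser allele frequency, counting two copies per homozygote and
  one of each per heterozygote; undefined for all-missing or multi-allelic
  markers.

A marker is kept iff **all** of GenTrain > 0.5, missing rate < 0.20, het
rate < 0.05 and MAF > 0.05 hold, with *strict* inequalities — these are the
thresholds as conventionally printed for such arrays, and printing them as
strict operators is taken literally, so a GenTrain of exactly 0.5 fails.
The four filters are applied jointly to statistics computed once, never
sequentially re-computed, which makes the result independent of marker
order and of the order the criteria are listed in; a marker failing several
criteria is tallied under each. Missing GenTrain and undefined MAF fail
their criteria (conservative). Tightening any threshold can only shrink the
kept set, a property the test suite asserts.

Gap statistics are computed within chromosomes only; "fraction of gaps
shorter than *t*" is a strict inequality, matching the usual phrasing of
array density reports. Marker density uses half-open 100-kb windows
`[k·w+1, (k+1)·w]` whose counts sum to the number of mapped markers.

## Distance and tree

The distance between two lines is the **polymorphic-SNP ratio**: the
proportion of pairwise-complete markers (non-missing in both lines) at
which the canonical calls differ, a heterozygous call being a distinct
state. Two interpretation choices were open:

* *Missing data.* Whether published pipelines drop all markers with any
  missingness or use pairwise-complete markers is usually unstated;
  pairwise-complete is chosen (and the supporting marker count `n_valid`
  is reported per pair) because it wastes no data and keeps each pair's
  denominator explicit. A pair sharing no complete marker has no defined
  distance and is an error, not an `NA`.
* *Het weighting.* The plain reading of "ratio of polymorphic SNPs" is a
  full mismatch whenever calls differ; that is the default. An
  `allele-sharing` mode (half mismatch when calls share exactly one
  allele, a common IBS convention) is available behind a flag for users
  who want distances less sensitive to residual heterozygosity.

The tree is canonical neighbor joining with the Studier–Keppler $O(n^3)$
selection criterion — the standard "improved" formulation of NJ. Published
pipelines sometimes cite variance-weighted variants (BIONJ-family) without
giving formulas; canonical NJ is implemented because it is the
reconstruction-consistent baseline whose behavior is fully testable: on an
additive matrix it must reproduce the generating topology and branch
lengths exactly, which the suite checks against an exhaustive least-squares
oracle over all topologies (n ≤ 6) and by path-length identity up to 12
taxa at 1e−9. Branch lengths of real (non-additive) data therefore need not
match any particular published figure. Numerical conventions: Q-ties break
to the smallest (row, column) pair in current matrix order (new nodes rank
last); negative branch lengths are clamped to zero with the pre-clamp value
logged on the tree, since downstream Newick consumers expect non-negative
lengths; the final two nodes are joined by a single edge, so every internal
node has degree three.

Newick export is deterministic — six-decimal branch lengths, children
ordered by smallest descendant leaf label, labels quoted when they contain
blanks or syntax characters — so identical analyses are diffable.

**Group extraction.** Collections are reported as *k* groups, but cluster
extraction rules are rarely stated in publications. The package removes the
k−1 longest internal edges (ties by edge index) and labels the resulting
leaf components I, II, … by decreasing size. This is deterministic,
testable, and recovers planted structure. In the degenerate regime where
k−1 exceeds the number of internal edges (k near the leaf count, e.g. the
k = n singleton case), the longest remaining edges whose removal still
separates leaves are cut greedily; this extension only matters beyond the
useful range of the method.

## Background maps

Per line and chromosome, calls are classified hom/het/missing and the
chromosome is tiled by hom/het fragments:

* missing calls are transparent (runs are defined over non-missing calls) —
  the graphical-genotyping convention draws only two colors;
* het runs shorter than `min_run` calls (default **3**) are absorbed into
  the homozygous context: an isolated het call is far more likely a
  clustering artifact than a real residual fragment, while three
  consecutive het calls at typical marker spacing already span tens of kb.
  `min_run = 1` disables smoothing; absorbed counts are reported;
* fragment boundaries sit at the inter-marker midpoint (rounded down), and
  terminal fragments extend to bp 1 and the chromosome end, so fragments
  tile the chromosome exactly and bp fractions are well defined;
* a chromosome with no usable call becomes a single hom fragment flagged
  low-confidence.

The per-line heterozygosity profile is het bp / chromosome bp (and genome
wide). Because boundaries are midpoints, a planted het block's recovered bp
can differ from the planted span by at most about one inter-marker gap per
block edge — the suite asserts exactly that bound. Chromosome lengths are
configuration (the 12 rice chromosome lengths of the IRGSP-1.0 assembly
ship as the default table), not hard-coded logic.

## Functional alleles

A gene is called per line by comparing its calls at the gene's markers to a
**representative haplotype**:

* missing fraction > `max_missing` (default **0.2**, mirroring the
  marker-level missing filter; no per-gene rule is ever published) →
  `undetermined`; a gene with no usable call is also undetermined;
* any non-missing het call → `heterozygous` — favorable alleles in
  breeding are fixed alleles, so het lines are reported separately and are
  not counted favorable (nearly moot in inbred cohorts);
* otherwise the line *matches* iff all non-missing calls equal the
  representative's, and the call is `favorable` when the match agrees with
  the representative's orientation. The orientation flag exists because
  published catalogs mix representatives carrying the favorable allele
  (match ⇒ favorable) with donors known to carry the unfavorable allele
  (mismatch ⇒ favorable).

Cohort percentages are rounded **half-up to one decimal**, the convention
of printed breeding tables (banker's rounding would disagree on exact
halves). The denominator is explicit: the default counts every evaluated
sample (undetermined and heterozygous included), with a `determinate`
alternative — published tables for the same collection are not always
consistent about whether wild accessions and the control are in the
denominator, so the policy is a visible knob rather than a hidden choice.
Per-variety favorable counts are summarised over bins 0/1/2/3/4+, and
co-occurrence of a gene set is the share of lines favorable for *all*
members, which can never exceed the minimum member frequency.

## The synthetic collection generator

Raw genotypes of the motivating collections are not deposited, so the
generator defines the study conditions the package is exercised under:

* ~2,000 markers placed uniformly per chromosome (allocation proportional
  to chromosome length), 43 samples in three groups — the desk-scale
  mirror of a 44k × 158 panel;
* a shared base haplotype of homozygous calls; each group founder flips a
  `p_div = 0.2` fraction of markers to the alternate homozygote; each
  variety flips a `p_within = 0.02` fraction of its founder. Expected
  within-group distance is then ≈ 2·p_within and between-group distance
  ≈ 2·p_div(1−p_div), so planted groups are recoverable whenever
  p_div ≫ p_within;
* group 1 is the **wild-dominated group**: the wild accessions (het call
  fraction drawn from [0.2, 0.6]) plus a couple of companion varieties
  with elevated heterozygosity ([0.1, 0.3]). Real collections behave this
  way — the wild material and a few heterogeneous varieties cluster
  together as the most divergent group — and a generator that instead
  scatters wilds inside a large cultivated group plants a truth the tree
  correctly refuses to reproduce: NJ isolates the high-het samples on a
  long internal edge before it separates cultivated groups;
* inbred varieties receive residual het *blocks* (5–15 consecutive
  markers) totalling a genome-bp fraction drawn from [0, 0.05], recorded
  as ground truth for segmentation tests;
* one near-duplicate cluster of three "introduced" varieties (mutual
  divergence 0.002) emulates elite material genotyped under several names;
* gene markers are appended complete, homozygous and missing-free, with
  the representative haplotype planted in an exact number of carriers, so
  planted frequency reports are exact by construction; background markers
  get 2% missing calls;
* all randomness flows from one seed: a configuration is a deterministic,
  byte-identical recipe.

What the generator does **not** emulate: linkage disequilibrium,
recombination maps, coalescent genealogies or selection (the analyses use
genotype identity only, so none is needed for correctness testing), and —
deliberately — the spatial structure of wild-accession heterozygosity,
which is planted as scattered calls rather than the large heterozygous
chromosome fragments of real outcrossed genomes. Run-based smoothing
therefore damps the wilds' het *bp* fraction relative to their het *call*
fraction; conclusions about real wild material should rest on the call
classification, which the tests check directly. Passing tests demonstrate
algorithmic correctness under these conditions, not distributional realism
of real arrays.

## Problem sizes and runtime choices

The test suite and the acceptance script run at the desk scale chosen for
the generator: 2,000 markers × 43 samples for structure recovery (20
seeded replicates), 1,200 markers × 10 samples for segmentation recovery,
cohorts of 154–158 samples for the frequency worked examples, and n ≤ 12
(n ≤ 6 for the exhaustive oracle) for NJ verification. These sizes keep a
full run in tens of seconds while leaving every statistic far from its
small-sample regime; the implementation itself has no scale-dependent
switches, and the O(n³) NJ handles the few-hundred-sample panels the
package targets comfortably.

## Known limitations

* Distances are dissimilarities, not metrics; no triangle inequality is
  asserted or needed by NJ.
* The group-cut rule is one reasonable convention; hierarchical
  clusterings cut at a height would give different (also defensible)
  groupings.
* The shipped starter gene catalog is structural — real marker positions
  and representative haplotype sequences of the cloned-gene panels are not
  public — so it documents the expected catalog shape rather than enabling
  out-of-the-box calling on real arrays.
* Bootstrap support, rooted trees, model-based distances and
  admixture-type analyses are out of scope.
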