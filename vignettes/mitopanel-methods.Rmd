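---
title: "Methods: the mitopanel identification engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mitopanel identification engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopanel)
```

`mitopanel` identifies vertebrate species from nanopore reads of a tetraplex
mitochondrial mini-barcode panel (CYTB, COI, 16S and 12S rRNA). This vignette
documents the model behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations. It states no empirical result
beyond what the test suite and `scripts/acceptance.R` compute.

## The tagmentation read model

Amplicons carry a tandemly repeated 13-bp tail at each primer's 5' end
(CYTB `[AGTGTCCTGCTAG]2`, COI `[CTGAGGTGATCAG]2`, 16S `[AACATGTGGTAAG]2`,
12S `[TTATTCGCACACT]2`), giving each primer a 26-nt extension whose only
role is to be a landing pad for the transposase. The top strand of an
amplicon is `tail + F + insert + rc(R) + rc(tail)`; expected insert lengths
are CYTB 307, COI 214, 12S 111 and 16S 103 bp.

The rapid indexing kit is modelled as exactly one double-strand break per
molecule, uniform over the internal positions, with the sample index
attached to both internal 5' ends. Each molecule therefore yields two
candidate reads: the right fragment follows the top strand to the amplicon
3' end (distal end `rc(R) + rc(tail)` — a "forward" read) and the left
fragment follows the bottom strand to the amplicon 5' end (distal end
`rc(F) + rc(tail)` — a "reverse" read). Two consequences drive the rest of
the pipeline:

* every read is ragged at its proximal (breakpoint) end, so consensus
  sequences are only trustworthy towards the distal end, and forward and
  reverse consensuses are built and classified separately;
* a read is assignable to a barcode only when its distal end retains the
  primer; fragments that break too close to an amplicon end are lost, which
  is modelled rather than corrected.

One breakpoint per molecule is the simplest model consistent with how the
kit is described; multiple transposition events per molecule would shorten
fragments further but not change the read structure at the retained ends.

## Read preparation

**Filtering.** Mean read quality is defined as
`Q = -10 log10(mean_i 10^(-q_i/10))` — the Phred transform of the mean
per-base error probability, which is the semantics commonly used by
long-read quality filters. Defaults: `min_quality = 11`,
`min_length = 100`, `max_length = 500` (inclusive bounds). The rejection
counts are reported with length checked before quality so that the counts
partition the input.

**Index demultiplexing.** The best approximate occurrence of each sample
index is sought in the first 60 bases (edit distance, default
`max_edit = 3`); the winning index must be unique at the best distance,
otherwise the read stays unassigned. Trimming removes everything through
the index match. The 60-base window and the edit limit are generous for
~24-bp indices while keeping cross-index collisions effectively impossible
for well-separated index sets.

**Barcode/strand assignment.** The reverse complements of all eight primers
are searched in a distal window of `1.5 x (primer + tail length)`; the
per-primer edit limit defaults to `ceil(0.25 x primer length)`, tolerant of
roughly 10–15% read error without letting distinct primers collide. A hit to
`rc(reverse_primer)` of barcode b gives (b, forward); `rc(forward_primer)`
gives (b, reverse). Ties break by lowest edit distance, then longest primer,
then fixed panel order (CYTB, COI, 16S, 12S) for determinism. The primer and
everything distal of it (the tail) are trimmed. Degenerate IUPAC positions in
primers match their code set at zero cost; the search is a small C++ dynamic
program validated against a brute-force matcher in the tests.

## Clustering and consensus

Within each (sample, barcode, strand) bin, reads are sorted canonically
(length descending, then sequence, then id) and clustered greedily: a read
joins the first cluster whose representative it matches at
`identity_threshold = 0.80` (read aligned end-to-end against a
representative substring — the distal anchoring comes free because bin
members share their distal terminus), otherwise it founds a cluster. The
0.8 default accommodates two reads each carrying ~8–10% error while keeping
species two substitutions-per-site classes apart in separate clusters; it is
configurable.

Retention applies two thresholds: a cluster must contain at least
`abundance_ratio x bin size` reads (default 0.1%) *and* at least the
mode's support floor — 100 supporting reads in single-source mode
(consensuses below that are discarded), 21 in mixture mode ("more than 20",
about three times the highest cluster support expected in a negative
control; `derive_mixture_threshold()` recomputes it from an actual negative
control). The abundance denominator is the post-filter read count of the
bin, which the published description leaves open.

The consensus is a star alignment against the cluster representative (the
founding, longest read), majority per column; majority deletions remove a
column, majority insertions at a junction insert the most common run, and
ties resolve to the representative's base. Proximal columns with coverage
below `max(3, 30% of members)` are trimmed — this is the ragged-breakpoint
side. At most the 500 longest members are used, bounding runtime. This
star-plus-majority design was chosen over partial-order alignment because it
is deterministic and accurate at amplicon lengths ≤ ~360 bp; its one known
bias is that a deletion error present in the representative and in no other
member is recoverable only via the insertion vote, so consensus accuracy
under heavy indel noise is slightly below its accuracy under substitution
noise (the test suite quantifies the substitution-only case: exact recovery
in ≥ 99/100 seeded simulations at 5% substitutions, 50 reads).

## Classification

Each consensus is aligned (affine-gap local alignment, +2/−3, gap open −5,
gap extend −2; a gap of length L costs `|open| + L|extend|`) against every
reference record in both orientations — reverse-strand consensuses are
bottom-strand, so single-orientation search would see only spurious short
perfect matches. The hit table mirrors BLAST `-outfmt 7` columns
(`qseqid qlen evalue qcovs pident staxids stitle scomnames`), with
`E = K m n exp(-lambda S)` (defaults λ = 0.625, K = 0.41) as a ranking
surrogate: the database here is small and E is never interpreted
statistically. Rows sort by E-value, then pident, qcovs, accession, making
ranking a total order. An externally produced table in the same dialect can
be ingested (`read_hit_table`), so a real BLAST run can substitute for the
built-in aligner. A single exact search mode is provided; a seeded heuristic
mode was considered and rejected because the exhaustive search is already
fast at this database scale and a second code path would be hard to
validate.

Filtering retains, per query: the best row per taxid, rows with
`pident >= 90`, species-ranked taxids only (operationalised as taxonomy rank
== species rather than name heuristics), non-`ncRNA_other` records (the 12S
and 16S barcode loci are themselves rRNA and are never excluded — the rule
targets miscellaneous non-coding RNA predictions), and all rows tied with
the best survivor on (E-value, pident).

## Species calling

A barcode identifies only when both strand consensuses have retained hits;
its candidates are the intersection of the two strands' top-tied taxid sets
(an empty intersection keeps the union and marks the barcode
strand-discordant rather than discarding it — the cross-barcode majority
then adjudicates). Numt flagging has two triggers: a nuclear-flagged top
record (applied to one-strand results as well, since a nuclear pseudogene
can dominate a single strand's bin), or disagreement with the majority
species. The majority is computed once over all identifying barcodes and a
tied majority flags nothing — a leave-one-out majority would flag every
barcode in a 2-vs-2 split, which is why it was not used. Flagged barcodes
are excluded from the final call.

The single-source call is the unique species present in every identifying
barcode's candidate set (a strict-majority variant is available via
`call_rule = "majority"`); failing that, the call ascends to the lowest
common ancestor of all pooled candidates and reports its rank (genus,
tribe, family, …). The LCA rule is monotone: removing a barcode's evidence
can only coarsen the level, never flip a species-level call to a different
species. A mixture species is reported when at least two barcodes have
both-strand support for it; the report is qualitative (read counts are
listed for transparency, proportions are deliberately not derived).

## Panel discrimination assessment

`k2p_distance` uses the closed form
`d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]` with pairwise deletion of
non-ACGT sites (the common distance-software default) and raises an error at
saturation rather than returning NaN. `nj_tree` delegates Saitou–Nei
agglomeration to ape; negative branch lengths are kept internally and
clamped to zero only when trees are written. Bootstrap supports resample
alignment columns with replacement; replicates whose distance matrix
saturates are skipped, counted, and excluded from the support denominator.

A species is *resolved* at a barcode when its sequences form an exclusive
group separable by one edge of the unrooted NJ tree and no foreign sequence
is identical to one of its members; *incorrectly placed* when some member
lies strictly closer (K2P) to a foreign sequence than to every conspecific;
*unresolved* otherwise. The strict-inequality form matters: two species
sharing an identical haplotype at one barcode are mutually unresolved
there — not incorrect — and can be rescued by another barcode, which is
exactly the combined rule (resolved overall iff at least one barcode
resolves and none places incorrectly). Resolution is structural; bootstrap
supports are reported but do not gate it, since the original procedure was a
visual tree inspection. Species with a single sequence cannot fail the
nearest-neighbour test and are flagged `single_sequence`; species absent
from a barcode are data-deficient there rather than unresolved.

## The synthetic-data generator

The generator exists so that every stage is testable offline. Species barcode
inserts evolve from one random ancestor per barcode by i.i.d. substitutions —
`between_species_divergence = 0.15` from the ancestor by default (pairwise
species divergence roughly twice that), `within_species_divergence = 0.005`
for extra reference copies, numts at `numt_divergence = 0.08` flagged as
nuclear records. No indel divergence is simulated between species, so
synthetic barcode sets are natively aligned and the discrimination module
needs no external MSA. Read noise defaults to 4% substitutions, 2%
insertions, 2% deletions (~8% total, nanopore-high-accuracy-like);
per-base qualities are Normal(14, 3) clipped to [2, 40], chosen so that a
typical read's mean quality (~13) passes the Q ≥ 11 filter while the tail of
the distribution exercises it — qualities are nominal basecaller confidence
and are deliberately not coupled to the realised errors. Adapters are
omitted (adapter trimming happens upstream of scope); reads begin at the
index.

What the generator does *not* emulate: homopolymer-biased indels, chimeric
reads, index hopping, PCR amplification bias between barcodes, degraded-DNA
length biases, and real taxonomic sequence structure (synthetic species are
equidistant star-like clades grouped two per genus). Passing tests therefore
demonstrate the correctness of the decision logic and its robustness to
idealised nanopore noise — not performance on real flow-cell data.

## Problem sizes and numerical choices

The bundled checks run at desk scale, as the package's own choice of study
size: the mixture check uses 5 species × 5,000 reads with the published
thresholds verbatim; single-source and numt simulations use 640 reads per
sample with the support floor scaled to 30 (the 100-read floor presumes
tens of thousands of reads per sample; the floor-to-depth ratio is kept
comparable). The numt robustness suite plants one nuclear copy per species
at 8% divergence amplifying at 65% of the affected barcode's molecules, so
the nuclear consensus outranks the mitochondrial one and the flagging path
is genuinely exercised. All randomness descends from a single seed; the
pipeline itself is deterministic (canonical sort before clustering, total
order on hit tables, fixed tie-breaks), which the byte-identity tests
verify.

Degenerate inputs are defined rather than accidental: empty read sets
produce a zero-call report; a consensus of Ns produces an empty hit table; a
saturated K2P pair is an error; an NJ input needs ≥ 3 taxa; an
all-zero distance matrix yields a star tree.

## Limitations

* The E-value column is a ranking surrogate, not a calibrated statistic.
* Consensus accuracy under heavy indel noise is bounded by the
  representative's deletions (see above); quality-weighted or partial-order
  consensus would improve it at the cost of determinism and speed.
* The discrimination module requires pre-aligned, equal-length barcode
  segments; multiple sequence alignment is out of scope.
* Mixture calls are presence/absence only; read counts must not be read as
  proportions because amplification efficiency differs between species and
  barcodes.
* The default panel ships synthetic placeholder primers; real analyses must
  supply the validated primer sequences via the panel configuration.
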