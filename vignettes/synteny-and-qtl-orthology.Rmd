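---
title: "Synteny mapping, rearrangement calling and QTL orthology with synqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny mapping, rearrangement calling and QTL orthology with synqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synqtl)
```

synqtl implements an anchor-based comparison of two related plant
genomes. This vignette describes the models and procedures behind each
stage, the parameters that matter and why their defaults were chosen,
what the synthetic-data generator does and does not emulate, and the
numerical choices and known limitations a user should be aware of.

## The anchor model

Every analysis starts from *anchors*: query sequences (CDS, genetic-map
markers, primers) uniquely aligned to a target genome, giving coordinate
correspondences between the two genomes. Internally every interval is
0-based half-open — the BED convention — so spans are `end - start` with
no off-by-one corrections anywhere; conversion from the 1-based closed
coordinates of GFF3 and tabular BLAST happens only at the parse and
serialize boundaries. Identity and coverage are stored as fractions in
[0, 1]; policy files may state either fractions or percentages via a
`units` key, avoiding double normalization. The strand of an anchor is
the orientation of its alignment on the target; the query orientation of
a genetic-map marker is undefined.

## Hit filtering, best hits, co-location

A `filter_policy()` bundles up to five thresholds: minimum identity,
minimum coverage, minimum aligned length, minimum matching bp, maximum
mismatching bp. All comparisons are **inclusive**: a "cut-off" of 80%
identity retains a hit at exactly 0.80. This choice is deliberate — the
printed boundary values of a published policy should pass their own
filter. Six presets ship with the package, one per dataset comparison in
the Solanaceae setting (CDS-to-genome at 80/75/200; own-genome markers
at 98% identity, ≥ 200 matching, ≤ 50 mismatching bp; cross-genome map
markers at 75/40/200; and eggplant markers on the fragmented eggplant
draft at 75% identity, ≥ 100 matching, ≤ 50 mismatching bp).

Multi-hit queries are resolved by strict lexicographic priority on
(match bp, identity, coverage) — matching bp first. Full ties break
deterministically on the lowest target chromosome name, then the lowest
start, so repeated runs give identical output.

Co-located queries (two genes aligned to one locus — paralogs collapsing
onto one ortholog, or CDS stacking on non-coding sequence) are detected
by linking hits on the same chromosome whose interval hulls overlap or
sit within a tolerance (default 25 bp; the CDS screening recipe uses
50 bp). The tolerance applies to the *gap between hulls*, not to
midpoints, so partial alignments are included. Groups are connected
components of this relation — transitive closure, since a chain of
mutually close hits is one locus. The package computes components via
`IRanges::reduce()`; the test suite checks the result against an
independent O(n²) pairwise union-find oracle, keeping the two routes
separate.

Primer-pair anchoring enumerates forward × reverse hit combinations on
one chromosome, requires opposite strands (standard PCR geometry; a flag
disables it) and an outer-edge span within a slack of the expected
amplicon length. The slack is relative (default ±25%) because
intron-length variation between species makes exact spans unrealistic;
among valid combinations the span closest to the expected length wins.
Unpaired markers carry a reason code (`no-common-chrom`,
`strand-incompatible`, `no-span-match`).

## Chaining and rearrangement classification

Visual dot-plot inspection is formalized in two steps.

**Chaining** (`chain_anchors()`) is greedy single-linkage per chromosome
pair: sort anchors by target position; extend the current block while
the next anchor is within `max_gap_bp` on both genomes and continues the
block's query-order direction; otherwise start a new block. Blocks with
fewer than `min_anchors` anchors are dropped (their indices are
reported, so anchors are conserved: each is in exactly one block or in
the dropped set). Defaults — `max_gap_bp` 3 Mb, `min_anchors` 3 — are
matched to CDS-anchor densities of roughly one anchor per 150 kb, where
a 3 Mb gap tolerance bridges ordinary density fluctuations without
bridging distinct chromosome territories. When the query axis is a
genetic map, the query-side gap bound is set in cM (`max_gap_query`) and
all span thresholds apply to the physical target genome only.

**Classification** (`call_rearrangements()`) first coalesces
target-adjacent blocks of a pair that share orientation and continue the
query progression. This repair step exists because the greedy rule is
deliberately simple: one stray anchor absorbed into a run (a
filter-passing spurious hit, or a paralog that won best-hit selection)
splits the run in two, and jitter can flip the local order of two close
anchors. The continuation test allows a forward query gap up to
`max_gap_query` but a backward step of only 5% of it — a block that
*retraces* the query interval of its neighbour is two copies, not two
fragments — and is retried with each piece's second-extreme anchor
position so a single absorbed outlier cannot block the repair.

Calls are then made per coalesced block with target span at least
`min_span_bp` (default 0.5 Mb, the conventional reporting threshold for
these genome comparisons):

- **duplication** first: two blocks of one query chromosome whose query
  hulls overlap by at least half of the smaller hull, with equal
  orientation, disjoint target intervals, and *interleaved* anchor
  support (the larger block has anchors strictly inside the smaller's
  interval). Interleaving is the discriminating signature: two real
  copies split a segment's queries between two loci, so each block's
  anchors thread through the other's interval, whereas the host block
  around a transposed segment has a coverage hole exactly there. A
  plain reciprocal-overlap rule fails whenever best-hit selection splits
  the copies unevenly, which is why the test is anchored in coverage
  rather than hull geometry. Blocks in a duplication group are not
  additionally classified under the remaining rules — a dispersed copy
  on another chromosome would otherwise always masquerade as a
  translocation.
- **translocation**: the block's query chromosome differs from the
  plurality (orthologous) partner of its target chromosome. A reciprocal
  arm exchange therefore yields two calls, one per direction.
- **inversion**: orthologous pair, but orientation opposite to the
  pair's dominant orientation, computed weighted by anchor count so a
  large inversion on a small chromosome arm cannot flip the reference
  orientation.
- **transposition**: orthologous pair and dominant orientation, but
  displaced out of rank order. Two complementary tests against a larger
  block of the same pair: query-interval nesting inside the other
  block's hull (the host chained through the excision hole), or a
  disjoint-interval order violation (the host split at the hole). Both
  imply the block has jumped past at least one full block.

Span estimates extend each block hull to the midpoint between its
outermost anchor and the nearest retained anchor outside the block — an
unbiased breakpoint estimate. The raw hull systematically underestimates
event spans by about one anchor spacing per side, enough to push events
near the 0.5 Mb threshold below it.

Centromeric regions are not masked by default; small calls near
centromeres of fragmented assemblies can reflect scaffold-anchoring
errors, and a coordinate mask can be applied upstream by filtering hits
before chaining.

## Genetic-to-physical projection

The conversion rate between map and sequence is local: between two
neighbouring anchored markers it is |Δbp|/ΔcM; co-segregating pairs
(ΔcM = 0) are unusable and pairs whose anchors land on different
chromosomes span a rearrangement — both are errors, not warnings.
Anchors disagreeing with their linkage group's majority chromosome are
excluded from the scaffold before projection and reported; they sit on
translocated segments and would otherwise inject absurd rates.

`project_qtl()` offers two modes. The default `local_rate` mode
reproduces the classical procedure: find the anchor pair flanking the
QTL peak, interpolate the peak, and multiply the confidence-interval
width in cM by the local rate, laying the physical interval around the
projected peak so that the cM asymmetry of the interval is preserved
(its total width is exactly width × rate). Whether the original
procedure centred the physical interval on the peak or on the interval
midpoint is not specified anywhere; centring on the peak was chosen
because the peak is the only point with a model-based location. The
`piecewise` mode interpolates peak and both bounds independently through
the full monotone scaffold; it is offered because a single local rate
can misplace wide intervals on maps with strong recombination-rate
variation, and the simulation study below quantifies exactly that.
Non-monotone scaffolds (local inversions) are resolved for piecewise
mode by longest-increasing-subsequence selection, keeping the
interpolant a function; dropped anchors are reported. Projection beyond
the terminal anchors extrapolates with the terminal interval's rate and
is always flagged. Per-environment confidence intervals are averaged
element-wise before projection; with one environment the interval is
unchanged.

## QTL orthology

Trait relatedness is an explicit user-supplied table (`trait_equivalence()`),
never string matching: grouping peduncle, fruit and flowering-time
traits is expert judgement, and the shipped default table
(`inst/extdata/trait_groups.yaml`) only reproduces a standard grouping
for fruit crops. Major QTL are those with PVE ≥ 10 (inclusive). Pairs
require the same reference chromosome, related traits, and interval gap
at most `proximity_bp`; clusters are single-linkage merges with gap at
most `merge_gap_bp`. Both default to 1 Mb — the scale of the narrowest
reported cluster intervals in this literature — and both are exposed as
parameters. One-species clusters are first-class outputs: a cluster of
co-localized QTL with no counterpart in the other species is a finding,
not a failure. Monotonicity holds by construction: increasing the
proximity never removes a pair, and decreasing the span threshold never
removes a rearrangement call.

## The synthetic-data generator

The generator defines the package's study conditions. Two genomes of 12
chromosomes × 25 Mb carry 400 anchors per chromosome (one per ~62 kb).
Real Solanaceae chromosomes are an order of magnitude longer, but all
the geometry scales with the ratio of event span to anchor spacing, and
these sizes keep the full validation battery (hundreds of histories)
inside minutes. Per history, event counts are drawn uniformly: 2–4
inversions, 1–2 reciprocal translocations, 0–1 transpositions, 0–1
duplications (3–8 events in total), with spans of 1–3 Mb. Placement is
structured so events are independently detectable: inversions,
transposition sources/destinations and duplication sources occupy the
proximal 5–55% of a chromosome, translocation breakpoints the distal
60–90% (the distal arm-swap geometry of the canonical pepper/tomato
exchange), at most one event per chromosome, transposition displacement
at least 5 Mb (beyond the chaining gap bound), and duplication copies
dispersed to one position on each of two *other* chromosomes. Dispersing
the copies models a duplicative transposition and guarantees the two
copies can never be absorbed into one block by the repair step.

Anchor identity and coverage are Beta-distributed with means above the
CDS filter thresholds (truncated just above them, so the quality filter
removes no genuine anchor), plus a 10% contaminant fraction drawn below
threshold so `filter_hits()` does real work. Default noise: 5% spurious
filter-passing hits, 5% missing anchors, 1% paralogous extra hits, and
±5 kb positional jitter. All randomness flows from a single seed through
an isolated RNG (`withr::with_seed`), leaving the session RNG
untouched; anchor bookkeeping (placed + duplication copies − deleted +
spurious + paralogs + contaminants = output) reconciles exactly.

What the generator does **not** emulate: sequence-level artefacts (no
FASTA; anchors are coordinate objects), repeat families and centromeric
anchor deserts, assembly fragmentation (every chromosome is one
scaffold), nested or overlapping rearrangements, and genome-size
asymmetry between the two species. Passing the validation battery
therefore demonstrates the correctness of the chaining, classification
and projection logic under realistic anchor noise — not robustness to
misassembled references or to rearrangements that overlap each other.

The map/QTL generator builds a monotone cM↔bp function per linkage
group — linear, or a logistic sigmoid mimicking suppressed centromeric
recombination — places markers every ~2 cM along it, and records every
QTL's true physical peak and interval. Two-environment confidence
intervals are jittered symmetrically around the true interval so their
average equals it exactly, which closes the loop for the projection
test. The planted orthology study places 8 two-species and 6 one-species
cluster loci, all major, at well-separated positions.

## Validation results the package computes

The acceptance script (`scripts/acceptance.R`) and the test suite
recompute, from scratch: filter and co-location equivalence against
brute-force oracles; rearrangement recall and precision over 100
histories (noise-free recovery is exact; under default noise both stay
above 0.9); the 0.5 Mb span rule gating a planted 0.4 Mb inversion;
linear-map projection exact to machine precision and sigmoid-map
piecewise projection within one local anchor spacing for ≥ 95% of QTL;
recovery of the planted 8 + 6 cluster structure; and byte-identical
outputs across repeated runs of one configuration and seed. The vignette
states no number that those runs do not themselves produce.

## Numerical and degenerate-input choices

- Ties in best-hit selection, colocation ordering, block and cluster ids
  are all broken positionally (lowest chromosome string, lowest start),
  so every output is reproducible byte for byte.
- Anchors with equal query midpoints do not break a chain's direction
  (the step sign 0 is compatible with either direction).
- `bp` columns are serialized with explicit integer formatting — never
  scientific notation — so written tables parse back to identical
  values.
- Empty inputs are legal everywhere and produce empty, correctly typed
  outputs; fatal errors are reserved for contract violations (negative
  tolerances, inverted confidence intervals, missing required columns,
  co-segregating rate pairs).
- Workflow configs are validated against a closed key set before any
  stage runs; unknown keys are errors, not warnings.

## Known limitations

- Breakpoints are resolved to anchor midpoints, not base pairs; calls
  carry spans, not sequence-level breakpoint coordinates.
- The transposition tests require the displaced block to jump past at
  least one other block of its pair; short-range displacement inside one
  gap is not callable.
- Chromosome orthology by plurality assumes no target chromosome is
  dominated by translocated material (arm swaps below ~50% of anchors).
- The duplication rule reports groups of retracing blocks; it does not
  distinguish segmental duplication in the target genome from paralogous
  expansion in the query.
- No statistical significance is attached to blocks or clusters (no
  Poisson block test, no cluster enrichment test); counts and spans are
  reported as-is.
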