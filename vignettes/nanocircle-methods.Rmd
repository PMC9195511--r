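---
title: "Detecting circular DNA from long reads: the nanocircle model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circular DNA from long reads: the nanocircle model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocircle)
```

## The problem

Extrachromosomal circular DNA (eccDNA, and its large oncogene-bearing form
ecDNA) is detected here from long reads sequenced out of circle-enriched
libraries: exonuclease digestion removes linear DNA and rolling-circle
amplification boosts circular templates, so read depth is expected to be
near zero outside circles and high inside them, and reads that cross a
circle junction map as split alignments. `nanocircle` consumes the mapped
reads (any long-read mapper; the package reads standard SAM/BAM with
supplementary alignments and SA tags), reconstructs candidate circles from
depth changes and split reads, scores each candidate with a posterior
probability, and reports annotated calls.

## The breakpoint graph

Aligned segments are reduced to two evidence layers:

* a **depth profile**: each retained segment increments a counter at its
  start and decrements one at its end; the cumulative sum is a step
  function giving the depth at every base. Depth is counted over the full
  reference span of a segment (the mosdepth-style estimator): deletions
  inside one alignment still count as covered, clipped bases do not.
  Supplementary segments count; secondary alignments are discarded.
* **split links**: for each read, its aligned segments are ordered along
  the query; every adjacent pair contributes one link whose endpoints are
  the reference positions where the alignment breaks, each annotated with
  the side on which the aligned segment lies.

The directed **breakpoint graph** has a node wherever the depth
*classification* changes and at every split-link endpoint. The
classification of an interval with mean depth $d$ uses two thresholds:
covered when $d \ge \theta$ (default $\theta = 1$), read-free when
$d \le \theta_0$ (default $\theta_0 = 0$, i.e. literally no covering
reads), indeterminate in between. Adjacent nodes on a contig are joined by
a *coverage* edge (covered), a *deletion* edge (read-free; deletions inside
circles are a known artifact of the library preparation), or no edge.
Split links add *split* edges; a split connection that coincides with a
covered neighbour pair becomes a single *coverage+split* edge. All
connections are stored as directed edge pairs so that a circle can be
traversed in either rotation.

Two implementation choices deserve emphasis:

* **Why classification changes, not raw depth changes.** With real reads,
  every read start and end changes the depth, which would place nodes
  throughout every covered segment and make covered segments traversable
  only through runs of consecutive coverage edges — which the plausibility
  rule below forbids. Classification transitions recover the intended
  graph: on idealized, perfectly stacked reads the two rules coincide.
* **Breakpoint clustering.** Split endpoints are noisy (mappers place the
  break within a few bases). Endpoints within `merge_tol` (default 10 bp)
  on one contig are clustered to their median position and links are
  re-pointed to the cluster representative. This tolerance is distinct
  from the 3 bp window used for QC display classification.

## Plausible circular paths

A circular path is *plausible* if its edges alternate between
coverage-type edges and junction-type edges (split or deletion): every
second edge must be a coverage edge, otherwise no reference interval would
actually be covered. The simplest plausible circle is two nodes joined by
coverage+split edges, one direction serving as the covered segment and the
other as the junction.

Detection proceeds exactly in three steps:

1. **Prune** nodes with no incident coverage edge — they cannot lie on a
   plausible path. Pruning re-derives neighbour edges among the survivors
   (so a stray split endpoint inside a read-free interval does not sever
   the deletion edge across it) and iterates to a fixpoint; it is
   idempotent.
2. **Partition** the pruned graph into strongly connected components
   (igraph); every circular path lies within one SCC.
3. **Enumerate** simple cycles per SCC with a Johnson-style depth-first
   search that applies the alternation constraint *during* the search.
   Nodes not incident to both a coverage-capable and a junction-capable
   edge are excluded up front. Candidates are canonicalized (rotation
   fixed to the lexicographically smallest node; a cycle and its reverse
   traversal share one canonical form) and deduplicated.

SCCs can contain exponentially many cycles, so the search carries two
caps: `max_cycles` (default 10,000) aborts enumeration outright, and
`max_edges` (default 64) prunes paths beyond that depth; either sets a
`truncated` flag on the result. Restricting to *simple* cycles is a
documented limitation: a circle that traverses the same locus twice (an
internal duplication) is out of reach. Candidates whose junctions are all
deletions are dropped unless `require_split = FALSE`: a circle claim with
no split-read evidence anywhere is not falsifiable by this data type.

## Candidate events and scoring

Each candidate becomes a chain of VCF 4.2 breakends (`SVTYPE=BND`), one
reciprocal pair per junction, grouped by an `EVENT` id; deletion junctions
are emitted as breakends too, with their type in `INFO/JTYPE`. Coordinates
are 0-based half-open internally and converted to 1-based only at this
boundary. The package reads its own dialect back losslessly
(`INFO/SEGS` carries the covered segments).

The posterior model is deliberately simple and fully declared (the
original workflow delegates scoring to an external probabilistic caller
with pair-HMM realignment, which is out of scope here). For junction $j$,
let $k_j$ be the (MAPQ-weighted) number of reads whose split links match
both breakends within a tolerance, and $c_j$ the number of reads whose
alignment instead runs straight through a breakend. With
$n_j = k_j + c_j$,

$$\Lambda = \prod_j \frac{\mathrm{Bin}(k_j \mid n_j, \rho)}
                         {\mathrm{Bin}(k_j \mid n_j, \varepsilon)},
\qquad
P(\text{circle} \mid \text{reads}) = \frac{\pi \Lambda}{\pi \Lambda + 1 - \pi},$$

where $\rho$ (default 0.9) is the expected support fraction at a true
junction in a circle-enriched library, $\varepsilon$ (default 0.01) the
rate at which artifacts present as junction support, and $\pi$ (default
0.5) the prior. Binomial coefficients cancel in the ratio; computation is
in log space. A junction with no informative reads contributes a factor of
1, so a candidate with no evidence scores the prior. Reads are weighted by
$1 - 10^{-\mathrm{MAPQ}/10}$, a crude stand-in for the mapping uncertainty
a realignment model would handle. The posterior is monotone increasing in
each $k_j$ and decreasing in each $c_j$; calls are filtered at
`min_prob` (default 0.95) and reported with genes overlapped
(BED/GFF3 via rtracklayer/GenomicRanges) and a junction-spanning sequence
(default 2 kb flanks, the usual primer-design window).

## The synthetic benchmark

The simulator emulates the evaluation design of the original study at desk
scale: circles at 25x read depth with junction-crossing split reads, plus
linear whole-genome background reads at 1x that model incompletely
digested linear DNA. Three topologies are generated: a single-segment
circle (one split junction), a chimeric circle of two segments on
different contigs (two split junctions), and a circle with an internal
deletion (two covered segments, one deletion junction and one split
junction). Reads are sampled from random rotations of each circle, with
log-normal lengths (median 8 kb) capped at the circle length so a read
crosses each junction at most once; a read crossing a split junction
becomes primary + supplementary alignments (SA tags written on SAM
export), while a read crossing a deletion junction is physically
fragmented into unlinked reads — that is what makes the deletion edge
(read-free interval, no split links) emerge from data. Junction-endpoint
jitter (uniform within ±`jitter` bp) models mapper imprecision at breaks.
Error rates default to 5% substitutions, 3% insertions, 4% deletions and
matter only when sequences or CIGARs are emitted; alignment spans, which
drive detection, are exact by construction. The simulator does not model
trained, sequence-context-dependent nanopore error profiles, chimera
artifacts of rolling-circle amplification, or mapping ambiguity in
repetitive sequence — passing benchmarks therefore demonstrate the graph
reconstruction and scoring machinery, not robustness to every failure
mode of real libraries.

Evaluation declares a call correct when it has the same number of covered
segments as a true circle and every breakpoint lies within `match_tol`
(default 50 bp), with one-to-one (maximum bipartite) matching;
recall $= |C \cap T| / |T|$ and precision $= |C \cap T| / |C|$, defining
$0/0 = 1$. Coverage sweeps simulate once at 25x and thin reads per
molecule to 5/10/15x, so lower coverages are true subsamples.

### Study parameters

The packaged benchmark (see `tests/testthat/test-acceptance.R`) uses a
5 Mb genome in four 1.25 Mb contigs, 20 circles of 2–50 kb with the three
topologies mixed evenly, 25x circle coverage and 1x background, seed
20220530. Detection for this study sets:

* $\theta = 8$ and $\theta_0 = 4$: with a 1x linear background the strict
  defaults are inappropriate — background lies far below $\theta_0 = 4$
  (a Poisson(1) depth exceeds 4 with probability < 0.4%), while circle
  segments at 10x and above lie safely over $\theta = 8$. This is also
  why a with-deletion circle's gap, which carries only background reads,
  still classifies as read-free and yields its deletion edge.
* `max_del_len = 20000`: deletion gaps inside circles are bounded by the
  circle size (at most ~10 kb here), whereas read-free intervals between
  unrelated covered loci can be arbitrarily long; without the cap such
  intervals act as junctions and close composite false cycles through
  several circles at once. The default remains uncapped, matching the
  strict zero-coverage rule under which a deletion edge requires a truly
  empty library.

Under these conditions the suite verifies exact recovery (recall and
precision 1.0) at 25x without jitter, recall ≥ 0.9 at 5 bp jitter with
precision ≥ 0.95, and mean recall non-decreasing over the 5/10/15/25x
sweep with three replicates. At 5x the circles fall below $\theta = 8$ and
essentially nothing is called (precision stays 1 by the 0/0 convention) —
the monotone recall curve, not the absolute level at the lowest coverage,
is the claim being checked.

## Numerical and degenerate-input choices

* Depth for graph building is computed after the `mapq_min` filter
  (default 0, so effectively unfiltered); the same threshold applies to
  split links. QC tables filter at their own MAPQ threshold because the
  display question ("how clean is this circle?") differs from the calling
  question.
* Depth-class boundary cases: an interval with mean depth exactly
  $\theta$ is covered; exactly $\theta_0$ is read-free; `theta_zero` must
  be strictly below `theta`.
* Cluster representatives use the lower median, keeping node positions at
  observed integer coordinates.
* A split link whose two endpoints collapse into one node after
  clustering is dropped as uninformative.
* Empty inputs flow through: no reads give an empty profile, an empty
  graph, no candidates, a header-only VCF and a header-only report.
* Ties in the report ordering (equal posterior) break by circle length,
  descending; candidate ids are assigned in canonical-signature order, so
  all outputs are byte-stable for identical inputs and parameters.

## Known limitations

* Circles revisiting a locus (duplications within a circle) are invisible
  to simple-cycle enumeration.
* Orientation is recorded on links and written into breakend brackets,
  but the plausibility rule ignores strand, so inversion-containing
  circles are enumerated permissively rather than being validated against
  link orientation.
* The scoring model ignores alignment ambiguity beyond MAPQ and performs
  no realignment; posteriors from saturated junctions round to 1.0 and
  carry no calibrated uncertainty in between.
* No copy-number-aware decomposition: overlapping circles sharing loci
  are reported as the set of plausible cycles the graph supports.
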