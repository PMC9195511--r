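# nanocircle

Detection of extrachromosomal circular DNA (eccDNA/ecDNA) from mapped
long-read sequencing of circle-enriched libraries.

Circle-enrichment chemistry (exonuclease digestion of linear DNA followed
by rolling-circle amplification) leaves read depth near zero outside
circular templates and high inside them, and reads crossing a circle
junction map as split alignments. `nanocircle` turns a coordinate-sorted
SAM/BAM of such reads into circle calls:

1. **Evidence** — a read-depth step function (increment/decrement counters
   at segment starts/ends, cumulative sum) and split-read junction links
   from supplementary alignments / SA tags.
2. **Breakpoint graph** — a directed graph `G = (V, E)`: nodes at loci
   where the depth classification changes or where split reads start/end;
   edges typed *coverage* (mean depth ≥ θ), *deletion* (read-free
   interval), *split* (≥ 1 split read), or *coverage+split*.
3. **Plausible circular paths** — prune nodes without coverage edges,
   split into strongly connected components, and enumerate simple cycles
   that alternate between coverage edges and split/deletion edges ("every
   second edge is a coverage edge"). The simplest circle is two nodes
   joined by coverage+split edges.
4. **Calling** — each candidate becomes a chain of VCF breakends
   (`SVTYPE=BND`, reciprocal mates, grouped by `EVENT`) and receives a
   posterior probability from a binomial junction-support model: per
   junction with `k` supporting of `n` informative reads, the Bayes factor
   `Bin(k | n, ρ) / Bin(k | n, ε)` (ρ = expected support at a true
   junction, default 0.9; ε = artifact rate, default 0.01) combines across
   junctions, and `posterior = πΛ / (πΛ + 1 − π)` with prior π = 0.5.
5. **Report** — TSV of calls with genes covered (BED/GFF3 annotation),
   junction coordinates, support counts, and junction-spanning sequence
   (2 kb flanks) for PCR primer design; graph exports as GraphML/DOT.

A simulator generates benchmark data matching the published evaluation
design — circles at 25x with junction-crossing reads, three topologies
(simple / two-contig chimeric / internal deletion), 1x linear background —
and an evaluator computes `recall = |C∩T|/|T|` and `precision = |C∩T|/|C|`
with breakpoint tolerance, plus coverage sweeps by per-molecule
subsampling.

## Worked example

```r
library(nanocircle)

cfg   <- sim_config(seed = 42, n_circles = 3, size_range = c(3e3, 2e4))
ref   <- simulate_reference(n_contigs = 2, lengths = 3e5, seed = 42)
truth <- simulate_truth(ref, cfg)
sim   <- simulate_alignments(ref, truth, cfg)

res <- detect_circles(segments = sim$segments,
                      theta = 8, theta_zero = 4, max_del_len = 20000)
res$filtered[, c("circle_id", "n_segments", "circle_length", "prob", "segments")]
#>   circle_id n_segments circle_length prob                                  segments
#> 1  circle_1          2         17828    1 contig1:139497-148410;contig2:86075-94988
#> 2  circle_3          2         14991    1 contig2:151420-158914;contig2:161913-169408
#> 3  circle_2          1         14544    1                       contig1:64912-79455

ev <- evaluate_calls(res$filtered_candidates, truth)
sprintf("recall %.2f precision %.2f", ev$recall, ev$precision)
#> [1] "recall 1.00 precision 1.00"
```

The three simulated circles come back exactly: `circle_1` is the chimeric
circle joining the two contigs, `circle_3` the circle with an internal
deletion (two covered segments on one contig), `circle_2` the simple
single-segment circle; each call's posterior saturates at 1 because every
junction is crossed by ~25x of split reads while almost nothing spans it.
`theta = 8` / `theta_zero = 4` separate circle coverage (25x) from the 1x
linear background; with a clean library the defaults
(`theta = 1`, `theta_zero = 0`, no deletion-length cap) apply. Segment
coordinates are printed 1-based inclusive; VCF positions are 1-based as
usual.

File-based runs mirror this: `run_simulate()` writes
`reference.fasta` / `reads.sam` (with SA tags) / `truth.tsv`, and
`run_detect()` writes `depth.tsv`, `split_links.tsv`, `graph.graphml`,
`graph.dot`, `candidates.vcf`, `calls.vcf`, `report.tsv` and
`provenance.json`. A command-line wrapper with `detect`, `simulate`,
`evaluate`, `sweep` and `qc` subcommands is installed at
`inst/cli/nanocircle`.

See `vignettes/nanocircle-methods.Rmd` for the model, its assumptions,
parameter choices and limitations.

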