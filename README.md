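# itermeta

Iterative metagenome assembly with unaligned-read recycling.

## The problem

Shotgun metagenomes have wildly uneven coverage: dominant community members
are over-sequenced while rare taxa are buried. A single de novo assembly of
such data tunes itself to the dominant coverage, so reads from low-abundance
genomes are discarded as noise and those organisms never make it into the
assembly — the downstream taxonomic profile is biased toward whatever
assembled first.

`itermeta` attacks this with a simple recycling loop. Each round:

1. optionally draw a random subsample (fraction *R* ∈ (0, 1]) of the reads
   still in play;
2. assemble the subsample;
3. align **all** remaining reads back to the new contigs — a read that aligns
   end-to-end with at most *m* mismatches is *utilised* and leaves the pool;
4. stop when the cumulative utilisation reaches a threshold (default 70%),
   a maximum number of iterations is hit (default 5), the pool empties, or
   an iteration utilises nothing; otherwise feed the unaligned residue into
   the next round.

Per-iteration assemblies are concatenated into a combined assembly. Because
each round re-estimates its coverage expectations on a pool from which the
dominant genomes have already been subtracted, material that was below the
coverage cutoff in round one assembles cleanly in round two. Subsampling
(`R < 1`) additionally caps the per-round assembly size, a
divide-and-conquer mode for datasets too large to assemble in one piece.

The headline metric is the **alignment rate** (utilisation)

> 100 × (reads aligned to the assembly) / (reads provided),

alongside N50, contig-length statistics, the **false-base rate** (percentage
of assembly positions no read covers when the input is mapped back) and,
when reference genomes are known, the per-contig **score**

> score = coverage% / 100 × identity%  ∈ [0, 100],

where 100 means the entire contig exactly matches a reference region. The
shift in per-iteration taxonomic profiles is tested with a chi-square test
for homogeneity followed by pairwise two-proportion z-tests under
Benjamini–Hochberg correction, summarised as compact letter groups.

Everything is self-contained: a builtin de Bruijn unitig assembler, a
builtin ungapped seed-and-extend aligner, and a seedable uneven-abundance
community simulator with truth labels, so the whole pipeline runs and is
tested without external tools or downloads. External assemblers can be
plugged in through a one-function backend contract.

## Worked example

Simulate a 5-genome community with a steep abundance gradient, run three
recycling iterations, and test whether the iterations recover different
taxa:

```r
library(itermeta)

truth <- simulate_community(community_spec(
  n_genomes = 5, genome_length = c(4000, 6000), total_reads = 20000,
  read_length = 100, error_rate = 0.01, seed = 42))

res <- itermeta_run(truth$reads, itermeta_config(
  max_iterations = 3, align_threshold_pct = 100, seed = 42))
res
#> <itermeta_result> 3 iteration(s) over 20000 reads (stop: max_iterations)
#>   utilised 19695 reads (98.47%); 109 contigs, 36810 bp combined
#> # A tibble: 3 × 13
#>   iteration n_candidates n_subsampled n_newly_aligned cumulative_utilisation_pct
#>       <int>        <int>        <int>           <int>                      <dbl>
#> 1         1        20000        20000           17909                       89.5
#> 2         2         2091         2091            1512                       97.1
#> 3         3          579          579             274                       98.5
```

A single pass utilised 89.5% of the reads; recycling the residue twice
brings that to 98.5%. Where did the gain come from? Label each contig by
the majority truth taxon of its reads and tabulate reads per iteration:

```r
hits <- tidy_hits(res)
ct <- contig_taxa_from_truth(hits, setNames(truth$reads$taxon, truth$reads$id))
(prof <- profile_from_labels(hits, ct))
#>   iteration g001 g002 g003 g004 g005
#> 1         1 5996 4871 3895 2615  532
#> 2         2   12    5    9  199 1287
#> 3         3   30   29   22  111   82
compare_iterations(prof)
#> <iteration_comparison> chi-square = 1.127e+04 (df=8), p = 0
#>   15 pairwise z-tests, 14 significant after BH (alpha=0.05)
#>   letters: 1=a 2=b 3=c
```

The rarest genome (`g005`) is almost absent from the first-pass assembly
and dominates iteration 2 — exactly the lost-information recovery the
workflow exists for — and the per-iteration profiles differ significantly
(no two iterations share a letter). Against the truth genomes the contigs
are accurate: `best_reference_match(res$combined, truth$genomes)` gives a
mean contig score of 100.

`autoplot(res)` draws the utilisation curve;
`plot_profile(prof, compare_iterations(prof))` draws the per-iteration
stacked taxon bars with their significance letters.

The same pipeline is scriptable from a shell via the bundled CLI
(`system.file("cli", "itermeta", package = "itermeta")`) with subcommands
`simulate`, `run`, `stats` and `compare-profiles`.

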