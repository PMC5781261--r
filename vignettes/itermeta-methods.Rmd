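---
title: "Methods: iterative assembly by unaligned-read recycling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative assembly by unaligned-read recycling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A metagenome is a mixture of genomes at very different abundances, hence
very different sequencing coverage. De novo assemblers behave like coverage
classifiers: k-mers far below the dominant coverage look like sequencing
error and are discarded, so low-abundance genomes fragment or vanish and
the reads they contributed go unused.

`itermeta` treats the *unused* reads as the signal. One run is a sequence
of rounds; round $i$ holds a candidate pool $P_i$ (initially all reads):

1. **Subsample** $S_i \subseteq P_i$, a simple random sample without
   replacement of size $\max(1, \mathrm{round}(R_i\,|P_i|))$; $R_i = 1$
   takes the whole pool without touching the RNG.
2. **Assemble** $S_i$ into contigs $C_i$.
3. **Align** every read in $P_i$ (not only $S_i$) to $C_i$; aligned reads
   are *utilised* and leave the pool, the rest form $P_{i+1}$.
4. **Assess**: stop when $\sum_j |A_j| / |P_1| \cdot 100$ reaches the
   alignment threshold (default 70%), when the configured number of
   iterations (default 5) has run, when $P_{i+1}$ is empty, or when a round
   utilised nothing (stall guard — without it, unassemblable residue would
   loop forever).

Aligning the full pool rather than the subsample is what makes the
partition shrink correctly: a read utilised by any round's contigs is never
re-tested, so each read is counted in exactly one round and cumulative
utilisation is non-decreasing. These two invariants (disjointness,
conservation) are asserted by the test suite on every fixture.

The per-round assemblies are concatenated — contig ids prefixed `it<i>_` —
into the combined assembly; no deduplication is attempted, since round
$i$'s contigs only exist because rounds $1..i-1$ failed to absorb those
reads. An optional final re-assembly feeds the combined contigs back
through the assembler at the same k so contigs overlapping by at least
$k-1$ consistent bases merge; contigs are single sequences rather than
reads, so coverage pruning is disabled for that pass (every contig k-mer
would otherwise be a singleton and the whole assembly would be erased).

## The builtin assembler

The assembler is a deliberately minimal de Bruijn unitig assembler: the
contribution of this package is the iteration logic, and a small,
deterministic assembler keeps every downstream claim testable.

* **Graph.** Nodes are canonical k-mers (the lexicographically smaller of a
  k-mer and its reverse complement) with exact occurrence counts; k-mers
  containing `N` are skipped. k must be odd — an even k admits
  reverse-complement palindromes, which would make a node its own
  neighbour — and at most 31 (2-bit encoding in a 64-bit word).
* **Pruning.** K-mers below a count cutoff are removed. The cutoff has two
  modes. `fixed` uses `min_kmer_cov` (default 2, dropping singleton error
  k-mers). `auto` — the default, and the mode the workflow relies on — uses
  `max(min_kmer_cov, floor(auto_frac * E))` where $E$ is the expected
  coverage estimated as the median k-mer count over k-mer *instances*
  (counts weighted by count, so the estimate tracks where the sequenced
  bases actually are) and `auto_frac = 0.5`, the conventional
  half-expected-coverage cutoff of expected-coverage-aware assemblers.
  This relative cutoff is the mechanism that makes iteration work: in
  round one $E$ reflects the dominant genomes and rare genomes fall below
  the bar; in round two the dominant reads are gone, $E$ drops, and the
  same rare material assembles. With an absolute cutoff and $R = 1$,
  round two would see the identical graph and recover nothing.
* **Unitigs.** Contigs are maximal non-branching paths: extension proceeds
  only through a unique successor whose predecessor is also unique; no
  greedy extension through branches, no bubble popping, no tip clipping
  beyond the coverage prune, no scaffolding. Contigs shorter than
  `min_contig_len` (default $2k-1$, i.e. at least $k$ k-mers) are dropped.
* **Determinism.** Each unitig is emitted as the lexicographically smaller
  of its two orientations; output is sorted by length (descending) then
  sequence. Identical input — in any read order — gives byte-identical
  FASTA.

External assemblers satisfy the same contract (`(reads, params) ->`
contigs tibble) through `register_backend()`; `velvet` and `abyss`
adapters are included as command templates but require the executables and
are not exercised by the tests.

## The builtin aligner

The aligner answers one question per read: does it belong to the assembly?
A read aligns iff some placement, discovered through an exact seed match
(default seed length 22), yields a full-length, end-to-end, **ungapped**
alignment with at most `max_mismatches` mismatches (default
$\lceil 0.04 \times \text{read length} \rceil$, roughly the tolerance of a
short-read mapper run with one permitted seed mismatch). Both strands are
searched via canonical seeds. Among qualifying placements the fewest
mismatches wins; ties break by contig order, then position, then `+`
strand, so results are deterministic. Multi-mapping reads contribute
coverage only at that single reported placement, keeping coverage mass
equal to (hits × read length).

Two consequences worth knowing:

* A placement whose every clean stretch is shorter than the seed cannot be
  found. With the default 4% mismatch cap this is vanishingly rare for
  ≥75 bp reads; the oracle tests use a seed short enough that the seeded
  search is provably exhaustive.
* Reads shorter than the seed are never tested; they are reported
  separately (`n_too_short`) and counted as unaligned.

Coordinates are 0-based half-open internally; gapped alignment, quality
scores and mapping qualities are out of scope.

## Quality metrics

* **N50**: first length, in descending order, whose running sum reaches at
  least half the total (ties resolved by the ≥ convention on both
  comparisons).
* **Alignment rate / utilisation**: `100 * aligned / total input reads`.
  The stopping rule compares *cumulative utilisation* against the
  threshold; for the combined assembly the numerator is the cumulative
  aligned count over all rounds.
* **False-base rate**: percentage of assembly positions with zero coverage
  when the remaining pool of each round is mapped to that round's contigs.
* **Contig score**: for each contig, the best reference placement is found
  by exact 31-mer anchoring followed, per candidate diagonal and strand,
  by the maximal-scoring ungapped segment (match +1, mismatch −2, best
  segment by Kadane's algorithm); across diagonals the placement with the
  most identical bases wins, ties broken by score, then reference order,
  then `+` strand, then leftmost. Then
  `score = coverage% / 100 × identity%`, where coverage is the matched
  segment's share of the contig and identity the matched segment's
  identical fraction. This replaces a BLAST-based search so the package
  has no external database or tool dependency; the matched region is one
  maximal ungapped segment, a documented simplification relative to
  gapped HSPs. The score formula itself is unchanged by the substitution.
* **Length SD** is the population standard deviation (÷ n) by default,
  switchable to sample.

## The statistics layer

Per-iteration taxonomic profiles (iterations × taxa read counts; labels
from simulation truth or any user-supplied contig → taxon table, since
database annotation is outside this package's scope) are compared with:

1. A Pearson chi-square test for homogeneity (no Yates correction by
   default; a flag enables it for 2×2), via `stats::chisq.test`.
2. When it rejects at `alpha` (default 0.05): all pairwise-iteration,
   per-taxon pooled two-proportion z-tests,
   $z = (\hat p_1 - \hat p_2) / \sqrt{\hat p(1-\hat p)(1/n_1 + 1/n_2)}$,
   with two-sided normal p-values. A pooled proportion of exactly 0 or 1
   has zero variance; those comparisons return $p = 1$ and are flagged
   degenerate rather than producing `NaN`.
3. Benjamini–Hochberg correction applied across the *entire* batch of
   (taxon × iteration-pair) z-tests — the most conservative reading of an
   unscoped correction — via `stats::p.adjust`. The chi-square p-value
   itself is not multiplicity-corrected.
4. Compact letter display: a greedy clique cover of the
   pairwise-non-significance graph (a pair is non-significant when no
   taxon's q-value falls below `alpha`), deterministic in iteration order.
   Iterations share a letter iff they are not significantly different.

Contig labelling from truth uses a majority vote of aligned reads'
taxa, ties broken lexicographically, zero-hit contigs labelled
`unclassified`.

## The simulator

The generator emulates an uneven single-genome-per-species community:
i.i.d. uniform-composition genomes; abundances interpolated linearly (or
log-uniformly, as a configuration hook) between 0.66% and 0.22% across
ranks and renormalised — a linear rank gradient is the single-knob way to
produce the graded unevenness that motivates iteration; reads drawn by
abundance-weighted genome choice, uniform start, uniform strand, and
i.i.d. substitutions. The standard study community is 20 genomes of
5–10 kb with 200,000 × 100 bp reads at 1% error: large enough that the
first-pass assembly visibly drops the rare tail, small enough that a full
three-run comparison completes in well under a minute.

What it does not emulate — and therefore what passing tests cannot speak
to: indels and quality-score-correlated errors (the aligner is ungapped by
design, so the substitution-only model is the matching choice), paired
ends, strain mixtures, conserved inter-species homology, GC bias, and
real-scale genome lengths. Read ids encode the source genome, so truth
survives FASTA round trips.

Determinism: every generator draws from one seeded stream
(`withr::with_seed`); the read simulator seeds at `seed + 1` so genomes
and reads are independently reproducible; a workflow run seeds once and
consumes the stream in iteration order, so per-iteration subsamples are
reproducible yet distinct. The C++ error sampler draws from R's RNG, so a
single `set.seed` governs everything.

## Degenerate inputs and edge rules

* Empty read set, empty contig set, assembler that returns nothing: the
  run records a zero-utilisation iteration and the stall guard stops it.
* Duplicate read ids are rejected at parse time (uniqueness is assumed by
  the partition bookkeeping); paired files, if supplied, are simply
  concatenated as independent single-end reads.
* `N` bases are accepted on input; k-mers and seeds containing them are
  skipped, and `N` never matches during mismatch counting.
* All-zero rows/columns of a profile are dropped with a warning before the
  chi-square test; a table left with fewer than 2×2 informative cells is
  an error, not a silent p-value.

## Problem sizes in the test suite

Unit tests run on hand-checkable fixtures (tens of reads, genomes of
0.5–5 kb) with independent oracles: a string-level canonical k-mer tally,
an exhaustive all-placements aligner, brute-force N50/false-base/BH
implementations, and closed-form chi-square/z values. The end-to-end
checks use the standard 200k-read community described above, plus a
50k-read zero-error variant for the exact-score limit and 1000-replicate
multinomial simulations for type-I calibration of the homogeneity test.

## Known limitations

* k and seed lengths are capped at 31 by the 2-bit encoding; larger k
  requires an external backend.
* The unitig assembler does not resolve repeats longer than $k-1$ or pop
  error bubbles; under high error with a fixed cutoff, fragmented output
  is expected (the auto cutoff absorbs most of this).
* The reference matcher reports a single ungapped segment; a contig
  spanning a reference indel scores below its gapped-alignment identity.
* Stopping compares cumulative utilisation only after a completed
  iteration; there is no mid-round early exit.
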