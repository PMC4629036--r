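---
title: "Reference-assisted assembly of closely related genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-assisted assembly of closely related genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refasm)
```

## The problem and the model

Many sequencing protocols (ChIP-seq, RNA-seq, resequencing of mutants or
evolved lines) produce reads from a genome that is *almost*, but not
exactly, the deposited reference of the species — typically around 1%
divergence. Mapping the reads to the reference silently erases those
differences; assembling the reads de novo discards the reference and, at
the modest coverages typical of such experiments, produces short and
incomplete contigs.

`refasm` takes the middle road. The reference is converted into
**pseudoreads**: paired-end reads tiled deterministically across every
chromosome, so the assembler always has full, uniform coverage to work
with. Pseudoreads carry deliberately low base qualities, so they act as a
scaffold of last resort: wherever the experimental reads carry information,
they outvote the reference. The co-assembled contigs are then mapped back
onto the reference, and the reference is *edited* — each well-mapped contig
segment replaces the corresponding reference segment — producing a genome
that (a) covers everything the reference covered and (b) agrees with the
experimental reads wherever they spoke.

The key assumption is **close relatedness**: contig placement uses the
reference to decide order and orientation, so structural rearrangements
between reference and sample are out of scope, as are genomes whose size
makes desk-scale de Bruijn assembly impractical (the approach is aimed at
microbe-to-invertebrate scale, not human scale).

## Pipeline stages and their parameters

### Pseudoreads (`generate_pseudoreads`)

For each chromosome of length $\mathrm{Len}$ and each start
$p \in \{0, n, 2n, \dots\}$ with $p + d \le \mathrm{Len}$, one pair is
emitted: mate 1 is the forward window $[p, p+m)$; mate 2 is the reverse
complement of $[p+d-m, p+d)$. All bases carry Phred quality $q$.

| parameter | default | meaning |
|---|---|---|
| `m` | 100 b | pseudoread length |
| `n` | 30 b | tiling step; mate-1 coverage is ≈ m/n ≈ 3.3× |
| `d` | 1000 b | outer fragment length (mate-1 start to mate-2 end) |
| `q` | 10 | Phred quality of every pseudoread base |

Two conventions here were genuinely open and are this package's documented
choices. First, `d` is interpreted as the distance from the mate-1 *start*
to the mate-2 window *end* — the outer fragment length — which with the
defaults gives a 1000 b fragment with an 800 b inner gap, a long-insert
library. Second, pairs whose mate-2 window would overrun the chromosome are
*skipped entirely* rather than truncated: fixed-length reads keep the
downstream k-mer bookkeeping simple and the loss is at most `d` bases of
tail tiling per chromosome. Windows containing `N` are emitted unchanged;
the assembler refuses to form k-mers across `N`.

### Co-assembly (`assemble`)

The internal micro-assembler builds a de Bruijn graph on canonical k-mers
(the lexicographic minimum of a k-mer and its reverse complement, so both
strands collapse onto one node; `k` must be odd, which avoids
self-reverse-complementary k-mers). Each k-mer occurrence adds the sum of
the Phred qualities of its bases to the node's weight. Contigs are
extracted greedily: starting from the heaviest unvisited k-mer, the walk
extends in both directions, and at every branch the heaviest surviving
successor wins; an exact tie goes to the alphabetically earliest base, so
assembly is fully deterministic given the input.

The weight rule is what makes co-assembly work: at a site where the sample
differs from the reference, the experimental k-mers (few, but high
quality) outweigh the pseudoread k-mers (uniform coverage, but q = 10), so
the walk follows the sample allele. The losing side of such a bubble
becomes a short dead-end path that falls below `min_contig_len`
(default 100 b) and is discarded.

| parameter | default | meaning |
|---|---|---|
| `k` | 21 | k-mer size, odd, 11–31 (two-bit packed) |
| `min_contig_len` | 100 b | shortest emitted contig |
| `min_kmer_count` | 1 | solidity threshold; 1 suffices because pseudoreads guarantee coverage and the bundled simulator defaults to error-free reads; raise it for noisy read sets |

The assembler is deliberately minimal — unitig-style paths with greedy
bubble resolution, no pair-aware scaffolding, no repeat untangling — because
the pipeline treats the assembler as a swappable component; the
`run_external_assembler()` adapter accepts any command template with
`{reads}`/`{out}` placeholders and ingests the FASTA it produces.

### Contig mapping (`map_contigs`)

A k-mer index of the reference (seed length 15, every reference position,
seeds occurring more than 100 times skipped as repetitive) is queried with
seeds sampled every 5 bases along each contig orientation. Hits are grouped
by diagonal (clusters split at diagonal gaps above 500), chained into a
monotone anchor set (per-step diagonal drift at most 100), and the gaps
between anchors, plus the two flanks, are closed with unit-cost
edit-distance alignment; each inter-anchor segment and flank is aligned
with a band of at least 20 columns scaled to the segment. Anchoring the
band per segment rather than holding one fixed diagonal across the whole
contig keeps memory linear and tolerates the indel drift that accumulates
over long contigs. Identity is `100 × matches / alignment columns` (gap
columns count), reported to two decimals — the same convention in which
`show-coords` %IDY is consumed. Pre-computed MUMmer `show-coords` tab files
can be ingested with `read_coords()` instead, bypassing the aligner; both
paths produce the same record type.

Records below `min_idy` (default 90% — the genomes are assumed very closely
related) or from contigs shorter than `min_match_len` (default 65 b, a
MUMmer-like minimum useful alignment) are suppressed, as are loci whose
anchor support is too thin to align usefully. Oversized unalignable
stretches inside a mapping (anchor gaps beyond 20 kb, or flank alignments
beyond 25M DP cells) are charged as all-gap columns rather than aligned;
a contig with such a stretch either survives with a proportionally reduced
identity or falls below the identity floor.

### Reference editing (`select_best_mappings`, `resolve_overlaps`, `splice_reference`)

A contig may map to several loci. For each contig the mapping with the
highest $Q_\mathrm{map} = L \times \mathrm{idy}$ is kept; exact ties break
to the smaller (chromosome, start, strand `+` first) for determinism.
Selection already removes most multiple coverage; what remains is
overlapping reference intervals from *different* contigs, resolved greedily
by preferring the beginning of contigs to the ends: at every reference
position the covering placement with the larger start wins, so an earlier
placement's tail is trimmed against the next surviving start.

Two situations are underdetermined by that rule and resolved as package
choices. A placement completely nested inside another keeps its whole
interval, and the host contributes both flanks (this maximises retained
assembly sequence while honouring the preference for beginnings). And
because coords-level input has no per-column alignment, trimming a
placement by $t$ reference columns removes
$\lfloor t \cdot L_\mathrm{contig} / L_\mathrm{ref} \rfloor$ contig bases —
proportional scaling, rounded toward fewer contig bases.

Splicing rebuilds each chromosome left to right, copying unreplaced
reference verbatim and substituting each placement's (reverse-complemented,
for minus-strand mappings) contig segment. Lengths need not be conserved
per segment (indels), but the identity
`edited = reference − replaced + used` always holds and is asserted in the
tests. The edit report carries the edited length, replaced length, the
replaced fraction of the reference (`% ref`), the used fraction of the
assembly (`% asm`), the number of contributing contigs, and optionally the
identity of the edited reference to the original.

### Evaluation (`evaluate_assembly` and friends)

* `TL` — total contig length (reported in bases and Mb; Mb values round
  half up to 2 decimals, matching the usual table formatting).
* `N50` — shortest contig of the minimal largest-contig prefix covering
  half of TL (checked in the tests against exhaustive subset enumeration).
* `IDY`/`Error` — assembly mapped to the *target*; IDY is the
  length-weighted mean of per-mapping identities, Error = 100 − IDY. When a
  region maps twice, both mappings enter the weighted mean (the weighted
  average is taken over mappings, not over a deduplicated cover). Genomes
  are compared by cutting them into ~10 kb chunks first.
* identical bases — IDY × TL.
* covered target bases — the *union* (not sum) of mapped target intervals,
  on half-open intervals with adjacent intervals merging; the companion
  count is the number of largest contigs whose mapped intervals reach half
  the target.
* `Cov` — read length × number of reads / genome size.

### Synthetic data (`random_genome`, `evolve`, `simulate_reads`)

The generators emulate the simulation design the pipeline is meant for:
a multi-chromosome random reference; a target evolved from it by
independent per-base substitutions (default rate 0.01) and short indels
(default rate 5×10⁻⁴ each, geometric lengths of mean 3), with every event
recorded in a truth log that reconstructs the target exactly; and uniform
paired-end reads from the target (default 70 b reads, 500 ± 50 b fragments,
fixed Q40 bases, error-free by default, with an optional i.i.d.
substitution error rate). Seeds are explicit arguments everywhere; there is
no hidden RNG state.

What the generators deliberately do **not** emulate: rearrangements,
duplications and mobile elements; repeat structure (the random reference is
essentially repeat-free at k = 21); instrument-specific error and quality
profiles; GC or positional coverage bias. Passing tests on this synthetic
regime therefore demonstrate the pipeline's core promise — recovering
point-mutation-scale divergence — not robustness to repeat-heavy or
biased real data. On real genomes with substantial repeat content the
ambiguous-mapping fraction and the misassembly rate will both be higher.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; the 1-based
  inclusive show-coords convention is converted exactly once at the I/O
  boundary (minus-strand query coordinates are written reversed).
* FASTQ qualities are Sanger Phred+33, range 0–93; 94 is an error, not a
  clamp. Ambiguity codes other than `N` are rejected loudly rather than
  folded to `N`.
* All tie-breaks (assembly branch votes, seed order, $Q_\mathrm{map}$
  selection, overlap winners) are total orders, so every stage is
  deterministic and re-runs byte-reproduce every artifact.
* Degenerate inputs: an empty read set assembles to an empty contig set;
  reads all shorter than k warn and return empty; chromosomes shorter than
  `d` yield no pseudoreads; zero placements make splicing the identity on
  the reference; an assembly with no mappings to the target has undefined
  identity and raises an error rather than reporting 0 or 100.

## Problem sizes

The test suite exercises the pipeline end to end at 20–100 kb and the
full scaled-down study at 1 Mb (three chromosomes, 1% SNPs plus indels,
~110,000 error-free 70 b pairs ≈ 15×, k = 21) over three seeds, taking the
median contig error; `scripts/acceptance.R` repeats that 1 Mb protocol from
scratch for any seed. These sizes were chosen so a single run completes in
about a minute on one core while keeping per-chromosome lengths three
orders of magnitude above the k-mer size.

## Known limitations

* Repeats longer than k collapse in the de Bruijn graph; the greedy walk
  stops rather than untangling them, and repetitive seeds are skipped in
  mapping, so heavy repeat content fragments the assembly and inflates the
  ambiguous fraction.
* A misassembled (chimeric or partially inverted) contig is mapped as a
  single record whose unalignable interior is charged as gap columns; a
  MUMmer-style split into multiple alignments would instead report several
  high-identity segments. This makes the reported Error conservative in the
  presence of misassemblies; the acceptance protocol's median over seeds
  absorbs the occasional outlier.
* Contig order and orientation come entirely from the reference; pair
  information is not used for scaffolding, and true structural variation
  between sample and reference will be silently normalised toward the
  reference layout.
* The evolver applies events to the reference coordinate system only;
  nested/overlapping indel chains are linearised (later events inside an
  earlier deletion are dropped), which is adequate at the ~1% rates it
  targets.
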