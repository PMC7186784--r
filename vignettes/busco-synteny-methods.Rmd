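---
title: "Ortholog-anchored macrosynteny and assembly statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ortholog-anchored macrosynteny and assembly statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buscosynteny)
```

# The method

## Single-copy orthologs as synteny anchors

Synteny is used here in the strict sense of conservation of the order of
orthologous genes between species. The anchor unit is the BUSCO single-copy
ortholog (SCO): a gene from a lineage-specific catalog (a few thousand
genes expected to be present exactly once) whose status in a given assembly
is `Complete`. Because a `Complete` BUSCO has exactly one placement per
genome, the intersection of two genomes' SCO sets defines an unambiguous
one-to-one coordinate mapping — no alignment, no annotation transfer, no
paralogy resolution. `Duplicated` orthologs are counted in summaries but
excluded from synteny: a gene with two copies cannot anchor a one-to-one
link. `Fragmented` placements are excluded as unreliable.

The assumptions this rests on:

* both assemblies are chromosome-level — on fragmented assemblies the
  chromosome-pair graph degenerates into many tiny components and the
  event logic below reads noise;
* the BUSCO catalog is dense enough that every chromosome carries multiple
  SCOs (a few per chromosome at minimum; see `min_links`);
* gene content is conserved — the method sees only presence and position,
  not sequence divergence.

## From links to events

`build_links()` joins the two placement sets on ortholog id. Each shared
SCO becomes one link `(chrom_a, start_a, end_a, chrom_b, start_b, end_b)`;
link coordinates span the full gene interval because Circos link records
take ranges.

`filter_single_relocations()` removes links whose `(chrom_a, chrom_b)` pair
has fewer than `min_links` supporting SCOs (default 2). A chromosome pair
supported by one ortholog — a *single relocation* — is one gene moving, not
a chromosome rearranging. The threshold is deliberately exposed: the
definition of "too few to interpret" is a judgment call, and on sparse
catalogs a higher value may be warranted. Filtering removes these links
from event analysis entirely, not only from diagrams, because a singleton
pair cannot evidence a fusion or fission.

`build_graph()` collapses the surviving links into a bipartite graph —
chromosomes as vertices, chromosome pairs as edges weighted by link count —
and `event_report()` classifies each connected component by the number of
chromosomes `a` and `b` it contains on each side:

| a | b | classification | events |
|---|---|----------------|--------|
| 1 | 1 | `one_to_one`   | 0      |
| 1 | >1 | `fusion_in_a` | b − 1  |
| >1 | 1 | `fission_in_a`| a − 1  |
| >1 | >1 | `complex`    | ≥ a + b − 2 |

For a complex component `a + b − 2` is reported as a *minimum*: a connected
bipartite component can always be produced by merging all `a` chromosomes
(`a − 1` fusions) and resplitting into `b` (`b − 1` fissions), and no
shorter fusion/fission sequence exists (verified in the test suite by
breadth-first search over all small bipartite topologies). The true history
is underdetermined at this resolution, so no attempt is made to narrate it.

Event labels are *relative*: a `fusion_in_a` component is equally a fission
in B. Polarity — which lineage changed — requires an outgroup; with three
genomes, an event shared by two of them parsimoniously belongs to the
third's lineage. The package reports two-genome comparisons and leaves the
three-way argument to the analyst, flagging the ambiguity in every report.

Chromosomes with no surviving links are listed as `unlinked` rather than
entering the event count: absence of shared SCOs is a data property (sparse
catalog, unplaced scaffolds), not a rearrangement.

## Merging forward and reverse-complement BUSCO runs

Gene predictors embedded in BUSCO are not perfectly strand-symmetric:
running the same catalog on the reverse complement of an assembly recovers
orthologs the forward run missed. `remap_revcomp()` maps a placement
`[s, e]` on the reverse complement of a scaffold of length `L` to
`[L − e + 1, L − s + 1]` — an involution that preserves interval length —
and `merge_runs()` keeps, per ortholog, the better record under the
precedence `Complete > Duplicated > Fragmented > Missing`. On a status tie
the forward record wins: the forward assembly is the published coordinate
frame, and there is no principled reason to prefer the revcomp locus when
both runs agree on status. This tie rule is a package decision; the
alternative (preferring the higher-scoring record) changes coordinates
only, never status counts.

## Assembly statistics

`assembly_report()` computes the Assemblathon-lineage metric set at
scaffold and contig level. Conventions, all following that script lineage:

* **Gap definition.** A contig is a maximal scaffold span containing no run
  of ≥ `min_gap` consecutive `N` (default 10, case-insensitive); shorter
  N-runs stay inside contigs. Leading/trailing qualifying runs are gaps
  that bound no contig — no zero-length contigs are emitted — but their
  bases still count toward scaffold totals, so
  Σ contig + Σ gap = Σ scaffold holds on every input.
* **Nx/Lx.** Lengths are sorted descending; `Nx` is the length of the
  sequence at which the cumulative sum first reaches ⌈x% of the total⌉
  (total includes `N` residues), `Lx` its 1-based rank. Ties take the
  earlier, larger-length rank.
* **Median.** Integer output: an even count takes the lower of the two
  central values.
* **Means** are reported rounded to the nearest integer in the text
  rendering; the report object keeps full precision.
* **Threshold rows** ("> 1 Kb" … "> 10 Mb") report counts and
  count-percentages (share of sequences, not of bases).
* **Scaffolded vs unscaffolded.** A scaffold with ≥1 qualifying gap is
  scaffolded and its contigs are "in scaffolds"; a gap-free scaffold is one
  unscaffolded contig. The percentage of assembly in scaffolded contigs is
  computed over total contig bases, so the two percentages always sum
  to 100.
* **Composition** is case-insensitive, with percentages over all residues
  including `N`; residues outside `{A,C,G,T,N}` (IUPAC ambiguity codes)
  are one pooled class. Contig-level composition is derived exactly from
  scaffold composition minus gap bases (gaps are all `N`).
* No minimum contig length: real assemblies contain contigs of a few dozen
  bases and they are counted.

# The simulator

`simulate_pair()` draws an ancestral karyotype, places the ortholog catalog
uniformly (chromosome choice proportional to length; intervals
non-overlapping, laid out by distributing the free slack uniformly),
overwrites N-gap runs into ortholog-free regions, and derives genome B by
applying an ordered event list: fusion concatenates two chromosomes with a
100-`N` junction (so the fused chromosome is one scaffold of two contigs —
the same fixture exercises the statistics and the synteny engines), fission
splits at a uniform breakpoint outside any ortholog (100 retries, then a
configuration error), relocation moves one ortholog to a uniform free
position on another chromosome. BUSCO status noise (missing, duplicated,
fragmented) is applied independently per genome after the events, mimicking
per-assembly dropout. All randomness flows from one integer seed; identical
configurations give byte-identical outputs.

Default conditions (chosen once, as the study conditions the package
validates under): a 27-chromosome ancestor with two fusions — giving a
25-chromosome derived genome, the emydid-like contrast that motivates the
method — a 3,950-ortholog catalog (the size of a typical tetrapod BUSCO
set), noise rates 1.5% missing / 0.6% duplicated / 2.7% fragmented (the
order observed in high-quality chelonian assemblies), and five gap runs of
10–8,000 bp per chromosome (mean ≈ 4 kb, the order of real inter-contig
breaks). Chromosome lengths default to 0.2–0.8 Mb — three orders of
magnitude below real chromosomes — because the method consumes ortholog
*density per chromosome*, not absolute length; sequence scale only affects
FASTA generation cost. A random fusion may draw an already-fused
chromosome, chaining three ancestral chromosomes into one: the component
then carries two events, which is why recovery is measured in events, not
components.

What the simulator does **not** emulate: sequence evolution (content is
uniform random; substitutions, repeats and GC structure are irrelevant to a
coordinate-based method), inversions (orientation is recorded but never
consumed — position-only links cannot see them), translocation of multi-gene
segments (only whole-chromosome events and single-ortholog relocations),
and assembly error (misjoins, collapsed repeats). Passing the validation
suite therefore demonstrates correct event arithmetic under clean
chromosome-level input, not robustness to assembly artifacts.

# Validation design and problem sizes

The test suite checks each stage against an independent oracle: a linear
character-scan oracle for contig decomposition, a step-by-step
cumulative-sum oracle for Nx/Lx (1,000 random multisets), algebraic
involution checks for coordinate remapping (10,000 random intervals), BFS
over fusion/fission sequences for the minimum-event claim, and the
simulator's planted truth for end-to-end recovery: 200 seeded replicates
with 0–5 fusions on a 6-chromosome ancestor carrying 20 SCOs per
chromosome, zero noise, requiring exact event recovery in ≥95% of
replicates (observed: 100%) and zero spurious events in every null
replicate. `scripts/acceptance.R` re-runs the default-conditions simulation
and the replicate experiment from scratch and writes the measured
quantities as JSON.

Two further checks compare the statistics and merge engines against a
published ~2.3-Gb chromosome-level turtle assembly and its BUSCO runs;
they require those reference files locally (supplied via `options()`, see
`tests/testthat/test-acceptance.R`) and fail informatively when absent.

# Degenerate inputs and edge behavior

* Empty FASTA → empty record set with a warning; duplicate scaffold ids →
  error (downstream coordinate lookups require uniqueness).
* BUSCO rows with `Start > End` (minus-strand predictions in some builds)
  are normalized by swapping, with a message; unknown statuses and
  non-numeric coordinates are errors carrying line numbers.
* An ortholog id present in only one of two runs being merged is treated
  as `Missing` in the other, with a warning.
* Two `Complete` records for one ortholog id in one genome is an integrity
  error, never silently resolved.
* `min_links = 1` disables relocation filtering; `max_gap_a = Inf` (the
  default) makes blocks positionally unbounded, since event logic operates
  at whole-chromosome resolution.
* Circos writers are byte-deterministic (links sorted by chromosome,
  start, ortholog id) and, in strict mode, reject links outside the
  karyotype.

# Known limitations

* Event counts between two genomes are minima and relative; complex
  components are not decomposed into ordered histories.
* Inversions and intra-chromosomal rearrangements are invisible by design.
* The method inherits BUSCO's blind spots: catalog genes absent from a
  lineage, and chromosomes with few catalog genes (microchromosomes),
  contribute weak or no signal — raising `min_links` trades sensitivity on
  such chromosomes for robustness.
* Statistics are computed in memory on full sequence strings; assemblies in
  the multi-gigabase range are handled, but streaming parsing is not
  attempted.
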