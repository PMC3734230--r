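---
title: "Methods: comparative analysis of plant mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of plant mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

Plant mitochondrial genomes are large, recombination-prone molecules
conventionally assembled as a circular "master circle". `mtcompare`
implements the comparative analyses such a genome invites once it is
annotated: the repeat landscape, chloroplast-to-mitochondrion DNA transfer
(MTPT), the origin census of mitochondrial tRNAs, circular gene-order
synteny, masked shared-sequence totals, and a conserved-gene concatenation
phylogeny. Annotation itself (gene calling, tRNA prediction) is an upstream
input, not something the package re-does.

The data model is deliberately small. A genome is a circular string over
A,C,G,T,N. Features live in a tidy table with one row per exon, 1-based
inclusive coordinates, and a `start > end` convention for intervals that
wrap through the origin (wrapping features are never split in two). A
trans-spliced gene such as *nad1* appears as one feature per cis-contiguous
exon block, sharing the locus name and carrying a `trans_block` label
(`nad1e`, `nad1d`, ...): those blocks are independent transcription units
and are treated as separate entries in the gene order. Duplicate gene
copies share the locus label and differ in `copy_index`, matching the
convention that duplicates "carry the same number" in published gene-order
maps.

## Coordinate and rounding conventions

* Intergenic gaps are `start2 - end1 - 1` in the transcription direction,
  modulo the genome length on origin-spanning pairs. Zero means touching
  genes; negative values report coding overlap. Published cluster tables
  print positive gaps under this same convention but print overlaps as
  `start2 - end1`; we keep the single uniform formula (one testable rule)
  and document that our overlap values are one less than those printed.
* Percentages are rounded half-away-from-zero at one decimal. This is the
  rule under which the published genic and repeat coverages (9.9%, 1.1%,
  18.9%, ...) recompute exactly from their integer totals; base R's
  half-to-even rounding does not reproduce them.
* GFF3 output stays 1-based inclusive; BED output converts exactly to
  0-based half-open. Conversions are bit-exact in both directions.

# The matching engine

One seed-and-extend engine (`find_local_matches()`) backs the repeat
scanner, the MTPT scanner and the shared-sequence stage:

1. exact `k`-mer seeds on both strands (2-bit encoded; words containing N
   are skipped; words occurring more than `max_occ` times are dropped as
   low-complexity guards);
2. chaining of seeds along exact diagonals with a bounded start-to-start
   gap;
3. a maximum-scoring-subsegment (Kadane) trim of each chained core, because
   a chain can absorb a stray same-diagonal seed from flanking sequence and
   otherwise dilute the hit below the identity floor;
4. ungapped X-drop extension (+1 match, -2 mismatch, drop 12) trimmed back
   to the score maximum;
5. an identity polish that keeps walking outward and accepts a new
   (matching) end position while the whole hit stays at or above the
   identity floor and the freshly added segment stays within 15 points of
   it. The polish recovers the full span of a uniformly diverged region
   instead of stopping at the score optimum, while random flanking sequence
   (~25% matches) halts it within a few bases; ends are always trimmed to
   exact matches.

The alignment model is substitutions-only, matching the generator's default
divergence process; under indel divergence the engine reports the best
ungapped pieces rather than one gapped alignment, which is a documented
limitation. Self-comparison excludes the trivial diagonal and mirror
duplicates; circular genomes are scanned as the doubled sequence, with
coordinates folded back modulo the length and "shadow" fragments of
origin-spanning hits removed by circular containment.

Seed sizes are per-stage defaults, chosen for the divergence regime each
stage faces: 15 for repeat self-comparison (published plant-mtDNA repeat
families sit mostly above 90% identity; the lowest printed family is
83.2%), 6 for the MTPT scan, and 11 for shared-sequence totals. The MTPT
choice is the one that matters: segments as short as 36 bp at the 80%
reporting floor often lack any intact 11-mer (at 7 mutations in 36 bp the
chance of an intact 6-mer run is ~99.7%, of an intact 11-mer only ~55%), so
a conventional word size silently loses exactly the short diverged
segments the survey is about. With `k = 6`, chaining plus the identity
polish, planted-insert recall at the study conditions is complete in the
test suite. All three are config arguments.

# Repeat landscape

`find_repeats()` clusters hit copies by single linkage: copy intervals
overlapping reciprocally by at least half are one copy; hits link copies
into families; orientation parity is propagated over the hit graph from the
lowest-coordinate copy. A family is DR when all copies share orientation,
IR for an opposite two-copy family, IR/DR for three or more copies in mixed
orientations. `rep_length` is the longest alignment in the family and
family identity is the minimum pairwise identity among its copies; families
are numbered R01, R02, ... by decreasing length with ties broken by first
start. The landscape table uses closed-open size classes on the published
boundaries (20-39, ..., 100-999, >=1000); per-class totals sum copy
lengths, while overall coverage merges copy intervals first, which is why
overall coverage can sit well below the class sum when large repeats
overlap other copies.

# MTPT scanning and classification

`scan_plastid_homologs()` filters hits at 80% identity (the conventional
reporting floor) and 30 bp (just under the smallest published segment,
36 bp), merges overlapping mitochondrial intervals at merge distance 0, and
keeps the best-identity chloroplast source per merged segment. Counts are
therefore merge-parameter-sensitive, which is worth remembering when
comparing against published per-species counts. Classification is by the
chloroplast annotation of the source interval: tRNA genes take precedence,
then photosynthesis-related genes (psa*/psb*/pet*/rbcL/ndh*), else
"other". Coverage summaries use merged non-redundant intervals.

# tRNA origin census and gain/loss placement

A mitochondrial tRNA is chloroplast-like when its best local alignment to a
chloroplast tRNA of the same isotype reaches 85% identity (inclusive) over
at least 90% of its own length; both floors are arguments. The thresholds
sit between the MTPT reporting floor (80%) and the near-identity of recent
transfers, so known cp-derived tRNAs classify as cp-like while diverged
native tRNAs do not. Classification is per annotated gene, not per
isotype.

On a fixed, user-supplied species tree (never estimated here), cp-like
presence evolves under Dollo parsimony - a single uptake, counted on the
stem when every tip carries the character, with unlimited subsequent
losses - while native presence is loss-only below the root, reflecting a
primitively complete ancestral tRNA set. Both placements are provably
minimal (the test suite checks them against exhaustive enumeration over all
internal labelings) and ties are resolved by delaying events toward the
tips. `replay_events()` replays an event table down the tree; replays
reproduce the observed grid exactly, which the suite asserts on random
grids.

# Gene order and synteny

The circular gene order contains protein and rRNA entries only (tRNAs,
pseudogenes and remnants excluded), sorted by start coordinate, with
trans-spliced blocks as separate entries. A shared adjacency is an
unordered label pair adjacent in both genomes with the same relative
orientation (a flag disables orientation awareness); each label pair counts
once regardless of copy multiplicity, so multicopy loci cannot inflate
counts. `count_synteny_clusters()` defaults to "pair" mode (any two linked
genes are one cluster, the convention of the published 25-genome matrix)
and offers "run" mode (maximal chains) for the multi-gene cluster view.
Strict adjacency is required - no tolerance for an intervening gene -
because the published counting note does not license a gap tolerance.
Cluster status in a genome is "#" (member missing, taking precedence), "+"
(members consecutive in either circular direction on one strand), or "-"
(broken).

# Masked shared sequence

Before pairwise comparison, `mask_genome()` removes chloroplast-derived
intervals and every copy but the first of each repeat family at or above
1 kb (the top published size class; the cutoff is an argument because the
source convention is unstated). Removed intervals become N in the masked
sequence, so the engine can never match them; the kept/removed partition is
exact. `shared_length()` is query-based (merged query intervals), and the
matrix reports both directions because the symmetrization of the published
table is unstated; directional totals agree within a few percent on
generator panels. Search parameters (70% identity, 50 bp, word 11) are
explicit configuration embedded in rendered outputs.

# Concatenated phylogeny

`concatenate_loci()` joins per-locus alignments head-to-tail in a stated
order, with partition bookkeeping and strict errors on missing species
(one designated copy per species is required for multicopy loci). The
21-locus conserved roster (17 respiratory complex genes plus ccmB, ccmC,
ccmFC, ccmFN) and its five functional subsets are built in. Distances are
p-distances with pairwise deletion - the simplest defensible choice since
no substitution-model protocol is published for these trees. Neighbor
joining is implemented in the package because the required behavior is
contractual: negative branch estimates are clamped to zero with the
deficit moved to the sister branch, and Q-criterion ties break
deterministically by taxon-name order. On additive matrices it is exact
(100-tree property test, cross-checked against `ape::nj` topologies);
Robinson-Foulds distances go through `phangorn::RF.dist` and are verified
against a brute-force bipartition comparison. Maximum-likelihood inference
and bootstrap support are out of scope.

# The synthetic genome generator

`generate_mt_genome()` emulates the architecture the analyses consume:

* background sequence i.i.d. at GC 0.45 (plant mtDNA-like; no Markov
  structure - the simplest null that still exercises identity thresholds,
  and a documented limitation: real intergenic mtDNA is not i.i.d.);
* a higher-plant gene roster with ten co-transcribed clusters, trans-spliced
  nad1/nad5 blocks, multi-exon genes and three rRNAs;
* planted repeat families across the published size classes (20 bp up into
  the multi-kb class) in DR/IR/IR-DR orientations at configurable
  divergence (default 0: the calibration points the validation suite uses
  are divergence 0 and 2%);
* a compact annotated chloroplast partner (default 30 kb) carrying tRNA,
  photosynthesis and other genes, from which MTPT insertions (36-2,185 bp,
  identity uniform on [0.8, 1], mirroring the >=80% reporting floor) and
  cp-like tRNA copies are drawn;
* native tRNAs as annotated background sequence.

Placement draws every element first and then packs largest-first, sampling
uniformly over all feasible positions with a clearance margin, so packing
fails only when the plans genuinely do not fit; failures raise an
"infeasible packing" error naming the overflow. Everything is deterministic
under the mandatory seed, and a truth table records every planted element.

`generate_related_pair()` derives genome B from A by block inversions and
transpositions acting between features (cut points fall in inter-feature
sequence, so genes are never split; tRNAs inside a block travel with it),
and records the surviving shared-adjacency count computed by direct
enumeration on the abstract orders - independent of the package's adjacency
code. `generate_species_set()` evolves the root genome down a tree with
per-branch substitution rates and scripted per-branch events (cp-like tRNA
gains, tRNA losses, block inversions).

What passing tests on this generator do show: correct interval arithmetic,
recall of planted homology at stated divergences, correct family/orientation
logic, minimal parsimony placements, exact NJ on additive distances, and
deterministic end-to-end behavior. What they do not show: performance of
the thresholds on real mtDNA, where repeats are not i.i.d.-background
insertions, MTPT boundaries are blurred by post-insertion rearrangement,
and gene conversion homogenizes repeat copies.

# Problem sizes and numerical choices

The validation suite scales simulations to keep each property check fast
while preserving the conditions it certifies: repeat-recall fixtures are
15 kb genomes carrying one family per size class (hundreds of seeds),
MTPT fixtures 20 kb mt genomes against an 18 kb chloroplast with seven-plus
inserts each, panels 30-60 kb with thinned rosters, and the full pipeline
runs at 60-100 kb. Parsimony placements are checked against exhaustive
enumeration on 6-taxon trees (32 internal labelings), NJ on up to 10 taxa.
Degenerate inputs are defined, not special-cased: empty annotations
tabulate to zeros, empty repeat sets give an all-zero landscape, an empty
kept set warns and shares 0 bp, and a single-group panel warns that
universal and group-specific cluster sets coincide.

# Known limitations

* Ungapped extension: indel-diverged copies report as split hits, so
  alignment lengths equal coordinate spans here, whereas published family
  sizes can exceed spans under gapped alignment.
* Query-based shared totals are not exactly symmetric; both directions are
  reported rather than silently averaged.
* The MTPT count depends on merge distance; only totals and coverage are
  robust across conventions.
* Dollo/loss-only models exclude recurrent identical uptakes and
  regain-after-loss by construction.
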