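---
title: "camlocus: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{camlocus: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(camlocus)
```

This vignette is the package's own account of its methods: the models and
signals it relies on, the tunable parameters with their defaults and
rationale, what the synthetic-locus generator does and does not emulate,
and the design choices made where more than one reasonable option existed.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Coordinates and sequence conventions

All coordinates are 1-based, fully closed intervals (GenBank style), on the
forward axis of the scaffold; the length of `[start, end]` is
`end − start + 1`. Minus-strand genes keep forward-axis exon coordinates
with the coding order recorded by the strand — a single coordinate frame
keeps the co-linearity and consensus stages simple. Input residues are
normalized to uppercase `A/C/G/T/N`; IUPAC ambiguity codes other than `N`
are mapped to `N` with a warning rather than rejected, because draft
assemblies routinely carry stray codes.

## Recombination-signal model

A recombination signal (RS) is modeled as the canonical heptamer `CACAGTG`
and nonamer `ACAAAAACC` separated by a 12- or 23-bp spacer. `scan_rss()`
counts mismatches against these consensus strings (defaults: heptamer ≤ 2,
nonamer ≤ 3, spacer within ±1 bp of its class) on both strands; the score
is the mismatch sum. A mismatch count against a consensus, rather than a
position-weight matrix, was chosen deliberately: no per-position weights
are available for the target loci, the thresholds stay interpretable, and
the scanner is exactly checkable against brute-force window enumeration
(which the test suite does). All maxima are arguments.

Classification distinguishes a *functional* RS (heptamer ≤ 1 and nonamer
≤ 2 mismatches) from a detected-but-degraded one; the latter is an
ORF-level conserved-feature alteration, not a pseudogenizing lesion. This
mirrors the F-vs-ORF distinction of IMGT-style functionality without
inventing pseudogene calls from signal decay alone.

## Gene finding

V genes are placed by seeded homology: exact 11-mers sampled from each
reference template vote on (reference, diagonal) pairs; diagonals within
3 bp are clustered (small indels), and each placement is scored by ungapped
percent identity over the V-exon (accepting a position that matches under
either of the two top-voted diagonals, so a single 1-bp indel does not
halve the identity). Accepted placements (default ≥ 60 % identity) project
the leader exon, splice dinucleotides and the abutting 23-RS onto the
scaffold. Crucially, these signals are *evaluated and recorded*, not used
as acceptance gates: a model with a broken donor site or a degraded RS is
still reported, carrying flags, so that classification can call P or ORF
with reasons. Lesion-free genes do satisfy all signal requirements
(acceptor `AG`, leader donor `GT`, proper 23-RS abutting the V-exon within
0–1 bp).

Boundary refinement uses hysteresis: the projected exon boundary is kept
unless an offset within ±2 bp improves the RS mismatch total by at least 2.
A real 1-bp deletion shifts the RS by one position and wins by a large
margin (its signal is intact at the shifted position); a chance near-match
next to a merely degraded RS almost never clears the margin. This keeps
frameshift detection (exon length modulo 3 against the reference) reliable
without letting RS-threshold boundary noise displace exon edges.

D segments are too short (~14 bp) for homology, so `find_d_genes()` is
purely signal-based: an inward-facing 12-RS then ≤ 25 bp then a 23-RS.
Cryptic RS pairs do arise by chance in hundreds of kilobases — with the
default maxima roughly one spurious D-shaped pair per 300 kb — so the
pipeline restricts D calls to a window (default 800 bp) immediately
upstream of each homology-confirmed J cluster and keeps the best-scoring
candidate per cluster. This mirrors how D-J-C units are annotated against
a reference locus in practice; the standalone scanner remains available
and unrestricted.

J exons are placed by homology, validated by their 5' 12-RS and 3' donor
`GT`, and translated in the frame fixed by the donor (the last complete
codon ends at the exon boundary) to record whether the conserved
Phe-Gly-X-Gly (FGXG) motif is present. Its absence — as in natural
variants reading FGLS — downgrades a J gene to ORF, not P, since such
genes are still tabulated among genes rather than pseudogenes. C genes are
placed as 4-exon templates with `GT`/`AG` checked at every junction and the
spliced translation attached.

## Functionality classes

`classify_gene()` applies, in severity order `nd > P > ORF > F`:

* `nd` — any exon overlaps an N-gap or runs off the scaffold end
  (dominates everything; an incomplete sequence cannot be classified);
* `P` — in-frame stop codon, frameshift (coding length differs from the
  reference length modulo 3), non-canonical obligatory splice
  dinucleotide, or missing leader (V genes);
* `ORF` — reading frame intact but a conserved feature altered: RS above
  the functional threshold, coding length outside the expected range, or
  FGXG absent (J genes);
* `F` — none of the above; the reasons vector is empty.

Expected coding lengths default to V-exon 280–310 bp, D 10–20 bp, J
40–60 bp, C spliced CDS 500–560 bp. The length criterion is stated
qualitatively in annotation practice; these brackets cover the canonical
segment sizes with slack and are exposed as arguments. Multiple P-level
reasons are all reported; ties are never collapsed.

## Subgroups and nomenclature

Pairwise identity is computed from a global Needleman–Wunsch alignment
(match +1, mismatch −1; an L-bp gap costs 5 + (L − 1), i.e. gap opening 4
plus 1 per base in Biostrings' parameterization — the reading of "open −5,
extend −1" in which the first gap base costs 5). Identity is matching
columns over aligned columns, excluding end-gap overhangs from the
denominator because draft gene calls may truncate termini. Subgroups are
the single-linkage components of the graph with edges at identity strictly
greater than 75 % ("more than 75 %"), which matches the transitive way
subgroup membership is used in immunogenetics and makes the union-find
oracle in the tests exact. Subgroup numbering follows the 5'-most member,
so input order is irrelevant.

A subgroup inherits the name of its best-identity reference subgroup when
that identity clears the same threshold; multi-member subgroups append
`S1, S2, ...` in genomic order; unmatched subgroups get provisional numbers
after the last reference number. Positional-override naming (a gene kept
on its positional name despite closer phylogenetic affinity elsewhere) is
supported only through an explicit user-supplied alias in the fixture's
reconciled name column, never inferred.

## Phylogenetics

Distances are p-distances — base differences per site — after complete
deletion: every column holding `-` or `N` in any row is removed globally.
Trees come from the Saitou–Nei neighbor-joining agglomeration with the
Q-criterion and standard branch lengths; ties in Q break on the
lexicographically smallest pair of cluster labels, so results are
deterministic. Negative branch lengths are clamped to zero with the
deficit moved to the sister branch, preserving the joined pair's path
length (a common convention; the choice is logged here because the
algorithm's sources are silent on it). Trees are returned as `ape::phylo`
objects, so newick round-trips and plotting are standard; `ape::nj` serves
as an independent cross-check in the tests, never as the implementation.
Bootstrap supports resample retained columns with replacement and report,
for each internal edge of the original tree, the percentage of replicate
trees containing the same split. Tree lengths are printed to 8 decimal
places.

Published tree statistics that depend on a specific aligner and program
build (sums of branch lengths, exact retained-position counts) are not
reproduction targets; the package promises the NJ and p-distance contracts
above, verified on additive matrices where the answer is exact.

## Comparative layer

`pip_segments()` produces ungapped local alignments (k-mer seeds, diagonal
merging, X-drop-style extension, per-diagonal merging) — the percentage
identity plot view in which long horizontal lines indicate co-linearity and
interruptions betray assembly gaps; `N` never matches, so a gap run breaks
the homology line, as it should. Gapped chaining is deliberately out of
scope. GC is reported per window over non-N bases, with all-N windows
`NA`, never 0.

The per-subgroup summary counts genes, pseudogenes and `nd` calls per
species; the functional percentage is `(total − P − nd) / total`, rounded —
the denominator includes `nd` genes, the reading under which the published
per-species percentages are reproducible from their own table. The
transcribed table ships verbatim, including its printed totals row; where a
printed total disagrees with the column sum (the human column differs by
one), `summarize_annotation()` preserves both and flags the inconsistency
rather than silently reconciling it. The same policy covers the other
internal tensions of the source tables (a pseudogene tally stated as six
where the marks sum to seven; a functional percentage stated as 80 where
the table arithmetic gives 73): the fixtures carry the table as printed,
and the one gene-level contradiction (TRBV12S1 listed both as a shared
pseudogene and as functional in the wild Bactrian camel) is resolved in
favor of the explicit gene-level statement, which also makes the stated
per-species pseudogene count (nine) come out exactly.

The consensus ("virtual") locus applies the 2-of-3 rule: a gene is
consensus if present in at least two of the three species, its label is
the one shared by at least two, and any disagreement among the carrying
species is recorded as a variation note. Genes present in one species only
are listed as unconfirmed. With no majority label (e.g. F/ORF/nd), the
consensus label is `nd` and the disagreement is noted — the map never
invents a call.

## The synthetic locus generator

`generate_locus()` emulates the architecture the annotation stage targets:
5' marker gene; a V region of `n_v_genes` genes in `n_subgroups` subgroups
(each V: 48-bp leader starting `ATG`, 90-bp `GT..AG` intron, 294-bp V-exon,
23-RS abutting the exon); TRY-like single-exon protease genes, all but one
in a block after the first V and the last before cluster 1; `n_djc_clusters`
D-J-C clusters (14-bp D between inward-facing 12/23-RSs, 6–7 J genes each
with 12-RS, FGXG-bearing 48-bp exon and donor `GT`, a 4-exon C gene whose
spliced CDS encodes 178 residues plus the stop); one V gene in inverted
orientation 3' of the clusters; 3' marker gene. Subgroup ancestors derive
from one archetype mutated at `subgroup_divergence` (default 0.35
substitutions/site, putting between-subgroup identity far below the 75 %
threshold); members derive from their ancestor at
`within_subgroup_divergence` (default 0.05, keeping within-subgroup
identity far above it). Coding mutations that would create an in-frame
stop are skipped, and splice/start elements are protected, so an
intended-functional gene is actually functional. RS elements are planted
as consensus with light noise bounded inside the functional band (heptamer
≤ 1, nonamer ≤ 2 mismatches) — unbounded noise would silently convert
intended-F genes to ORF and break the planted labels.

Lesions are drawn per V gene with probability `pseudogene_rate` from
`lesion_mix`: `stop` (one sense codon → stop, in frame), `frameshift`
(1-bp deletion in the V-exon), `splice` (donor or acceptor dinucleotide
broken) plant label P; `rs_defect` (3 heptamer positions mutated) plants
label ORF. The truth table records coordinates, strand, subgroup, label
and lesion for every gene; `fragment_assembly()` additionally remaps truth
onto overlapping or gapped scaffolds and can deliberately split a gene
(marked `nd`). A single RNG stream per seed, consumed in configuration
order, makes generation byte-reproducible.

What the generator does **not** emulate: interspersed repeats (no
LINE/SINE content — repeat quantification is out of scope), allelic
polymorphism, expression evidence, sequencing error models, and TRY gene
internal structure beyond a single-exon CDS (the real genes' exon count is
not modeled; this is a modeling choice, not a claim about the biology).
Passing the recovery tests therefore demonstrates correctness of the
detection logic under the planted signal model, not performance on real
draft assemblies, whose repeat content and error processes are richer.

## Problem sizes and numerical choices

The default configuration (33 V genes, 26 subgroups, three clusters,
6/7/6 J genes, five TRY genes, GC 0.45) mirrors the camelid architecture;
with the default inter-V spacing of 6.5–8.5 kb the locus comes out near
300 kb. The test suite and the acceptance script run the same architecture
at 2–3 kb spacing (~130 kb loci) — the package's own choice of problem
size, which preserves every structural feature while keeping a 20-seed,
two-rate study comfortably fast; spacing affects only intergenic sequence,
which the detectors ignore except for background false-positive
opportunity, and the larger default has been observed to behave
identically in spot checks (the suite itself fixes the smaller size so its
numbers are exactly reproducible).

Other numerical choices: k-mer seeding uses k = 11 with a 4-bp stride and
≥ 5 diagonal votes for V/C/TRY templates (k = 11, 2-bp stride, ≥ 3 votes
for the short J exons); duplicate-region detection anchors on 32-mers and
extends to maximal exact repeats ≥ 200 bp, requiring both copies to
contain a gene model and marking the 3'-most copy as the exclusion
candidate; scaffold stitching accepts exact terminal overlaps only
(≥ 100 bp by default) — inexact merging is a non-goal, and exactness makes
the all-pairs oracle trivial. Ties between references at equal identity go
to the lexicographically smallest name; ties in NJ's Q to the smallest
label pair; both for determinism, not biology.

## Known limitations

* Homology placement assumes the reference library contains a relative of
  every gene; a V subgroup absent from the references is invisible to
  `find_v_genes` (RS scanning alone will still see its 23-RS).
* The D-window heuristic cannot find a D gene whose cluster lost all J
  genes to an assembly gap.
* `pip_segments` is ungapped by design; a single diverged indel-rich
  region appears as several short segments rather than one gapped match.
* Bootstrap supports are attached to the original-tree splits
  (majority mapping); alternative splits' frequencies are not reported.
* On real assemblies, repeat-derived spurious seeds may require masking
  upstream of the pipeline; the package does none.
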