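---
title: "Evaluating mate-pair scaffolding of repeat-rich chromosome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating mate-pair scaffolding of repeat-rich chromosome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffeval)
```

## Scope and model

`scaffeval` quantifies what long-insert mate-pair (MP) data does to a
fragmented shotgun assembly of a repeat-rich chromosome arm, and how much
the resulting scaffolds can be trusted. The package evaluates; it does not
assemble, align or scaffold real data. Its inputs are the tabular artifacts
those tools produce — FASTA sequences, AGP compositions, BLAST-style
tabular hits, read-placement tables — or synthetic equivalents generated
with full ground truth.

Three measurement families sit at the core:

1. **Mate-pair classification.** A pair with both reads placed on the same
   sequence is classified by the strands of its reads in left-to-right
   coordinate order: `RF` is the outward-facing geometry a circularization
   MP protocol should produce, `FR` is the inward geometry of short-insert
   paired-end (PE) contamination, and `FF_RR` (both reads one strand) is
   the signature of an inversion chimera introduced by multiple
   displacement amplification (MDA). Orientation is deliberately defined on
   coordinate-sorted reads rather than read-number order, so it is
   invariant to which mate a sequencer calls "read 1". The insert estimate
   is the outermost span covering both reads — the implied fragment
   length. Pairs on different sequences get orientation `NA` and no insert;
   they carry link evidence, not geometry.

2. **Gene-space fragmentation.** Reference proteins are located in the
   assembly through a translated-search hit table that passes four filters
   (quality gate, de-duplication, cross-protein overlap resolution,
   repeat/spurious-gene exclusion; details below). Per gene, *total
   coverage* sums all hit lengths relative to protein length (repeat genes
   exceed 1), and *adjusted coverage* counts unique covered residues. With
   AC the mean adjusted coverage over genes (hits pooled assembly-wide)
   and SC the mean best single-sequence coverage, the Gene Fragmentation
   Index `GFI = (AC - SC)/AC` isolates fragmentation from completeness: AC
   is invariant under scaffolding, so any GFI decrease is attributable to
   gene parts being joined.

3. **Scaffold reliability.** Misjoins are estimated two ways. The *synteny*
   route uses sequences carrying exactly two full-length reference
   homologs: if scaffolding is sound, the proportion of such pairs that are
   neighbours on the reference gene order (≤ 50 ranks apart, same
   chromosome) should be no lower in scaffolds than in contigs; a one-sided
   bootstrap (resample contig observations with replacement, p = fraction
   of resamples with proportion ≤ the scaffold proportion, equality
   counted) tests that. The *BAC* route assigns scaffolds to independent
   BAC clone sequences (> 99% identity over ≥ 2.5 kb) and scores the
   proportion of member contigs concordant with the assigned BAC (> 99%
   identity over > 50% of the contig); normalizing by scaffold length
   gives the Scaffold Reliability Index (SRI). The two routes see different
   genomic landscapes: synteny only inspects gene-bearing sequences, BACs
   sample everything.

## The hit-filtering rules

The filters run in order on the full hit table:

1. **Quality gate** (protein-level): a query protein is retained, with all
   of its hits, iff at least one hit has alignment length ≥ 30 aa and
   identity ≥ 70%. The gate is deliberately protein-level — a gene with one
   solid exon hit keeps its short flanking exon hits, which legitimately
   contribute coverage. Both thresholds are inclusive.
2. **De-duplication**: within one (query, target) pair, hits identical on
   query start/end, mismatches, gap length and identity collapse to one.
   Equal hits on different targets are genuine repeats, not duplicates.
3. **Overlap resolution**: per query, the mean e-value of all its hits is
   computed; for any two hits of *different* proteins on one target
   overlapping by more than 5 bp of target coordinates, the hit of the
   protein with the higher mean e-value is discarded. The rule is applied
   as a mark-and-sweep against the full incoming table: a hit is removed
   iff *some* overlapping competitor from a better protein exists, whether
   or not that competitor is itself removed. This makes the outcome
   order-independent and exactly reproducible by a naive O(n²) oracle —
   the property the test suite checks on 500 random tables. Ties on mean
   e-value fall back to higher hit identity, then lexicographically
   smaller query id — no standard convention exists, so the tie-break is
   chosen purely for determinism. Overlap is measured in target
   (nucleotide) space because the 5 bp tolerance is a bp quantity; query
   space is in amino acids.
4. **Gene exclusion**: genes with total coverage strictly > 5 (typical of
   transposon-associated coding sequence hit many times over) or adjusted
   coverage strictly < 10% are dropped from all analyses. The boundaries
   5.0 and 0.10 survive, matching the strict inequalities as stated.

Two definitional points were genuinely open and are resolved as package
design decisions, each behind an explicit switch or mode:

* **SC averaging.** "Mean per-sequence coverage" could average over all
  gene-by-sequence pairs or take each gene's best sequence. The default is
  the per-gene maximum (`gfi(..., sc_mode = "max")`): the alternative lets
  a spurious 2-residue secondary hit drag SC down, which measures hit
  scatter rather than fragmentation. `sc_mode = "mean_pairs"` provides the
  other reading.
* **Full-length calling.** `mode = "coverage"` requires one sequence to
  cover ≥ 70% of the protein (inclusive). `mode = "start_stop"`
  additionally requires that sequence's hits to reach residue 1 and the
  final residue — the most literal reading of a start-to-stop criterion.

## The synthetic study conditions

The generator's defaults emulate, at desk scale, a flow-sorted MDA-amplified
wheat chromosome arm; they are fixed once and all pipeline-level tests run
under them.

| parameter | default | rationale |
|---|---|---|
| `genome_length` | 2 Mb | desk-scale arm analogue; large enough for ~350 contigs and 120 genes |
| `repeat_fraction` | 0.80 | repeat content of the motivating genome (> 80%) |
| `repeat_unit_length` | 4600 bp | mean transposon repeat length; sets contig scale ~1–2 kb N50 |
| `n_genes` | 120 | gene rank range must well exceed the 50-rank neighbour threshold |
| `exons_per_gene` | 1–5 | multi-exon structure so genes can split across contigs |
| `gene_length_aa` | 80–300 aa | typical plant protein range at this scale |
| insert specs | 2/3/5 kb, sd 10%, reads 45/35/35 bp, 3000 pairs each | the three MP libraries and read lengths of the motivating study |
| `chimera_rate` | 0.38 | FF/RR fraction observed in MDA mate-pair data |
| `pe_contamination_rate` | 0.30 | PE fraction implied by the observed FR share |
| `scaffold_join_error_rate` | 0.05 | low error regime of a stringent scaffolder |

Mechanistic choices:

* **Repeat layout.** `round(repeat_fraction × L / unit)` identical copies
  of one random repeat unit are placed by uniform stick-breaking, so
  inter-repeat distances are exponential-like with a long tail — contigs
  (the unique segments between copies) then have the realistic skewed
  length distribution in which some contigs are long enough to host whole
  genes and ≥ 2.5 kb BAC alignments, and most are short. The realized
  repeat fraction deviates from the request by at most half a repeat unit.
* **Genes** are placed left-to-right in unique sequence with spacers drawn
  from a short/long mixture (40% within a gene island, 60% a 1–5 kb jump),
  giving clusters spread along the arm. An exon that does not fit in the
  remaining unique segment moves to the next segment, so its intron spans
  one or more repeat copies — exactly the configuration that fragments a
  gene across contigs after assembly. Exons never overlap repeats; rank
  order equals coordinate order.
* **Libraries.** True MP fragments draw Normal(mean, sd) lengths with
  outward (RF) geometry; PE contaminants draw log-normal lengths with
  median ≈ 500 bp truncated at 1000 bp (the observed short-insert
  contamination peak) with FR geometry; chimeras are modelled as
  inverted-segment fusions — both reads on one strand — with log-normal
  spans truncated at 2 kb. A read maps iff it lies wholly inside one unique
  segment; reads in repeats or straddling junctions go unmapped, which is
  what produces singleton and unaligned pairs. Which physical read is
  "read 1" is randomized so classification cannot exploit read order.
* **Scaffolds with controlled errors.** A withheld donor pool supplies
  foreign contigs; the rest are chained in genome order. Each extension is
  a correct join, an inversion (adjacent contig, flipped), or a foreign
  insertion (a donor spliced in, corrupting the joins into and out of it),
  with inversion and insertion drawn equally often at per-step
  probabilities solved so the realized incorrect-join fraction equals the
  requested rate (tested at 3 binomial standard deviations on ~1000
  joins). Donors left unused become single-contig scaffolds, so every
  contig appears exactly once; joins across a withheld donor's home
  position are flagged correct, i.e. correctness is defined relative to the
  contig pool available to the scaffolder.
* **Protein hits and BAC tables** are emitted from truth with exact
  coordinates and 100% identity; optional noise adds sub-threshold hits
  (short and low-identity) and duplicate rows to exercise filters 1–2.
  BAC alignment rows are the interval overlaps between contig (or
  scaffold-lifted) origins and BAC intervals. `extract_bacs()` samples
  random clones as a real BAC set would; `tile_bacs()` provides
  deterministic overlapping windows when a validation needs every scaffold
  fully contained in some BAC.

What the generator does **not** model: sequencing errors and base-quality,
alignment ambiguity in repeats (repeat reads are simply unmapped rather
than multi-mapped), collapsed repeat copies inside contigs, chimeric
contigs, diverged repeat families, and codon-level protein evolution
(identity is binary truth/noise). Consequently a passing test suite shows
the *statistics* behave correctly under the stated mixture and error
models; it does not certify behaviour under aligner-specific artifacts of
real data, and the status proportions (singleton/unaligned) are more
pessimistic than reality because repeat-derived reads never map.

## Numerical and procedural choices

* Internal coordinates are 0-based half-open; BLAST tabular and AGP files
  keep their native 1-based inclusive conventions, converted only at the
  I/O boundary. Minus-strand hits are normalized to ordered intervals plus
  a strand flag.
* N50 uses the descending cumulative-sum convention ("first length at
  which the running total reaches half the assembly"); ties and boundary
  cases follow from that definition and are cross-checked against an
  exhaustive oracle.
* Coverage arithmetic treats published read counts as read *pairs* of the
  stated read length (`pairs × 2 × read_len / arm_size`) — the reading
  consistent with the printed per-arm fold coverages it reproduces.
* The SRI length unit is configurable and recorded in the output
  (default per Kb). A per-bp normalization of a 0–1 proportion yields
  values too small to be meaningfully compared across assemblies;
  comparisons are only valid within one unit choice. Single-contig
  scaffolds carry no joins and are excluded from SRI summaries via
  `multi_contig_scaffolds()`.
* Scaffold–BAC assignment ambiguity is resolved by the largest total
  aligned span, ties to the lexicographically smallest BAC id.
* One global integer seed drives everything; each stage derives a child
  seed from the seed and the stage name (`stage_seed()`), so any stage can
  be rerun in isolation with identical results, and package internals
  never perturb the caller's RNG state.
* Degenerate inputs fail loudly: empty assemblies, empty libraries, empty
  observation sets and zero AC are errors, not silent NA propagation;
  readers report the offending line for malformed rows and never drop rows
  silently.

## Interface decisions

The package's interface is its functions (`simulate_dataset()`,
`run_pipeline()`, `coverage_sweep()`, and the per-stage functions), plus
`scripts/acceptance.R` for a seed-to-JSON reproduction of the headline
numbers. Stage outputs are written as TSV plus one JSON summary per run —
plain-text, diffable artifacts; no binary or HTML report is produced. The
coverage sweep does not re-run a real scaffolder: it rebuilds scaffolds
from link support alone (pairs bridging two contigs, threshold `k`), with
contig order laid out from truth — explicitly a surrogate adequate for
studying how link evidence responds to coverage, not ordering accuracy.

## Problem sizes

The shipped tests and the acceptance script run at deliberately modest
sizes chosen once for the package: a 2 Mb default genome (0.5 Mb for most
unit fixtures), 9000 mate pairs per pipeline run and 10,000 for
class-recovery checks, 500 random instances per oracle-equivalence
property, 1000 simulated studies (B = 200, n = 200) for bootstrap
calibration, and 20 seeds for the SRI discrimination property. The
statistics themselves are size-agnostic; scaling the simulation up changes
runtimes, not code paths.

## Known limitations

* The synteny route is blind to misjoins between gene-poor contigs and to
  any error in sequences with fewer or more than two full-length homologs.
* BAC concordance cannot see orientation errors: an inverted contig still
  aligns to its BAC over its full length. Inversion errors are therefore
  detectable in this framework only through the truth ledger (or, on real
  data, not at all by SRI) — a property inherited from the measure itself.
* With a single reference chromosome in the simulator, cross-chromosome
  non-neighbour pairs arise only via the rank distance, not chromosome
  identity; the predicate handles both, but the default conditions
  exercise mainly the rank route.
* The bootstrap's p-value is slightly conservative at small n because
  equality counts toward the numerator; calibration at n = 200, B = 200 is
  within two percentage points of nominal 5%.
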