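---
title: "Curating Merlin-like TIR transposons: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating Merlin-like TIR transposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tircurator)
```

## The problem

*Merlin* is a superfamily of Class II (DNA) transposons related to the
bacterial IS*1595* insertion-sequence family. A *Merlin* element consists of
a single transposase gene flanked by terminal inverted repeats (TIRs) of
roughly 24–462 bp whose 5' repeat starts with `GG` (and whose 3' repeat
therefore ends with `CC`), and each genomic insertion is flanked by an 8- or
9-bp target site duplication (TSD) — a direct repeat of host sequence
created at integration. The transposase carries the diagnostic
DDE_Tnp_IS1595 domain (~130 aa): three conserved residue blocks, with the
catalytic aspartate–aspartate–glutamate (D-D-E) triad anchored one residue
per block.

Manual curation of these elements in a new genome assembly answers, copy by
copy: where are the transposase copies, where does each element begin and
end, does it retain TIRs and a TSD (evidence of genuine transposition and of
recency), is the catalytic motif intact, do copies fall into families with a
shared TIR, is there internal tandem-repeat structure, and could the
sequence be bacterial contamination rather than a eukaryotic element? This
package turns that manual protocol into testable code, and ships a
synthetic-genome simulator so every stage can be validated against a known
ground truth.

## The pipeline and its models

`run_pipeline()` composes the stages in the order a curator works:

1. **Translated search** (`translated_search()`): tblastn of query
   transposases against the assembly, with the curation expect-value cutoff
   of 1e-3 (first-round discovery uses 1e-4). Overlapping same-strand hits
   from different queries collapse to the best one; same-strand hits within
   300 bp merge into one copy, because pseudogenized copies split alignments.
2. **Copy extraction** (`extract_copies()`): each merged hit cluster is
   extracted with 2000 bp flanks (enough to cover the largest reported TIR
   plus slack), the ORF re-called in the window, and the copy provisionally
   labelled intact / frameshifted / remnant from the motif and frame
   evidence.
3. **Boundary inference** (`infer_boundaries()`): copies of a putative
   family are aligned with their flanks (MAFFT); flanks of independently
   transposed copies are unrelated, so mean pairwise column identity
   collapses outside the element. The boundary is the outermost column where
   a 15-column smoothed identity stays at or above 0.5; ends are then
   trimmed to a column that itself clears the threshold and starts a
   sustained (10-column) conserved stretch, because isolated chance-identical
   flank columns otherwise stop the trim early. Ends whose conserved run
   touches the alignment edge are *unresolved* (identical flanks — e.g.
   segmental duplications — carry no boundary signal) and leave the
   provisional interval untouched.
4. **TIR detection** (`find_tirs()`): a self inverted-repeat search.
   Anchor pairs near the two ends are extended inward while the cumulative
   mismatch fraction stays ≤ 0.5 — permissive enough for highly imperfect
   TIRs (12 mismatches in 26 positions) — stopping after 4 consecutive
   mismatches; each anchor reports its best-scoring prefix
   (score = length − 2 × mismatches). The pipeline searches anchors up to
   ~30 bp from the nominal ends *including into the flanks*, so an
   alignment boundary that is off by a few tens of bp can be corrected in
   either direction. Among GG-compatible candidates (≤ 1 deviation from the
   `GG…CC` convention across the four terminal positions), anchors near the
   nominal termini are preferred on score; a candidate is only allowed to
   move the element limits if its score is at least 8, i.e. clearly above
   chance — a genuinely weak TIR must not have its boundary overwritten by a
   random repeat elsewhere in the window.
5. **TSD detection** (`find_tsd()`): the longest k in 7–10 such that the
   k-mer immediately 5' of the element equals the k-mer immediately 3' of
   it, exactly (TSD conservation is the recency/transposition signal;
   allowing mismatches would blur it — a tunable `max_mismatch` exists).
   Boundary jitter of ±3 bp is scanned; in the pipeline, candidates are
   scored `k − 2·(implied GG…CC deviations) − min(|shift|, 3)`. The
   convention term matters: elements start with `GG`, so whenever the host
   base after the true TSD happens to be `G`, a naive longest-match rule
   would report a k+1 "TSD" that steals the element's terminal base. An
   exact duplication found at a shifted boundary then *pins* the element
   limits — the shift is absorbed into the coordinates, exactly the way a
   curator settles limits where TIR and TSD evidence agree. When the
   alignment boundary was fuzzy the search retries with jitter ±10.
6. **Classification** (`classify_copy()`): family candidate = TIR
   (GG-compatible) + TSD; group member = intact motif without TIR+TSD
   (candidate domesticates or decaying copies); remnant otherwise.
7. **Families and groups** (`assign_families()`): single-linkage clustering
   of family candidates at p-distance ≤ 0.25 over aligned elements, then
   splitting clusters whose member TIRs differ at > 30% of positions;
   groups are clustered the same way. Consensus sequences use strict
   majority with IUPAC degeneracy for split columns — the display convention
   for mismatching TIR positions (R, Y, S, W, K, M…).
8. **Tandem repeats** (`find_tandem_repeats()`): a self-contained
   Tandem-Repeats-Finder-style detector; candidate periods come from shifted
   self-match fractions, runs must keep ≥ 0.8 cumulative match and at least
   half-matched 12-mers locally, and nested repeats at clearly different
   scales (period ratio ≥ 2) are all reported — the published elements
   include 5 units of a 6-bp repeat inside 2.3 units of a 52-bp repeat.
9. **Contamination** (`screen_protein()`, `screen_context()`): best local
   alignment identity (BLOSUM62) against a bacterial reference set with a
   ≥ 50% query-coverage floor; identity strictly above 0.80 is a
   contaminant, 0.40–0.80 is suspect and needs corroboration from ≥ 2
   neighbouring ORFs that are themselves bacterial-like.

## Key tunables

| parameter | default | meaning |
|---|---|---|
| `evalue_round1` / `evalue_round2` | 1e-4 / 1e-3 | discovery / curation expect-value cutoffs |
| `merge_gap` | 300 bp | max gap between hits merged into one copy |
| `flank_bp` | 2000 bp | extraction flank; must exceed max TIR + TSD + slack |
| `boundary_margin` | 1500 bp | window around the hit used for boundary alignment; must exceed the distance from the ORF to the farthest element edge |
| TIR `max_mismatch_frac` | 0.5 | cumulative mismatch ceiling during extension |
| TIR `stop_run` | 4 | consecutive mismatches that stop extension |
| TSD `k_range` / `jitter` | 7–10 / ±3 | duplication lengths and boundary slack |
| `family_linkage` | 0.25 | single-linkage p-distance ceiling within a family |
| `tir_split` | 0.30 | TIR dissimilarity that splits a cluster |
| `contamination_identity` | 0.80 (strict >) | bacterial-identity rule |
| `cluster_identity`, `domain_min_aa`, `trim_gap_threshold`, `final_min_aa` | 0.70, 115, 0.4, 110 | matrix-preparation protocol |

The per-copy GG convention is applied with a tolerance of one deviating
position (of the four terminal convention bases). The convention is a
family-consensus statement; individual copies accumulate substitutions
after insertion, including at their termini, and demanding an exact per-copy
`GG…CC` measurably discards genuinely intact copies already at 5%
divergence.

## The DDE block profile

The published reference for the three-block architecture is an alignment
figure whose residue rows are not machine-readable, so the package builds
its scoring profile from a synthetic eight-row block alignment
(`DDE_BLOCK_ROWS`) that reproduces the documented architecture: block widths
of 12/14/12 columns, strongly conserved anchor columns holding D, D and E,
a block1–block2 spacing of 50–70 aa in typical elements (the allowed scan
range is 40–120 aa to cover reported ~110 aa outliers), and a short
block2–block3 spacing (allowed 10–60 aa). Columns are +0.5-pseudocount
frequencies scored as log2 odds against a uniform background; the scan is a
dynamic program over block placements with ties broken leftmost, and the
default acceptance threshold is 70% of the profile's score on its own
consensus — calibrated so that the false-positive rate on random 400-aa
proteins is below 1% (a property the test suite measures). The simulator
draws its transposase ORFs from the same profile, which makes the scanner's
positive class realistic by construction; on real data the profile should be
rebuilt from a curated alignment via `dde_profile()` / `read_profile()`.

## What the simulator emulates — and what it does not

`simulate_genome()` plants, per family: TIRs of specified length and
planted 5'-vs-3' mismatch count, per-copy independent TSDs (distinct across
copies, as true transposition produces), internal tandem tracts with
optional nesting, per-copy substitution divergence, frameshifted copies
(1-bp ORF deletion), remnants (40–80% truncations — the published remnants
have no stated model, so this is a stand-in), segmental-duplication copies
that carry 300 bp of shared flank, and bacterial-like contaminant contigs
whose ORFs are decoy proteins mutated by ~2%.

Three deliberate idealisations matter when reading test results:

* **Feature maximality.** Planted TIRs are made non-extendable (the first
  three inward base pairs are forced to mismatch) and TSDs non-extendable
  (no homopolymers; the outward base pair mismatches). Without this, chance
  complementarity makes the "true" TIR length ill-defined rather than the
  detector wrong.
* **Purifying selection.** In intact copies, substitutions that would
  create a premature stop, destroy the ATG, or destroy the terminal stop
  are reverted. Diverged-but-preserved ORFs are exactly what selection
  produces in real genomes; without this, every copy at 15% divergence
  would be a pseudogene and "intact" would be unmeasurable.
* **i.i.d. background.** Host sequence is uniform random (optional GC),
  with no genes, repeats or low-complexity tracts. Consequently the false
  positive landscape of real assemblies (satellites, other TE families,
  segmental duplications of host genes) is not represented, and passing
  recall/precision tests here bounds detector logic, not real-genome
  performance.

Divergence emulation for the published copy-pair identities is constructed,
not asserted: `sim_diverged_orf_pair()` plants a target number of
nonsynonymous changes in the conserved core and synonymous third-position
changes elsewhere (the signature of purifying selection), then the package
*measures* nucleotide and amino-acid identity with its own p-distance code.
`sim_homolog_pair()` likewise builds a cross-species protein pair with a
prescribed fraction of identical and of similar (positive-BLOSUM62)
positions and measures identity by local alignment; a ±2 percentage-point
band covers aligner variation.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 output is 1-based
  inclusive; elements are reported on the strand of the transposase ORF and
  `tir5` always refers to the element's 5' repeat on that strand.
* p-distances use pairwise deletion; pairs with zero comparable sites are
  flagged and neighbor-joining refuses them by name. NJ itself is `ape::nj`
  (deterministic); bootstrap resamples columns and counts splits of the
  reference tree.
* The degenerate consensus emits a plain base only on a strict majority;
  50/50 columns get the minimal covering IUPAC code, degenerate input codes
  vote fractionally (which makes the consensus idempotent), and
  gap-majority columns are dropped.
* `find_tsd` ranks candidates rather than returning the first match; the
  scoring is documented above. `find_tirs` reports alternates, and its
  `extendable` flag records extensions stopped by the mismatch-run rule —
  the published "extendable with additional mismatches" situation.
* Single copies leave boundaries unresolved; copies at contig edges carry
  truncation flags and are undetermined (NA, not FALSE) for the
  segmental-duplication test; empty inputs yield empty outputs, not errors.

## Problem sizes

The bundled analyses and tests run on genomes of 15–250 kb with 1–21
planted copies, chosen so each reconstruction isolates one published
finding at the published parameter values (e.g. 2 copies at 99% identity
with 39-bp TIRs and a 9-bp TSD; 4 copies of a 2570-bp element carrying
2.3 × 52-bp and nested 5 × 6-bp repeats; seven 3-copy families with
distinct 23–29 bp TIRs; 20 genomes of five copies at 15% divergence for
recall). These sizes keep every stage's behaviour interpretable against the
truth record while exercising the same code paths a full assembly would.

## Known limitations

* The translated search is delegated to command-line BLAST+ (`tblastn`),
  and alignment to MAFFT; both must be on `PATH`. Externally produced
  12-column tabular hits and aligned FASTA are accepted as drop-in inputs.
* The block profile is synthetic (above); absolute scan scores are
  meaningful only relative to this profile.
* Nested or composite insertions, TIR secondary structure, and
  satellite-homogenization dynamics are out of scope; the Zn_Tnp_IS1595
  N-terminal domain (absent from the elements this package targets) is not
  modelled.
* Bayesian/ML tree inference is external by design: the package prepares
  filtered, trimmed PHYLIP/NEXUS matrices (`size_filter()` >115 aa →
  `identity_cluster()` at 70% → alignment → `trim_columns()` at 0.4 gap
  threshold → `final_length_filter()` ≥110 aa, in that order — the order is
  part of the protocol and permuting it changes the output, which the test
  suite demonstrates).
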