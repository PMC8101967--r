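# tircurator

Structural curation of *Merlin*-like TIR DNA transposons in genome
assemblies.

*Merlin* is a superfamily of Class II (DNA) transposons related to the
bacterial IS*1595* family. An element is a transposase gene flanked by
terminal inverted repeats (TIRs, 24–462 bp, 5' repeat starting `GG`), and
each insertion is bracketed by an 8–9 bp target site duplication (TSD): a
direct repeat of host sequence whose per-copy variation is the fingerprint
of genuine transposition. The transposase carries the diagnostic
DDE_Tnp_IS1595 domain — three conserved residue blocks holding the
catalytic D-D-E triad, with ~50–70 residues between blocks 1 and 2.

The package turns the manual curation protocol for these elements into
code: translated search for transposase copies (`translated_search`, a
tblastn wrapper with a tabular-import adapter), copy extraction with flanks
(`extract_copies`), element boundary inference from multi-copy alignments
(`infer_boundaries`), imperfect-TIR and TSD detection (`find_tirs`,
`find_tsd`), DDE-motif scanning (`scan_dde`), classification of copies into
families / groups / remnants and family assignment with degenerate TIR
consensus (`classify_copy`, `assign_families`, `degenerate_consensus`),
NJ trees with bootstrap (`nj_tree`, `bootstrap_support`), internal
tandem-repeat annotation (`find_tandem_repeats`), bacterial-contamination
screening (`screen_protein`, `screen_context`), and preparation of
filtered/trimmed domain matrices for external tree inference
(`extract_domain`, `size_filter`, `identity_cluster`, `trim_columns`,
`final_length_filter`, `export_matrix`). `run_pipeline` composes the whole
chain. A synthetic-genome simulator (`simulate_genome`) plants elements
with full ground truth so every stage is testable without external data.

The methods vignette (`vignettes/merlin-curation-methods.Rmd`) documents
the models, thresholds and design decisions.

## Requirements and installation

R (≥ 4.1) with Biostrings, GenomicRanges, rtracklayer, ape and jsonlite;
command-line BLAST+ (`makeblastdb`, `tblastn`) and MAFFT on `PATH`.

```sh
R CMD INSTALL .
# tests:
Rscript -e 'testthat::test_dir("tests/testthat", package = "tircurator", load_package = "installed")'
```

## Worked example

The numbered scripts under `analysis/` form a small end-to-end study.
`analysis/01_simulate.R` builds a 50-kb genome with two planted families
(3 copies each: 30-bp TIRs with 8-bp TSDs, and 24-bp TIRs with 9-bp TSDs at
2% divergence) plus one bacterial contaminant contig;
`analysis/02_curate.R` runs the pipeline against it:

```
recovered 6 / 6 planted copies
families: 2 (planted: 2); groups: 0
  F1: 3 members, modal TSD 9 bp, activity unclear
  F2: 3 members, modal TSD 8 bp, activity recent
```

Both planted families are recovered with correct memberships and modal TSD
lengths; the zero-divergence family is dated `recent` (near-identical
copies with distinct TSDs), while 2% divergence already moves the other to
`unclear`. `analysis/04_phyloprep.R` then extracts the conserved domain
from each copy, applies the >115-aa size filter and 70% identity
clustering, aligns, trims at the 0.4 gap threshold and exports the final
matrix (here 2 representatives × 164 columns) as PHYLIP and NEXUS.

The same calls work on a real assembly: replace the simulated FASTA with
the genome, supply known transposase proteins as queries, and pass a
bacterial protein FASTA for the contamination screen.

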