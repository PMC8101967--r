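#!/usr/bin/env Rscript
# Build the simulated study genomes used throughout the analysis: a
# two-family host genome with a contaminant contig, and write the genome,
# the ground truth (TSV + GFF3) and the query transposases under results/.

suppressMessages(library(tircurator))
dir.create("results/simulated", showWarnings = FALSE, recursive = TRUE)

specs <- list(
  family_spec("F1", tir_length = 30L, tsd_length = 8L, n_copies = 3L,
              orf_length = 300L),
  family_spec("F2", tir_length = 24L, tsd_length = 9L, n_copies = 3L,
              orf_length = 280L, per_copy_divergence = 0.02,
              frameshift_fraction = 0, remnant_fraction = 0))

sim <- simulate_genome(specs, background_length = 40000L,
                       contaminant_count = 1L, seed = 11L)

write_fasta(sim$genome, "results/simulated/genome.fa")
write_fasta(setNames(sim$truth$proteins, names(sim$truth$proteins)),
            "results/simulated/queries.faa")
write_fasta(sim$truth$decoys, "results/simulated/bacterial_decoys.faa")
write_truth(sim$truth, "results/simulated/truth")

message(sprintf("simulated %d contigs (%d bp total), %d planted copies, %d contaminant contig(s)",
                length(sim$genome), sum(nchar(sim$genome)),
                nrow(sim$truth$copies), length(sim$truth$contaminants)))
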