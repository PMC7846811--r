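#!/usr/bin/env Rscript
# Stage 1 — simulate the two-molecule study.
#
# Generates an ancestral mitogenome with the standard vertebrate gene
# order, evolves it into two molecules ~10.4% apart with triplicated,
# concertedly evolving non-coding blocks, and simulates a long-read
# mixture in which the minor molecule carries ~14.5% of the reads.
# Everything downstream (02-06) works from the files written here.

suppressMessages(library(mitotwin))
dir.create("scratch/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1)
truth <- simulate_truth_set(cfg, short_reads = TRUE)

cat(sprintf("ancestor: %d bp, 37 genes + %d NC blocks\n",
            genome_length(truth$ancestor), cfg$nc_block_count))
cat(sprintf("realized M1-M2 divergence: %.2f%% (target %.1f%%)\n",
            100 * truth$realized_divergence, 100 * cfg$target_divergence))
cat(sprintf("long-read mixture: %d reads (%.1f%% truly M2)\n",
            nrow(truth$reads_long),
            100 * mean(truth$reads_long$true_origin == "M2")))

L <- genome_length(truth$m1)
write_fasta(setNames(truth$m1$sequence, "M1"), "scratch/data/m1.fa")
write_fasta(setNames(truth$m2$sequence, "M2"), "scratch/data/m2.fa")
write_annotations(truth$m1$annotations, "scratch/data/m1_annotations.tsv",
                  seqid = "M1", genome_length = L)
write_fastq(truth$reads_long, "scratch/data/reads_long.fq")
write_fastq(truth$reads_short, "scratch/data/reads_short.fq")
write_truth_manifest(truth, "scratch/data/truth.json")
cat("wrote genomes, annotations, reads and truth manifest to scratch/data/\n")
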