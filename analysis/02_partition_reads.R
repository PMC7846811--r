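#!/usr/bin/env Rscript
# Stage 2 — partition the read mixture between the two molecules.
#
# Each long read is aligned against both candidate references; the 5%
# divergence cutoff (margin rule at 2.5 identity points, reads >= 500 bp)
# splits the pool into M1, M2 and unassigned. The minor-molecule fraction
# with its Wilson interval, per-molecule coverage, and a majority-vote
# consensus of the minor molecule are written to results/.

suppressMessages(library(mitotwin))

m1 <- read_fasta("scratch/data/m1.fa")
m2 <- read_fasta("scratch/data/m2.fa")
reads <- read_fastq("scratch/data/reads_long.fq", platform = "long")
truth <- jsonlite::read_json("scratch/data/truth.json")
reads$true_origin <- unlist(truth$read_origins)[reads$id]

asg <- assign_reads(reads, m1, m2, delta = 0.05, min_len = 500L)
print(asg)
called <- asg$call %in% c("M1", "M2")
cat(sprintf("assignment accuracy among called reads: %.2f%%\n",
            100 * mean(asg$call[called] == asg$true_origin[called])))

mix <- mixture_fraction(asg)
print(mix)
cov1 <- coverage_summary(asg, m1, "M1"); print(cov1)
cov2 <- coverage_summary(asg, m2, "M2"); print(cov2)

write.table(as.data.frame(asg), "results/assignment_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(mixture = unclass(mix),
       coverage_m1 = unclass(cov1), coverage_m2 = unclass(cov2)),
  "results/partition_summary.json", auto_unbox = TRUE, digits = NA)

# the minor molecule's consensus comes from the deep short-read mixture
# (a handful of long reads at ~2-4x cannot support a consensus; the study
# likewise assembled the second molecule from its short-read pool)
short <- read_fastq("scratch/data/reads_short.fq", platform = "short_pe")
asg_s <- assign_reads(short, m1, m2, delta = 0.05, min_len = 50L)
cns <- consensus_from_assignment(asg_s, short, m2, "M2", min_breadth = 0.95)
idn <- mean(strsplit(cns$sequence, "")[[1]] == strsplit(m2[[1]], "")[[1]])
cat(sprintf("M2 consensus from %d assigned short reads: %.3f%% identical to truth\n",
            sum(asg_s$call == "M2"), 100 * idn))
write_fasta(setNames(cns$sequence, cns$id), "results/m2_consensus.fa")
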