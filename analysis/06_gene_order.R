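#!/usr/bin/env Rscript
# Stage 6 — gene-order rearrangement report.
#
# Compares the rearranged Tuatara gene order (Fig-style fixture shipped
# with the package) and the simulated genomes' standard order against the
# plesiomorphic vertebrate arrangement, as signed circular permutations.

suppressMessages(library(mitotwin))

std <- standard_vertebrate_order()
tua <- tuatara_order()
rep_ <- compare_orders(tua, std)
print(rep_)

m1seq <- read_fasta("scratch/data/m1.fa")[[1]]
ann <- read_annotations("scratch/data/m1_annotations.tsv",
                        genome_length = nchar(m1seq))
sim_order <- extract_order(mito_genome("M1", m1seq, annotations = ann))
sim_rep <- compare_orders(sim_order, std)
cat(sprintf("simulated genome vs standard order: %d breakpoints (NC blocks: +%d)\n",
            sim_rep$breakpoint_count, sim_rep$extra_noncoding_blocks))

jsonlite::write_json(
  list(tuatara_vs_standard = list(
         breakpoints = rep_$breakpoint_count,
         moved_genes = rep_$moved_genes,
         duplicated = rep_$duplicated_elements,
         extra_nc_blocks = rep_$extra_noncoding_blocks),
       simulated_vs_standard = list(
         breakpoints = sim_rep$breakpoint_count,
         extra_nc_blocks = sim_rep$extra_noncoding_blocks)),
  "results/gene_order.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/gene_order.json\n")
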