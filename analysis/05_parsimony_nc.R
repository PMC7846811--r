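#!/usr/bin/env Rscript
# Stage 5 — concerted evolution of the non-coding blocks by parsimony.
#
# The six NC blocks (three per molecule) are analysed by exact
# branch-and-bound parsimony: if duplicated blocks evolved independently,
# orthologous blocks (all NC1, all NC2, ...) would cluster; under
# concerted evolution, blocks cluster by genome. Bootstrap and decay
# support the genome clades, and Templeton tests reject monophyly of each
# block class.

suppressMessages(library(mitotwin))

m1seq <- read_fasta("scratch/data/m1.fa")[[1]]
ann <- read_annotations("scratch/data/m1_annotations.tsv",
                        genome_length = nchar(m1seq))
m1 <- mito_genome("M1", m1seq, annotations = ann)
m2 <- mito_genome("M2", read_fasta("scratch/data/m2.fa")[[1]],
                  annotations = ann)

aln <- nc_block_alignment(m1, m2)
write_alignment(aln, "results/nc_blocks.fa")
res <- branch_and_bound_search(aln)
print(res)
write_trees(res$shortest_trees, "results/nc_shortest_trees.nwk")
cons <- strict_consensus(res$shortest_trees)
write_trees(cons, "results/nc_strict_consensus.nwk")

bs <- bootstrap_support(aln, replicates = 1000, seed = 1)
print(bs$support)

m1_clade <- grep("^M1_", names(aln), value = TRUE)
dec <- decay_index(aln, m1_clade)
cat(sprintf("decay index of the %s clade: %d steps\n",
            paste(m1_clade, collapse = "+"), dec))

mono <- lapply(c("NC1", "NC2", "NC3"), function(b) {
  grp <- grep(paste0("_", b, "$"), names(aln), value = TRUE)
  m <- test_monophyly(aln, grp)
  cat(sprintf("monophyly of %s: +%d steps, Templeton p = %.3g\n",
              b, m$step_difference, m$templeton$p_two_tailed))
  list(block = b, step_difference = m$step_difference,
       p = m$templeton$p_two_tailed)
})

jsonlite::write_json(
  list(length = res$length, n_sites = res$n_sites,
       n_parsimony_informative = res$n_parsimony_informative,
       n_shortest_trees = length(res$shortest_trees),
       bootstrap = bs$support, m1_clade_decay = dec, monophyly = mono),
  "results/nc_parsimony.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/nc_parsimony.json and newick trees\n")
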