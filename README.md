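# mitotwin

Detection and characterization of two deeply divergent mitochondrial
genomes co-existing in one individual.

Animal mitochondrial variation is usually low-level heteroplasmy; deeply
divergent co-existing molecules were known only from bivalve mollusks
until whole-genome sequencing of a single Tuatara (*Sphenodon
punctatus*) revealed two complete mitochondrial molecules — M1 and M2,
~10% divergent, the minor one at roughly 1/7th concentration — plus a
drastically rearranged gene order with three concertedly evolving
Control-Region-like non-coding blocks. `mitotwin` re-implements that
discovery-and-validation analysis as a tested, reusable R pipeline for
anyone screening deep sequencing data for a second mitochondrial
molecule:

- **Read/contig partitioning** between two candidate molecules by
  alignment identity with a divergence cutoff (`assign_reads`,
  `screen_contigs`), with coverage summaries, Wilson-interval mixture
  fractions (`mixture_fraction`), majority-vote consensus
  (`consensus_from_assignment`), k-mer repeat detection
  (`kmer_repeat_scan`) and contaminant purging (`decontaminate`).
- **Mitochondrial validation** (`genome_qc`): strand composition bias,
  clean translation under the vertebrate mitochondrial code (NCBI
  table 2), tRNA cloverleaf folding including D-arm replacement loops
  (`fold_trna`), and O_L-like stem-loop scanning (`scan_ol_stemloop`).
- **Divergence and clock dating** (`pairwise_p_distance`, `clock_date`):
  uncorrected p-distance with exclusion masks, converted to time at the
  empirical rate of 1.3% divergence per million years, `t = 100·d / r`.
- **Exact parsimony hypothesis testing** (`branch_and_bound_search`,
  `bootstrap_support`, `decay_index`, `templeton_test`,
  `test_monophyly`): all minimum-length trees by branch and bound,
  constrained searches, Bremer decay, and the paired-sites Wilcoxon
  signed-ranks (Templeton) test with exact small-sample p-values.
- **Gene-order comparison** (`extract_order`, `compare_orders`): signed
  circular permutations with breakpoint counts, moved genes, and
  duplicated elements.
- A **synthetic-data generator** (`sim_config`, `simulate_truth_set`)
  whose defaults emulate the study conditions (18,078 bp circular
  genomes at 10.4% divergence, triplicated 99%-identical NC blocks,
  14.5% minor-molecule read share, 100 bp/180 bp paired-end reads,
  indel-rich long reads averaging 2504.5 bp at 17x) with truth labels
  for every read and substitution.

## Worked example

```r
library(mitotwin)

cfg   <- sim_config(seed = 1)          # the study conditions
truth <- simulate_truth_set(cfg)       # two genomes + long-read mixture

truth$realized_divergence
#> [1] 0.1039938

asg <- assign_reads(truth$reads_long, truth$m1, truth$m2,
                    delta = 0.05, min_len = 500)
asg
#> <assignment_table> 138 reads: M1=123 M2=15
mixture_fraction(asg)
#> <mixture_estimate> 123 + 15 = 138 assignable; minor M2 at 10.9% (95% CI 6.7-17.2%)
coverage_summary(asg, truth$m1, "M1")
#> <coverage_summary> M1: 123 reads, 100.0% of reference covered, depth 18.6 ...

genome_qc(truth$m2)
#> <genome_qc_report> PASS | guanine 15.6% | translation clean | 22/22 tRNAs fold | ...

aln <- dna_alignment(c(M1 = truth$m1$sequence, M2 = truth$m2$sequence))
clock_date(pairwise_p_distance(aln, "M1", "M2"), rate = 1.3)
#> <clock_date> 10.4% at 1.30%/MY -> 8.0 million years

nc  <- nc_block_alignment(truth$m1, truth$m2)
branch_and_bound_search(nc)
#> <parsimony_result> 9 shortest tree(s) of length 114; 859 sites, 91 parsimony-informative
test_monophyly(nc, c("M1_NC1", "M2_NC1"))$step_difference   # concerted evolution
#> [1] 89

compare_orders(tuatara_order(), standard_vertebrate_order())
#> <rearrangement_report> 8 breakpoints; moved: Cytb, ND4, ND5, ND6, trnE, trnF,
#>   trnH, trnL(CUN), trnP, trnS(AGY), trnT; duplicated: trnK, trnL(CUN); extra NC blocks: 2
```

Reading those numbers: the two simulated molecules realize the 10.4%
target divergence; every long read ≥ 500 bp is assigned to its true
molecule of origin; the minor molecule's share estimate carries a 95%
Wilson interval that covers the simulated 14.5%; both genomes pass every
mitochondrial hallmark check; the divergence dates to ~8 million years
at 1.3%/MY; the six non-coding blocks cluster by genome (forcing
orthologous blocks together costs ~90 extra steps — the concerted
evolution signature); and the rearranged gene order differs from the
standard vertebrate arrangement by 8 breakpoints with two duplicated
elements and two extra non-coding blocks.

The `analysis/` directory holds the same workflow as numbered driver
scripts (`01_simulate.R` … `06_gene_order.R`), each a thin narrative
wrapper over the package that prints what it found and writes its
tables under `results/` (bulky intermediates go to `scratch/`). The
methods vignette (`vignettes/dual-mitogenome-analysis.Rmd`) documents
the models, parameter choices, numerical conventions and limitations.

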