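test_that("base composition is exact and strand-aware", {
  expect_equal(base_composition("AAAA")$guanine_pct_heavy, 0)
  bc <- base_composition("ACGTN")
  expect_equal(unname(bc$heavy$counts), c(1L, 1L, 1L, 1L))
  expect_equal(sum(bc$heavy$pct), 100)
  # light strand of an A-rich heavy strand is T-rich
  bc2 <- base_composition("AAAAAAAAGG")
  expect_equal(unname(bc2$light$counts["T"]), 8L)
  expect_error(base_composition("NNN"), "no unambiguous")
  set.seed(4)
  big <- rand_dna(100000)
  expect_lt(abs(base_composition(big)$guanine_pct_heavy - 25), 1)
})

test_that("translation uses the vertebrate mitochondrial code", {
  r <- mitotwin:::translate_one_cds("ATGTGATAA")
  expect_equal(r$protein, "MW")        # TGA is Trp, not stop
  expect_length(r$internal_stop_positions, 0)
  expect_equal(r$stop_codon, "TAA")

  r2 <- mitotwin:::translate_one_cds("ATGAGAAAATAA")
  expect_equal(r2$internal_stop_positions, 2L)   # AGA is Ter

  r3 <- mitotwin:::translate_one_cds("ATAGCCAAA")  # ATA is Met
  expect_equal(substr(r3$protein, 1, 1), "M")
})

test_that("incomplete terminal stops are flagged, not failed", {
  rT <- mitotwin:::translate_one_cds("ATGCCCT")
  expect_true(rT$incomplete_stop)
  expect_length(rT$internal_stop_positions, 0)
  rTA <- mitotwin:::translate_one_cds("ATGCCCTA")
  expect_true(rTA$incomplete_stop)
  rbad <- mitotwin:::translate_one_cds("ATGCCCGG")   # not a codon multiple
  expect_false(rbad$frame_ok)
})

test_that("translate_cds reverse-complements light-strand CDS", {
  cds <- "ATGAAACCCTGA"
  g <- mito_genome("g", paste0(revcomp(cds), "AAAA"),
                   annotations = gene_annotation("ND6", "CDS", 0L,
                                                 nchar(cds), "light"))
  rep <- translate_cds(g)
  expect_true(rep$pass)
  expect_equal(rep$cds$ND6$protein, "MKPW")
  # strand invariant: same CDS on the heavy strand gives the same protein
  g2 <- mito_genome("g2", paste0(cds, "AAAA"),
                    annotations = gene_annotation("ND6", "CDS", 0L,
                                                  nchar(cds), "heavy"))
  expect_equal(translate_cds(g2)$cds$ND6$protein, rep$cds$ND6$protein)
})

test_that("a canonical cloverleaf folds with all four arms", {
  set.seed(31)
  templ <- mitotwin:::make_trna_template("CAT")
  f <- fold_trna(templ)
  expect_true(f$success)
  expect_setequal(f$arms, c("acceptor", "D", "anticodon", "T"))
  expect_false(f$d_arm_replacement_loop)
  expect_equal(f$anticodon, "CAT")
  # folding is invariant to where the gene sat in the genome (the search
  # sees only the sequence)
  expect_identical(fold_trna(templ)$layout, f$layout)
})

test_that("a scrambled D-stem is recognized as a replacement loop", {
  set.seed(32)
  templ <- mitotwin:::make_trna_template("GCA")
  x <- strsplit(templ, "")[[1]]
  # break the D stem beyond the 1-slack allowance, keeping length
  d5 <- mitotwin:::.TRNA_LAYOUT$d5 + 1L
  d3 <- mitotwin:::.TRNA_LAYOUT$d3 + 1L
  x[d5] <- c("A", "A", "A", "A")
  x[d3] <- c("C", "C", "C", "C")
  f <- fold_trna(paste0(x, collapse = ""))
  expect_true(f$success)
  expect_true(f$d_arm_replacement_loop)
  expect_false("D" %in% f$arms)
})

test_that("random 70-mers almost never fold", {
  set.seed(33)
  fails <- vapply(1:60, function(i) !fold_trna(rand_dna(70))$success,
                  logical(1))
  expect_gte(mean(fails), 0.95)
})

test_that("stem-loop scan finds a constructed hairpin with tRNA overlaps", {
  set.seed(34)
  stem <- "GGCATCGATCGA"                  # 12 bp stem, GGC motif at base
  loop <- "TTTTTTTT"                      # 8 nt loop
  hair <- paste0(stem, loop, revcomp(stem))
  # non-pairing bases flank the hairpin so the stem cannot extend
  lead <- paste0(rand_dna(59), "A"); tail <- paste0("A", rand_dna(59))
  seqn <- paste0(lead, hair, tail)
  # annotate tRNAs overlapping the hairpin by 14 bp upstream, 2 bp down
  h0 <- nchar(lead)
  h1 <- h0 + nchar(hair)
  ann <- gene_annotation(c("trnN", "trnC"), "tRNA",
                         start = c(h0 + 14L - 60L, h1 - 2L),
                         end = c(h0 + 14L, h1 - 2L + 60L),
                         strand = "light")
  g <- mito_genome("g", seqn, annotations = ann)
  hits <- scan_ol_stemloop(g, window = c(h0 - 5L, h1 + 5L), min_stem = 8L)
  expect_gte(nrow(hits), 1L)
  top <- hits[which.max(hits$stem_length), ]
  expect_equal(top$position, h0)
  expect_equal(top$stem_length, 12L)
  expect_equal(top$loop_length, 8L)
  expect_equal(top$overlap_upstream_trna, 14L)
  expect_equal(top$overlap_downstream_trna, 2L)
  expect_true(top$elongation_motif_present)
})

test_that("a hairpin-free window yields no hits", {
  g <- mito_genome("g", strrep("A", 400),
                   annotations = gene_annotation("x", "rRNA", 0L, 400L))
  hits <- scan_ol_stemloop(g, window = c(10L, 200L))
  expect_equal(nrow(hits), 0L)
})

test_that("site class fractions reproduce the published arithmetic", {
  tab <- data.frame(site = 1:55,
                    class = c(rep("transmembrane", 43), rep("loop", 12)),
                    flagged = TRUE)
  res <- site_class_fraction(tab)
  expect_equal(unname(res$pct_of_flagged["transmembrane"]), 78L)
  # no flagged sites -> all zero
  tab$flagged <- FALSE
  expect_true(all(site_class_fraction(tab)$pct_of_flagged == 0))
  # randomized labels track the class base rate
  set.seed(35)
  n <- 4000
  tab2 <- data.frame(site = seq_len(n),
                     class = sample(c("transmembrane", "loop"), n, TRUE,
                                    prob = c(0.3, 0.7)),
                     flagged = runif(n) < 0.5)
  res2 <- site_class_fraction(tab2)
  expect_lt(abs(res2$pct_of_flagged["transmembrane"] - 30), 4)
  expect_error(site_class_fraction(tab2[0, ]), "empty")
})
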