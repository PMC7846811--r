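test_that("self comparison is the zero report, rotation/reflection invariant", {
  std <- standard_vertebrate_order()
  z <- compare_orders(std, std)
  expect_equal(z$breakpoint_count, 0L)
  expect_length(z$moved_genes, 0L)
  expect_equal(nrow(z$duplicated_elements), 0L)
  expect_equal(z$extra_noncoding_blocks, 0L)

  # a rotated and a reflected copy canonicalize to the same order
  raw <- as.data.frame(std)
  rot <- gene_order(raw$name[c(10:nrow(raw), 1:9)],
                    raw$strand[c(10:nrow(raw), 1:9)],
                    raw$copy_index[c(10:nrow(raw), 1:9)],
                    pseudo = raw$pseudo[c(10:nrow(raw), 1:9)])
  expect_equal(rot$name, std$name)
  refl <- gene_order(rev(raw$name),
                     ifelse(rev(raw$strand) == "heavy", "light", "heavy"),
                     rev(raw$copy_index), pseudo = rev(raw$pseudo))
  expect_equal(refl$name, std$name)
  expect_equal(refl$strand, std$strand)
  expect_equal(compare_orders(rot, std)$breakpoint_count, 0L)
})

test_that("breakpoints match a brute-force adjacency count", {
  # swap one adjacent pair in a small synthetic order
  base <- gene_order(paste0("g", 1:8))
  swapped <- gene_order(paste0("g", c(1, 2, 4, 3, 5:8)))
  rep_ <- compare_orders(base, swapped)
  # brute force: circular signed adjacencies of A not found in B
  adj <- function(nm) {
    n <- length(nm)
    paste(paste0("+", nm), paste0("+", nm[c(2:n, 1)]), sep = ">")
  }
  canon <- function(keys) {
    flip <- function(x) ifelse(substr(x, 1, 1) == "+",
                               sub("^\\+", "-", x), sub("^-", "+", x))
    parts <- strsplit(keys, ">", fixed = TRUE)
    vapply(parts, function(p)
      min(paste(p[1], p[2], sep = ">"),
          paste(flip(p[2]), flip(p[1]), sep = ">")), character(1))
  }
  a <- canon(adj(base$name)); b <- canon(adj(swapped$name))
  expect_equal(rep_$breakpoint_count, sum(!(a %in% b)))
  expect_gt(rep_$breakpoint_count, 0L)
  # symmetry on the shared single-copy set
  expect_equal(compare_orders(swapped, base)$breakpoint_count,
               rep_$breakpoint_count)
})

test_that("a strand flip counts as movement even in place", {
  a <- gene_order(paste0("g", 1:6))
  b <- gene_order(paste0("g", 1:6), strand = c("heavy", "light", "heavy",
                                               "heavy", "heavy", "heavy"))
  rep_ <- compare_orders(a, b)
  expect_true("g2" %in% rep_$moved_genes)
  expect_gt(rep_$breakpoint_count, 0L)
})

test_that("the rearranged order vs the standard order shows the known features", {
  rep_ <- compare_orders(tuatara_order(), standard_vertebrate_order())
  expect_true(all(c("ND5", "ND6", "Cytb", "trnH", "trnT", "trnS(AGY)",
                    "trnE", "trnL(CUN)") %in% rep_$moved_genes))
  expect_setequal(rep_$duplicated_elements$symbol, c("trnL(CUN)", "trnK"))
  expect_true(rep_$duplicated_elements$pseudo[
    rep_$duplicated_elements$symbol == "trnK"])
  expect_false(rep_$duplicated_elements$pseudo[
    rep_$duplicated_elements$symbol == "trnL(CUN)"])
  expect_equal(rep_$extra_noncoding_blocks, 2L)
  expect_gt(rep_$breakpoint_count, 0L)
})

test_that("extract_order is rotation invariant on annotated genomes", {
  anc <- shared_truth()$ancestor
  o1 <- extract_order(anc)
  # rotate the genome by shifting all annotations
  L <- genome_length(anc)
  shift <- 5000L
  ann <- anc$annotations
  ann$start <- (ann$start + shift) %% L
  ann$end <- ann$start + (anc$annotations$end - anc$annotations$start)
  g2 <- mito_genome("rot", paste0(substr(anc$sequence, L - shift + 1L, L),
                                  substr(anc$sequence, 1L, L - shift)),
                    annotations = ann)
  o2 <- extract_order(g2)
  expect_equal(o2$name, o1$name)
  expect_equal(o2$strand, o1$strand)
})

test_that("insufficient shared genes raises an error", {
  a <- gene_order(c("g1", "g2", "g3"))
  b <- gene_order(c("g1", "g2", "h3"))
  expect_error(compare_orders(a, b), "fewer than 4")
})
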