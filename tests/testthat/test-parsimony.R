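test_that("Fitch counts the textbook AABB case", {
  aln <- dna_alignment(c(a1 = "AC", a2 = "AC", b1 = "TC", b2 = "TC"))
  t_good <- ape::read.tree(text = "((a1,a2),(b1,b2));")
  t_bad <- ape::read.tree(text = "((a1,b1),(a2,b2));")
  expect_equal(fitch_length(t_good, aln)$length, 1)
  expect_equal(fitch_length(t_bad, aln)$length, 2)
  # invariant site contributes no steps on any tree
  expect_equal(fitch_length(t_good, aln)$site_lengths[2], 0)
  # additivity
  fl <- fitch_length(t_bad, aln)
  expect_equal(fl$length, sum(fl$site_lengths))
})

test_that("informative-site counting matches a brute-force per-site check", {
  aln <- dna_alignment(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"))
  expect_equal(count_informative_sites(aln), 0L)
  one <- dna_alignment(c(a = "A", b = "A", c = "C", d = "C"))
  expect_equal(count_informative_sites(one), 1L)
  set.seed(81)
  for (rep in 1:5) {
    aln <- rand_aln(sample(4:7, 1), 30)
    m <- as.matrix(aln)
    oracle <- sum(vapply(seq_len(ncol(m)), function(j) {
      tb <- table(m[, j][m[, j] %in% c("A", "C", "G", "T")])
      sum(tb >= 2) >= 2
    }, logical(1)))
    expect_equal(count_informative_sites(aln), oracle)
  }
})

test_that("branch and bound equals exhaustive enumeration (spot check)", {
  skip_if_not_installed("phangorn")
  set.seed(82)
  for (rep in 1:10) {
    n <- sample(5:7, 1)
    aln <- rand_aln(n, sample(15:30, 1))
    res <- branch_and_bound_search(aln)
    ph <- phangorn::phyDat(as.matrix(aln), type = "DNA")
    allt <- phangorn::allTrees(n, tip.label = rownames(as.matrix(aln)))
    sc <- vapply(allt, function(t) phangorn::fitch(t, ph), numeric(1))
    expect_equal(res$length, min(sc))
    k_mine <- sort(vapply(res$shortest_trees, tree_key, character(1)))
    k_orac <- sort(vapply(allt[sc == min(sc)], tree_key, character(1)))
    expect_equal(k_mine, k_orac)
  }
})

test_that("the AABB pattern yields the matching split uniquely", {
  aln <- dna_alignment(c(a1 = strrep("A", 5), a2 = strrep("A", 5),
                         b1 = strrep("C", 5), b2 = strrep("C", 5)))
  res <- branch_and_bound_search(aln)
  expect_equal(length(res$shortest_trees), 1L)
  expect_equal(res$length, 5)
  key <- clade_key(c("a1", "a2"), c("a1", "a2", "b1", "b2"))
  expect_true(key %in% mitotwin:::.split_keys(res$shortest_trees[[1]]))
})

test_that("constrained searches are never shorter than unconstrained", {
  set.seed(83)
  for (rep in 1:5) {
    aln <- rand_aln(6, 25)
    free <- branch_and_bound_search(aln)
    grp <- sample(rownames(as.matrix(aln)), 3)
    con <- branch_and_bound_search(aln, constrain_monophyly = grp)
    expect_gte(con$length, free$length)
  }
})

test_that("taxon guard refuses oversized exact searches", {
  aln <- rand_aln(17, 10)
  expect_error(branch_and_bound_search(aln), "heuristic")
})

test_that("bootstrap is deterministic and finds clean signal", {
  set.seed(84)
  # 20 consistent informative sites split two clades, plus noise columns
  clade1 <- c("x1", "x2", "x3"); clade2 <- c("y1", "y2", "y3")
  sig <- c(rep("A", 3), rep("C", 3))
  rows <- vapply(seq_len(6), function(i)
    paste0(c(rep(sig[i], 20), sample(c("A", "C", "G", "T"), 10, TRUE)),
           collapse = ""), character(1))
  names(rows) <- c(clade1, clade2)
  aln <- dna_alignment(rows)
  bs1 <- bootstrap_support(aln, replicates = 100, seed = 9)
  bs2 <- bootstrap_support(aln, replicates = 100, seed = 9)
  expect_identical(bs1$support, bs2$support)
  key <- clade_key(clade1, names(rows))
  sup <- bs1$support$support[bs1$support$clade == key]
  expect_gte(sup, 95)
})

test_that("an invariant alignment supports nothing", {
  aln <- dna_alignment(setNames(rep(strrep("A", 30), 5), paste0("t", 1:5)))
  res <- branch_and_bound_search(aln)
  expect_equal(res$length, 0)
  # every topology is equally short: strict consensus is a star with no
  # internal splits
  cons <- strict_consensus(res$shortest_trees)
  expect_length(mitotwin:::.split_keys(cons), 0L)
})

test_that("decay equals the number of uncontradicted supporting sites", {
  # k sites support (a,b) against (c,d,e); nothing contradicts
  for (k in c(2L, 4L)) {
    rows <- c(a = strrep("A", k), b = strrep("A", k), c = strrep("C", k),
              d = strrep("C", k), e = strrep("C", k))
    # pad with invariant columns so the signal is the only information
    rows <- paste0(rows, strrep("G", 10))
    names(rows) <- c("a", "b", "c", "d", "e")
    aln <- dna_alignment(rows)
    expect_equal(decay_index(aln, c("a", "b")), k)
  }
  # unsupported clade decays by zero (with a warning)
  aln2 <- dna_alignment(c(a = "AAG", b = "CAG", c = "ACG", d = "CCG",
                          e = "AAG"))
  expect_warning(d0 <- decay_index(aln2, c("b", "c")), "no shortest tree")
  expect_lte(d0, 0)
})

test_that("whole-tree collapse equals the minimum clade decay", {
  skip_if_not_installed("phangorn")
  set.seed(85)
  aln <- rand_aln(6, 40)
  res <- branch_and_bound_search(aln)
  cons <- strict_consensus(res$shortest_trees)
  keys <- mitotwin:::.split_keys(cons)
  expect_gte(length(keys), 1L)
  decays <- suppressWarnings(vapply(keys, function(k)
    decay_index(aln, strsplit(k, "|", fixed = TRUE)[[1]]), numeric(1)))
  # independent oracle: over all topologies, the shortest tree lacking at
  # least one consensus clade exceeds the optimum by exactly min(decays)
  allt <- phangorn::allTrees(6, tip.label = rownames(as.matrix(aln)))
  ph <- phangorn::phyDat(as.matrix(aln), type = "DNA")
  sc <- vapply(allt, function(t) phangorn::fitch(t, ph), numeric(1))
  lacks <- vapply(allt, function(t)
    !all(keys %in% mitotwin:::.split_keys(t)), logical(1))
  expect_equal(min(sc[lacks]) - res$length, min(decays))
})

test_that("Templeton is degenerate on identical trees and exact on constructed signal", {
  set.seed(86)
  aln <- rand_aln(6, 30)
  res <- branch_and_bound_search(aln)
  t1 <- res$shortest_trees[[1]]
  same <- templeton_test(aln, t1, t1)
  expect_true(same$no_difference)
  expect_equal(same$p_two_tailed, 1.0)

  # 10 sites all favoring one tree by one step: exact p = 2 * (1/2^10)
  clade1 <- c("p1", "p2"); clade2 <- c("q1", "q2")
  rows <- c(p1 = strrep("A", 10), p2 = strrep("A", 10),
            q1 = strrep("C", 10), q2 = strrep("C", 10))
  aln2 <- dna_alignment(rows)
  good <- ape::read.tree(text = "((p1,p2),(q1,q2));")
  bad <- ape::read.tree(text = "((p1,q1),(p2,q2));")
  tt <- templeton_test(aln2, bad, good)
  expect_equal(tt$n_differing_sites, 10L)
  expect_equal(tt$method, "exact")
  expect_equal(tt$p_two_tailed, 2 / 2^10)
})

test_that("Templeton matches a sign-permutation brute force and is antisymmetric", {
  set.seed(87)
  done <- 0
  while (done < 8) {
    aln <- rand_aln(6, 20)
    res <- branch_and_bound_search(aln)
    t1 <- res$shortest_trees[[1]]
    t2 <- ape::unroot(ape::rtree(6, tip.label = sample(paste0("t", 1:6))))
    sa <- fitch_length(t1, aln)$site_lengths
    sb <- fitch_length(t2, aln)$site_lengths
    d <- (sa - sb)[sa != sb]
    if (length(d) < 1 || length(d) > 12) next
    tt <- templeton_test(aln, t1, t2)
    r <- rank(abs(d)); n <- length(d)
    obs <- sum(r[d > 0]); mu <- sum(r) / 2
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    tp <- signs %*% r
    p_bf <- mean(abs(tp - mu) >= abs(obs - mu) - 1e-9)
    expect_equal(tt$p_two_tailed, p_bf)
    # z from the tie-corrected formula
    ties <- table(abs(d))
    varw <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    expect_equal(tt$z, (obs - n * (n + 1) / 4) / sqrt(varw))
    # swapping the trees negates z and preserves p
    rev <- templeton_test(aln, t2, t1)
    expect_equal(rev$z, -tt$z)
    expect_equal(rev$p_two_tailed, tt$p_two_tailed)
    done <- done + 1
  }
})

test_that("monophyly testing reports zero difference for a true clade", {
  rows <- c(a1 = strrep("A", 6), a2 = strrep("A", 6),
            b1 = strrep("C", 6), b2 = strrep("C", 6), out = strrep("G", 6))
  aln <- dna_alignment(rows)
  mono <- test_monophyly(aln, c("a1", "a2"))
  expect_equal(mono$step_difference, 0)
  expect_equal(mono$templeton$p_two_tailed, 1.0)
})

test_that("strict consensus collapses exactly the conflicting splits", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  expect_identical(strict_consensus(list(t1)), t1)
  trees <- c(t1, t2); class(trees) <- "multiPhylo"
  cons <- strict_consensus(trees)
  k <- mitotwin:::.split_keys(cons)
  expect_true(all(k %in% intersect(mitotwin:::.split_keys(t1),
                                   mitotwin:::.split_keys(t2))))
  t3 <- ape::read.tree(text = "((a,b),(c,x),e);")
  trees2 <- c(t1, t3); class(trees2) <- "multiPhylo"
  expect_error(strict_consensus(trees2), "leaf set")
})

test_that("concatenation applies exclusion and gap rules exactly", {
  tr <- shared_truth()
  genomes <- list(M1 = tr$m1, M2 = tr$m2)
  genes <- c("ND1", "ATP8", "ND4L", "Cytb")
  plain <- build_concatenation(genomes, genes,
                               rules = concatenation_rules(exclude_last = c()))
  lens <- vapply(genes, function(g) {
    ann <- tr$m1$annotations
    i <- ann$name == g
    ann$end[i] - ann$start[i]
  }, numeric(1))
  expect_equal(attr(plain, "site_count"), sum(lens))
  # bicistronic exclusions shorten the matching partitions exactly
  cut <- build_concatenation(genomes, genes)
  expect_equal(attr(cut, "site_count"), sum(lens) - 96L - 7L)
  expect_equal(sum(attr(cut, "site_genes") == "ATP8"), lens[["ATP8"]] - 96L)
  expect_error(build_concatenation(genomes, c("NOPE")), "lacks gene")
})

test_that("length-difference gap rules pad the shorter rows at stated offsets", {
  # one allele 21 nt (7 codons) longer: the shorter row receives 15 gaps
  # after nt 3 and 6 gaps after nt 10 (offsets in its own coordinates)
  set.seed(88)
  core <- rand_dna(30)
  extra1 <- rand_dna(15); extra2 <- rand_dna(6)
  long_allele <- paste0(substr(core, 1, 3), extra1,
                        substr(core, 4, 10), extra2,
                        substr(core, 11, 30))
  mk <- function(id, s) mito_genome(id, s, annotations = gene_annotation(
    "Cytb", "CDS", 0L, nchar(s), "heavy"))
  genomes <- list(short = mk("short", core), long = mk("long", long_allele))
  rules <- concatenation_rules(
    exclude_last = c(),
    gap_insertions = list(list(gene = "Cytb", rows = "short",
                               after_nt = c(3L, 10L), n = c(15L, 6L))))
  aln <- build_concatenation(genomes, "Cytb", rules = rules)
  expect_equal(attr(aln, "site_count"), nchar(long_allele))
  srow <- unclass(aln)[["short"]]
  expect_equal(substr(srow, 4, 18), strrep("-", 15))
  expect_equal(substr(srow, 26, 31), strrep("-", 6))
  expect_equal(gsub("-", "", srow), core)
  expect_equal(unclass(aln)[["long"]], long_allele)
})
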