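# shared mixture for several assignment tests
local_mixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- shared_truth()
      cfg <- tr$config
      r1 <- simulate_long_reads(tr$m1, cfg)
      r2 <- simulate_long_reads(tr$m2, cfg)
      mixed <- mix_reads(r1, r2, cfg$minor_fraction, seed = 99)
      cache <<- list(truth = tr, reads = mixed,
                     assignments = assign_reads(mixed, tr$m1, tr$m2))
    }
    cache
  }
})

test_that("every read receives exactly one call and counts partition", {
  mx <- local_mixture()
  asg <- mx$assignments
  expect_equal(nrow(asg), nrow(mx$reads))
  expect_true(all(asg$call %in% c("M1", "M2", "unassigned", "too_short")))
  expect_equal(sum(table(asg$call)), nrow(mx$reads))
  expect_true(all((asg$call == "too_short") == (asg$length < 500L)))
})

test_that("assignment recovers true origins on the synthetic mixture", {
  asg <- local_mixture()$assignments
  called <- asg$call %in% c("M1", "M2")
  expect_gt(sum(called), 0)
  expect_gte(mean(asg$call[called] == asg$true_origin[called]), 0.99)
})

test_that("swapping the reference labels swaps the calls", {
  mx <- local_mixture()
  sub <- mx$reads[seq_len(min(40L, nrow(mx$reads))), , drop = FALSE]
  class(sub) <- c("read_set", "data.frame")
  a12 <- assign_reads(sub, mx$truth$m1, mx$truth$m2)
  a21 <- assign_reads(sub, mx$truth$m2, mx$truth$m1)
  swap <- c(M1 = "M2", M2 = "M1", unassigned = "unassigned",
            too_short = "too_short")
  expect_equal(unname(swap[a12$call]), a21$call)
})

test_that("ties and short reads follow the decision rule", {
  tr <- shared_truth()
  frag <- genome_subseq(tr$m1, 1000L, 1800L)
  # a read aligned equally well to both references (same reference twice)
  tie <- assign_reads(read_set("r1", frag), tr$m1, tr$m1, check_refs = FALSE)
  expect_equal(tie$call, "unassigned")
  shorty <- assign_reads(read_set("r2", substr(frag, 1, 400)),
                         tr$m1, tr$m2)
  expect_equal(shorty$call, "too_short")
  empty <- assign_reads(read_set(character(), character()), tr$m1, tr$m2)
  expect_equal(nrow(empty), 0L)
})

test_that("contig screening separates molecules and flags chimeras", {
  tr <- shared_truth()
  contigs <- c(
    m1_frag = genome_subseq(tr$m1, 100L, 2100L),
    m2_a = genome_subseq(tr$m2, 3000L, 5500L),
    m2_b = genome_subseq(tr$m2, 9000L, 10500L),
    chimera = paste0(genome_subseq(tr$m1, 0L, 1000L),
                     genome_subseq(tr$m2, 8000L, 9000L)))
  sc <- screen_contigs(contigs, tr$m1, tr$m2)
  expect_true("m1_frag" %in% sc$primary)
  expect_setequal(sc$secondary, c("m2_a", "m2_b"))
  expect_true("chimera" %in% sc$ambiguous)
})

test_that("a single full-molecule read gives breadth 100 at unit depth", {
  tr <- shared_truth()
  L <- genome_length(tr$m1)
  rs <- read_set("full", tr$m1$sequence, true_origin = "M1")
  asg <- assign_reads(rs, tr$m1, tr$m2)
  cov <- coverage_summary(asg, tr$m1, "M1")
  expect_equal(cov$breadth, 100)
  expect_equal(cov$depth$min, 1L)
  expect_equal(cov$depth$max, 1L)
})

test_that("coverage at study depths mirrors the two-molecule asymmetry", {
  mx <- local_mixture()
  cov1 <- coverage_summary(mx$assignments, mx$truth$m1, "M1")
  cov2 <- coverage_summary(mx$assignments, mx$truth$m2, "M2")
  expect_gte(cov1$breadth, 99.5)          # ~17x major molecule
  expect_gte(cov2$breadth, 90)            # minor molecule, ~1/7th depth
  expect_gt(cov1$depth$mean, cov2$depth$mean)
  none <- coverage_summary(mx$assignments[0, , drop = FALSE], mx$truth$m1,
                           "M1")
  expect_equal(none$breadth, 0)
  expect_null(none$depth)
})

test_that("mixture fractions carry Wilson intervals", {
  est <- mixture_from_counts(176980L, 30005L)
  expect_equal(est$n_assignable, 206985L)
  expect_equal(round(100 * est$minor_fraction, 1), 14.5)
  expect_lt(est$ci_low, est$minor_fraction)
  expect_gt(est$ci_high, est$minor_fraction)
  zero <- mixture_from_counts(10L, 0L)
  expect_equal(zero$minor_fraction, 0)
  expect_error(mixture_from_counts(0L, 0L), "no assignable")
})

test_that("consensus is a fixed point on error-free reads", {
  cfg <- sim_config(seed = 57, long_error_sub = 0, long_error_ins = 0,
                    long_error_del = 0)
  anc <- generate_ancestor(cfg)
  pr <- evolve_pair(anc, cfg)
  rs <- simulate_long_reads(pr$m1, cfg, depth = 25)
  asg <- assign_reads(rs, pr$m1, pr$m2)
  cns <- consensus_from_assignment(asg, rs, pr$m1, "M1")
  expect_identical(cns$sequence, pr$m1$sequence)
  expect_length(cns$uncovered_positions, 0L)
})

test_that("consensus tolerates default sequencing errors at depth", {
  tr <- shared_truth()
  cfg <- tr$config
  rs <- simulate_short_reads(tr$m1, cfg, depth = 50)
  asg <- assign_reads(rs, tr$m1, tr$m2, min_len = 50L)
  cns <- consensus_from_assignment(asg, rs, tr$m1, "M1")
  idn <- mean(strsplit(cns$sequence, "")[[1]] ==
                strsplit(tr$m1$sequence, "")[[1]])
  expect_gte(idn, 0.9999)
})

test_that("consensus from the mixture differs from the other molecule like the genomes do", {
  mx <- local_mixture()
  cns <- consensus_from_assignment(mx$assignments, mx$reads, mx$truth$m1,
                                   "M1")
  d_to_m2 <- mean(strsplit(cns$sequence, "")[[1]] !=
                    strsplit(mx$truth$m2$sequence, "")[[1]])
  expect_lt(abs(d_to_m2 - mx$truth$realized_divergence), 0.02)
})

test_that("k-mer scan flags a constructed tandem duplication", {
  set.seed(58)
  uniq <- rand_dna(6000)
  block <- substr(uniq, 2001, 2300)
  dup_genome <- paste0(substr(uniq, 1, 2300), block,
                       substr(uniq, 2301, 6000))
  g <- mito_genome("dup", dup_genome)
  cfg <- sim_config(seed = 58, short_error = 0, genome_length = 18078)
  rs <- simulate_short_reads(g, cfg, depth = 60)
  ks <- kmer_repeat_scan(rs, g, k = 31)
  expect_gt(nrow(ks$flagged), 0)
  # flagged regions concentrate on the duplicated block
  hit <- sum(pmax(0, pmin(ks$regions$end, 2600) - pmax(ks$regions$start, 2000)))
  all_flagged <- sum(ks$regions$end - ks$regions$start)
  expect_gte(hit / all_flagged, 0.8)
})

test_that("k-mer scan sees the triplicated NC blocks at ~3x modal count", {
  # depth matters: the 1.6x threshold separates Poisson noise from true
  # repeats only once k-mer coverage is a few dozen, as in deep short-read
  # data sets
  tr <- shared_truth()
  cfg <- sim_config(seed = 59, short_error = 0)
  rs <- simulate_short_reads(tr$m1, cfg, depth = 150)
  ks <- kmer_repeat_scan(rs, tr$m1, k = 71)
  nc <- tr$m1$annotations[tr$m1$annotations$kind == "NC", ]
  nc_lo <- min(nc$start); nc_hi <- max(nc$end)
  hit <- sum(pmax(0, pmin(ks$regions$end, nc_hi) -
                    pmax(ks$regions$start, nc_lo)))
  expect_gte(hit / sum(ks$regions$end - ks$regions$start), 0.8)
  # most of the triplicated region is recovered
  expect_gte(hit / (nc_hi - nc_lo), 0.8)
  # NC k-mers occur at roughly three times the modal count
  expect_gt(median(ks$flagged$count) / ks$modal_count, 2.5)
})

test_that("a unique-sequence genome yields no repeat flags", {
  set.seed(60)
  g <- mito_genome("u", rand_dna(8000))
  cfg <- sim_config(seed = 60, short_error = 0)
  rs <- simulate_short_reads(g, cfg, depth = 150)
  ks <- kmer_repeat_scan(rs, g, k = 41)
  expect_equal(nrow(ks$flagged), 0L)
})

test_that("decontamination purges spiked contaminant reads only", {
  tr <- shared_truth()
  cfg0 <- sim_config(seed = 61, long_error_sub = 0, long_error_ins = 0,
                     long_error_del = 0)
  target <- simulate_long_reads(tr$m1, cfg0, depth = 2)
  cont <- simulate_long_reads(tr$m2, cfg0, depth = 1)
  cont$id <- paste0("spike_", cont$id)
  pool <- bind_read_sets(target, cont)
  dc <- decontaminate(pool, tr$m2, identity_threshold = 0.95)
  expect_setequal(dc$purged$id, cont$id)
  expect_setequal(dc$kept$id, target$id)
  expect_equal(nrow(dc$kept) + nrow(dc$purged), nrow(pool))
  # threshold 1.0 purges exact matches only
  dc2 <- decontaminate(pool, tr$m2, identity_threshold = 1.0)
  expect_true(all(dc2$identity[dc2$purged$id] >= 1))
})
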