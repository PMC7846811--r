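test_that("the ancestor is deterministic, standard-ordered, and passes QC", {
  cfg <- sim_config(seed = 5)
  a1 <- generate_ancestor(cfg)
  a2 <- generate_ancestor(cfg)
  expect_identical(a1$sequence, a2$sequence)
  expect_equal(genome_length(a1), cfg$genome_length)

  std <- standard_vertebrate_order()
  got <- extract_order(a1)
  expect_equal(got$name[got$kind != "NC"], std$name[std$kind != "NC"])
  expect_equal(got$strand[got$kind != "NC"], std$strand[std$kind != "NC"])

  qc <- genome_qc(a1)
  expect_true(qc$pass)
  expect_true(all(vapply(qc$trna, function(f) f$success, logical(1))))
})

test_that("generated tRNAs carry their expected anticodons", {
  anc <- shared_truth()$ancestor
  for (g in c("trnF", "trnM", "trnW")) {
    f <- fold_trna(gene_sequence(anc, g))
    expect_true(f$success)
    expect_equal(f$anticodon, mitotwin:::.TRNA_ANTICODONS[[g]],
                 info = g)
  }
})

test_that("evolve_pair hits the divergence target and keeps QC closure", {
  tr <- shared_truth()
  expect_lt(abs(tr$realized_divergence - 0.104), 0.005)
  expect_true(genome_qc(tr$m1)$pass)
  expect_true(genome_qc(tr$m2)$pass)
  # same config twice is bit-identical
  pair2 <- evolve_pair(tr$ancestor, tr$config)
  expect_identical(pair2$m1$sequence, tr$m1$sequence)
})

test_that("zero target divergence returns identical genomes", {
  cfg <- sim_config(seed = 3, target_divergence = 0)
  anc <- generate_ancestor(cfg)
  pr <- evolve_pair(anc, cfg)
  expect_identical(pr$m1$sequence, pr$m2$sequence)
  expect_equal(pr$realized_divergence, 0)
})

test_that("NC blocks show the concerted-evolution identity structure", {
  tr <- shared_truth()
  blk <- function(g, i) {
    ann <- g$annotations
    nc <- ann[ann$name == paste0("NC", i), ]
    genome_subseq(g, nc$start, nc$end)
  }
  pid <- function(a, b) mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  # within-genome copies nearly identical
  expect_gte(pid(blk(tr$m1, 1), blk(tr$m1, 2)), 0.99)
  expect_gte(pid(blk(tr$m2, 2), blk(tr$m2, 3)), 0.99)
  # orthologous blocks diverge like the molecules
  expect_lt(abs(pid(blk(tr$m1, 1), blk(tr$m2, 1)) - 0.9), 0.03)
})

test_that("short reads have the configured geometry", {
  cfg <- sim_config(seed = 9, short_error = 0)
  anc <- generate_ancestor(cfg)
  rs <- simulate_short_reads(anc, cfg, depth = 50)
  L <- genome_length(anc)
  expect_lt(abs(nrow(rs) - 50 * L / 100), 0.1 * 50 * L / 100)
  expect_true(all(nchar(rs$sequence) == 100L))
  # error-free reads are exact substrings of the doubled genome
  doubled <- paste0(anc$sequence, anc$sequence)
  some <- rs$sequence[sample.int(nrow(rs), 50)]
  fwd <- vapply(some, grepl, logical(1), x = doubled, fixed = TRUE)
  rev <- vapply(vapply(some, revcomp, character(1)), grepl, logical(1),
                x = doubled, fixed = TRUE)
  expect_true(all(fwd | rev))
  # mates are reciprocal
  expect_true(all(rs$mate_id[match(rs$mate_id, rs$id)] == rs$id))
})

test_that("long-read lengths match the configured law", {
  cfg <- sim_config(seed = 13, full_read_prob = 0)
  anc <- generate_ancestor(cfg)
  rs <- simulate_long_reads(anc, cfg, n_reads = 10000)
  lens <- nchar(rs$sequence)
  # error process inflates/deflates lengths slightly; compare the sampled
  # pre-error law via a clean config
  cfg0 <- sim_config(seed = 13, long_error_sub = 0, long_error_ins = 0,
                     long_error_del = 0, full_read_prob = 0)
  rs0 <- simulate_long_reads(anc, cfg0, n_reads = 10000)
  lens0 <- nchar(rs0$sequence)
  expect_lt(abs(mean(lens0) - 2504.5) / 2504.5, 0.05)
  expect_gte(min(lens0), 514L)
  expect_lte(max(lens0), 16978L)
  # with errors, mean shifts by at most the indel-rate imbalance
  expect_lt(abs(mean(lens) - mean(lens0)) / mean(lens0), 0.05)
})

test_that("error-free long reads are substrings of the doubled genome", {
  cfg <- sim_config(seed = 17, long_error_sub = 0, long_error_ins = 0,
                    long_error_del = 0, full_read_prob = 0)
  anc <- generate_ancestor(cfg)
  rs <- simulate_long_reads(anc, cfg, depth = 3)
  doubled <- paste0(anc$sequence, anc$sequence)
  hit <- vapply(seq_len(nrow(rs)), function(i) {
    s <- rs$sequence[i]
    grepl(s, doubled, fixed = TRUE) || grepl(revcomp(s), doubled, fixed = TRUE)
  }, logical(1))
  expect_true(all(hit))
})

test_that("full-molecule reads align once per strand", {
  cfg <- sim_config(seed = 21, long_error_sub = 0, long_error_ins = 0,
                    long_error_del = 0, full_read_prob = 1)
  anc <- generate_ancestor(cfg)
  rs <- simulate_long_reads(anc, cfg, n_reads = 2)
  expect_true(all(rs$full_molecule))
  expect_true(all(nchar(rs$sequence) == 2L * genome_length(anc)))
  r <- rs$sequence[1]
  half1 <- substr(r, 1L, genome_length(anc))
  half2 <- substr(r, genome_length(anc) + 1L, nchar(r))
  expect_identical(half2, revcomp(half1))
  doubled <- paste0(anc$sequence, anc$sequence)
  expect_true(grepl(half1, doubled, fixed = TRUE) ||
                grepl(revcomp(half1), doubled, fixed = TRUE))
})

test_that("mix_reads draws a binomial minor share and is deterministic", {
  mk <- function(tag, n) read_set(paste0(tag, seq_len(n)),
                                  replicate(n, rand_dna(30)),
                                  true_origin = tag)
  set.seed(1)
  m1 <- mk("M1", 20000); m2 <- mk("M2", 5000)
  mx <- mix_reads(m1, m2, 0.145, seed = 7, n_total = 20000)
  n2 <- sum(mx$true_origin == "M2")
  # binomial 99% interval around 2900
  expect_true(abs(n2 - 2900) < qnorm(0.995) * sqrt(20000 * 0.145 * 0.855) + 1)
  mx2 <- mix_reads(m1, m2, 0.145, seed = 7, n_total = 20000)
  expect_identical(mx$id, mx2$id)
  # symmetric half-half case
  mx3 <- mix_reads(mk("A", 5000), mk("B", 5000), 0.5, seed = 1,
                   n_total = 5000)
  expect_lt(abs(mean(mx3$true_origin == "B") - 0.5), 0.05)
  expect_error(mix_reads(m1, m2, 1.2, seed = 1), "minor_fraction")
})

test_that("the truth manifest records origins and divergence", {
  cfg <- sim_config(seed = 23, depth_major = 3)
  ts <- simulate_truth_set(cfg)
  p <- withr::local_tempfile(fileext = ".json")
  write_truth_manifest(ts, p)
  man <- jsonlite::read_json(p)
  expect_equal(man$realized_divergence, ts$realized_divergence)
  expect_equal(length(man$read_origins), nrow(ts$reads_long))
})
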