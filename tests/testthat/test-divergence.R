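test_that("p-distance matches hand counts and handles masks and gaps", {
  aln <- dna_alignment(c(a = "ACGT", b = "ACGA"))
  d <- pairwise_p_distance(aln, "a", "b")
  expect_equal(d$d, 0.25)
  expect_equal(d$sites_compared, 4L)

  same <- dna_alignment(c(a = "ACGTAC", b = "ACGTAC"))
  expect_equal(pairwise_p_distance(same, "a", "b")$d, 0)

  # gaps and N are pairwise-deleted
  g <- dna_alignment(c(a = "AC-TN", b = "ACGTA"))
  dg <- pairwise_p_distance(g, "a", "b")
  expect_equal(dg$sites_compared, 3L)
  expect_equal(dg$d, 0)

  # masking the mismatching column removes it; masking never increases
  # compared sites
  m <- exclusion_mask("ALL", 3L, 4L)
  dm <- pairwise_p_distance(aln, "a", "b", m)
  expect_equal(dm$sites_compared, 3L)
  m2 <- exclusion_mask(c("ALL", "a"), c(3L, 0L), c(4L, 2L))
  expect_lte(pairwise_p_distance(aln, "a", "b", m2)$sites_compared,
             dm$sites_compared)
  expect_error(pairwise_p_distance(aln, "a", "b",
                                   exclusion_mask("ALL", 0L, 4L)),
               "no comparable")
})

test_that("group divergence reduces to pairwise for singletons", {
  aln <- dna_alignment(c(a = "ACGTACGT", b = "ACGTACGA", c = "ACGTACGA"))
  expect_equal(mean_group_divergence(aln, "a", "b"),
               pairwise_p_distance(aln, "a", "b")$d)
  expect_equal(mean_group_divergence(aln, c("b", "c"), "a"), 0.125)
  expect_error(mean_group_divergence(aln, character(), "a"), "non-empty")
})

test_that("clock dating reproduces the published conversions", {
  expect_equal(clock_date(0.101, 1.3)$time_my_1dp, 7.8)
  expect_equal(clock_date(0.016, 1.3)$time_my_1dp, 1.2)
  expect_equal(clock_date(0, 1.3)$time_my, 0)
  expect_error(clock_date(0.1, 0), "rate")
  # monotone in the mismatch count
  aln <- dna_alignment(c(a = strrep("A", 20),
                         b = paste0(strrep("C", 5), strrep("A", 15)),
                         c = paste0(strrep("C", 9), strrep("A", 11))))
  t_b <- clock_date(pairwise_p_distance(aln, "a", "b"))$time_my
  t_c <- clock_date(pairwise_p_distance(aln, "a", "c"))$time_my
  expect_lt(t_b, t_c)
})

test_that("generated pairs date back to target / rate", {
  tr <- shared_truth()
  aln <- dna_alignment(c(M1 = tr$m1$sequence, M2 = tr$m2$sequence))
  d <- pairwise_p_distance(aln, "M1", "M2")
  expect_equal(d$d, tr$realized_divergence)
  dt <- clock_date(d, rate = 1.3)
  expect_lt(abs(dt$time_my - 100 * 0.104 / 1.3), 100 * 0.005 / 1.3 + 1e-9)
})

test_that("population-structure divergences are recovered from a synthetic set", {
  # north/south M1 populations ~1% apart, M2 ~10% out: derive rows from
  # the shared pair by sprinkling extra within-M1 differences
  tr <- shared_truth()
  set.seed(71)
  mutate_frac <- function(s, f) {
    x <- strsplit(s, "")[[1]]
    at <- sample(length(x), round(f * length(x)))
    x[at] <- vapply(x[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste0(x, collapse = "")
  }
  north <- mutate_frac(tr$m1$sequence, 0.005)
  south <- mutate_frac(tr$m1$sequence, 0.005)
  aln <- dna_alignment(c(north = north, south = south,
                         M2 = tr$m2$sequence))
  d_ns <- mean_group_divergence(aln, "north", "south")
  d_m2 <- mean_group_divergence(aln, c("north", "south"), "M2")
  expect_lt(abs(d_ns - 0.01), 0.002)
  expect_lt(abs(d_m2 - tr$realized_divergence), 0.01)
})
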