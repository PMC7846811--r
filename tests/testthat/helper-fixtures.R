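# shared fixtures and small independent oracles used across test files

rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste0(sample(bases, n, replace = TRUE), collapse = "")
}

rand_aln <- function(n_taxa, n_sites, prefix = "t") {
  rows <- replicate(n_taxa, rand_dna(n_sites))
  names(rows) <- paste0(prefix, seq_len(n_taxa))
  dna_alignment(rows)
}

# canonical topology signature: sorted canonical split keys
tree_key <- function(t) {
  labs <- sort(t$tip.label)
  pp <- ape::prop.part(ape::unroot(t))
  ks <- vapply(pp, function(p) {
    side <- sort(t$tip.label[p])
    other <- setdiff(labs, side)
    if (labs[1] %in% side) side <- other
    if (length(side) < 2 || length(side) > length(labs) - 2)
      return(NA_character_)
    paste(side, collapse = ",")
  }, character(1))
  paste(sort(unique(ks[!is.na(ks)])), collapse = ";")
}

# plain-R Needleman-Wunsch with affine gaps (gap of length k costs
# open + k * extend); independent oracle for the C++ aligner
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, open = -4,
                            ext = -1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- open + i * ext
  for (j in seq_len(m)) Y[1, j + 1] <- open + j * ext
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (x[i] == y[j]) match else mismatch
    M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] + open + ext, X[i, j + 1] + ext,
                           Y[i, j + 1] + open + ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + open + ext, Y[i + 1, j] + ext,
                           X[i + 1, j] + open + ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# one shared default-parameter truth set, built lazily (several test files
# need the same study conditions; genomes are deterministic given the seed)
shared_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 101)
      anc <- generate_ancestor(cfg)
      pair <- evolve_pair(anc, cfg)
      cache <<- list(config = cfg, ancestor = anc, m1 = pair$m1,
                     m2 = pair$m2,
                     realized_divergence = pair$realized_divergence)
    }
    cache
  }
})
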