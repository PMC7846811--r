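#' Simulation configuration
#'
#' Parameters of the synthetic two-molecule study. Defaults emulate the
#' conditions under which the dual mitogenome was discovered: an ~18.1 kb
#' circular genome, 10.4% nucleotide divergence between molecules, three
#' nearly identical non-coding (Control-Region-like) blocks per genome,
#' a 14.5% minor-molecule read share, 100 bp paired-end reads with 180 bp
#' inserts, and indel-rich long reads averaging 2504.5 bp (sd 2409.2,
#' clipped to \[514, 16978\]) at ~17x major-molecule depth.
#'
#' @param seed integer RNG seed. Every generator operation derives its own
#'   stream from this seed plus a fixed per-operation offset.
#' @param genome_length genome size in bp (>= 16000).
#' @param target_divergence target pairwise nucleotide divergence between
#'   the two molecules (proportion).
#' @param kappa transition/transversion ratio of the K2P substitution
#'   process.
#' @param nc_block_count number of non-coding blocks.
#' @param nc_within_identity target pairwise identity between NC copies
#'   within one genome (the concerted-evolution signature).
#' @param minor_fraction expected minor-molecule share of the read mixture.
#' @param short_read_length,insert_mean,short_error short paired-end read
#'   length (bp), mean insert size (bp; sd is 10% of the mean) and
#'   substitution error rate.
#' @param long_length_mean,long_length_sd,long_length_min,long_length_max
#'   long-read length law: lognormal moment-matched to (mean, sd), clipped
#'   to \[min, max\].
#' @param long_error_sub,long_error_ins,long_error_del long-read per-base
#'   substitution / insertion / deletion rates.
#' @param depth_major fold-coverage of the major molecule.
#' @param full_read_prob probability that a long read is a full-molecule
#'   two-strand read (the genome concatenated with its reverse complement,
#'   emulating end-connected native strands).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 18078L,
                       target_divergence = 0.104,
                       kappa = 4.0,
                       nc_block_count = 3L,
                       nc_within_identity = 0.99,
                       minor_fraction = 0.145,
                       short_read_length = 100L,
                       insert_mean = 180L,
                       short_error = 0.001,
                       long_length_mean = 2504.5,
                       long_length_sd = 2409.2,
                       long_length_min = 514L,
                       long_length_max = 16978L,
                       long_error_sub = 0.03,
                       long_error_ins = 0.025,
                       long_error_del = 0.025,
                       depth_major = 17,
                       full_read_prob = 0.01) {
  cfg <- as.list(environment())
  rates <- c(target_divergence = target_divergence,
             nc_within_identity = nc_within_identity,
             short_error = short_error, long_error_sub = long_error_sub,
             long_error_ins = long_error_ins, long_error_del = long_error_del,
             full_read_prob = full_read_prob)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  if (minor_fraction <= 0 || minor_fraction >= 1)
    stop("minor_fraction must lie in (0, 1)")
  lens <- c(genome_length, short_read_length, insert_mean, long_length_min,
            long_length_max)
  if (any(lens <= 0)) stop("lengths must be positive")
  if (genome_length < 16000L) stop("genome_length must be >= 16000")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# Per-operation RNG offsets; each generator op seeds its own stream so
# operations are reproducible independently of call order.
.sim_offsets <- c(ancestor = 101L, evolve = 202L, short = 303L, long = 404L,
                  mix = 505L)

.seed_for <- function(config, op, extra = 0L) {
  s <- (config$seed + .sim_offsets[[op]] + extra) %% .Machine$integer.max
  set.seed(as.integer(s))
}

.BASES <- c("A", "C", "G", "T")
# Heavy-strand base usage with the mitochondrial anti-guanine bias
.BASE_PROBS <- c(A = 0.33, C = 0.28, G = 0.14, T = 0.25)
.MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

rand_bases <- function(n) sample(.BASES, n, replace = TRUE, prob = .BASE_PROBS)

# Standard mitochondrial tRNA anticodons (DNA alphabet)
.TRNA_ANTICODONS <- c(
  "trnF" = "GAA", "trnV" = "TAC", "trnL(UUR)" = "TAA", "trnI" = "GAT",
  "trnQ" = "TTG", "trnM" = "CAT", "trnW" = "TCA", "trnA" = "TGC",
  "trnN" = "GTT", "trnC" = "GCA", "trnY" = "GTA", "trnS(UCN)" = "TGA",
  "trnD" = "GTC", "trnK" = "TTT", "trnG" = "TCC", "trnR" = "TCG",
  "trnH" = "GTG", "trnS(AGY)" = "GCT", "trnL(CUN)" = "TAG", "trnE" = "TTC",
  "trnT" = "TGT", "trnP" = "TGG")

# Cloverleaf template layout (71 nt): acceptor 7 bp, D arm 4 bp stem with
# 8 nt loop, anticodon arm 5 bp stem with 7 nt loop, 4 nt variable arm,
# T arm 5 bp stem with 7 nt loop. Offsets are 0-based within the gene.
.TRNA_LAYOUT <- list(
  acc5 = 0:6, sp1 = 7:8, d5 = 9:12, dloop = 13:20, d3 = 21:24, sp2 = 25L,
  ac5 = 26:30, acloop = 31:37, ac3 = 38:42, var = 43:46, t5 = 47:51,
  tloop = 52:58, t3 = 59:63, acc3 = 64:70)

# Positions whose mutation could break the cloverleaf or the anticodon;
# held immutable by evolve_pair()
.TRNA_IMMUTABLE <- sort(unique(c(.TRNA_LAYOUT$acc5, .TRNA_LAYOUT$d5,
                                 .TRNA_LAYOUT$d3, .TRNA_LAYOUT$ac5,
                                 .TRNA_LAYOUT$ac3, .TRNA_LAYOUT$t5,
                                 .TRNA_LAYOUT$t3, .TRNA_LAYOUT$acc3,
                                 33:35)))

.revcomp_chars <- function(x) rev(chartr("ACGT", "TGCA", x))

make_trna_template <- function(anticodon) {
  stopifnot(nchar(anticodon) == 3L)
  acc5 <- rand_bases(7L)
  d5 <- rand_bases(4L)
  ac5 <- rand_bases(5L)
  t5 <- rand_bases(5L)
  x <- character(71L)
  x[.TRNA_LAYOUT$acc5 + 1L] <- acc5
  x[.TRNA_LAYOUT$sp1 + 1L] <- rand_bases(2L)
  x[.TRNA_LAYOUT$d5 + 1L] <- d5
  x[.TRNA_LAYOUT$dloop + 1L] <- rand_bases(8L)
  x[.TRNA_LAYOUT$d3 + 1L] <- .revcomp_chars(d5)
  x[.TRNA_LAYOUT$sp2 + 1L] <- rand_bases(1L)
  x[.TRNA_LAYOUT$ac5 + 1L] <- ac5
  x[.TRNA_LAYOUT$acloop + 1L] <- c("C", "T", strsplit(anticodon, "")[[1]],
                                   "A", "A")
  x[.TRNA_LAYOUT$ac3 + 1L] <- .revcomp_chars(ac5)
  x[.TRNA_LAYOUT$var + 1L] <- rand_bases(4L)
  x[.TRNA_LAYOUT$t5 + 1L] <- t5
  x[.TRNA_LAYOUT$tloop + 1L] <- rand_bases(7L)
  x[.TRNA_LAYOUT$t3 + 1L] <- .revcomp_chars(t5)
  x[.TRNA_LAYOUT$acc3 + 1L] <- .revcomp_chars(acc5)
  paste0(x, collapse = "")
}

make_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  n_codon <- len %/% 3L - 2L
  codons <- character(n_codon)
  need <- seq_len(n_codon)
  while (length(need)) {
    cand <- paste0(rand_bases(length(need)), rand_bases(length(need)),
                   rand_bases(length(need)))
    ok <- !(cand %in% .MITO_STOPS)
    codons[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  paste0("ATG", paste0(codons, collapse = ""), "TAA")
}

make_ol_spacer <- function() {
  stem <- c(rand_bases(9L), "G", "G", "C")   # elongation motif at stem base
  paste0(paste0(stem, collapse = ""), paste0(rand_bases(8L), collapse = ""),
         paste0(.revcomp_chars(stem), collapse = ""))
}

# The standard vertebrate mito gene model: feature order around the circle.
# CDS lengths are typical vertebrate values (multiples of 3); all tRNAs use
# the 71 nt cloverleaf template; NC blocks sit at the control-region locus
# between trnP and trnF.
.gene_model <- function(genome_length, nc_block_count) {
  feat <- function(name, kind, strand, len)
    data.frame(name = name, kind = kind, strand = strand, len = len,
               stringsAsFactors = FALSE)
  t71 <- function(name, strand = "heavy") feat(name, "tRNA", strand, 71L)
  base <- rbind(
    t71("trnF"), feat("rrnS", "rRNA", "heavy", 950L), t71("trnV"),
    feat("rrnL", "rRNA", "heavy", 1600L), t71("trnL(UUR)"),
    feat("ND1", "CDS", "heavy", 957L), t71("trnI"), t71("trnQ", "light"),
    t71("trnM"), feat("ND2", "CDS", "heavy", 1038L), t71("trnW"),
    t71("trnA", "light"), t71("trnN", "light"),
    feat("OL", "spacer", "heavy", 32L),
    t71("trnC", "light"), t71("trnY", "light"),
    feat("COI", "CDS", "heavy", 1551L), t71("trnS(UCN)", "light"),
    t71("trnD"), feat("COII", "CDS", "heavy", 687L), t71("trnK"),
    feat("ATP8", "CDS", "heavy", 165L), feat("ATP6", "CDS", "heavy", 681L),
    feat("COIII", "CDS", "heavy", 783L), t71("trnG"),
    feat("ND3", "CDS", "heavy", 348L), t71("trnR"),
    feat("ND4L", "CDS", "heavy", 294L), feat("ND4", "CDS", "heavy", 1377L),
    t71("trnH"), t71("trnS(AGY)"), t71("trnL(CUN)"),
    feat("ND5", "CDS", "heavy", 1812L), feat("ND6", "CDS", "light", 522L),
    t71("trnE", "light"), feat("Cytb", "CDS", "heavy", 1140L),
    t71("trnT"), t71("trnP", "light"))
  fixed <- sum(base$len)
  nc_total <- genome_length - fixed
  block <- nc_total %/% nc_block_count
  if (block < 60L)
    stop("genome_length too small to host the gene model plus ",
         nc_block_count, " non-coding blocks")
  rem <- nc_total - block * nc_block_count
  base$len[base$name == "rrnL"] <- base$len[base$name == "rrnL"] + rem
  nc <- feat(paste0("NC", seq_len(nc_block_count)), "NC", "heavy", block)
  rbind(base, nc)
}

#' Generate an ancestral mitochondrial genome
#'
#' Builds a circular genome carrying the 37 genes of the standard vertebrate
#' mitochondrial order plus Control-Region-like non-coding blocks (identical
#' copies in the ancestor) and an O_L-like stem-loop spacer between tRNA-Asn
#' and tRNA-Cys. All CDS are valid vertebrate-mito-code ORFs (ATG start,
#' terminal stop, no internal stops); tRNA genes are instantiated from a
#' cloverleaf-compatible template with perfect Watson-Crick stems.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param id genome id.
#' @return a `mito_genome` with a `sim_info` element recording immutable
#'   (structure-bearing) positions and NC block placement, used by
#'   [evolve_pair()].
#' @export
generate_ancestor <- function(config, id = "ancestor") {
  stopifnot(inherits(config, "sim_config"))
  .seed_for(config, "ancestor")
  model <- .gene_model(config$genome_length, config$nc_block_count)
  pieces <- character(nrow(model))
  immutable <- integer(0)
  pos <- 0L
  ann <- list()
  nc_master <- NULL
  nc_starts <- integer(0)
  for (i in seq_len(nrow(model))) {
    m <- model[i, ]
    if (m$kind == "tRNA") {
      templ <- make_trna_template(.TRNA_ANTICODONS[[m$name]])
      seq_i <- if (m$strand == "light")
        paste0(.revcomp_chars(strsplit(templ, "")[[1]]), collapse = "")
      else templ
      off <- if (m$strand == "light") m$len - 1L - .TRNA_IMMUTABLE
             else .TRNA_IMMUTABLE
      immutable <- c(immutable, pos + off)
    } else if (m$kind == "CDS") {
      s <- make_cds(m$len)
      seq_i <- if (m$strand == "light")
        paste0(.revcomp_chars(strsplit(s, "")[[1]]), collapse = "") else s
      ends <- c(0:2, (m$len - 3L):(m$len - 1L))   # start + stop codons
      off <- if (m$strand == "light") m$len - 1L - ends else ends
      immutable <- c(immutable, pos + off)
    } else if (m$kind == "rRNA") {
      seq_i <- paste0(rand_bases(m$len), collapse = "")
    } else if (m$kind == "spacer") {
      seq_i <- make_ol_spacer()
      immutable <- c(immutable, pos + 0:(m$len - 1L))
    } else { # NC
      if (is.null(nc_master)) nc_master <- paste0(rand_bases(m$len),
                                                  collapse = "")
      seq_i <- nc_master
      nc_starts <- c(nc_starts, pos)
    }
    pieces[i] <- seq_i
    if (m$kind != "spacer")
      ann[[length(ann) + 1L]] <- data.frame(
        name = m$name, kind = m$kind, start = pos, end = pos + m$len,
        strand = m$strand, copy_index = 1L, pseudo = FALSE,
        stringsAsFactors = FALSE)
    pos <- pos + m$len
  }
  stopifnot(pos == config$genome_length)
  g <- mito_genome(id, paste0(pieces, collapse = ""), circular = TRUE,
                   annotations = do.call(rbind, ann))
  g$sim_info <- list(immutable = sort(unique(immutable)),
                     nc_starts = nc_starts,
                     nc_len = model$len[model$kind == "NC"][1L])
  g
}

# ---- divergence process ----------------------------------------------------

# codon lookup for CDS-safe substitutions: for every genome position inside
# a CDS, the three genome positions of its codon in sense order + strand
.cds_index <- function(ann, L) {
  cds <- ann[ann$kind == "CDS", , drop = FALSE]
  idx <- vector("list", L)
  for (i in seq_len(nrow(cds))) {
    p <- cds$start[i]:(cds$end[i] - 1L)
    sense <- if (cds$strand[i] == "light") rev(p) else p
    codon_of <- rep(seq_len(length(p) %/% 3L), each = 3L)
    for (ci in unique(codon_of)) {
      trip <- sense[codon_of == ci]
      for (q in trip) idx[[q + 1L]] <- list(trip = trip,
                                            strand = cds$strand[i])
    }
  }
  idx
}

.comp_base <- c(A = "T", C = "G", G = "C", T = "A")
.ts_partner <- c(A = "G", G = "A", C = "T", T = "C")

# allowed replacement bases at genome position p (0-based) given CDS safety
.safe_alts <- function(chars, p, cds_idx) {
  cur <- chars[p + 1L]
  alts <- setdiff(.BASES, cur)
  info <- cds_idx[[p + 1L]]
  if (is.null(info)) return(alts)
  ok <- logical(length(alts))
  for (k in seq_along(alts)) {
    tmp <- chars[info$trip + 1L]          # genome bases in sense position order
    tmp[info$trip == p] <- alts[k]
    codon <- if (info$strand == "light")
      paste0(.comp_base[tmp], collapse = "") else paste0(tmp, collapse = "")
    ok[k] <- !(codon %in% .MITO_STOPS)
  }
  alts[ok]
}

# K2P-weighted choice among allowed alternative bases
.k2p_pick <- function(cur, allowed, kappa) {
  if (!length(allowed)) return(NA_character_)
  w <- ifelse(allowed == .ts_partner[[cur]], kappa, 1)
  if (length(allowed) == 1L) allowed else sample(allowed, 1L, prob = w)
}

.mutate_sites <- function(chars, sites, cds_idx, kappa, pool_spare) {
  for (p in sites) {
    alts <- .safe_alts(chars, p, cds_idx)
    b <- .k2p_pick(chars[p + 1L], alts, kappa)
    if (is.na(b)) {
      # no safe substitution here; take a spare site instead
      if (!length(pool_spare)) next
      p2 <- pool_spare[1L]; pool_spare <- pool_spare[-1L]
      alts <- .safe_alts(chars, p2, cds_idx)
      b <- .k2p_pick(chars[p2 + 1L], alts, kappa)
      if (is.na(b)) next
      chars[p2 + 1L] <- b
    } else chars[p + 1L] <- b
  }
  chars
}

#' Evolve a divergent genome pair from an ancestor
#'
#' Each lineage receives half the target divergence under a K2P substitution
#' process (transition bias `kappa`). CDS substitutions are constrained
#' never to create internal stop codons; tRNA stems, anticodons, start/stop
#' codons and the O_L spacer are held immutable so both genomes retain all
#' mitochondrial hallmark features. Non-coding blocks evolve via a per-genome
#' master copied to every block with small independent noise, producing the
#' concerted-evolution signature: copies within a genome stay nearly
#' identical while orthologous blocks between genomes diverge like the rest
#' of the molecule.
#'
#' @param ancestor genome from [generate_ancestor()].
#' @param config a [sim_config()].
#' @return list with elements `m1`, `m2` (each a `mito_genome` tagged
#'   `M1`/`M2`) and `realized_divergence`.
#' @export
evolve_pair <- function(ancestor, config) {
  stopifnot(inherits(config, "sim_config"), !is.null(ancestor$sim_info))
  .seed_for(config, "evolve")
  L <- genome_length(ancestor)
  d <- config$target_divergence
  info <- ancestor$sim_info
  B <- info$nc_len
  nblk <- length(info$nc_starts)
  chars0 <- strsplit(ancestor$sequence, "")[[1]]

  if (d == 0) {
    m1 <- ancestor; m1$id <- paste0(ancestor$id, "_M1"); m1$molecule_tag <- "M1"
    m2 <- ancestor; m2$id <- paste0(ancestor$id, "_M2"); m2$molecule_tag <- "M2"
    return(list(m1 = m1, m2 = m2, realized_divergence = 0))
  }

  nc_sites <- unlist(lapply(info$nc_starts, function(s) s + 0:(B - 1L)))
  nc1 <- info$nc_starts[1L] + 0:(B - 1L)
  pool <- setdiff(0:(L - 1L), c(info$immutable, nc_sites))
  cds_idx <- .cds_index(ancestor$annotations, L)

  # per-copy NC noise: half of (1 - within identity) so that two
  # independently noised copies differ at ~(1 - nc_within_identity)
  eps <- (1 - config$nc_within_identity) / 2
  d_nc_lin <- round(d * B / 2)                     # NC master subs per lineage
  e_noise <- round(nblk * B * 2 * eps * (1 - d))   # expected net noise diffs
  d1_total <- round(d * L) - 2L * d_nc_lin * nblk - e_noise
  d1_total <- max(d1_total, 0L)
  if (d1_total > length(pool))
    stop("target divergence too high for the mutable site pool (",
         d1_total, " > ", length(pool), ")")

  picked <- sample(pool, min(length(pool), d1_total + 200L))
  sites1 <- picked[seq_len(ceiling(d1_total / 2))]
  sites2 <- picked[ceiling(d1_total / 2) + seq_len(floor(d1_total / 2))]
  spare <- picked[-seq_len(d1_total)]

  g1 <- .mutate_sites(chars0, sites1, cds_idx, config$kappa,
                      spare[seq_along(spare) %% 2L == 1L])
  g2 <- .mutate_sites(chars0, sites2, cds_idx, config$kappa,
                      spare[seq_along(spare) %% 2L == 0L])

  # NC master evolution (disjoint site sets between lineages), then copy
  # the evolved master to every block and add per-copy noise
  nc_pick <- sample(nc1, min(B, 2L * d_nc_lin))
  for (p in nc_pick[seq_len(d_nc_lin)])
    g1[p + 1L] <- .k2p_pick(g1[p + 1L], setdiff(.BASES, g1[p + 1L]),
                            config$kappa)
  for (p in nc_pick[d_nc_lin + seq_len(d_nc_lin)])
    g2[p + 1L] <- .k2p_pick(g2[p + 1L], setdiff(.BASES, g2[p + 1L]),
                            config$kappa)
  for (g in c("g1", "g2")) {
    ch <- get(g)
    master <- ch[nc1 + 1L]
    for (s in info$nc_starts) {
      blk <- master
      # fixed per-copy count (not a binomial draw): two copies then differ
      # at <= 2*floor(eps*B) <= (1 - nc_within_identity)*B sites, so the
      # within-genome identity floor holds deterministically
      nmut <- floor(eps * B)
      if (nmut > 0) {
        at <- sample.int(B, nmut)
        blk[at] <- vapply(blk[at], function(b)
          sample(setdiff(.BASES, b), 1L), character(1L))
      }
      ch[s + 1:B] <- blk
    }
    assign(g, ch)
  }

  realized <- mean(g1 != g2)
  if (abs(realized - d) > 0.005)
    stop(sprintf(paste0("realized divergence %.4f misses target %.4f ",
                        "(budget %d sites, pool %d)"),
                 realized, d, d1_total, length(pool)))
  m1 <- mito_genome(paste0(ancestor$id, "_M1"), paste0(g1, collapse = ""),
                    circular = TRUE, annotations = ancestor$annotations,
                    molecule_tag = "M1")
  m2 <- mito_genome(paste0(ancestor$id, "_M2"), paste0(g2, collapse = ""),
                    circular = TRUE, annotations = ancestor$annotations,
                    molecule_tag = "M2")
  m1$sim_info <- info; m2$sim_info <- info
  list(m1 = m1, m2 = m2, realized_divergence = realized)
}

# ---- read simulation -------------------------------------------------------

.id_offset <- function(genome)
  sum(utf8ToInt(genome$id)) %% 997L

# vectorized reverse complement for plain character vectors
.revcomp_vec <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(ch)
    paste0(rev(ch), collapse = ""), character(1), USE.NAMES = FALSE)
}

.apply_subs <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    at <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in at) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(.BASES, cur), 1L)
    }
  }
  seqs
}

.apply_indel_errors <- function(s, sub_rate, ins_rate, del_rate) {
  x <- strsplit(s, "")[[1]]
  n <- length(x)
  u <- runif(n)
  del <- u < del_rate
  subp <- !del & u < del_rate + sub_rate
  if (any(subp)) {
    x[subp] <- vapply(x[subp], function(b)
      sample(setdiff(.BASES, b), 1L), character(1L))
  }
  ins <- runif(n) < ins_rate
  extra <- character(n)
  if (any(ins)) extra[ins] <- sample(.BASES, sum(ins), replace = TRUE)
  x[del] <- ""
  paste0(paste0(x, extra), collapse = "")
}

#' Simulate short paired-end reads
#'
#' Fragments are placed uniformly on the circle (wrapping the origin),
#' with insert sizes ~ Normal(`insert_mean`, 0.1 x `insert_mean`);
#' both 100 bp ends are reported, the second reverse-complemented, with
#' substitution errors at `short_error`. Reads carry the source molecule
#' as `true_origin`.
#'
#' @param genome source `mito_genome`.
#' @param config a [sim_config()].
#' @param depth target fold-coverage (default `config$depth_major`).
#' @return a [read_set()] with `platform = "short_pe"`.
#' @export
simulate_short_reads <- function(genome, config, depth = config$depth_major) {
  stopifnot(inherits(config, "sim_config"))
  .seed_for(config, "short", .id_offset(genome))
  L <- genome_length(genome)
  rl <- config$short_read_length
  n_pairs <- max(1L, round(depth * L / (2 * rl)))
  doubled <- paste0(genome$sequence, genome$sequence)
  frag_len <- pmax(rl, round(rnorm(n_pairs, config$insert_mean,
                                   0.1 * config$insert_mean)))
  frag_len <- pmin(frag_len, L)
  start <- sample.int(L, n_pairs, replace = TRUE) - 1L
  frags <- substring(doubled, start + 1L, start + frag_len)
  r1 <- substr(frags, 1L, rl)
  r2 <- .revcomp_vec(substring(frags, frag_len - rl + 1L, frag_len))
  r1 <- .apply_subs(r1, config$short_error)
  r2 <- .apply_subs(r2, config$short_error)
  base_id <- sprintf("%s_p%05d", genome$id, seq_len(n_pairs))
  org <- if (is.null(genome$molecule_tag)) NA_character_ else genome$molecule_tag
  read_set(id = c(paste0(base_id, "/1"), paste0(base_id, "/2")),
           sequence = c(r1, r2), platform = "short_pe",
           mate_id = c(paste0(base_id, "/2"), paste0(base_id, "/1")),
           true_origin = org)
}

#' Simulate long single-molecule reads
#'
#' Lengths follow a lognormal moment-matched to
#' (`long_length_mean`, `long_length_sd`), clipped to
#' \[`long_length_min`, `long_length_max`\]; starts are uniform on the
#' circle and orientation is random. Indel-rich errors are applied at the
#' configured substitution/insertion/deletion rates. With probability
#' `full_read_prob` a read is a full-molecule two-strand read: the rotated
#' genome concatenated with its reverse complement, emulating
#' end-connected native strands.
#'
#' @param genome source `mito_genome`.
#' @param config a [sim_config()].
#' @param depth target fold-coverage (default `config$depth_major`).
#' @param n_reads override the read count directly.
#' @return a [read_set()] with `platform = "long"`.
#' @export
simulate_long_reads <- function(genome, config, depth = config$depth_major,
                                n_reads = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .seed_for(config, "long", .id_offset(genome))
  L <- genome_length(genome)
  n <- if (is.null(n_reads))
    max(1L, round(depth * L / config$long_length_mean)) else n_reads
  m <- config$long_length_mean; s <- config$long_length_sd
  sig2 <- log(1 + s^2 / m^2)
  lens <- round(rlnorm(n, log(m) - sig2 / 2, sqrt(sig2)))
  lens <- pmin(pmax(lens, config$long_length_min), config$long_length_max)
  lens <- pmin(lens, L)
  doubled <- paste0(genome$sequence, genome$sequence)
  start <- sample.int(L, n, replace = TRUE) - 1L
  full <- runif(n) < config$full_read_prob
  fwd <- runif(n) < 0.5
  seqs <- substring(doubled, start + 1L, start + lens)
  if (any(full)) {
    for (i in which(full)) {
      rot <- substring(doubled, start[i] + 1L, start[i] + L)
      seqs[i] <- paste0(rot, revcomp(rot))
    }
  }
  flip <- !fwd
  seqs[flip] <- .revcomp_vec(seqs[flip])
  if (config$long_error_sub > 0 || config$long_error_ins > 0 ||
      config$long_error_del > 0) {
    seqs <- vapply(seqs, .apply_indel_errors, character(1L),
                   sub_rate = config$long_error_sub,
                   ins_rate = config$long_error_ins,
                   del_rate = config$long_error_del, USE.NAMES = FALSE)
  }
  org <- if (is.null(genome$molecule_tag)) NA_character_ else genome$molecule_tag
  rs <- read_set(id = sprintf("%s_L%05d", genome$id, seq_len(n)),
                 sequence = seqs, platform = "long", true_origin = org)
  rs$full_molecule <- full
  rs
}

#' Mix two read pools at a given minor fraction
#'
#' Draws a mixture in which the expected share of `reads_m2` equals
#' `minor_fraction` (the per-read origin is Bernoulli, so realized counts
#' are binomial). Truth labels are retained. Deterministic given `seed`.
#'
#' @param reads_m1,reads_m2 [read_set()] pools (major, minor).
#' @param minor_fraction expected share of `reads_m2` in (0, 1).
#' @param seed integer seed.
#' @param n_total mixture size; default uses as much of both pools as the
#'   fraction allows.
#' @return a shuffled [read_set()].
#' @export
mix_reads <- function(reads_m1, reads_m2, minor_fraction, seed,
                      n_total = NULL) {
  if (minor_fraction <= 0 || minor_fraction >= 1)
    stop("minor_fraction must lie in (0, 1)")
  if (!nrow(reads_m1) || !nrow(reads_m2)) stop("both read pools must be non-empty")
  set.seed(as.integer(seed %% .Machine$integer.max))
  n1p <- nrow(reads_m1); n2p <- nrow(reads_m2)
  if (is.null(n_total))
    n_total <- floor(min(n1p / (1 - minor_fraction), n2p / minor_fraction))
  n2 <- rbinom(1L, n_total, minor_fraction)
  n2 <- min(n2, n2p); n1 <- min(n_total - n2, n1p)
  take1 <- reads_m1[sample.int(n1p, n1), , drop = FALSE]
  take2 <- reads_m2[sample.int(n2p, n2), , drop = FALSE]
  common <- intersect(names(take1), names(take2))
  out <- rbind(as.data.frame(take1)[common], as.data.frame(take2)[common])
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}

#' Generate a complete synthetic truth set
#'
#' Convenience composition: ancestor, divergent pair, per-molecule long
#' reads, and the mixed pool at the configured minor fraction.
#'
#' @param config a [sim_config()].
#' @param short_reads also simulate short paired-end reads (mixed at the
#'   same fraction)?
#' @return list with `config`, `ancestor`, `m1`, `m2`,
#'   `realized_divergence`, `reads_long` (mixed), and optionally
#'   `reads_short`.
#' @export
simulate_truth_set <- function(config, short_reads = FALSE) {
  anc <- generate_ancestor(config)
  pair <- evolve_pair(anc, config)
  long1 <- simulate_long_reads(pair$m1, config)
  long2 <- simulate_long_reads(pair$m2, config)
  out <- list(config = config, ancestor = anc, m1 = pair$m1, m2 = pair$m2,
              realized_divergence = pair$realized_divergence,
              reads_long = mix_reads(long1, long2, config$minor_fraction,
                                     seed = config$seed + 11L))
  if (short_reads) {
    s1 <- simulate_short_reads(pair$m1, config, depth = 50)
    s2 <- simulate_short_reads(pair$m2, config, depth = 50)
    out$reads_short <- mix_reads(s1, s2, config$minor_fraction,
                                 seed = config$seed + 12L)
  }
  out
}

#' Write a truth manifest as JSON
#'
#' Records seeds, realized divergence and per-read origin labels so a
#' simulated data set written to FASTA/FASTQ can be re-linked to its truth.
#'
#' @param truth output of [simulate_truth_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(truth, path) {
  man <- list(seed = truth$config$seed,
              genome_length = truth$config$genome_length,
              target_divergence = truth$config$target_divergence,
              realized_divergence = truth$realized_divergence,
              minor_fraction = truth$config$minor_fraction,
              read_origins = setNames(as.list(truth$reads_long$true_origin),
                                      truth$reads_long$id))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
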