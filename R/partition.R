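#' @importFrom IRanges IRanges coverage
NULL

.preset_for <- function(platform) ifelse(platform == "short_pe", "sr",
                                         "map-ont")

#' Assign reads to one of two candidate molecules
#'
#' Each read is aligned (either orientation, circular references doubled)
#' against both candidate references and receives a gap-compressed identity
#' to each. Reads shorter than `min_len` are set aside (`too_short`). A
#' read is called for the molecule with the higher identity when the
#' identity difference reaches `delta_rel`; otherwise (including exact
#' ties) it is `unassigned`. The default margin is half the divergence
#' cutoff `delta`: a read truly from one molecule is expected to lose the
#' full inter-molecule divergence against the wrong reference while noise
#' is symmetric, so half the cutoff separates the two populations. Raw
#' identities are always emitted so alternative decision rules can be
#' applied post hoc. Reads aligning to only one molecule are called from
#' the single finite identity (margin measured against identity 0).
#'
#' @param reads a [read_set()].
#' @param ref_m1,ref_m2 `mito_genome` or named character references.
#' @param delta divergence cutoff (default 0.05, adopted because the two
#'   molecules are ~10% divergent).
#' @param min_len minimum read length considered (default 500 bp).
#' @param delta_rel identity margin required to call (default `delta / 2`).
#' @param circular treat references as circular?
#' @param check_refs warn if the two references are less than `delta`
#'   divergent?
#' @return data frame of class `assignment_table`: per read `id`, `length`,
#'   `identity_m1`, `identity_m2`, spans, `call`
#'   (`M1`/`M2`/`unassigned`/`too_short`), plus `true_origin` when present.
#'   Attributes record the parameters and discordant mate pairs.
#' @export
assign_reads <- function(reads, ref_m1, ref_m2, delta = 0.05, min_len = 500L,
                         delta_rel = delta / 2, circular = TRUE,
                         check_refs = TRUE) {
  if (!nrow(reads)) {
    out <- data.frame(id = character(0), length = integer(0),
                      identity_m1 = numeric(0), identity_m2 = numeric(0),
                      call = character(0))
    class(out) <- c("assignment_table", "data.frame")
    return(out)
  }
  r1 <- .as_named_seqs(ref_m1); r2 <- .as_named_seqs(ref_m2)
  if (check_refs && nchar(r1[[1L]]) == nchar(r2[[1L]])) {
    dref <- mean(strsplit(r1[[1L]], "")[[1L]] != strsplit(r2[[1L]], "")[[1L]])
    if (dref <= delta)
      warning(sprintf("reference divergence %.3f <= delta %.3f: calls %s",
                      dref, delta, "will be unreliable"))
  }
  len <- nchar(reads$sequence)
  out <- data.frame(id = reads$id, length = len,
                    identity_m1 = NA_real_, identity_m2 = NA_real_,
                    span_start_m1 = NA_integer_, span_end_m1 = NA_integer_,
                    span_start_m2 = NA_integer_, span_end_m2 = NA_integer_,
                    call = "too_short", stringsAsFactors = FALSE)
  if ("true_origin" %in% names(reads)) out$true_origin <- reads$true_origin
  eligible <- len >= min_len
  if (any(eligible)) {
    for (pf in unique(reads$platform[eligible])) {
      sel <- which(eligible & reads$platform == pf)
      seqs <- setNames(reads$sequence[sel], reads$id[sel])
      h1 <- .batch_identity(seqs, r1, circular, .preset_for(pf))
      h2 <- .batch_identity(seqs, r2, circular, .preset_for(pf))
      out$identity_m1[sel] <- h1$identity
      out$identity_m2[sel] <- h2$identity
      out$span_start_m1[sel] <- h1$span_start
      out$span_end_m1[sel] <- h1$span_end
      out$span_start_m2[sel] <- h2$span_start
      out$span_end_m2[sel] <- h2$span_end
    }
    i1 <- out$identity_m1[eligible]; i2 <- out$identity_m2[eligible]
    call <- rep("unassigned", sum(eligible))
    call[i1 - i2 >= delta_rel] <- "M1"
    call[i2 - i1 >= delta_rel] <- "M2"
    call[i1 == 0 & i2 == 0] <- "unassigned"
    out$call[eligible] <- call
  }
  # pair-level reconciliation: discordant mates reported, never overridden
  disc <- character(0)
  if ("mate_id" %in% names(reads) && any(!is.na(reads$mate_id))) {
    cl <- setNames(out$call, out$id)
    paired <- reads$id[!is.na(reads$mate_id)]
    mate <- setNames(reads$mate_id, reads$id)
    both <- paired[cl[paired] %in% c("M1", "M2") &
                   cl[mate[paired]] %in% c("M1", "M2")]
    disc <- both[cl[both] != cl[mate[both]]]
  }
  attr(out, "params") <- list(delta = delta, min_len = min_len,
                              delta_rel = delta_rel, circular = circular)
  attr(out, "discordant_pairs") <- disc
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' @export
print.assignment_table <- function(x, ...) {
  cat(sprintf("<assignment_table> %d reads: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$call)), table(x$call)),
                    collapse = " ")))
  invisible(x)
}

#' Partition assembly contigs between two molecules
#'
#' Screens contigs by divergence (1 - gap-compressed identity) to each
#' reference: a contig at least `min_div` divergent from one reference and
#' less than `min_div` from the other is attributed to the closer molecule;
#' anything else (including chimeras matching both closely) is ambiguous.
#'
#' @param contigs named character vector (>= 200 bp each).
#' @param ref_primary,ref_secondary references.
#' @param min_div minimum divergence cutoff (default 0.05).
#' @param circular treat references as circular?
#' @return list with `primary`, `secondary`, `ambiguous` (contig names)
#'   and `table` (per-contig divergences).
#' @export
screen_contigs <- function(contigs, ref_primary, ref_secondary,
                           min_div = 0.05, circular = TRUE) {
  contigs <- .as_named_seqs(contigs)
  if (any(nchar(contigs) < 200L))
    stop("contigs must be >= 200 bp")
  d1 <- 1 - .batch_identity(contigs, ref_primary, circular)$identity
  d2 <- 1 - .batch_identity(contigs, ref_secondary, circular)$identity
  to_primary <- d1 < min_div & d2 >= min_div
  to_secondary <- d2 < min_div & d1 >= min_div
  tab <- data.frame(id = names(contigs), div_primary = d1, div_secondary = d2,
                    set = ifelse(to_primary, "primary",
                                 ifelse(to_secondary, "secondary",
                                        "ambiguous")))
  list(primary = names(contigs)[to_primary],
       secondary = names(contigs)[to_secondary],
       ambiguous = names(contigs)[!to_primary & !to_secondary],
       table = tab)
}

#' Coverage summary of reads assigned to one molecule
#'
#' Per-position depth computed from aligned reference spans (circular wrap
#' respected via the doubled-reference coordinates), with breadth = % of
#' reference positions covered at least once, and depth / read-length
#' summary statistics.
#'
#' @param assignments an [assign_reads()] table.
#' @param reference the reference the spans refer to.
#' @param which_molecule `"M1"` or `"M2"`.
#' @return list of class `coverage_summary`; depth statistics are `NULL`
#'   when no reads are assigned.
#' @export
coverage_summary <- function(assignments, reference, which_molecule = "M1") {
  ref <- .as_named_seqs(reference)
  L <- nchar(ref[[1L]])
  sel <- assignments$call == which_molecule
  scol <- paste0("span_start_", tolower(which_molecule))
  ecol <- paste0("span_end_", tolower(which_molecule))
  sel <- sel & !is.na(assignments[[scol]])
  if (!any(sel)) {
    return(structure(list(molecule = which_molecule, n_reads = 0L,
                          breadth = 0, depth = NULL, read_length = NULL),
                     class = "coverage_summary"))
  }
  s <- assignments[[scol]][sel]; e <- assignments[[ecol]][sel]
  e <- pmin(e, s + 2L * L)          # a full two-strand read covers twice
  cov <- IRanges::coverage(IRanges::IRanges(start = s + 1L, end = e),
                           width = 3L * L)
  v <- as.integer(cov)
  depth <- v[seq_len(L)] + v[L + seq_len(L)] + v[2L * L + seq_len(L)]
  lens <- assignments$length[sel]
  structure(list(molecule = which_molecule, n_reads = sum(sel),
                 breadth = 100 * mean(depth >= 1L),
                 depth = list(mean = mean(depth), sd = sd(depth),
                              min = min(depth), max = max(depth)),
                 read_length = list(mean = mean(lens), sd = sd(lens),
                                    min = min(lens), max = max(lens))),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  if (x$n_reads == 0L) {
    cat(sprintf("<coverage_summary> %s: no reads assigned\n", x$molecule))
  } else {
    cat(sprintf(paste0("<coverage_summary> %s: %d reads, %.1f%% of reference ",
                       "covered, depth %.1f (sd %.1f, min %d, max %d), read ",
                       "length %.1f (sd %.1f, min %d, max %d)\n"),
                x$molecule, x$n_reads, x$breadth, x$depth$mean, x$depth$sd,
                x$depth$min, x$depth$max, x$read_length$mean,
                x$read_length$sd, x$read_length$min, x$read_length$max))
  }
  invisible(x)
}

.wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Minor-molecule mixture fraction
#'
#' Fraction of assignable reads attributed to the minor molecule, with a
#' 95% Wilson score interval.
#'
#' @param assignments an [assign_reads()] table with at least one read
#'   called `M1` or `M2`.
#' @return list of class `mixture_estimate`: `n_m1`, `n_m2`,
#'   `n_assignable`, `minor_molecule`, `minor_fraction`, `ci_low`,
#'   `ci_high`.
#' @export
mixture_fraction <- function(assignments) {
  n1 <- sum(assignments$call == "M1")
  n2 <- sum(assignments$call == "M2")
  mixture_from_counts(n1, n2)
}

#' @rdname mixture_fraction
#' @param n_m1,n_m2 read counts assigned to each molecule.
#' @export
mixture_from_counts <- function(n_m1, n_m2) {
  n <- n_m1 + n_m2
  if (n < 1L) stop("no assignable reads")
  minor <- if (n_m2 <= n_m1) "M2" else "M1"
  k <- min(n_m1, n_m2)
  ci <- .wilson_ci(k, n)
  structure(list(n_m1 = n_m1, n_m2 = n_m2, n_assignable = n,
                 minor_molecule = minor, minor_fraction = k / n,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"])),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf(paste0("<mixture_estimate> %d + %d = %d assignable; minor %s ",
                     "at %.1f%% (95%% CI %.1f-%.1f%%)\n"),
              x$n_m1, x$n_m2, x$n_assignable, x$minor_molecule,
              100 * x$minor_fraction, 100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Majority-vote consensus from assigned reads
#'
#' Desk-scale consensus builder: reads called for the target molecule are
#' mapped back to its reference (doubled for circularity), a pileup is
#' computed, and each position takes the majority base (ties resolve to
#' the reference base when it is among the tied bases, else
#' alphabetically). Positions with no coverage retain the reference base
#' and are flagged.
#'
#' @param assignments an [assign_reads()] table.
#' @param reads the [read_set()] the table was computed from.
#' @param reference the target molecule's reference.
#' @param which_molecule `"M1"` or `"M2"`.
#' @param min_breadth required breadth (proportion; default 0.99).
#' @return a `mito_genome` with element `uncovered_positions` (0-based).
#' @export
consensus_from_assignment <- function(assignments, reads, reference,
                                      which_molecule = "M1",
                                      min_breadth = 0.99) {
  ref <- .as_named_seqs(reference)
  L <- nchar(ref[[1L]])
  sel_ids <- assignments$id[assignments$call == which_molecule]
  if (!length(sel_ids)) stop("no reads assigned to ", which_molecule)
  sel <- reads[reads$id %in% sel_ids, , drop = FALSE]
  qp <- .tmp_fasta(setNames(sel$sequence, sel$id), "cns")
  rp <- .tmp_fasta(setNames(paste0(ref, ref), names(ref)), "cnsref")
  sam <- tempfile("cns", fileext = ".sam")
  on.exit(unlink(c(qp, rp, sam, paste0(sam, ".bam"), paste0(sam, ".bam.bai")),
                 force = TRUE), add = TRUE)
  preset <- .preset_for(sel$platform[1L])
  status <- system2("minimap2", c("-ax", preset, "-t", "1", "--secondary=no",
                                  shQuote(rp), shQuote(qp)),
                    stdout = sam, stderr = FALSE)
  if (status != 0) stop("minimap2 failed with status ", status)
  bam <- Rsamtools::asBam(sam, destination = paste0(sam, ".bam"),
                          overwrite = TRUE, indexDestination = TRUE)
  pp <- Rsamtools::PileupParam(max_depth = 100000L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  pu <- Rsamtools::pileup(bam, pileupParam = pp)
  pos0 <- (pu$pos - 1L) %% L
  counts <- stats::aggregate(count ~ pos0 + nucleotide,
                             data = data.frame(pos0 = pos0,
                                               nucleotide = as.character(pu$nucleotide),
                                               count = pu$count),
                             FUN = sum)
  counts <- counts[counts$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
  refchars <- strsplit(ref[[1L]], "")[[1L]]
  breadth <- length(unique(counts$pos0)) / L
  if (breadth < min_breadth)
    stop(sprintf(paste0("breadth %.1f%% below required %.1f%%: more ",
                        "coverage needed for a consensus"),
                 100 * breadth, 100 * min_breadth))
  cons <- refchars
  covered <- logical(L)
  for (p in unique(counts$pos0)) {
    cc <- counts[counts$pos0 == p, , drop = FALSE]
    mx <- max(cc$count)
    cand <- sort(cc$nucleotide[cc$count == mx])
    cons[p + 1L] <- if (refchars[p + 1L] %in% cand) refchars[p + 1L]
                    else cand[1L]
    covered[p + 1L] <- TRUE
  }
  g <- mito_genome(paste0(names(ref), "_", which_molecule, "_consensus"),
                   paste0(cons, collapse = ""), circular = TRUE)
  g$uncovered_positions <- which(!covered) - 1L
  g
}

#' k-mer repeat scan
#'
#' Counts canonical k-mers in a read set and flags those whose count
#' reaches `threshold` x `expected_depth` — the signature of repeated
#' sequence (e.g. a tandem duplication, or the triplicated non-coding
#' blocks) that a draft assembly may have collapsed. Flagged k-mers are
#' localized on the draft genome by exact matching (both strands, origin
#' wrap respected).
#'
#' @param reads a [read_set()] (reads shorter than `k` are skipped and
#'   counted).
#' @param draft_genome `mito_genome` or named character draft to localize
#'   hits on.
#' @param k odd k-mer size in 15-101 (default 71).
#' @param expected_depth expected k-mer coverage of unique sequence (note:
#'   a k-mer occurs in roughly `depth * (read_len - k + 1) / read_len`
#'   reads, less than the base depth). Default: the modal k-mer count
#'   after discarding singletons, a robust empirical estimate when most of
#'   the genome is unique (sequencing-error k-mers dominate the
#'   singletons).
#' @param threshold flagging multiple (default 1.6).
#' @return list of class `kmer_repeat_scan`: `flagged` (k-mer, count),
#'   `regions` (merged intervals on the draft, 0-based half-open),
#'   `modal_count`, `expected_depth`, `n_skipped`.
#' @export
kmer_repeat_scan <- function(reads, draft_genome, k = 71L,
                             expected_depth = NULL, threshold = 1.6) {
  if (k %% 2L == 0L || k < 15L || k > 101L)
    stop("k must be odd and within 15-101")
  seqs <- reads$sequence
  short <- nchar(seqs) < k
  n_skipped <- sum(short)
  seqs <- seqs[!short]
  if (!length(seqs)) stop("no reads of length >= k")
  km <- unlist(lapply(seqs, function(s)
    substring(s, seq_len(nchar(s) - k + 1L), k:nchar(s))))
  km <- km[!grepl("N", km, fixed = TRUE)]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  canon <- pmin(km, rc)
  tab <- table(canon)
  counts <- as.integer(tab)
  nonsingle <- counts[counts > 1L]
  modal <- if (length(nonsingle))
    as.integer(names(sort(table(nonsingle), decreasing = TRUE))[1L])
  else 1L
  if (is.null(expected_depth)) expected_depth <- modal
  cut <- threshold * expected_depth
  flagged <- names(tab)[counts >= cut]
  regions <- NULL
  if (length(flagged)) {
    ref <- .as_named_seqs(draft_genome)[[1L]]
    doubled <- Biostrings::DNAString(paste0(ref, ref))
    L <- nchar(ref)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(flagged))
    hits_f <- Biostrings::matchPDict(pd, doubled)
    pd_rc <- Biostrings::PDict(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(flagged)))
    hits_r <- Biostrings::matchPDict(pd_rc, doubled)
    st <- c(unlist(lapply(hits_f, BiocGenerics::start)),
            unlist(lapply(hits_r, BiocGenerics::start)))
    st <- st[st <= L]
    if (length(st)) {
      ir <- IRanges::reduce(IRanges::IRanges(start = st, width = k))
      regions <- data.frame(start = BiocGenerics::start(ir) - 1L,
                            end = pmin(BiocGenerics::end(ir), L))
    }
  }
  structure(list(flagged = data.frame(kmer = flagged,
                                      count = counts[counts >= cut]),
                 regions = regions, modal_count = modal,
                 expected_depth = expected_depth, n_skipped = n_skipped),
            class = "kmer_repeat_scan")
}

#' Purge contaminant reads
#'
#' Splits a read set into reads matching a contaminant reference at or
#' above `identity_threshold` (purged) and the rest (kept) — the
#' mitochondrial analogue of purging a foreign mt-genome from a mined
#' transcriptome library. Deterministic; `kept` and `purged` partition the
#' input.
#'
#' @param reads a [read_set()].
#' @param contaminant_reference the contaminant genome.
#' @param identity_threshold minimum gap-compressed identity to purge
#'   (default 0.90; 1.0 purges exact matches only).
#' @param circular treat the contaminant reference as circular?
#' @return list with `kept` and `purged` [read_set()]s and `identity`
#'   (per-read identity to the contaminant).
#' @export
decontaminate <- function(reads, contaminant_reference,
                          identity_threshold = 0.90, circular = TRUE) {
  ref <- .as_named_seqs(contaminant_reference)
  if (!nchar(ref[[1L]])) stop("contaminant reference must be non-empty")
  if (!nrow(reads)) return(list(kept = reads, purged = reads,
                                identity = numeric(0)))
  idn <- numeric(nrow(reads))
  for (pf in unique(reads$platform)) {
    sel <- reads$platform == pf
    idn[sel] <- .batch_identity(setNames(reads$sequence[sel], reads$id[sel]),
                                ref, circular, .preset_for(pf))$identity
  }
  purge <- idn >= identity_threshold
  keep_rs <- function(df) { class(df) <- c("read_set", "data.frame"); df }
  list(kept = keep_rs(reads[!purge, , drop = FALSE]),
       purged = keep_rs(reads[purge, , drop = FALSE]),
       identity = setNames(idn, reads$id))
}
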