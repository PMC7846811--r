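#' Strand base composition
#'
#' Exact counts and percentages of A/C/G/T on both strands, with the
#' heavy-strand guanine percentage reported separately (mitochondrial
#' genomes show a strong strand bias against guanine on the heavy strand).
#' The heavy strand is defined as the strand given in the genome sequence;
#' `N` bases are excluded from denominators.
#'
#' @param genome a `mito_genome` (or a plain character sequence).
#' @return list of class `composition_report` with `heavy`, `light`
#'   count/percentage tables and `guanine_pct_heavy`.
#' @export
base_composition <- function(genome) {
  seq <- if (inherits(genome, "mito_genome")) genome$sequence
         else normalize_dna(genome)
  tab_for <- function(s) {
    x <- strsplit(s, "")[[1]]
    counts <- vapply(c("A", "C", "G", "T"), function(b) sum(x == b), integer(1))
    denom <- sum(counts)
    if (denom == 0L) stop("sequence contains no unambiguous bases")
    list(counts = counts, pct = 100 * counts / denom)
  }
  heavy <- tab_for(seq)
  light <- tab_for(revcomp(seq))
  structure(list(heavy = heavy, light = light,
                 guanine_pct_heavy = unname(heavy$pct["G"])),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("<composition_report> heavy strand (%):",
      paste(sprintf("%s=%.1f", names(x$heavy$pct), x$heavy$pct),
            collapse = " "),
      sprintf("| guanine %.1f%%\n", x$guanine_pct_heavy))
  invisible(x)
}

# NCBI translation table 2 (vertebrate mitochondrial):
# TGA=Trp, ATA=Met, AGA/AGG=Ter
.mito_code <- function() Biostrings::getGeneticCode("2")

#' Translate a single CDS under the vertebrate mitochondrial code
#' @param cds sense-strand CDS nucleotide string.
#' @return list(protein, start_codon, stop_codon, stop_complete,
#'   incomplete_stop, frame_ok, internal_stop_positions).
#' @keywords internal
translate_one_cds <- function(cds) {
  code <- .mito_code()
  n <- nchar(cds)
  rem <- n %% 3L
  incomplete <- FALSE
  stop_codon <- NA_character_
  if (rem == 1L && substr(cds, n, n) == "T") {
    incomplete <- TRUE; stop_codon <- "T.."
    cds_use <- substr(cds, 1L, n - 1L)
  } else if (rem == 2L && substr(cds, n - 1L, n) == "TA") {
    incomplete <- TRUE; stop_codon <- "TA."
    cds_use <- substr(cds, 1L, n - 2L)
  } else cds_use <- cds
  frame_ok <- nchar(cds_use) %% 3L == 0L
  if (!frame_ok) cds_use <- substr(cds_use, 1L, nchar(cds_use) %/% 3L * 3L)
  codons <- substring(cds_use, seq(1L, nchar(cds_use), 3L),
                      seq(3L, nchar(cds_use), 3L))
  aa <- ifelse(grepl("[^ACGT]", codons), "X",
               unname(code[match(codons, names(code))]))
  aa[is.na(aa)] <- "X"
  k <- length(aa)
  if (!incomplete && k > 0L && aa[k] == "*") {
    stop_codon <- codons[k]
    aa <- aa[-k]; codons <- codons[-k]; k <- k - 1L
  }
  internal <- which(aa == "*")
  list(protein = paste0(aa, collapse = ""),
       start_codon = if (k > 0L) codons[1L] else NA_character_,
       stop_codon = stop_codon,
       stop_complete = !incomplete && !is.na(stop_codon),
       incomplete_stop = incomplete,
       frame_ok = frame_ok,
       internal_stop_positions = internal)
}

#' Translate all annotated CDS of a genome
#'
#' Light-strand CDS are reverse-complemented before translation. Incomplete
#' terminal stop codons (`T` or `TA` at the CDS end, completed by
#' polyadenylation in vivo) are accepted and flagged, not failed. A CDS
#' whose length is not a codon multiple after stop-completion handling is
#' reported per gene, not fatal.
#'
#' @param genome an annotated `mito_genome`.
#' @return list of class `translation_report`: per-CDS results plus
#'   overall `pass` (no internal stops in any CDS).
#' @export
translate_cds <- function(genome) {
  ann <- genome$annotations
  cds <- ann[ann$kind == "CDS" & !ann$pseudo, , drop = FALSE]
  if (!nrow(cds)) stop("genome has no CDS annotations")
  res <- lapply(seq_len(nrow(cds)), function(i) {
    s <- gene_sequence(genome, cds$name[i], cds$copy_index[i])
    c(list(gene = cds$name[i]), translate_one_cds(s))
  })
  names(res) <- cds$name
  pass <- all(vapply(res, function(r)
    length(r$internal_stop_positions) == 0L, logical(1)))
  structure(list(cds = res, pass = pass), class = "translation_report")
}

#' @export
print.translation_report <- function(x, ...) {
  bad <- names(x$cds)[vapply(x$cds, function(r)
    length(r$internal_stop_positions) > 0L, logical(1))]
  cat(sprintf("<translation_report> %d CDS, %s\n", length(x$cds),
              if (x$pass) "all clean" else
                paste("internal stops in:", paste(bad, collapse = ", "))))
  invisible(x)
}

# ---- tRNA folding ----------------------------------------------------------

# a stem "pairs" if every position is Watson-Crick except at most one,
# which may be a G-U wobble or a mismatch
.stem_ok <- function(x, i5, j3, len) {
  a <- x[i5 + seq_len(len) - 1L]
  b <- x[j3 + len - seq_len(len)]
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
        (a == "G" & b == "C") | (a == "C" & b == "G")
  sum(!wc) <= 1L
}

.stem_score <- function(x, i5, j3, len) {
  a <- x[i5 + seq_len(len) - 1L]
  b <- x[j3 + len - seq_len(len)]
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
        (a == "G" & b == "C") | (a == "C" & b == "G")
  2L * sum(wc)
}

.fold_grid_cache <- new.env(parent = emptyenv())

.fold_grid <- function(n) {
  key <- as.character(n)
  if (!is.null(.fold_grid_cache[[key]])) return(.fold_grid_cache[[key]])
  grid <- expand.grid(a = 6:8, s1 = 1:3, d = c(0L, 3L, 4L), dl = 4:14,
                      s2 = 0:2, v = 3:9, t = 4:5, tl = 5:9,
                      KEEP.OUT.ATTRS = FALSE)
  # D region length: stem-loop-stem, or a bare replacement loop when d = 0
  grid$dreg <- ifelse(grid$d == 0L, grid$dl, 2L * grid$d + grid$dl)
  total <- 2L * grid$a + grid$s1 + grid$dreg + grid$s2 + 17L + grid$v +
    2L * grid$t + grid$tl
  grid <- grid[total == n, , drop = FALSE]
  grid$p <- grid$a + grid$s1 + 1L             # start of the D region
  grid$q <- grid$p + grid$dreg + grid$s2      # start of the anticodon stem
  grid$r <- grid$q + 17L + grid$v             # start of the T stem
  .fold_grid_cache[[key]] <- grid
  grid
}

#' Fold a candidate tRNA sequence into a cloverleaf
#'
#' Constrained combinatorial search (not free-energy minimization): the
#' acceptor stem is 6-8 bp anchored at the sequence ends, the D arm has a
#' 3-4 bp stem or is replaced by a loop (the D-arm replacement loop seen in
#' some mitochondrial tRNAs, e.g. tRNA-Cys), the anticodon arm is a 5 bp
#' stem with a 7 nt loop, and the T arm a 4-5 bp stem. Each stem tolerates
#' at most one G-U wobble or mismatch. The best-scoring architecture (most
#' paired bases) wins; ties resolve to the first in deterministic
#' enumeration order. The anticodon is the center of the anticodon loop.
#'
#' @param sequence 55-95 nt candidate sequence (sense strand of the tRNA).
#' @return list of class `trna_structure` with `success`, `arms`,
#'   `d_arm_replacement_loop`, `anticodon`, `layout`, `score`; on failure
#'   `success = FALSE` (no exception).
#' @export
fold_trna <- function(sequence) {
  sequence <- normalize_dna(sequence)
  n <- nchar(sequence)
  if (n < 55L || n > 95L)
    stop("fold_trna expects 55-95 nt, got ", n)
  x <- strsplit(sequence, "")[[1]]
  grid <- .fold_grid(n)
  # acceptor depends only on a; anticodon arm only on q: pre-check both
  acc_ok <- vapply(6:8, function(a) .stem_ok(x, 1L, n - a + 1L, a),
                   logical(1))
  grid <- grid[acc_ok[grid$a - 5L], , drop = FALSE]
  if (nrow(grid)) {
    qs <- sort(unique(grid$q))
    q_ok <- vapply(qs, function(q) .stem_ok(x, q, q + 12L, 5L), logical(1))
    grid <- grid[q_ok[match(grid$q, qs)], , drop = FALSE]
  }
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- g$p; q <- g$q; r <- g$r
    if (g$d > 0L && !.stem_ok(x, p, p + g$d + g$dl, g$d)) next
    if (!.stem_ok(x, r, r + g$t + g$tl, g$t)) next
    score <- .stem_score(x, 1L, n - g$a + 1L, g$a) +
      (if (g$d > 0L) .stem_score(x, p, p + g$d + g$dl, g$d) else 0L) +
      .stem_score(x, q, q + 12L, 5L) +
      .stem_score(x, r, r + g$t + g$tl, g$t)
    if (is.null(best) || score > best$score) {
      best <- list(score = score, g = g, q = q)
    }
  }
  if (is.null(best)) {
    return(structure(list(success = FALSE, arms = character(0),
                          d_arm_replacement_loop = NA, anticodon = NA_character_,
                          layout = NULL, score = 0L),
                     class = "trna_structure"))
  }
  g <- best$g
  anticodon <- paste0(x[best$q + 7:9], collapse = "")
  arms <- c("acceptor", if (g$d > 0L) "D", "anticodon", "T")
  structure(list(success = TRUE, arms = arms,
                 d_arm_replacement_loop = g$d == 0L,
                 anticodon = anticodon,
                 layout = as.list(g), score = best$score),
            class = "trna_structure")
}

#' @export
print.trna_structure <- function(x, ...) {
  if (!x$success) cat("<trna_structure> fold failure\n")
  else cat(sprintf("<trna_structure> arms: %s%s | anticodon %s | score %d\n",
                   paste(x$arms, collapse = "+"),
                   if (x$d_arm_replacement_loop) " (D-arm replacement loop)"
                   else "", x$anticodon, x$score))
  invisible(x)
}

# ---- O_L-like stem-loop scan ----------------------------------------------

#' Scan for O_L-like stem-loop structures
#'
#' Searches the region between tRNA-Asn and tRNA-Cys (the canonical
#' light-strand replication origin locus; a caller-specified window
#' overrides) for hairpins with stem >= `min_stem` and loop length in
#' \[3, 20\]. Each hit is reported with its overlap into flanking tRNA
#' annotations and whether the heavy-strand `GGC` elongation motif (the
#' complement of the 3'-GCC-5' template identified as the light-strand
#' elongation point) occurs within the hairpin span.
#'
#' @param genome a `mito_genome`.
#' @param window optional `c(start, end)` 0-based half-open window; default
#'   spans from the start of tRNA-Asn to the end of tRNA-Cys.
#' @param min_stem minimum stem length (default 5).
#' @return data frame of class `stem_loop_hits` (possibly empty): position,
#'   stem_length, loop_length, tRNA overlaps, motif flag.
#' @export
scan_ol_stemloop <- function(genome, window = NULL, min_stem = 5L) {
  ann <- genome$annotations
  if (is.null(window)) {
    i_n <- which(ann$name == "trnN"); i_c <- which(ann$name == "trnC")
    if (!length(i_n) || !length(i_c)) {
      warning("no tRNA-Asn/tRNA-Cys annotations and no window given")
      return(.empty_stemloops())
    }
    window <- c(ann$start[i_n[1L]], ann$end[i_c[1L]])
  }
  if (window[2L] <= window[1L]) {
    warning("empty scan window")
    return(.empty_stemloops())
  }
  s <- genome_subseq(genome, window[1L], window[2L])
  x <- strsplit(s, "")[[1]]
  n <- length(x)
  hits <- list()
  pair1 <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  # for every candidate loop, grow the stem outward to its maximal length
  for (u in seq_len(n)) {
    for (l in 3:20) {
      i <- u - 1L; j <- u + l
      s <- 0L
      while (i >= 1L && j <= n && pair1(x[i], x[j])) {
        s <- s + 1L; i <- i - 1L; j <- j + 1L
      }
      if (s >= min_stem) {
        hits[[length(hits) + 1L]] <-
          data.frame(position = window[1L] + (u - s) - 1L, stem_length = s,
                     loop_length = l,
                     span_end = window[1L] + (u + l + s) - 1L)
      }
    }
  }
  if (!length(hits)) return(.empty_stemloops())
  h <- do.call(rbind, hits)
  # keep maximal hits only: drop a hit whose span is inside another's
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    inside <- h$position <= h$position[i] & h$span_end >= h$span_end[i] &
      (h$position < h$position[i] | h$span_end > h$span_end[i])
    if (any(inside & keep)) keep[i] <- FALSE
  }
  h <- h[keep, , drop = FALSE]
  trna <- ann[ann$kind == "tRNA", , drop = FALSE]
  ol <- function(a1, a2, b1, b2) pmax(0L, pmin(a2, b2) - pmax(a1, b1))
  up <- integer(nrow(h)); down <- integer(nrow(h)); motif <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    ovl <- ol(h$position[i], h$span_end[i], trna$start, trna$end)
    before <- trna$start < h$position[i]
    up[i] <- if (any(ovl > 0 & before)) max(ovl[ovl > 0 & before]) else 0L
    down[i] <- if (any(ovl > 0 & !before)) max(ovl[ovl > 0 & !before]) else 0L
    motif[i] <- grepl("GGC",
                      genome_subseq(genome, h$position[i], h$span_end[i]),
                      fixed = TRUE)
  }
  out <- data.frame(position = h$position, stem_length = h$stem_length,
                    loop_length = h$loop_length,
                    overlap_upstream_trna = up, overlap_downstream_trna = down,
                    elongation_motif_present = motif)
  class(out) <- c("stem_loop_hits", "data.frame")
  out
}

.empty_stemloops <- function() {
  out <- data.frame(position = integer(0), stem_length = integer(0),
                    loop_length = integer(0),
                    overlap_upstream_trna = integer(0),
                    overlap_downstream_trna = integer(0),
                    elongation_motif_present = logical(0))
  class(out) <- c("stem_loop_hits", "data.frame")
  out
}

# ---- structural site-class summary ----------------------------------------

#' Summarize flagged sites per structural class
#'
#' Given an externally supplied table of amino-acid sites classified by
#' protein structural context (`transmembrane`, `loop`, `other`) with a
#' flag column (e.g. sites under putative positive selection), reports
#' per-class counts and the percentage of all flagged sites falling in each
#' class, rounded to integer percent.
#'
#' @param site_table data frame with columns `site`, `class`, `flagged`.
#' @return list with `counts` (per class: total and flagged) and
#'   `pct_of_flagged` (named integer percents).
#' @export
site_class_fraction <- function(site_table) {
  if (!nrow(site_table)) stop("empty site table")
  need <- c("site", "class", "flagged")
  miss <- setdiff(need, names(site_table))
  if (length(miss)) stop("site table missing columns: ",
                         paste(miss, collapse = ", "))
  classes <- c("transmembrane", "loop", "other")
  bad <- setdiff(unique(site_table$class), classes)
  if (length(bad)) stop("unknown site class: ", paste(bad, collapse = ", "))
  total_flagged <- sum(site_table$flagged)
  counts <- do.call(rbind, lapply(classes, function(cl) {
    inc <- site_table$class == cl
    data.frame(class = cl, n_sites = sum(inc),
               n_flagged = sum(site_table$flagged[inc]))
  }))
  pct <- if (total_flagged == 0L) setNames(rep(0L, length(classes)), classes)
  else setNames(as.integer(round(100 * counts$n_flagged / total_flagged)),
                classes)
  list(counts = counts, pct_of_flagged = pct, n_flagged = total_flagged)
}

# ---- aggregate QC ----------------------------------------------------------

#' Validate mitochondrial hallmark features of a genome
#'
#' Runs strand composition, CDS translation under the vertebrate
#' mitochondrial code, and cloverleaf folding of every annotated tRNA; also
#' reports O_L-like stem-loops in the canonical window when locatable.
#' Pass requires clean translation (no internal stops) and a successful
#' fold for every non-pseudo tRNA.
#'
#' @param genome an annotated `mito_genome`.
#' @return list of class `genome_qc_report` with `composition`,
#'   `translation`, `trna` (per-gene fold results), `stem_loops`, `pass`.
#' @export
genome_qc <- function(genome) {
  comp <- base_composition(genome)
  trans <- translate_cds(genome)
  ann <- genome$annotations
  trna_ann <- ann[ann$kind == "tRNA" & !ann$pseudo, , drop = FALSE]
  folds <- lapply(seq_len(nrow(trna_ann)), function(i)
    fold_trna(gene_sequence(genome, trna_ann$name[i], trna_ann$copy_index[i])))
  names(folds) <- paste0(trna_ann$name,
                         ifelse(trna_ann$copy_index > 1L,
                                paste0("#", trna_ann$copy_index), ""))
  sl <- tryCatch(suppressWarnings(scan_ol_stemloop(genome)),
                 error = function(e) .empty_stemloops())
  trna_pass <- all(vapply(folds, function(f) f$success, logical(1)))
  structure(list(composition = comp, translation = trans, trna = folds,
                 stem_loops = sl,
                 pass = trans$pass && trna_pass),
            class = "genome_qc_report")
}

#' @export
print.genome_qc_report <- function(x, ...) {
  nfail <- sum(!vapply(x$trna, function(f) f$success, logical(1)))
  cat(sprintf(paste0("<genome_qc_report> %s | guanine %.1f%% | translation ",
                     "%s | %d/%d tRNAs fold | %d stem-loop hit(s)\n"),
              if (x$pass) "PASS" else "FAIL",
              x$composition$guanine_pct_heavy,
              if (x$translation$pass) "clean" else "internal stops",
              length(x$trna) - nfail, length(x$trna), nrow(x$stem_loops)))
  invisible(x)
}
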