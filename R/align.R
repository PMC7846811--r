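#' @importFrom Biostrings DNAString DNAStringSet pairwiseAlignment nmatch
#'   nmismatch nindel writeXStringSet readDNAStringSet
NULL

.tmp_fasta <- function(seqs, prefix = "mt") {
  path <- tempfile(prefix, fileext = ".fa")
  write_fasta(seqs, path)
  path
}

.as_named_seqs <- function(x) {
  if (inherits(x, "mito_genome")) return(setNames(x$sequence, x$id))
  if (inherits(x, "read_set") || is.data.frame(x))
    return(setNames(x$sequence, x$id))
  stopifnot(is.character(x), !is.null(names(x)))
  x
}

# ---- exact single-pair identity (Biostrings engine) ------------------------

#' Alignment identity of a read against a reference
#'
#' Best local alignment of the read, in either orientation, against the
#' reference (doubled when circular so reads spanning the origin align
#' contiguously). Identity is gap-compressed:
#' `matches / (matches + mismatches + gap_openings)` — a gap of any length
#' counts once, limiting the influence of the long unread stretches typical
#' of single-molecule reads. The span is reported on the unwrapped
#' reference modulo its length.
#'
#' @param read read sequence (character) or single-row [read_set()].
#' @param reference a `mito_genome` or named character sequence.
#' @param circular treat the reference as circular?
#' @return list: `identity`, `span_start` (0-based), `span_end` (half-open;
#'   may exceed the reference length when the alignment wraps), `strand`
#'   (`+`/`-`), `score`.
#' @export
align_identity <- function(read, reference, circular = TRUE) {
  if (is.data.frame(read)) read <- read$sequence[1L]
  ref <- .as_named_seqs(reference)[[1L]]
  L <- nchar(ref)
  if (!nchar(read) || !L) stop("empty sequence")
  subj <- Biostrings::DNAString(if (circular) paste0(ref, ref) else ref)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  best <- NULL
  for (strand in c("+", "-")) {
    qry <- if (strand == "+") read else revcomp(read)
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(qry), subj,
                                        type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    if (is.null(best) || Biostrings::score(pa) > best$score)
      best <- list(pa = pa, strand = strand, score = Biostrings::score(pa))
  }
  pa <- best$pa
  nm <- Biostrings::nmatch(pa)
  nx <- Biostrings::nmismatch(pa)
  ind <- Biostrings::nindel(pa)
  gapo <- sum(Biostrings::insertion(ind)[, "Length"]) +
    sum(Biostrings::deletion(ind)[, "Length"])
  denom <- nm + nx + gapo
  if (denom == 0)
    return(list(identity = 0, span_start = NA_integer_,
                span_end = NA_integer_, strand = best$strand, score = 0))
  s <- BiocGenerics::start(Biostrings::subject(pa))
  e <- BiocGenerics::end(Biostrings::subject(pa))
  s0 <- (s - 1L) %% L
  list(identity = nm / denom,
       span_start = s0, span_end = s0 + (e - s + 1L),
       strand = best$strand, score = best$score)
}

# ---- batch identity via minimap2 -------------------------------------------

.minimap2_available <- function() nzchar(Sys.which("minimap2"))

# run minimap2 and parse PAF; returns one best record per query
.mm2_best <- function(query_path, ref_path, preset) {
  if (!.minimap2_available())
    stop("minimap2 not found on PATH; batch alignment requires it ",
         "(use align_identity() for single reads)")
  out <- tempfile("mm2", fileext = ".paf")
  status <- system2("minimap2",
                    c("-cx", preset, "-t", "1", "--secondary=no", "-N", "1",
                      shQuote(ref_path), shQuote(query_path)),
                    stdout = out, stderr = FALSE)
  if (status != 0) stop("minimap2 failed with status ", status)
  lines <- readLines(out, warn = FALSE)
  unlink(out)
  if (!length(lines))
    return(data.frame(qname = character(0), identity = numeric(0),
                      tstart = integer(0), tend = integer(0),
                      strand = character(0), nmatch = integer(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  de <- vapply(f, function(x) {
    tag <- grep("^de:f:", x, value = TRUE)
    if (length(tag)) as.numeric(sub("^de:f:", "", tag[1L])) else NA_real_
  }, numeric(1))
  df <- data.frame(qname = vapply(f, `[`, character(1), 1L),
                   strand = vapply(f, `[`, character(1), 5L),
                   tstart = as.integer(vapply(f, `[`, character(1), 8L)),
                   tend = as.integer(vapply(f, `[`, character(1), 9L)),
                   nmatch = as.integer(vapply(f, `[`, character(1), 10L)),
                   identity = 1 - de,
                   stringsAsFactors = FALSE)
  df <- df[order(df$qname, -df$nmatch, df$tstart), , drop = FALSE]
  df[!duplicated(df$qname), , drop = FALSE]
}

# gap-compressed identity of many sequences against one reference
.batch_identity <- function(seqs, reference, circular = TRUE,
                            preset = "map-ont") {
  seqs <- .as_named_seqs(seqs)
  refseq <- .as_named_seqs(reference)
  L <- nchar(refseq[[1L]])
  ref_use <- if (circular) setNames(paste0(refseq, refseq), names(refseq))
             else refseq
  qp <- .tmp_fasta(seqs, "qry")
  rp <- .tmp_fasta(ref_use, "ref")
  on.exit(unlink(c(qp, rp)))
  hits <- .mm2_best(qp, rp, preset)
  i <- match(names(seqs), hits$qname)
  idn <- ifelse(is.na(i), 0, hits$identity[i])
  idn[is.na(idn)] <- 0
  out <- data.frame(id = names(seqs),
                    identity = idn,
                    span_start = ifelse(is.na(i), NA_integer_,
                                        hits$tstart[i] %% L),
                    strand = ifelse(is.na(i), NA_character_, hits$strand[i]),
                    stringsAsFactors = FALSE)
  out$span_end <- ifelse(is.na(i), NA_integer_,
                         out$span_start + (hits$tend[i] - hits$tstart[i]))
  out
}

# ---- small-set progressive alignment ---------------------------------------

.seq_profile <- function(rows) {
  # rows: character matrix (sequences x positions) possibly with gaps
  n <- nrow(rows)
  prof <- matrix(0, 4L, ncol(rows))
  rownames(prof) <- c("A", "C", "G", "T")
  for (b in rownames(prof)) prof[b, ] <- colSums(rows == b) / n
  prof
}

.merge_alignments <- function(ma, mb, match, mismatch, gap_open, gap_extend) {
  res <- profile_align_cpp(.seq_profile(ma), .seq_profile(mb),
                           match, mismatch, gap_open, gap_extend)
  ncol_out <- length(res$ai)
  take <- function(m, idx) {
    out <- matrix("-", nrow(m), ncol_out, dimnames = list(rownames(m), NULL))
    nz <- idx > 0L
    out[, nz] <- m[, idx[nz], drop = FALSE]
    out
  }
  merged <- rbind(take(ma, res$ai), take(mb, res$bi))
  attr(merged, "score") <- res$score
  merged
}

#' Progressive multiple alignment for small sequence sets
#'
#' Pairwise profile alignment (global Needleman-Wunsch with affine gaps)
#' guided by a UPGMA tree built from k-mer frequency distances, merging
#' profiles progressively. Deterministic. Optional anchor intervals are
#' held gapless: the sequences are cut at the anchors (which must have
#' identical lengths across sequences) and only the intervening segments
#' are aligned — a stand-in for structure-guided manual adjustments such
#' as aligning tRNA genes by their cloverleaf arms. Intended for <= 20
#' sequences of moderate length; externally produced alignments can always
#' be loaded with [read_alignment()] instead.
#'
#' @param sequences named character vector (>= 2, non-empty).
#' @param anchors optional list, one `n x 2` matrix of 0-based half-open
#'   anchor intervals per sequence (same names and anchor count as
#'   `sequences`).
#' @param match,mismatch,gap_open,gap_extend scoring (a gap of length k
#'   costs `gap_open + k * gap_extend`).
#' @return a [dna_alignment()]; attribute `score` holds the final merge
#'   score.
#' @export
align_small_set <- function(sequences, anchors = NULL, match = 1,
                            mismatch = -1, gap_open = -4, gap_extend = -1) {
  sequences <- .as_named_seqs(sequences)
  if (length(sequences) < 2L) stop("need >= 2 sequences")
  if (any(!nchar(sequences))) stop("empty sequence in input")
  if (length(sequences) > 20L)
    warning("align_small_set is intended for <= 20 sequences")
  if (!is.null(anchors)) return(.align_with_anchors(sequences, anchors, match,
                                                    mismatch, gap_open,
                                                    gap_extend))
  if (length(unique(sequences)) == 1L)
    return(dna_alignment(sequences))
  w <- min(4L, min(nchar(sequences)))
  freq <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(sequences), width = w)
  freq <- freq / pmax(1, rowSums(freq))
  hc <- hclust(dist(freq), method = "average")
  mats <- lapply(sequences, function(s)
    matrix(strsplit(s, "")[[1L]], nrow = 1L))
  for (i in seq_along(mats)) rownames(mats[[i]]) <- names(sequences)[i]
  nodes <- vector("list", nrow(hc$merge))
  score <- NA_real_
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) mats[[-j]] else nodes[[j]]
    merged <- .merge_alignments(pick(hc$merge[k, 1L]), pick(hc$merge[k, 2L]),
                                match, mismatch, gap_open, gap_extend)
    score <- attr(merged, "score")
    nodes[[k]] <- merged
  }
  final <- nodes[[nrow(hc$merge)]]
  final <- final[match(names(sequences), rownames(final)), , drop = FALSE]
  out <- dna_alignment(setNames(apply(final, 1L, paste0, collapse = ""),
                                rownames(final)))
  attr(out, "score") <- score
  out
}

.align_segment_set <- function(sg, match, mismatch, gap_open, gap_extend) {
  # align one inter-anchor segment set; empty segments become all-gap rows
  if (all(!nchar(sg))) return(setNames(rep("", length(sg)), names(sg)))
  if (length(unique(sg)) == 1L) return(sg)
  nonempty <- sg[nchar(sg) > 0]
  sub <- if (length(nonempty) >= 2L)
    unclass(align_small_set(nonempty, match = match, mismatch = mismatch,
                            gap_open = gap_open, gap_extend = gap_extend))
  else nonempty
  out <- setNames(rep(strrep("-", nchar(sub[[1L]])), length(sg)), names(sg))
  out[names(sub)] <- sub
  out
}

.align_with_anchors <- function(sequences, anchors, match, mismatch,
                                gap_open, gap_extend) {
  stopifnot(is.list(anchors), setequal(names(anchors), names(sequences)))
  nm_all <- names(sequences)
  na <- unique(vapply(anchors[nm_all], nrow, integer(1)))
  if (length(na) != 1L) stop("all sequences need the same number of anchors")
  for (i in seq_len(na)) {
    lens <- vapply(nm_all, function(nm)
      anchors[[nm]][i, 2L] - anchors[[nm]][i, 1L], numeric(1))
    if (length(unique(lens)) != 1L)
      stop("anchor ", i, " has unequal lengths across sequences")
  }
  parts <- setNames(character(length(nm_all)), nm_all)
  for (i in seq_len(na + 1L)) {
    seg <- vapply(nm_all, function(nm) {
      a <- anchors[[nm]]
      from <- if (i == 1L) 0L else a[i - 1L, 2L]
      to <- if (i <= na) a[i, 1L] else nchar(sequences[[nm]])
      substr(sequences[[nm]], from + 1L, to)
    }, character(1))
    parts <- paste0(parts, .align_segment_set(seg, match, mismatch, gap_open,
                                              gap_extend)[nm_all])
    names(parts) <- nm_all
    if (i <= na) {
      anc <- vapply(nm_all, function(nm)
        substr(sequences[[nm]], anchors[[nm]][i, 1L] + 1L,
               anchors[[nm]][i, 2L]), character(1))
      parts <- setNames(paste0(parts, anc[nm_all]), nm_all)
    }
  }
  dna_alignment(parts)
}

#' Pairwise global alignment with affine gaps
#'
#' Thin two-sequence wrapper around the progressive aligner's scoring
#' engine; useful for checking scores and spot alignments.
#'
#' @param a,b sequences.
#' @inheritParams align_small_set
#' @return list: `score`, `alignment` (a 2-row [dna_alignment()]).
#' @export
nw_align <- function(a, b, match = 1, mismatch = -1, gap_open = -4,
                     gap_extend = -1) {
  ma <- matrix(strsplit(a, "")[[1L]], nrow = 1L, dimnames = list("a", NULL))
  mb <- matrix(strsplit(b, "")[[1L]], nrow = 1L, dimnames = list("b", NULL))
  merged <- .merge_alignments(ma, mb, match, mismatch, gap_open, gap_extend)
  list(score = attr(merged, "score"),
       alignment = dna_alignment(setNames(apply(merged, 1L, paste0,
                                                collapse = ""),
                                          rownames(merged))))
}
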