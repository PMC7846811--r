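#' Concatenation rules for multi-gene parsimony matrices
#'
#' Encodes the fixed editing rules applied when protein-coding genes are
#' concatenated across genomes: terminal overlaps of bicistronic gene
#' pairs are excluded (the last 96 nt of ATP8, overlapping ATP6, and the
#' last 7 nt of ND4L, overlapping ND4), and length-difference gaps may be
#' inserted into designated rows of a gene at stated nucleotide offsets
#' (e.g. a Cytb allele 7 codons longer than the rest requires 15 gap
#' positions after nt 9 and 6 gap positions after nt 873 in all shorter
#' rows).
#'
#' @param exclude_last named integer vector: gene -> number of terminal
#'   columns to drop.
#' @param gap_insertions list of `list(gene=, rows=, after_nt=, n=)`;
#'   `after_nt` refers to the row's original (ungapped) coordinates.
#' @return list of class `concat_rules`.
#' @export
concatenation_rules <- function(exclude_last = c(ATP8 = 96L, ND4L = 7L),
                                gap_insertions = list()) {
  structure(list(exclude_last = exclude_last,
                 gap_insertions = gap_insertions),
            class = "concat_rules")
}

.insert_gaps <- function(seq, after_nt, n) {
  # after_nt / n vectors, positions in original coordinates, applied left
  # to right with cumulative offsets
  o <- order(after_nt)
  after_nt <- after_nt[o]; n <- n[o]
  off <- 0L
  for (i in seq_along(after_nt)) {
    at <- after_nt[i] + off
    seq <- paste0(substr(seq, 1L, at), strrep("-", n[i]),
                  substr(seq, at + 1L, nchar(seq)))
    off <- off + n[i]
  }
  seq
}

#' Build a concatenated gene alignment across genomes
#'
#' Extracts each requested gene (sense strand) from every genome, aligns
#' the per-gene sequence set (rows of equal length stack directly;
#' otherwise [align_small_set()] is used unless gap-insertion rules already
#' equalize them), applies the exclusion and gap rules, and concatenates
#' partitions in the given gene order. The per-column source gene is kept
#' as the `site_genes` attribute.
#'
#' @param genomes list of annotated `mito_genome`s (named by id if the
#'   list is unnamed).
#' @param gene_set gene symbols, in concatenation order.
#' @param rules a [concatenation_rules()].
#' @return a [dna_alignment()] with attribute `site_genes`.
#' @export
build_concatenation <- function(genomes, gene_set,
                                rules = concatenation_rules()) {
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, function(g) g$id, character(1))
  parts <- list()
  site_genes <- character(0)
  for (gene in gene_set) {
    seqs <- vapply(names(genomes), function(nm) {
      tryCatch(gene_sequence(genomes[[nm]], gene),
               error = function(e)
                 stop("genome '", nm, "' lacks gene '", gene, "'",
                      call. = FALSE))
    }, character(1))
    for (gi in rules$gap_insertions) {
      if (gi$gene != gene) next
      rows <- intersect(gi$rows, names(seqs))
      for (r in rows) seqs[r] <- .insert_gaps(seqs[r], gi$after_nt, gi$n)
    }
    if (length(unique(nchar(seqs))) > 1L) {
      aln <- align_small_set(seqs)
      seqs <- setNames(unclass(aln), names(aln))
    }
    width <- nchar(seqs[[1L]])
    drop <- if (gene %in% names(rules$exclude_last))
      rules$exclude_last[[gene]] else NA_integer_
    if (!is.na(drop) && drop > 0L) {
      if (drop >= width) stop("exclusion rule drops all of ", gene)
      seqs <- substr(seqs, 1L, width - drop)
      width <- width - drop
    }
    parts[[gene]] <- seqs
    site_genes <- c(site_genes, rep(gene, width))
  }
  rows <- setNames(rep("", length(genomes)), names(genomes))
  for (gene in gene_set) rows <- paste0(rows, parts[[gene]][names(genomes)])
  out <- dna_alignment(setNames(rows, names(genomes)))
  attr(out, "site_genes") <- site_genes
  out
}
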