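#' Construct a mitochondrial genome object
#'
#' A `mito_genome` bundles a (usually circular) nucleotide sequence with its
#' gene annotations and an optional molecule label. Coordinates are held
#' internally 0-based half-open; circular features may have `end` exceeding
#' the sequence length by the wrapped amount (they are "unwrapped" across the
#' origin) and accessors return the concatenated subsequence.
#'
#' @param id character label.
#' @param sequence nucleotide string over `A,C,G,T,N` (case-insensitive;
#'   `U` is mapped to `T`).
#' @param circular logical; is the molecule circular?
#' @param annotations a data frame of gene annotations as produced by
#'   [gene_annotation()], or `NULL`.
#' @param molecule_tag optional molecule label, one of `"M1"`, `"M2"`,
#'   `"other"`.
#' @return an object of class `mito_genome`: a list with elements `id`,
#'   `sequence`, `circular`, `annotations`, `molecule_tag`.
#' @export
mito_genome <- function(id, sequence, circular = TRUE, annotations = NULL,
                        molecule_tag = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- normalize_dna(sequence)
  if (nchar(sequence) == 0L) stop("genome sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence))
    stop("genome sequence contains characters outside {A,C,G,T,N}")
  if (!is.null(molecule_tag))
    molecule_tag <- match.arg(molecule_tag, c("M1", "M2", "other"))
  g <- structure(list(id = id, sequence = sequence,
                      circular = isTRUE(circular),
                      annotations = NULL, molecule_tag = molecule_tag),
                 class = "mito_genome")
  if (!is.null(annotations)) g <- set_annotations(g, annotations)
  g
}

normalize_dna <- function(x) {
  x <- toupper(gsub("[\r\n \t]", "", x))
  gsub("U", "T", x, fixed = TRUE)
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %d bp, %s%s, %d annotations\n",
              x$id, genome_length(x),
              if (x$circular) "circular" else "linear",
              if (is.null(x$molecule_tag)) "" else paste0(", ", x$molecule_tag),
              if (is.null(x$annotations)) 0L else nrow(x$annotations)))
  invisible(x)
}

#' Genome length in bases
#' @param genome a `mito_genome`.
#' @return integer length.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' Build a gene annotation table
#'
#' Internal coordinates are 0-based half-open (`start < end`); for circular
#' features unwrapped across the origin, `end` may exceed the genome length.
#'
#' @param name gene symbols (e.g. `ND5`, `trnH`, `NC2`).
#' @param kind one of `CDS`, `tRNA`, `rRNA`, `NC` per feature.
#' @param start,end integer 0-based half-open coordinates.
#' @param strand `heavy` or `light` per feature.
#' @param copy_index integer >= 1, distinguishing duplicate copies.
#' @param pseudo logical, pseudogene flag (default `FALSE`).
#' @return a data frame with one row per feature.
#' @export
gene_annotation <- function(name, kind, start, end, strand = "heavy",
                            copy_index = 1L, pseudo = FALSE) {
  ann <- data.frame(name = as.character(name), kind = as.character(kind),
                    start = as.integer(start), end = as.integer(end),
                    strand = as.character(strand),
                    copy_index = as.integer(copy_index),
                    pseudo = as.logical(pseudo),
                    stringsAsFactors = FALSE)
  validate_annotations(ann)
  ann
}

validate_annotations <- function(ann, genome = NULL) {
  stopifnot(is.data.frame(ann))
  need <- c("name", "kind", "start", "end", "strand", "copy_index")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(ann$kind %in% c("CDS", "tRNA", "rRNA", "NC")))
    stop("unknown annotation kind: ",
         paste(unique(setdiff(ann$kind, c("CDS", "tRNA", "rRNA", "NC"))),
               collapse = ", "))
  if (!all(ann$strand %in% c("heavy", "light")))
    stop("unknown strand token: ",
         paste(unique(setdiff(ann$strand, c("heavy", "light"))), collapse = ", "))
  if (any(ann$start < 0L)) stop("annotation start < 0")
  if (any(ann$start >= ann$end)) stop("annotation start >= end after unwrapping")
  if (any(ann$kind == "CDS" & (ann$end - ann$start) < 3L))
    stop("CDS shorter than one codon")
  key <- paste(ann$name, ann$copy_index)
  if (anyDuplicated(key))
    stop("duplicate (name, copy_index): ", key[duplicated(key)][1L])
  if (!is.null(genome)) {
    L <- genome_length(genome)
    if (any(ann$start >= L)) stop("annotation start beyond genome length")
    lim <- if (genome$circular) 2L * L else L
    if (any(ann$end > lim)) stop("annotation end beyond genome bounds")
  }
  invisible(ann)
}

#' Attach annotations to a genome (with validation)
#' @param genome a `mito_genome`.
#' @param ann annotation data frame.
#' @return the genome with annotations set.
#' @export
set_annotations <- function(genome, ann) {
  if (!"pseudo" %in% names(ann)) ann$pseudo <- FALSE
  validate_annotations(ann, genome)
  genome$annotations <- ann[order(ann$start), , drop = FALSE]
  rownames(genome$annotations) <- NULL
  genome
}

#' Extract a (possibly origin-wrapping) subsequence
#'
#' @param genome a `mito_genome`.
#' @param start,end 0-based half-open coordinates; `end` may exceed the
#'   genome length for circular genomes (wraps across the origin).
#' @return character subsequence on the heavy strand.
#' @export
genome_subseq <- function(genome, start, end) {
  L <- genome_length(genome)
  stopifnot(start >= 0L, end > start)
  if (end <= L) return(substr(genome$sequence, start + 1L, end))
  if (!genome$circular) stop("interval beyond the end of a linear genome")
  if (end - start > L) stop("interval longer than the genome")
  paste0(substr(genome$sequence, start + 1L, L),
         substr(genome$sequence, 1L, end - L))
}

#' Extract the encoded (sense-strand) sequence of an annotated feature
#'
#' Heavy-strand features are returned as-is; light-strand features are
#' reverse-complemented so the result reads 5'->3' on the encoded strand.
#'
#' @param genome a `mito_genome`.
#' @param name gene symbol.
#' @param copy_index which copy (default 1).
#' @return character sequence.
#' @export
gene_sequence <- function(genome, name, copy_index = 1L) {
  ann <- genome$annotations
  i <- which(ann$name == name & ann$copy_index == copy_index)
  if (length(i) != 1L)
    stop("gene not found (or ambiguous): ", name, " copy ", copy_index,
         " in ", genome$id)
  s <- genome_subseq(genome, ann$start[i], ann$end[i])
  if (ann$strand[i] == "light") s <- revcomp(s) else s
}

#' Reverse complement of a DNA string
#' @param x character DNA string.
#' @return reverse complement (N preserved).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# ---- read sets -------------------------------------------------------------

#' Construct a read set
#'
#' A `read_set` is a data frame (one row per read) with columns `id`,
#' `sequence`, `quality`, `platform` (`short_pe` or `long`), `mate_id` and
#' `true_origin` (`M1`/`M2`, synthetic reads only; `NA` otherwise).
#'
#' @param id,sequence,quality,platform,mate_id,true_origin per-read vectors;
#'   `quality`, `mate_id`, `true_origin` may be `NA`.
#' @return a data frame of class `read_set`.
#' @export
read_set <- function(id, sequence, quality = NA_character_,
                     platform = "long", mate_id = NA_character_,
                     true_origin = NA_character_) {
  if (!length(id)) {
    rs <- data.frame(id = character(0), sequence = character(0),
                     quality = character(0), platform = character(0),
                     mate_id = character(0), true_origin = character(0),
                     stringsAsFactors = FALSE)
    class(rs) <- c("read_set", "data.frame")
    return(rs)
  }
  rs <- data.frame(id = as.character(id), sequence = toupper(as.character(sequence)),
                   quality = as.character(quality),
                   platform = as.character(platform),
                   mate_id = as.character(mate_id),
                   true_origin = as.character(true_origin),
                   stringsAsFactors = FALSE)
  validate_read_set(rs)
  class(rs) <- c("read_set", "data.frame")
  rs
}

validate_read_set <- function(rs) {
  if (anyDuplicated(rs$id)) stop("read ids must be unique")
  if (!all(rs$platform %in% c("short_pe", "long")))
    stop("platform must be short_pe or long")
  ok <- is.na(rs$quality) | nchar(rs$quality) == nchar(rs$sequence)
  if (!all(ok)) stop("quality length differs from sequence length for read ",
                     rs$id[!ok][1L])
  paired <- !is.na(rs$mate_id)
  if (any(paired)) {
    back <- rs$mate_id[match(rs$mate_id[paired], rs$id)]
    if (any(is.na(back)) || any(back != rs$id[paired]))
      stop("mate pairs must be reciprocal")
  }
  invisible(rs)
}

#' Combine read sets
#' @param ... `read_set` objects.
#' @return a single `read_set`.
#' @export
bind_read_sets <- function(...) {
  rs <- do.call(rbind, lapply(list(...), as.data.frame))
  validate_read_set(rs)
  class(rs) <- c("read_set", "data.frame")
  rs
}

# ---- multiple alignments ---------------------------------------------------

#' Construct a multiple alignment
#'
#' @param rows named character vector of equal-length gapped sequences over
#'   `A,C,G,T,N,-`.
#' @return object of class `dna_alignment`: the named vector with attribute
#'   `site_count`.
#' @export
dna_alignment <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 2L, !is.null(names(rows)))
  rows <- toupper(rows)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows must all have the same length")
  if (any(grepl("[^ACGTN-]", rows)))
    stop("alignment rows must be over {A,C,G,T,N,-}")
  if (anyDuplicated(names(rows))) stop("alignment row names must be unique")
  structure(rows, site_count = w, class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment> %d rows x %d sites\n", length(x),
              attr(x, "site_count")))
  invisible(x)
}

#' Alignment as a character matrix (rows x sites)
#' @param x a `dna_alignment`.
#' @param ... unused.
#' @return character matrix.
#' @export
as.matrix.dna_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(unclass(x), ""))
  rownames(m) <- names(x)
  m
}

#' Build an exclusion mask
#'
#' Half-open intervals of alignment (or sequence) columns to exclude, per
#' row or for all rows (`row = "ALL"`).
#'
#' @param row row names or `"ALL"`.
#' @param start,end 0-based half-open column intervals.
#' @return data frame of class `exclusion_mask`.
#' @export
exclusion_mask <- function(row = character(), start = integer(),
                           end = integer()) {
  m <- data.frame(row = as.character(row), start = as.integer(start),
                  end = as.integer(end), stringsAsFactors = FALSE)
  if (any(m$start < 0L) || any(m$end < m$start))
    stop("mask intervals must be non-negative with start <= end")
  class(m) <- c("exclusion_mask", "data.frame")
  m
}
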