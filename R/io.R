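#' Read a FASTA file
#'
#' Sequences are upper-cased and `U` mapped to `T`. Malformed input (text
#' before the first header, or a header with an empty record) raises a
#' parse error naming the offending line.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("FASTA parse error: empty file ", path)
  hdr <- grepl("^>", lines)
  first <- nonblank[1L]
  if (!hdr[first])
    stop("FASTA parse error at line ", first, ": expected '>' header")
  hpos <- which(hdr)
  for (i in seq_along(hpos)) {
    from <- hpos[i] + 1L
    to <- if (i < length(hpos)) hpos[i + 1L] - 1L else length(lines)
    if (to < from || !any(nzchar(gsub("[ \t]", "", lines[from:to]))))
      stop("FASTA parse error at line ", hpos[i], ": empty record")
  }
  # read without alphabet restriction, then normalize (U -> T, upper case)
  x <- Biostrings::readBStringSet(path)
  out <- normalize_dna_vec(as.character(x))
  bad <- grepl("[^ACGTN-]", out)
  if (any(bad))
    stop("FASTA parse error: unexpected characters in record ",
         names(x)[bad][1L])
  names(out) <- sub("[ \t].*$", "", names(x))
  out
}

normalize_dna_vec <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Write sequences to FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' Qualities are preserved verbatim; the platform tag is supplied by the
#' caller. Truncated records (line count not a multiple of 4) and
#' sequence/quality length mismatches are parse errors.
#'
#' @param path file path.
#' @param platform `"short_pe"` or `"long"` tag applied to all reads.
#' @return a [read_set()].
#' @export
read_fastq <- function(path, platform = "long") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ parse error: truncated record near line ", length(lines))
  if (!length(lines)) {
    return(read_set(character(), character(), platform = character()))
  }
  ids <- lines[seq(1L, length(lines), by = 4L)]
  if (!all(grepl("^@", ids)))
    stop("FASTQ parse error at line ",
         (which(!grepl("^@", ids))[1L] - 1L) * 4L + 1L, ": expected '@' header")
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("FASTQ parse error: sequence/quality length mismatch for record ",
         bad[1L], " (line ", (bad[1L] - 1L) * 4L + 2L, ")")
  read_set(id = sub("^@", "", sub("[ \t].*$", "", ids)),
           sequence = normalize_dna_vec(seqs),
           quality = quals, platform = platform)
}

#' Write a read set to FASTQ
#'
#' Reads without stored qualities are written with a uniform placeholder
#' quality (`I`).
#'
#' @param reads a [read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- ifelse(is.na(reads$quality),
                 vapply(nchar(reads$sequence),
                        function(n) strrep("I", n), character(1L)),
                 reads$quality)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", qual), con)
  invisible(path)
}

# ---- annotation tables -----------------------------------------------------

#' Read a tab-delimited gene annotation table
#'
#' External format is GFF-compatible 1-based inclusive with columns
#' `seqid, name, kind, start, end, strand, copy_index` (optional `pseudo`).
#' Circular features written with `end < start` are unwrapped across the
#' origin, which requires `genome_length`. Internal coordinates are 0-based
#' half-open.
#'
#' @param path file path.
#' @param genome_length genome length in bp; required to unwrap features
#'   crossing the origin.
#' @return annotation data frame (see [gene_annotation()]), with a `seqid`
#'   attribute.
#' @export
read_annotations <- function(path, genome_length = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("seqid", "name", "kind", "start", "end", "strand", "copy_index")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  start0 <- as.integer(tab$start) - 1L
  end0 <- as.integer(tab$end)
  wrap <- end0 <= start0
  if (any(wrap)) {
    if (is.null(genome_length))
      stop("features cross the origin; supply genome_length to unwrap")
    end0[wrap] <- end0[wrap] + as.integer(genome_length)
  }
  ann <- gene_annotation(name = tab$name, kind = tab$kind,
                         start = start0, end = end0, strand = tab$strand,
                         copy_index = tab$copy_index,
                         pseudo = if ("pseudo" %in% names(tab))
                           as.logical(tab$pseudo) else FALSE)
  attr(ann, "seqid") <- tab$seqid[1L]
  ann
}

#' Write an annotation table (1-based inclusive external coordinates)
#'
#' Inverse of [read_annotations()]: features whose internal `end` exceeds
#' `genome_length` are re-wrapped so the external row has `end < start`.
#'
#' @param ann annotation data frame.
#' @param path output path.
#' @param seqid sequence id for the first column.
#' @param genome_length genome length in bp (needed to re-wrap circular
#'   features).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, seqid = "genome",
                              genome_length = NULL) {
  validate_annotations(ann)
  start1 <- ann$start + 1L
  end1 <- ann$end
  if (!is.null(genome_length)) {
    wrap <- end1 > genome_length
    end1[wrap] <- end1[wrap] - as.integer(genome_length)
  }
  out <- data.frame(seqid = seqid, name = ann$name, kind = ann$kind,
                    start = start1, end = end1, strand = ann$strand,
                    copy_index = ann$copy_index,
                    pseudo = if ("pseudo" %in% names(ann)) ann$pseudo else FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- alignments ------------------------------------------------------------

#' Read an aligned FASTA file
#' @param path file path.
#' @return a [dna_alignment()].
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  rows <- toupper(as.character(x))
  names(rows) <- sub("[ \t].*$", "", names(x))
  dna_alignment(rows)
}

#' Write an alignment to FASTA
#' @param aln a [dna_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  x <- Biostrings::DNAStringSet(unclass(aln))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
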