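#' Construct a circular gene order
#'
#' A `gene_order` is a signed circular permutation of gene symbols: one row
#' per element around the circle, with strand carried as sign and duplicate
#' copies distinguished by `copy_index`. Orders are canonicalized by
#' rotation (anchor gene first) and reflection (anchor on the heavy
#' strand), so all downstream reports are rotation- and
#' reflection-invariant.
#'
#' @param name gene symbols in circular order.
#' @param strand `heavy`/`light` per element.
#' @param copy_index integer copy number (default 1).
#' @param kind feature kind (default inferred: `NC*` -> `NC`, else
#'   `gene`).
#' @param pseudo pseudogene flags.
#' @param anchor canonical rotation anchor (default `trnF`, near which
#'   vertebrate mt maps conventionally begin).
#' @return data frame of class `gene_order`.
#' @export
gene_order <- function(name, strand = "heavy", copy_index = 1L, kind = NULL,
                       pseudo = FALSE, anchor = "trnF") {
  if (is.null(kind)) kind <- ifelse(grepl("^NC", name), "NC", "gene")
  go <- data.frame(name = as.character(name), strand = as.character(strand),
                   copy_index = as.integer(copy_index),
                   kind = as.character(kind), pseudo = as.logical(pseudo),
                   stringsAsFactors = FALSE)
  if (!all(go$strand %in% c("heavy", "light")))
    stop("strand must be heavy or light")
  key <- paste(go$name, go$copy_index)
  if (anyDuplicated(key)) stop("duplicate (name, copy_index) in gene order")
  go <- .canonicalize_order(go, anchor)
  attr(go, "anchor") <- anchor
  class(go) <- c("gene_order", "data.frame")
  go
}

.rotate_rows <- function(go, k) {
  n <- nrow(go)
  if (k == 0L) return(go)
  go[c((k + 1L):n, seq_len(k)), , drop = FALSE]
}

.reflect_order <- function(go) {
  go <- go[rev(seq_len(nrow(go))), , drop = FALSE]
  go$strand <- ifelse(go$strand == "heavy", "light", "heavy")
  go
}

.canonicalize_order <- function(go, anchor) {
  i <- which(go$name == anchor & !go$pseudo)
  if (length(i)) {
    i <- i[1L]
    if (go$strand[i] == "light") {
      go <- .reflect_order(go)
      i <- which(go$name == anchor & !go$pseudo)[1L]
    }
    go <- .rotate_rows(go, i - 1L)
  }
  rownames(go) <- NULL
  go
}

#' @export
print.gene_order <- function(x, ...) {
  lab <- paste0(ifelse(x$strand == "light", "-", ""), x$name,
                ifelse(x$copy_index > 1L, paste0("#", x$copy_index), ""),
                ifelse(x$pseudo, "(psi)", ""))
  cat(sprintf("<gene_order> %d elements: %s\n", nrow(x),
              paste(lab, collapse = " ")))
  invisible(x)
}

#' Extract the gene order from an annotated genome
#'
#' Features are sorted by start position around the circle and the
#' canonical rotation applied. Same-strand CDS overlaps beyond the known
#' bicistronic pairs (ATP8/ATP6, ND4L/ND4) raise a warning.
#'
#' @param x an annotated `mito_genome` or an annotation data frame.
#' @param anchor canonical rotation anchor.
#' @return a [gene_order()].
#' @export
extract_order <- function(x, anchor = "trnF") {
  ann <- if (inherits(x, "mito_genome")) x$annotations else x
  if (is.null(ann) || !nrow(ann)) stop("no annotations")
  ann <- ann[order(ann$start), , drop = FALSE]
  cds <- ann[ann$kind == "CDS", , drop = FALSE]
  if (nrow(cds) > 1L) {
    for (i in seq_len(nrow(cds) - 1L)) {
      if (cds$end[i] > cds$start[i + 1L] &&
          cds$strand[i] == cds$strand[i + 1L]) {
        pair <- c(cds$name[i], cds$name[i + 1L])
        if (!(all(pair %in% c("ATP8", "ATP6")) ||
              all(pair %in% c("ND4L", "ND4"))))
          warning("unexpected same-strand CDS overlap: ",
                  paste(pair, collapse = "/"))
      }
    }
  }
  gene_order(ann$name, ann$strand, ann$copy_index,
             kind = ifelse(ann$kind == "NC", "NC", "gene"),
             pseudo = if ("pseudo" %in% names(ann)) ann$pseudo else FALSE,
             anchor = anchor)
}

.order_fixture <- function(file, anchor = "trnF") {
  path <- system.file("extdata", file, package = "mitotwin", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  gene_order(tab$name, tab$strand, tab$copy_index, pseudo = tab$pseudo,
             anchor = anchor)
}

#' Reference gene orders
#'
#' `standard_vertebrate_order()` is the plesiomorphic vertebrate
#' mitochondrial gene order with a single Control Region.
#' `tuatara_order()` is the rearranged Tuatara order: the section between
#' ND4 and tRNA-Phe carries ND6, tRNA-Glu, NC1, the first tRNA-Leu(CUN)
#' copy, ND5, tRNA-Thr, tRNA-His, NC2, the second tRNA-Leu(CUN) copy,
#' Cytb, tRNA-Pro, tRNA-Ser(AGY) and NC3, plus a pseudogenized duplicate
#' tRNA-Lys. Both ship as plain-text tables.
#'
#' @return a [gene_order()].
#' @export
standard_vertebrate_order <- function() .order_fixture("standard_vertebrate_order.tsv")

#' @rdname standard_vertebrate_order
#' @export
tuatara_order <- function() .order_fixture("tuatara_order.tsv")

# project an order to the given symbols, keeping circular sequence
.project <- function(go, symbols) {
  go[go$name %in% symbols, , drop = FALSE]
}

# signed circular adjacency keys of an order (on its current row sequence)
.adjacencies <- function(go) {
  n <- nrow(go)
  if (n < 2L) return(character(0))
  sgn <- ifelse(go$strand == "light", "-", "+")
  lab <- paste0(sgn, go$name)
  nxt <- c(2:n, 1L)
  a <- lab
  b <- lab[nxt]
  flip <- function(x) ifelse(substr(x, 1, 1) == "+",
                             sub("^\\+", "-", x), sub("^-", "+", x))
  # canonical undirected signed adjacency: (a -> b) == (-b -> -a)
  key1 <- paste(a, b, sep = ">")
  key2 <- paste(flip(b), flip(a), sep = ">")
  pmin(key1, key2)
}

#' Compare two gene orders
#'
#' Reports, on the shared gene set: `moved_genes` — genes with any changed
#' signed (predecessor, successor) neighborhood (genes flanking a
#' rearranged segment are therefore reported along with the segment
#' itself); `duplicated_elements` — symbols with extra copies in exactly
#' one order (pseudogene copies flagged and excluded from breakpoints);
#' `extra_noncoding_blocks` — difference in NC block counts; and
#' `breakpoint_count` — signed circular adjacencies of A absent from B,
#' computed on the shared single-copy gene set (duplicates and NC blocks
#' removed first, the standard convention for breakpoint distance).
#'
#' @param order_a,order_b [gene_order()]s sharing >= 4 single-copy genes.
#' @return list of class `rearrangement_report`.
#' @export
compare_orders <- function(order_a, order_b) {
  count_copies <- function(go)
    table(go$name[go$kind != "NC" & !go$pseudo])
  ca <- count_copies(order_a); cb <- count_copies(order_b)
  shared <- intersect(names(ca), names(cb))
  single <- shared[ca[shared] == 1L & cb[shared] == 1L]
  if (length(single) < 4L)
    stop("orders share fewer than 4 single-copy genes")
  pa <- .project(order_a[!order_a$pseudo, ], single)
  pb <- .project(order_b[!order_b$pseudo, ], single)
  adj_a <- .adjacencies(pa); adj_b <- .adjacencies(pb)
  breakpoints <- sum(!(adj_a %in% adj_b))

  # moved genes: neighborhoods on the shared (possibly duplicated) gene set
  nb_sets <- function(go) {
    p <- .project(go[!go$pseudo, ], shared)
    n <- nrow(p)
    sgn <- ifelse(p$strand == "light", "-", "+")
    lab <- paste0(sgn, p$name)
    prv <- lab[c(n, seq_len(n - 1L))]
    nxt <- lab[c(2:n, 1L)]
    # a gene's neighborhood includes its own strand, so a strand flip in
    # place still counts as movement
    split(paste(prv, sgn, nxt, sep = "|"), p$name)
  }
  na_ <- nb_sets(order_a); nb_ <- nb_sets(order_b)
  moved <- shared[vapply(shared, function(g)
    !setequal(na_[[g]], nb_[[g]]), logical(1))]

  dup_in <- function(go, other_counts) {
    cg <- table(go$name[go$kind != "NC"])
    cand <- names(cg)[cg > 1L]
    cand[!(cand %in% names(other_counts)) | other_counts[cand] <= 1L |
           is.na(other_counts[cand])]
  }
  all_cb <- table(order_b$name[order_b$kind != "NC"])
  all_ca <- table(order_a$name[order_a$kind != "NC"])
  dups <- unique(c(dup_in(order_a, all_cb), dup_in(order_b, all_ca)))
  dup_df <- do.call(rbind, lapply(dups, function(g) {
    rows <- rbind(order_a[order_a$name == g, ], order_b[order_b$name == g, ])
    data.frame(symbol = g, pseudo = any(rows$pseudo & rows$copy_index > 1L))
  }))
  if (is.null(dup_df)) dup_df <- data.frame(symbol = character(0),
                                            pseudo = logical(0))
  nc_a <- sum(order_a$kind == "NC"); nc_b <- sum(order_b$kind == "NC")
  structure(list(moved_genes = moved,
                 duplicated_elements = dup_df,
                 extra_noncoding_blocks = abs(nc_a - nc_b),
                 breakpoint_count = breakpoints),
            class = "rearrangement_report")
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat(sprintf(paste0("<rearrangement_report> %d breakpoints; moved: %s; ",
                     "duplicated: %s; extra NC blocks: %d\n"),
              x$breakpoint_count,
              if (length(x$moved_genes)) paste(x$moved_genes, collapse = ", ")
              else "none",
              if (nrow(x$duplicated_elements))
                paste(x$duplicated_elements$symbol, collapse = ", ")
              else "none",
              x$extra_noncoding_blocks))
  invisible(x)
}
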