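#' @importFrom ape consensus read.tree write.tree prop.part
NULL

# nucleotide -> Fitch bitmask; anything ambiguous is missing data (A|C|G|T)
.state_code <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.aln_states <- function(alignment) {
  m <- as.matrix(alignment)
  s <- matrix(15L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (b in names(.state_code)) s[m == b] <- .state_code[[b]]
  s
}

.compress_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  uk <- unique(key)
  idx <- match(key, uk)
  pat <- states[, match(uk, key), drop = FALSE]
  list(pat = pat, weights = as.numeric(tabulate(idx, length(uk))),
       site_pattern = idx)
}

# taxa sorted by decreasing Hamming distance to the first taxon: a simple
# addition order that tightens the branch-and-bound bound early
.addition_order <- function(states) {
  n <- nrow(states)
  d <- vapply(seq_len(n), function(i)
    sum(states[i, ] != states[1L, ]), integer(1))
  c(1L, setdiff(order(d, decreasing = TRUE), 1L))
}

# convert a branch-and-bound edge list (tips 0..n-1, internal >= n) to an
# ape "phylo", rooted at the internal node next to tip 0 (unrooted
# semantics: that node keeps degree 3)
.edges_to_phylo <- function(em, ntips, tipnames) {
  nn <- max(em) + 1L
  adj <- vector("list", nn)
  for (e in seq_len(nrow(em))) {
    u <- em[e, 1L] + 1L; v <- em[e, 2L] + 1L
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  root <- adj[[1L]][1L]
  newid <- integer(nn)
  next_int <- ntips + 1L
  newid[root] <- next_int; next_int <- next_int + 1L
  parent <- newid[root]; child <- 1L
  stack <- list(c(root, 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top[1L]; par <- top[2L]
    for (u in adj[[v]]) {
      if (u == par) next
      if (u <= ntips) {
        parent <- c(parent, newid[v]); child <- c(child, u)
      } else {
        newid[u] <- next_int; next_int <- next_int + 1L
        parent <- c(parent, newid[v]); child <- c(child, newid[u])
        stack[[length(stack) + 1L]] <- c(u, v)
      }
    }
  }
  tr <- structure(list(edge = cbind(parent, child),
                       tip.label = tipnames,
                       Nnode = next_int - ntips - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

# phylo -> 0-based edge list against a given tip-name order; internal node
# degrees are checked (only the root trifurcation / bifurcation allowed)
.phylo_to_edges <- function(tree, row_names) {
  if (!inherits(tree, "phylo")) stop("expected an ape 'phylo' tree")
  if (!all(tree$tip.label %in% row_names))
    stop("tree leaf without sequence: ",
         paste(setdiff(tree$tip.label, row_names), collapse = ", "))
  n <- length(tree$tip.label)
  deg <- tabulate(c(tree$edge[, 1L], tree$edge[, 2L]), n + tree$Nnode)
  if (any(deg[-seq_len(n)] > 3L))
    stop("multifurcating tree: resolve it before computing Fitch length")
  tree$edge - 1L
}

#' Fitch parsimony length of a tree
#'
#' Minimum substitution count under unordered unit-cost (Fitch) parsimony,
#' with gaps and ambiguous bases treated as missing data (they never
#' contribute steps).
#'
#' @param tree an ape `phylo` (unrooted semantics; binary, possibly with a
#'   root bifurcation).
#' @param alignment a [dna_alignment()] whose row names cover the tree
#'   leaves.
#' @return list with `length` (total steps) and `site_lengths` (per-site
#'   steps, in alignment column order).
#' @export
fitch_length <- function(tree, alignment) {
  states <- .aln_states(alignment)
  miss <- setdiff(tree$tip.label, rownames(states))
  if (length(miss)) stop("tree leaf without sequence: ",
                         paste(miss, collapse = ", "))
  states <- states[tree$tip.label, , drop = FALSE]
  em <- .phylo_to_edges(tree, rownames(states))
  cp <- .compress_patterns(states)
  steps <- fitch_eval_cpp(em, cp$pat, length(tree$tip.label) + tree$Nnode)
  site_lengths <- steps[cp$site_pattern]
  list(length = sum(site_lengths), site_lengths = site_lengths)
}

#' Count parsimony-informative sites
#'
#' A site is parsimony informative when at least two states are each
#' present in at least two taxa (gaps and `N` treated as missing).
#'
#' @param alignment a [dna_alignment()].
#' @return integer count.
#' @export
count_informative_sites <- function(alignment) {
  m <- as.matrix(alignment)
  if (nrow(m) < 4L) stop("need >= 4 rows")
  sum(apply(m, 2L, function(col) {
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    sum(tab >= 2L) >= 2L
  }))
}

#' Exact branch-and-bound maximum-parsimony search
#'
#' Finds every minimum-length unrooted binary topology by branch and bound
#' (exact for the supported taxon range). An optional constraint restricts
#' the search to trees in which a group is, or is not, monophyletic —
#' the machinery behind decay indices and constrained alternative
#' hypotheses.
#'
#' @param alignment a [dna_alignment()] with 4-16 rows.
#' @param constrain_monophyly optional leaf names that must form a clade.
#' @param forbid_monophyly optional leaf names that must NOT form a clade.
#' @param max_trees cap on stored equally short trees.
#' @return list of class `parsimony_result`: `shortest_trees` (multiPhylo),
#'   `length`, `site_lengths` (first tree), `n_sites`,
#'   `n_parsimony_informative`, `overflow`.
#' @export
branch_and_bound_search <- function(alignment, constrain_monophyly = NULL,
                                    forbid_monophyly = NULL,
                                    max_trees = 2000L) {
  states <- .aln_states(alignment)
  n <- nrow(states)
  if (n < 4L) stop("need >= 4 taxa")
  if (n > 16L)
    stop("more than 16 taxa: exact branch-and-bound is not attempted; ",
         "use a heuristic search tool for larger problems")
  if (!is.null(constrain_monophyly) && !is.null(forbid_monophyly))
    stop("give at most one of constrain_monophyly / forbid_monophyly")
  group <- integer(0); mode <- 0L
  if (!is.null(constrain_monophyly)) { mode <- 1L; gnames <- constrain_monophyly }
  if (!is.null(forbid_monophyly)) { mode <- 2L; gnames <- forbid_monophyly }
  if (mode > 0L) {
    bad <- setdiff(gnames, rownames(states))
    if (length(bad)) stop("constraint names not in alignment: ",
                          paste(bad, collapse = ", "))
    group <- match(gnames, rownames(states)) - 1L
    if (length(group) < 2L || length(group) > n - 2L)
      stop("constraint group must contain 2..(n-2) leaves")
  }
  cp <- .compress_patterns(states)
  ord <- .addition_order(states) - 1L
  res <- bab_cpp(cp$pat, cp$weights, ord, mode, group, as.integer(max_trees))
  trees <- lapply(res$trees, .edges_to_phylo, ntips = n,
                  tipnames = rownames(states))
  class(trees) <- "multiPhylo"
  sl <- if (length(trees)) fitch_length(trees[[1L]], alignment)$site_lengths
        else numeric(0)
  structure(list(shortest_trees = trees, length = res$length,
                 site_lengths = sl, n_sites = ncol(states),
                 n_parsimony_informative = count_informative_sites(alignment),
                 overflow = res$overflow),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf(paste0("<parsimony_result> %d shortest tree(s) of length %g; ",
                     "%d sites, %d parsimony-informative\n"),
              length(x$shortest_trees), x$length, x$n_sites,
              x$n_parsimony_informative))
  invisible(x)
}

# canonical name-keys for the non-trivial splits of a tree
.split_keys <- function(tree) {
  labs <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(part) {
    side <- sort(tree$tip.label[part])
    if (length(side) < 2L || length(side) > length(labs) - 2L)
      return(NA_character_)
    other <- setdiff(labs, side)
    if (labs[1L] %in% side) side <- other
    paste(side, collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Split key for a clade
#' @param clade leaf names on one side of the split.
#' @param all_leaves all leaf names.
#' @return canonical character key, as used by [bootstrap_support()].
#' @export
clade_key <- function(clade, all_leaves) {
  labs <- sort(all_leaves)
  side <- sort(clade)
  if (labs[1L] %in% side) side <- sort(setdiff(labs, side))
  paste(side, collapse = "|")
}

#' Nonparametric bootstrap support for parsimony clades
#'
#' Sites are resampled with replacement; each replicate is analysed by the
#' same exact branch-and-bound search and summarized by the strict
#' consensus of its shortest trees (so equal-length ties collapse rather
#' than voting arbitrarily). Support for a clade is the percentage of
#' replicate consensi containing it. Deterministic given `seed`.
#'
#' @param alignment a [dna_alignment()].
#' @param replicates number of bootstrap replicates.
#' @param seed integer seed.
#' @param clades optional list of leaf-name vectors to score; defaults to
#'   every non-trivial split of the strict consensus of the original
#'   shortest trees.
#' @return list with `reference` (strict consensus), `support` (data frame
#'   of clade keys and % support), `replicates`.
#' @export
bootstrap_support <- function(alignment, replicates = 1000L, seed = 1L,
                              clades = NULL) {
  stopifnot(replicates >= 1L)
  set.seed(as.integer(seed))
  states <- .aln_states(alignment)
  cp <- .compress_patterns(states)
  ord <- .addition_order(states) - 1L
  n <- nrow(states)
  base <- branch_and_bound_search(alignment)
  ref <- strict_consensus(base$shortest_trees)
  keys <- if (is.null(clades)) .split_keys(ref)
          else vapply(clades, clade_key, character(1),
                      all_leaves = rownames(states))
  hits <- setNames(numeric(length(keys)), keys)
  nsite <- ncol(states)
  for (r in seq_len(replicates)) {
    take <- sample.int(nsite, nsite, replace = TRUE)
    wts <- as.numeric(tabulate(cp$site_pattern[take], ncol(cp$pat)))
    res <- bab_cpp(cp$pat, wts, ord, 0L, integer(0), 500L)
    trees <- lapply(res$trees, .edges_to_phylo, ntips = n,
                    tipnames = rownames(states))
    class(trees) <- "multiPhylo"
    cons <- strict_consensus(trees)
    rk <- .split_keys(cons)
    hits[keys %in% rk] <- hits[keys %in% rk] + 1
  }
  list(reference = ref,
       support = data.frame(clade = keys,
                            support = 100 * unname(hits) / replicates),
       replicates = replicates)
}

#' Decay (Bremer) index of a clade
#'
#' Extra steps required by the shortest tree in which the clade is not
#' monophyletic, computed exactly via a reverse-constraint branch-and-bound
#' search: `decay = length(shortest tree lacking the clade) - length(global
#' shortest tree)`. If the clade occurs in no shortest tree the index is
#' <= 0 and a warning is raised.
#'
#' @param alignment a [dna_alignment()].
#' @param clade leaf names of the clade.
#' @return integer steps (class `numeric`).
#' @export
decay_index <- function(alignment, clade) {
  global <- branch_and_bound_search(alignment)
  anti <- branch_and_bound_search(alignment, forbid_monophyly = clade)
  d <- anti$length - global$length
  key <- clade_key(clade, rownames(as.matrix(alignment)))
  in_best <- any(vapply(global$shortest_trees,
                        function(t) key %in% .split_keys(t), logical(1)))
  if (!in_best)
    warning("clade is in no shortest tree; decay index reported as <= 0")
  d
}

#' Strict consensus of trees
#'
#' Retains exactly the splits present in every input tree.
#'
#' @param trees a `multiPhylo` (or list of `phylo`) on the same leaf set.
#' @return a `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) return(trees)
  if (!length(trees)) stop("no trees given")
  if (length(trees) == 1L) return(trees[[1L]])
  sets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(sets, identical, logical(1), y = sets[[1L]])))
    stop("trees must share an identical leaf set")
  ape::consensus(trees, p = 1, rooted = FALSE)
}

# ---- Templeton (Wilcoxon signed-ranks) test -------------------------------

# exact two-tailed p for the signed-rank statistic with midranks, by
# dynamic programming over the 2^n equally likely sign assignments
.signedrank_exact_p <- function(ranks, t_plus) {
  r2 <- as.integer(round(2 * ranks))
  tot <- sum(r2)
  v <- numeric(tot + 1L); v[1L] <- 1
  for (x in r2) {
    nv <- v
    nv[(x + 1L):(tot + 1L)] <- nv[(x + 1L):(tot + 1L)] + v[seq_len(tot + 1L - x)]
    v <- nv
  }
  v <- v / 2^length(r2)
  mu2 <- tot / 2
  t2 <- round(2 * t_plus)
  idx <- 0:tot
  sum(v[abs(idx - mu2) >= abs(t2 - mu2) - 1e-9])
}

#' Templeton test of two competing trees
#'
#' Paired-sites Wilcoxon signed-ranks comparison of per-site parsimony
#' lengths between two trees on the same leaf set. Sites with equal steps
#' are dropped; ranks of the absolute step differences use midranks for
#' ties; the z statistic uses the tie-corrected variance. The two-tailed p
#' is exact (full sign-assignment distribution) when the number of
#' differing sites is <= 20, otherwise the normal approximation is used.
#'
#' @param alignment a [dna_alignment()].
#' @param tree_a,tree_b ape `phylo` trees on identical leaf sets.
#' @return list of class `templeton_result`: `n_differing_sites`, `T_plus`,
#'   `T_minus`, `z`, `p_two_tailed`, `method`, `no_difference` flag.
#' @export
templeton_test <- function(alignment, tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop("trees must be on identical leaf sets")
  sa <- fitch_length(tree_a, alignment)$site_lengths
  sb <- fitch_length(tree_b, alignment)$site_lengths
  d <- sa - sb
  nz <- d[d != 0]
  if (!length(nz)) {
    return(structure(list(n_differing_sites = 0L, T_plus = 0, T_minus = 0,
                          z = 0, p_two_tailed = 1.0, method = "degenerate",
                          no_difference = TRUE),
                     class = "templeton_result"))
  }
  n <- length(nz)
  r <- rank(abs(nz))                      # midranks for ties
  t_plus <- sum(r[nz > 0])
  t_minus <- sum(r[nz < 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(nz))
  varw <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (varw > 0) (t_plus - mu) / sqrt(varw) else 0
  if (n <= 20L) {
    p <- .signedrank_exact_p(r, t_plus)
    method <- "exact"
  } else {
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(n_differing_sites = n, T_plus = t_plus, T_minus = t_minus,
                 z = z, p_two_tailed = min(1, p), method = method,
                 no_difference = FALSE),
            class = "templeton_result")
}

#' @export
print.templeton_result <- function(x, ...) {
  cat(sprintf(paste0("<templeton_result> n = %d differing sites, T+ = %g, ",
                     "T- = %g, z = %.3f, p = %.4g (%s)\n"),
              x$n_differing_sites, x$T_plus, x$T_minus, x$z, x$p_two_tailed,
              x$method))
  invisible(x)
}

#' Test monophyly of a group against the unconstrained optimum
#'
#' Searches for the shortest tree in which `group` is constrained
#' monophyletic and compares it to the global shortest tree by step
#' difference and a Templeton test. A positive step difference with small
#' p rejects the monophyly hypothesis.
#'
#' @param alignment a [dna_alignment()].
#' @param group leaf names (>= 2, proper subset).
#' @return list of class `monophyly_test`: `constrained`, `unconstrained`
#'   ([branch_and_bound_search()] results), `step_difference`, `templeton`.
#' @export
test_monophyly <- function(alignment, group) {
  unco <- branch_and_bound_search(alignment)
  cons <- branch_and_bound_search(alignment, constrain_monophyly = group)
  tt <- templeton_test(alignment, cons$shortest_trees[[1L]],
                       unco$shortest_trees[[1L]])
  structure(list(constrained = cons, unconstrained = unco,
                 step_difference = cons$length - unco$length,
                 templeton = tt),
            class = "monophyly_test")
}

#' @export
print.monophyly_test <- function(x, ...) {
  cat(sprintf(paste0("<monophyly_test> constrained %g vs unconstrained %g ",
                     "steps (+%g); Templeton p = %.4g\n"),
              x$constrained$length, x$unconstrained$length,
              x$step_difference, x$templeton$p_two_tailed))
  invisible(x)
}

#' Read / write trees in newick format
#' @param path file path.
#' @return `read_trees`: a `multiPhylo`; `write_trees`: `path` invisibly.
#' @export
read_trees <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) { tr <- list(tr); class(tr) <- "multiPhylo" }
  tr
}

#' @rdname read_trees
#' @param trees `phylo` or `multiPhylo`.
#' @export
write_trees <- function(trees, path) {
  ape::write.tree(trees, path)
  invisible(path)
}
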