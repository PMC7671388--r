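#' Parse a Newick string
#'
#' Thin wrapper around `ape::read.tree` that validates the input, collapses
#' a degree-2 root (so rooted inputs become their unrooted equivalent) and
#' checks leaf-label uniqueness.
#'
#' @param text a Newick string (trailing `;` optional).
#' @return an `ape::phylo` tree.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  if (!endsWith(txt, ";")) txt <- paste0(txt, ";")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick string: ", substr(txt, 1, 60))
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in Newick input")
  if (tr$Nnode >= 1L && ape::is.rooted(tr) && length(tr$tip.label) > 2L)
    tr <- ape::unroot(tr)
  ape::collapse.singles(tr)
}

#' Serialize a tree to Newick
#'
#' @param tree an `ape::phylo`.
#' @return a Newick string (with trailing `;`).
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

# nontrivial bipartitions of an unrooted tree as canonical strings: for
# every internal edge, the leaf set below it, represented by the side NOT
# containing the reference leaf (alphabetically first label), sorted and
# collapsed with "\r" separators.
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::collapse.singles(tree)
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L)
    tree <- ape::unroot(tree)
  tips <- tree$tip.label
  n <- length(tips)
  ref <- tips[order(tips)][1L]
  nnode <- tree$Nnode
  # leaf sets below each node by postorder accumulation
  below <- vector("list", n + nnode)
  for (i in seq_len(n)) below[[i]] <- tips[i]
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1]; ch <- edge[r, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  root <- n + 1L
  keys <- character(0)
  for (r in seq_len(nrow(edge))) {
    ch <- edge[r, 2]
    if (ch <= n) next                       # terminal edge: trivial split
    side <- below[[ch]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (ref %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Counts nontrivial bipartitions (internal edges) present in exactly one
#' of the two trees. The normalized distance divides by the total number
#' of nontrivial bipartitions present in the two trees (for two binary
#' trees on `n` leaves this is `2(n-3)`), so it lies in `[0, 1]` and
#' equals 1 iff no nontrivial bipartition is shared. Multifurcating trees
#' are allowed; they simply carry fewer bipartitions.
#'
#' @param t1,t2 `ape::phylo` trees (or Newick strings) on identical leaf
#'   sets.
#' @return a list with `absolute` and `normalized`.
#' @export
rf_distance <- function(t1, t2) {
  if (is.character(t1)) t1 <- parse_newick(t1)
  if (is.character(t2)) t2 <- parse_newick(t2)
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label))
    stop("trees must have identical leaf sets")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  absolute <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  denom <- length(b1) + length(b2)
  list(absolute = absolute,
       normalized = if (denom == 0L) 0 else absolute / denom)
}
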