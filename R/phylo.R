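#' Pairwise p-distance matrix from an alignment
#'
#' For every pair of rows, the fraction of mismatching sites over columns
#' where both rows are non-gap (pairwise deletion). A pair with zero
#' comparable columns is an error.
#'
#' @param alignment Named character vector of equal-length gapped rows.
#' @return Symmetric numeric matrix with zero diagonal, entries in [0, 1],
#'   dimnames set to the row ids.
#' @export
pDistance <- function(alignment) {
  if (length(alignment) < 2L) .stopf("p-distance needs at least two rows")
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  gap <- m == "-"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    nc <- sum(ok)
    if (nc == 0L)
      .stopf("no comparable columns between '%s' and '%s'",
             names(alignment)[i], names(alignment)[j])
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / nc
  }
  d
}

# Clamp negative NJ branch lengths to zero, moving the deficit onto the
# sister branch (floored at zero) so tip-to-tip path lengths change little.
.clampNegativeEdges <- function(tree) {
  if (is.null(tree$edge.length)) return(tree)
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    sibs <- which(tree$edge[, 1] == tree$edge[e, 1] &
                    seq_along(tree$edge.length) != e)
    if (length(sibs))
      tree$edge.length[sibs[1]] <-
        max(0, tree$edge.length[sibs[1]] + deficit)
  }
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via \pkg{ape}), followed by a
#' deterministic cleanup pass that clamps negative branch lengths to zero
#' and moves the deficit onto the sister branch. On additive distances the
#' true topology is recovered exactly.
#'
#' @param d Symmetric distance matrix with ids as dimnames (or a `dist`).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) .stopf("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) .stopf("distance matrix must be symmetric")
  tree <- ape::nj(d)
  .clampNegativeEdges(tree)
}

#' Write a tree as a Newick string
#'
#' @param tree An `ape::phylo` object.
#' @param digits Significant digits for branch lengths (default 6).
#' @return Newick string with branch lengths and trailing semicolon.
#' @export
treeToNewick <- function(tree, digits = 6L) {
  ape::write.tree(tree, digits = digits)
}

# canonical non-trivial bipartitions of an unrooted tree, each encoded as a
# sorted label string on the side not containing the reference tip
.bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character()
  n <- length(tips)
  for (p in parts) {
    side <- labs[p]
    if (ref %in% side) side <- setdiff(tips, side)
    k <- length(side)
    if (k >= 2L && k <= n - 2L)
      out <- c(out, paste(sort(side), collapse = "\r"))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the non-trivial bipartition sets of
#' two unrooted trees on the same leaves.
#'
#' @param t1,t2 `ape::phylo` trees with identical leaf sets.
#' @return Non-negative integer.
#' @export
robinsonFoulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    .stopf("trees have differing leaf sets")
  b1 <- .bipartitions(t1)
  b2 <- .bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Export sequon-presence annotations for a tree
#'
#' Mirrors presence/absence branch coloring: every leaf is classed
#' `with_NGS` (red) when its screening verdict carries at least one passing
#' extracellular sequon, else `without_NGS` (black), with per-loop bars for
#' EL1/EL2 and the taxon group. The flat table is consumable by external
#' tree viewers.
#'
#' @param tree An `ape::phylo` tree whose tips are screened protein ids.
#' @param result A [ScreenResult].
#' @return `data.frame` with columns `leaf`, `color_class`, `el1_bar`,
#'   `el2_bar`, `taxon_group`, one row per leaf in tip order.
#' @export
annotateTree <- function(tree, result) {
  v <- verdicts(result)
  sq <- sequons(result)
  leaves <- tree$tip.label
  hit <- match(leaves, v$protein_id)
  if (anyNA(hit))
    .stopf("leaf '%s' has no screening verdict", leaves[is.na(hit)][1])
  inLoop <- function(id, lab)
    any(sq$protein_id == id & sq$passes & sq$loop_label == lab)
  data.frame(
    leaf = leaves,
    color_class = ifelse(v$has_el_ngs[hit], "with_NGS", "without_NGS"),
    el1_bar = unname(vapply(leaves, inLoop, TRUE, lab = "EL1")),
    el2_bar = unname(vapply(leaves, inLoop, TRUE, lab = "EL2")),
    taxon_group = v$taxon_group[hit],
    stringsAsFactors = FALSE, row.names = NULL)
}
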