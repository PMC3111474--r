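#' Build a validated phylogeny for regulatory-state evolution
#'
#' Accepts an [ape::phylo] object, a Newick string, or a path to a Newick
#' file. Branch lengths are interpreted as divergence times in the same
#' units as the inverse of the gain/loss rates (see [tn_rates()]); they are
#' taken as-is, with no rescaling. Leaf (species) names must be unique and
#' nonempty, the tree must be rooted, and every branch needs a nonnegative
#' length.
#'
#' @param x an `ape` phylo object, a Newick string, or a file path.
#' @return An object of class `tn_tree`: the underlying `phylo` plus an
#'   indexed parent/child table used by the pruning recursions. Leaf names
#'   are exposed in sorted order via `$species`.
#' @examples
#' tr <- tn_tree("((human:0.25,mouse:0.25):0.15,cow:0.40);")
#' tr$species
#' @export
tn_tree <- function(x) {
  if (inherits(x, "tn_tree")) return(x)
  if (inherits(x, "phylo")) {
    phy <- x
  } else if (is.character(x) && length(x) == 1L) {
    phy <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
    if (is.null(phy)) stop_tn("could not parse Newick input")
  } else {
    stop_tn("'x' must be a phylo object, a Newick string, or a file path")
  }
  if (!ape::is.rooted(phy)) stop_tn("tree must be rooted")
  ntip <- length(phy$tip.label)
  if (ntip < 1L) stop_tn("tree has no leaves")
  if (anyDuplicated(phy$tip.label)) stop_tn("leaf names must be unique")
  if (any(!nzchar(phy$tip.label))) stop_tn("leaf names must be nonempty")
  if (is.null(phy$edge.length)) stop_tn("branch lengths are required on all branches")
  if (any(is.na(phy$edge.length)) || any(phy$edge.length < 0))
    stop_tn("all branch lengths must be nonnegative")

  nnode <- ntip + phy$Nnode
  parent <- rep(NA_integer_, nnode)
  blen <- rep(NA_real_, nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  blen[phy$edge[, 2L]] <- phy$edge.length
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])
  if (length(root) != 1L) stop_tn("tree must have exactly one root")
  children <- split(phy$edge[, 2L], factor(phy$edge[, 1L], levels = seq_len(nnode)))

  # postorder over internal nodes: children visited before parents
  post <- unique(ape::reorder.phylo(phy, "postorder")$edge[, 1L])

  structure(list(
    phylo = phy,
    n_tips = ntip,
    n_nodes = nnode,
    root = root,
    parent = parent,
    blen = blen,
    children = children,
    postorder_internal = post,
    tip_index = stats::setNames(seq_len(ntip), phy$tip.label),
    species = sort(phy$tip.label)
  ), class = "tn_tree")
}

#' @export
print.tn_tree <- function(x, ...) {
  cat(sprintf("tn_tree: %d species, %d nodes\n", x$n_tips, x$n_nodes))
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  cat("  newick :", write_tree_text(x), "\n")
  invisible(x)
}

#' Canonical Newick serialization of a phylogeny
#'
#' @param tree a [tn_tree()] (or anything it accepts).
#' @return A single Newick string with branch lengths.
#' @export
write_tree_text <- function(tree) {
  tree <- tn_tree(tree)
  ape::write.tree(tree$phylo)
}

#' @rdname write_tree_text
#' @param path output file path.
#' @export
write_tree_file <- function(tree, path) {
  writeLines(write_tree_text(tree), path)
  invisible(path)
}
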