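#' Read a gene tree from a Newick file
#'
#' Parses a Newick tree with `ape` and applies the package's support
#' dialect: numeric internal-node labels are bootstrap percentages on the
#' 0--100 scale. Labels that all fall in \[0, 1\] are stored verbatim and a
#' warning is raised -- no silent rescaling, since IQ-TREE-style ultrafast
#' bootstrap is written on 0--100 and a 0--1 file usually signals a unit
#' mix-up upstream. Missing branch lengths default to 0; negative branch
#' lengths are a format error.
#'
#' @param path Path to a Newick file (first tree is used).
#' @param support_convention `"internal_node_label"` (default) to parse
#'   numeric internal labels as support, or `"none"` to ignore them.
#' @return An `ape::phylo` with an additional `support` vector attribute
#'   aligned to internal nodes (`NA` where absent).
#' @export
read_newick <- function(path, support_convention = c("internal_node_label", "none")) {
  support_convention <- match.arg(support_convention)
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tree)) abort("Newick parse error: no tree in file")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (any(tree$edge.length < 0)) abort("negative branch length in Newick file")
  as_gene_tree(tree, support_convention = support_convention)
}

# Normalise an ape phylo into the package's gene-tree convention:
# tree$support numeric vector over internal nodes (length Nnode), NA when
# no (numeric) label is present.
as_gene_tree <- function(tree, support_convention = "internal_node_label") {
  assert_phylo(tree)
  supp <- rep(NA_real_, tree$Nnode)
  if (support_convention == "internal_node_label" && !is.null(tree$node.label)) {
    lab <- tree$node.label
    num <- suppressWarnings(as.numeric(lab))
    supp <- num
    finite <- supp[is.finite(supp)]
    if (length(finite) > 0L && all(finite >= 0 & finite <= 1) && any(finite > 0)) {
      warn(paste(
        "internal-node supports all lie in [0, 1];",
        "stored verbatim (expected bootstrap on the 0-100 scale)"
      ))
    }
    if (any(is.finite(supp) & (supp < 0 | supp > 100))) {
      abort("support values outside [0, 100]")
    }
  }
  tree$support <- supp
  tree
}

#' Median branch length of a gene tree
#'
#' The median over *all* branches, terminal and internal, zero-length
#' branches included. Even counts use the mean of the two central values.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @return Non-negative scalar.
#' @export
median_branch_length <- function(tree) {
  assert_phylo(tree)
  if (is.null(tree$edge.length) || length(tree$edge.length) == 0L) {
    abort("tree has no branches with lengths")
  }
  stats::median(tree$edge.length)
}

# --- bipartition machinery -------------------------------------------------

# For every internal, non-root node of `tree`, the set of tip labels on its
# side of the parent edge, together with that node's support. These are the
# non-trivial bipartitions of the unrooted tree. When the tree is stored
# rooted with a 2-degree root, the two root edges describe the same
# bipartition; the duplicate is dropped.
tree_bipartitions <- function(tree) {
  assert_phylo(tree)
  tree <- as_gene_tree_if_needed(tree)
  nt <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  desc <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- i
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]
    ch <- tr$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  root <- setdiff(unique(tr$edge[, 1L]), tr$edge[, 2L])
  internals <- setdiff(unique(tr$edge[, 2L]), seq_len(nt))
  out <- lapply(internals, function(v) {
    tips <- sort(tree$tip.label[desc[[v]]])
    list(
      node = v,
      tips = tips,
      support = tree$support[v - nt]
    )
  })
  # drop tautologies (side = all tips minus one, or everything): those are
  # trivial when the root has degree 2
  sizes <- vapply(out, function(b) length(b$tips), integer(1))
  out <- out[sizes >= 2L & sizes <= nt - 2L]
  # deduplicate complementary splits (possible with a degree-2 root)
  keys <- vapply(out, function(b) {
    side <- b$tips
    comp <- sort(setdiff(tree$tip.label, side))
    paste(if (paste(side, collapse = ";") < paste(comp, collapse = ";")) {
      side
    } else {
      comp
    }, collapse = ";")
  }, character(1))
  out[!duplicated(keys)]
}

as_gene_tree_if_needed <- function(tree) {
  if (is.null(tree$support)) tree <- as_gene_tree(tree) else tree
}

# TRUE when the unrooted tree displays the split `side | rest`.
# Trivial splits (|side| <= 1 or |rest| <= 1) are always displayed.
displays_split <- function(tree, side) {
  labels <- tree$tip.label
  side <- intersect(side, labels)
  rest <- setdiff(labels, side)
  if (length(side) <= 1L || length(rest) <= 1L) return(TRUE)
  bips <- tree_bipartitions(tree)
  key <- paste(sort(side), collapse = ";")
  key_c <- paste(sort(rest), collapse = ";")
  for (b in bips) {
    k <- paste(b$tips, collapse = ";")
    if (identical(k, key) || identical(k, key_c)) return(TRUE)
  }
  FALSE
}

#' Collapse weakly supported internal branches
#'
#' Contracts every internal branch whose support is less than or equal to
#' `support_threshold` into a polytomy; the contracted branch lengths are
#' discarded, all other branch lengths and supports are kept. Branches
#' with missing support are treated as support 0 (weak) and collapsed,
#' with a message. Idempotent.
#'
#' @param tree An `ape::phylo`; supports read from numeric internal node
#'   labels (see [read_newick()]).
#' @param support_threshold Inclusive threshold; default 50.
#' @return The collapsed `phylo`.
#' @export
collapse_weak_branches <- function(tree, support_threshold = 50) {
  tree <- as_gene_tree_if_needed(tree)
  nt <- length(tree$tip.label)
  root <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])
  internal_children <- setdiff(unique(tree$edge[, 2L]), seq_len(nt))
  supp <- tree$support[internal_children - nt]
  if (any(is.na(supp))) {
    inform("internal branches with missing support treated as support 0")
    supp[is.na(supp)] <- 0
  }
  drop_nodes <- internal_children[supp <= support_threshold]
  if (length(drop_nodes) == 0L) return(tree)
  contract_nodes(tree, drop_nodes)
}

# Contract the parent edges of the given internal nodes, reattaching their
# children to the nearest retained ancestor.
contract_nodes <- function(tree, drop_nodes) {
  nt <- length(tree$tip.label)
  n_nodes <- nt + tree$Nnode
  parent <- integer(n_nodes)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  dropped <- logical(n_nodes)
  dropped[drop_nodes] <- TRUE
  climb <- function(v) {
    while (dropped[v]) v <- parent[v]
    v
  }
  keep_edge <- !dropped[tree$edge[, 2L]]
  new_parent <- vapply(tree$edge[keep_edge, 1L], climb, integer(1))
  new_child <- tree$edge[keep_edge, 2L]
  new_len <- tree$edge.length[keep_edge]
  kept_internal <- sort(setdiff(
    unique(c(new_parent, new_child[new_child > nt])), seq_len(nt)
  ))
  remap <- integer(n_nodes)
  remap[seq_len(nt)] <- seq_len(nt)
  remap[kept_internal] <- nt + seq_along(kept_internal)
  out <- list(
    edge = cbind(remap[new_parent], remap[new_child]),
    edge.length = new_len,
    tip.label = tree$tip.label,
    Nnode = length(kept_internal)
  )
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  supp <- tree$support[kept_internal - nt]
  out$support <- supp
  out$node.label <- ifelse(is.na(supp), "", format(supp, trim = TRUE))
  out
}

#' Root-to-tip path lengths
#'
#' Sums branch lengths from the root to every leaf -- the classic
#' rate-inflation diagnostic: under a clock all values are equal, and a
#' rate-accelerated taxon stands out with the largest value.
#'
#' @param tree A rooted `ape::phylo`, or an unrooted one plus `outgroup`.
#' @param outgroup Optional taxon labels used to root an unrooted tree.
#' @return A tibble with `taxon` and `root_to_tip`.
#' @export
root_to_tip_lengths <- function(tree, outgroup = NULL) {
  assert_phylo(tree)
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup)) {
      abort("tree is unrooted: supply `outgroup` to root it")
    }
    og <- intersect(outgroup, tree$tip.label)
    if (length(og) == 0L) abort("no outgroup taxa present in tree")
    tree <- ape::root(tree, outgroup = og, resolve.root = TRUE)
  }
  depths <- ape::node.depth.edgelength(tree)
  tibble::tibble(
    taxon = tree$tip.label,
    root_to_tip = depths[seq_along(tree$tip.label)]
  )
}
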