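#' Gene concordance and discordance factors
#'
#' For every internal branch of a binary reference species tree, with
#' bipartition `X | Y` and the four incident subtrees `(S1, S2 | Y1, Y2)`,
#' a gene tree is *decisive* when it contains at least one taxon from each
#' of the four subtrees. Among decisive gene trees (restricted to their
#' own taxa):
#' * `gCF`: % displaying the reference split `(S1 u S2) | (Y1 u Y2)`;
#' * `gDF1`: % displaying the first nearest-neighbour-interchange
#'   alternative `(S1 u Y1) | (S2 u Y2)`;
#' * `gDF2`: % displaying the second alternative `(S1 u Y2) | (S2 u Y1)`;
#' * `gDFP`: the remainder (paraphyly/polytomy).
#'
#' Subtree order (hence which alternative is "first") follows the edge
#' order of the reference tree and is deterministic for a given file.
#' Reference branches around which the tree is not locally binary are
#' skipped with a warning.
#'
#' @param ref_tree Reference species tree (`ape::phylo`); unrooted
#'   internally.
#' @param gene_trees List of `ape::phylo` gene trees; taxa may be missing.
#' @return Tibble with one row per evaluated reference branch: `branch_id`,
#'   `split` (list-column of tip labels on the child side), `n_decisive`,
#'   `gCF`, `gDF1`, `gDF2`, `gDFP` (percentages, `NA` when no decisive
#'   tree).
#' @export
concordance_factors <- function(ref_tree, gene_trees) {
  branches <- ref_branch_contexts(ref_tree)
  if (length(branches) == 0L) {
    abort("reference tree has no internal branches to evaluate")
  }
  gene_splits <- lapply(gene_trees, function(g) {
    list(
      taxa = g$tip.label,
      sides = lapply(tree_bipartitions(g), `[[`, "tips")
    )
  })
  purrr::map_dfr(branches, function(br) {
    counts <- c(concord = 0L, nni1 = 0L, nni2 = 0L, para = 0L)
    for (gs in gene_splits) {
      s1 <- intersect(br$S1, gs$taxa)
      s2 <- intersect(br$S2, gs$taxa)
      y1 <- intersect(br$Y1, gs$taxa)
      y2 <- intersect(br$Y2, gs$taxa)
      if (!length(s1) || !length(s2) || !length(y1) || !length(y2)) next
      cls <- classify_quartet_split(gs, c(s1, s2), c(s1, y1), c(s1, y2))
      counts[cls] <- counts[cls] + 1L
    }
    n <- sum(counts)
    pct <- function(k) if (n > 0L) 100 * counts[[k]] / n else NA_real_
    tibble::tibble(
      branch_id = br$branch_id,
      split = list(sort(c(br$S1, br$S2))),
      n_decisive = n,
      gCF = pct("concord"), gDF1 = pct("nni1"),
      gDF2 = pct("nni2"), gDFP = pct("para")
    )
  })
}

# Decide which of the three resolutions a decisive gene tree displays.
# side_* are the taxa (present in the gene tree) forming one side of the
# concordant / NNI1 / NNI2 splits respectively.
classify_quartet_split <- function(gs, side_c, side_1, side_2) {
  displays <- function(side) {
    rest <- setdiff(gs$taxa, side)
    if (length(side) <= 1L || length(rest) <= 1L) return(TRUE)
    key <- paste(sort(side), collapse = ";")
    key_c <- paste(sort(rest), collapse = ";")
    for (s in gs$sides) {
      k <- paste(s, collapse = ";")
      if (identical(k, key) || identical(k, key_c)) return(TRUE)
    }
    FALSE
  }
  if (displays(side_c)) return("concord")
  if (displays(side_1)) return("nni1")
  if (displays(side_2)) return("nni2")
  "para"
}

# For each internal branch of the (unrooted) reference tree, the four
# incident subtrees' tip sets. Branch ids are stable: "b<child node id>"
# in the unrooted tree's numbering.
ref_branch_contexts <- function(ref_tree) {
  assert_phylo(ref_tree)
  tree <- ape::unroot(ref_tree)
  nt <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  desc <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- i
  for (k in seq_len(nrow(tr$edge))) {
    desc[[tr$edge[k, 1L]]] <- c(desc[[tr$edge[k, 1L]]], desc[[tr$edge[k, 2L]]])
  }
  root <- setdiff(unique(tr$edge[, 1L]), tr$edge[, 2L])
  children_of <- function(v) tr$edge[tr$edge[, 1L] == v, 2L]
  parent <- integer(nt + tr$Nnode)
  parent[tr$edge[, 2L]] <- tr$edge[, 1L]
  labels <- tree$tip.label
  out <- list()
  skipped <- 0L
  for (v in setdiff(unique(tr$edge[, 2L]), seq_len(nt))) {
    kids <- children_of(v)
    p <- parent[v]
    # subtrees on the far side of the branch: the parent's other children,
    # plus (when p is not the root) everything above p as one subtree
    sibs <- setdiff(children_of(p), v)
    far <- lapply(sibs, function(s) labels[desc[[s]]])
    if (p != root) {
      far <- c(far, list(setdiff(labels, labels[desc[[p]]])))
    }
    if (length(kids) != 2L || length(far) != 2L) {
      skipped <- skipped + 1L
      next
    }
    side <- labels[desc[[v]]]
    if (length(side) < 2L || length(side) > nt - 2L) next
    out[[length(out) + 1L]] <- list(
      branch_id = paste0("b", v),
      S1 = labels[desc[[kids[1L]]]],
      S2 = labels[desc[[kids[2L]]]],
      Y1 = far[[1L]],
      Y2 = far[[2L]]
    )
  }
  if (skipped > 0L) {
    warn(sprintf(
      "%d reference branch(es) skipped: tree not locally binary", skipped
    ))
  }
  out
}

#' Classify each gene at a focal reference branch
#'
#' Per-gene version of [concordance_factors()]: labels every gene tree as
#' `concordant`, `gD1`, `gD2` (supporting one of the two NNI
#' rearrangements at the focal branch) or `other` (not decisive, or
#' decisive but paraphyletic). Genes in the `gD1`/`gD2` classes are the
#' usual candidates for building alternative-topology datasets.
#'
#' @param ref_tree Reference species tree.
#' @param gene_trees Named list of gene trees (names = gene ids) or a
#'   tibble with `gene_id` and `tree` columns.
#' @param focal_branch A `branch_id` from [concordance_factors()], or a
#'   character vector of tip labels identifying one side of the branch.
#' @return Tibble: `gene_id`, `class`.
#' @export
classify_discordance <- function(ref_tree, gene_trees, focal_branch) {
  genes <- as_gene_table(gene_trees)
  branches <- ref_branch_contexts(ref_tree)
  br <- NULL
  if (is.character(focal_branch) && length(focal_branch) == 1L &&
      grepl("^b[0-9]+$", focal_branch)) {
    for (b in branches) if (b$branch_id == focal_branch) br <- b
  }
  if (is.null(br) && is.character(focal_branch)) {
    want <- sort(focal_branch)
    for (b in branches) {
      side <- sort(c(b$S1, b$S2))
      comp <- sort(setdiff(ref_tree$tip.label, side))
      if (identical(side, want) || identical(comp, want)) br <- b
    }
  }
  if (is.null(br)) abort("focal branch not found in reference tree")
  purrr::pmap_dfr(genes, function(gene_id, tree, ...) {
    gs <- list(
      taxa = tree$tip.label,
      sides = lapply(tree_bipartitions(tree), `[[`, "tips")
    )
    s1 <- intersect(br$S1, gs$taxa)
    s2 <- intersect(br$S2, gs$taxa)
    y1 <- intersect(br$Y1, gs$taxa)
    y2 <- intersect(br$Y2, gs$taxa)
    cls <- if (!length(s1) || !length(s2) || !length(y1) || !length(y2)) {
      "other"
    } else {
      switch(
        classify_quartet_split(gs, c(s1, s2), c(s1, y1), c(s1, y2)),
        concord = "concordant", nni1 = "gD1", nni2 = "gD2", para = "other"
      )
    }
    tibble::tibble(gene_id = gene_id, class = cls)
  })
}
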