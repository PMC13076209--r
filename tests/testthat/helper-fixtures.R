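# Small fixtures built in code, shared across test files.

tree_from_text <- function(text) {
  ogcurator:::as_gene_tree(ape::read.tree(text = text))
}

# 4-taxon alignment with known column classes
tiny_alignment <- function() {
  aa_alignment(c(
    t1 = "AAKLMG",
    t2 = "AAKLMG",
    t3 = "ACKIMG",
    t4 = "ACKI-G"
  ), id = "OGtiny")
}

random_alignment <- function(n_taxa, n_col, seed, p_gap = 0.1) {
  set.seed(seed)
  symbols <- c(ogcurator:::AA_ALPHABET, "-", "X")
  probs <- c(rep((1 - p_gap) / 20, 20), p_gap * 0.8, p_gap * 0.2)
  mat <- matrix(
    sample(symbols, n_taxa * n_col, replace = TRUE, prob = probs),
    nrow = n_taxa,
    dimnames = list(paste0("s", seq_len(n_taxa)), NULL)
  )
  aa_alignment(mat, id = paste0("rand", seed))
}

# Independent brute-force column classifier used as the oracle for
# parsimony-informative counting: counts states with rle() on sorted
# residues, a different route from the implementation's table().
oracle_site_counts <- function(aln) {
  m <- unclass(aln)
  variable <- 0L
  informative <- 0L
  for (j in seq_len(ncol(m))) {
    res <- m[, j]
    res <- res[res != "-" & res != "X"]
    if (length(res) < 2L) next
    runs <- rle(sort(res))
    if (length(runs$values) >= 2L) {
      variable <- variable + 1L
      if (sum(runs$lengths >= 2L) >= 2L) informative <- informative + 1L
    }
  }
  c(variable = variable, informative = informative)
}

# Independent concordance oracle: decide which resolution a full-taxon
# binary gene tree displays at a branch, via rooted monophyly checks.
oracle_branch_class <- function(gene_tree, side_c, side_1, side_2) {
  shows <- function(side) {
    others <- setdiff(gene_tree$tip.label, side)
    rooted <- ape::root(gene_tree, outgroup = others[1L], resolve.root = TRUE)
    ape::is.monophyletic(rooted, side)
  }
  if (shows(side_c)) return("concord")
  if (shows(side_1)) return("nni1")
  if (shows(side_2)) return("nni2")
  "para"
}

# residue matrix without the id attribute, for content comparisons
aln_chars <- function(aln) {
  x <- unclass(aln)
  attr(x, "id") <- NULL
  x
}
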