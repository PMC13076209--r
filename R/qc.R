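#' Define a clan
#'
#' A clan is the unrooted analogue of a monophyletic group: a set of taxa
#' that must sit on one side of some branch of the (unrooted) gene tree.
#' Typical use: each taxonomic order with more than one sampled species is
#' declared a clan, sharing one outgroup set.
#'
#' @param name Clan label.
#' @param members Character vector of taxon labels (non-empty).
#' @param outgroup Character vector of outgroup labels (disjoint from
#'   `members`).
#' @return A `clan_definition` list.
#' @export
clan_definition <- function(name, members, outgroup = character()) {
  members <- unique(as.character(members))
  outgroup <- unique(as.character(outgroup))
  if (length(members) == 0L) abort("clan members must be non-empty")
  if (length(intersect(members, outgroup)) > 0L) {
    abort("clan members and outgroup must be disjoint")
  }
  structure(
    list(name = name, members = members, outgroup = outgroup),
    class = "clan_definition"
  )
}

#' Read clan definitions and outgroup from a YAML config
#'
#' Expected layout:
#' ```yaml
#' outgroup: [Ovul, Vinf]
#' clans:
#'   Oegopsida: [Tpac, Dgig]
#'   Sepiida: [Aesc, Soff]
#' ```
#'
#' @param path YAML file path.
#' @return List with `clans` (list of [clan_definition()]) and `outgroup`.
#' @export
read_clan_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  outgroup <- as.character(cfg$outgroup %||% character())
  clans <- purrr::imap(cfg$clans, function(members, nm) {
    clan_definition(nm, members, outgroup)
  })
  list(clans = unname(clans), outgroup = outgroup)
}

#' Screen a gene tree for long terminal branches
#'
#' Excludes a gene when any *terminal* branch not leading to an outgroup
#' taxon is `ratio` times or longer than the median branch length of the
#' entire tree (all branches, terminal and internal; threshold inclusive).
#' With a zero median: if every branch is zero the tree carries no signal
#' and is retained; if some non-outgroup terminal is positive the ratio is
#' unbounded and the gene is excluded with reason `"degenerate median"`.
#'
#' @param tree An `ape::phylo` gene tree with branch lengths.
#' @param outgroup Taxon labels exempt from the screen (may be absent from
#'   the tree).
#' @param ratio Exclusion threshold; default 20.
#' @param gene_id Identifier copied into the verdict.
#' @return One-row verdict tibble: `gene_id`, `stage`, `decision`,
#'   `reason`, `statistic` (the maximum terminal-branch/median ratio).
#' @export
long_branch_filter <- function(tree, outgroup = character(), ratio = 20,
                               gene_id = NA_character_) {
  assert_phylo(tree)
  stopifnot(ratio > 0)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  nt <- length(tree$tip.label)
  term <- tree$edge[, 2L] <= nt
  term_len <- tree$edge.length[term]
  term_tax <- tree$tip.label[tree$edge[term, 2L]]
  ingroup <- !(term_tax %in% outgroup)
  med <- stats::median(tree$edge.length)
  verdict <- function(decision, reason, statistic) {
    tibble::tibble(
      gene_id = gene_id, stage = "long_branch",
      decision = decision, reason = reason, statistic = statistic
    )
  }
  if (!any(ingroup)) {
    return(verdict("retain", "no ingroup terminals", 0))
  }
  max_len <- max(term_len[ingroup])
  if (med == 0) {
    if (max_len > 0) {
      return(verdict("exclude", "degenerate median", Inf))
    }
    return(verdict("retain", "all branch lengths zero", 0))
  }
  max_ratio <- max_len / med
  if (max_ratio >= ratio) {
    verdict(
      "exclude",
      sprintf("terminal branch %.3g x median (threshold %g)", max_ratio, ratio),
      max_ratio
    )
  } else {
    verdict("retain", "no long terminal branch", max_ratio)
  }
}

#' Check one clan against a gene tree
#'
#' Evaluated in the unrooted sense: the clan is *satisfied* when no branch
#' bipartition of the tree is incompatible with it (for a binary tree this
#' is exactly "the clan members form one side of some branch"). A
#' bipartition is incompatible when clan members sit on both of its sides
#' and non-members are mixed among them on both sides. Otherwise the
#' verdict is `strong_violation` when some incompatible branch carries
#' support above `support_threshold` -- equivalently, the clan is still not
#' realizable after collapsing all weakly supported branches -- and
#' `weak_violation` when every conflicting branch is weak (support
#' `<= support_threshold`; missing support counts as 0).
#'
#' Clan members missing from the tree: if all are absent the call errors;
#' if some are absent they are dropped with a warning and the present
#' subset is evaluated; fewer than two present members is vacuously
#' satisfied.
#'
#' @param tree An `ape::phylo` gene tree with supports (see
#'   [read_newick()]).
#' @param clan A [clan_definition()].
#' @param support_threshold Inclusive weakness threshold; default 50
#'   (exclusion requires support strictly above it).
#' @param gene_id Identifier copied into the verdict.
#' @return One-row tibble: `gene_id`, `clan`, `status`,
#'   `max_conflicting_support` (`NA` when satisfied).
#' @export
clan_check <- function(tree, clan, support_threshold = 50,
                       gene_id = NA_character_) {
  assert_phylo(tree)
  tree <- as_gene_tree_if_needed(tree)
  members <- clan$members
  present <- intersect(members, tree$tip.label)
  if (length(present) == 0L) {
    abort(paste0(
      "all clan members absent from tree: ",
      paste(members, collapse = ", ")
    ))
  }
  if (length(present) < length(members)) {
    warn(paste0(
      "clan '", clan$name, "' members missing from tree: ",
      paste(setdiff(members, present), collapse = ", ")
    ))
  }
  result <- function(status, max_supp) {
    tibble::tibble(
      gene_id = gene_id, clan = clan$name, status = status,
      max_conflicting_support = max_supp
    )
  }
  if (length(present) < 2L) return(result("satisfied", NA_real_))
  conflicting <- numeric()
  for (b in tree_bipartitions(tree)) {
    x <- b$tips
    a_in <- length(intersect(present, x))
    b_in <- length(present) - a_in
    x_only <- length(x) - a_in
    y_only <- length(tree$tip.label) - length(x) - b_in
    if (a_in > 0L && b_in > 0L && x_only > 0L && y_only > 0L) {
      conflicting <- c(conflicting, if (is.na(b$support)) 0 else b$support)
    }
  }
  if (length(conflicting) == 0L) return(result("satisfied", NA_real_))
  status <- if (max(conflicting) > support_threshold) {
    "strong_violation"
  } else {
    "weak_violation"
  }
  result(status, max(conflicting))
}

#' Run the gene-tree quality cascade
#'
#' Applies the long-terminal-branch screen to every gene, then the clan
#' check to the survivors (short-circuit: a gene excluded for its branch
#' lengths gets no clan verdict). A gene is excluded at the clan stage when
#' *any* clan yields a strong violation; weak violations are retained on
#' the benefit of the doubt. Gene order is preserved.
#'
#' @param genes A tibble with columns `gene_id` and `tree` (list-column of
#'   `ape::phylo`), or a named list of trees.
#' @param clans List of [clan_definition()].
#' @param outgroup Character vector of outgroup taxa.
#' @param ratio Long-branch threshold (default 20).
#' @param support_threshold Clan-violation support threshold (default 50).
#' @return A tibble of per-gene, per-stage verdicts: `gene_id`, `stage`,
#'   `decision`, `reason`, `statistic`.
#' @export
qc_cascade <- function(genes, clans, outgroup = character(),
                       ratio = 20, support_threshold = 50) {
  genes <- as_gene_table(genes)
  if (nrow(genes) == 0L) {
    return(tibble::tibble(
      gene_id = character(), stage = character(), decision = character(),
      reason = character(), statistic = double()
    ))
  }
  purrr::pmap_dfr(genes, function(gene_id, tree, ...) {
    lb <- long_branch_filter(tree, outgroup, ratio, gene_id = gene_id)
    if (lb$decision == "exclude") return(lb)
    verdicts <- purrr::map_dfr(
      clans,
      function(cl) clan_check(tree, cl, support_threshold, gene_id = gene_id)
    )
    strong <- dplyr::filter(verdicts, .data$status == "strong_violation")
    cc <- if (nrow(strong) > 0L) {
      tibble::tibble(
        gene_id = gene_id, stage = "clan_check", decision = "exclude",
        reason = paste0(
          "strong violation of clan(s): ",
          paste(strong$clan, collapse = ", ")
        ),
        statistic = max(strong$max_conflicting_support)
      )
    } else {
      weak <- dplyr::filter(verdicts, .data$status == "weak_violation")
      tibble::tibble(
        gene_id = gene_id, stage = "clan_check", decision = "retain",
        reason = if (nrow(weak) > 0L) {
          paste0(
            "weak violation only (retained): ",
            paste(weak$clan, collapse = ", ")
          )
        } else {
          "all clans satisfied"
        },
        statistic = if (nrow(weak) > 0L) {
          max(weak$max_conflicting_support)
        } else {
          NA_real_
        }
      )
    }
    dplyr::bind_rows(lb, cc)
  })
}

as_gene_table <- function(genes) {
  if (inherits(genes, "data.frame")) {
    stopifnot(all(c("gene_id", "tree") %in% names(genes)))
    return(tibble::as_tibble(genes[, c("gene_id", "tree")]))
  }
  if (is.list(genes)) {
    if (length(genes) == 0L) {
      return(tibble::tibble(gene_id = character(), tree = list()))
    }
    if (is.null(names(genes))) abort("gene list must be named by gene id")
    return(tibble::tibble(gene_id = names(genes), tree = unname(genes)))
  }
  abort("`genes` must be a tibble or a named list of trees")
}
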