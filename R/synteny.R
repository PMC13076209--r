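#' Read an ortholog chromosome-assignment table
#'
#' Tab-separated with header `gene_id, species, chromosome, start_bp,
#' og_id`; positions are 1-based. `(gene_id, species)` pairs must be
#' unique.
#'
#' @param path TSV path.
#' @return A tibble with those five columns.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.table(
    path, header = TRUE, sep = "\t",
    colClasses = c("character", "character", "character", "integer", "character"),
    stringsAsFactors = FALSE
  )
  need <- c("gene_id", "species", "chromosome", "start_bp", "og_id")
  if (!all(need %in% names(df))) {
    abort(paste0(
      "ortholog table must have columns: ", paste(need, collapse = ", ")
    ))
  }
  df <- tibble::as_tibble(df[need])
  if (anyDuplicated(df[c("gene_id", "species")])) {
    abort("duplicate (gene_id, species) rows in ortholog table")
  }
  if (any(df$start_bp < 1L)) abort("positions must be >= 1 (1-based)")
  df
}

# one-to-one OGs between two species: og appears exactly once in each
one_to_one_ogs <- function(table, species_a, species_b) {
  for (sp in c(species_a, species_b)) {
    if (!sp %in% table$species) abort(paste0("species absent: ", sp))
  }
  keep_single <- function(df) {
    df |>
      dplyr::add_count(.data$og_id, name = "..n") |>
      dplyr::filter(.data$..n == 1L) |>
      dplyr::select(-"..n")
  }
  a <- keep_single(dplyr::filter(table, .data$species == species_a))
  b <- keep_single(dplyr::filter(table, .data$species == species_b))
  dplyr::inner_join(
    dplyr::select(a,
      og_id = "og_id", chr_a = "chromosome", pos_a = "start_bp"
    ),
    dplyr::select(b,
      og_id = "og_id", chr_b = "chromosome", pos_b = "start_bp"
    ),
    by = "og_id"
  )
}

#' Contingency table for one chromosome pair
#'
#' Over the one-to-one orthologs shared by two species: `a` = orthologs on
#' both `chr_a` (species A) and `chr_b` (species B); `b` = on `chr_a` but
#' not `chr_b`; `c` = on `chr_b` but not `chr_a`; `d` = on neither.
#'
#' @param table Ortholog table (see [read_ortholog_table()]).
#' @param species_a,species_b Species labels.
#' @param chr_a,chr_b Chromosome labels in species A / B.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
build_contingency <- function(table, species_a, species_b, chr_a, chr_b) {
  oo <- one_to_one_ogs(table, species_a, species_b)
  on_a <- oo$chr_a == chr_a
  on_b <- oo$chr_b == chr_b
  c(
    a = sum(on_a & on_b), b = sum(on_a & !on_b),
    c = sum(!on_a & on_b), d = sum(!on_a & !on_b)
  )
}

#' One-sided Fisher exact p-value (enrichment)
#'
#' The upper hypergeometric tail `P(X >= a)` for a 2x2 table
#' `(a, b, c, d)` -- the probability, under random assortment of the
#' `a+b+c+d` orthologs, of seeing `a` or more shared between the two
#' chromosomes. An all-zero table gives `p = 1`.
#'
#' @param counts Named or positional integer vector `(a, b, c, d)`.
#' @return p-value in (0, 1\].
#' @export
fisher_exact_greater <- function(counts) {
  stopifnot(length(counts) == 4L, all(counts >= 0))
  a <- counts[[1L]]; b <- counts[[2L]]; c_ <- counts[[3L]]; d <- counts[[4L]]
  if (a + b + c_ + d == 0L) return(1)
  stats::phyper(a - 1, a + b, c_ + d, a + c_, lower.tail = FALSE)
}

#' Detect significant macrosynteny blocks between two genomes
#'
#' Tests every chromosome pair sharing at least one one-to-one ortholog
#' with the one-sided Fisher exact test, applies Benjamini--Hochberg
#' correction across all tested pairs, and flags pairs with adjusted
#' `p <= alpha` as conserved blocks. Gene order within chromosomes is
#' ignored (macro-, not micro-synteny).
#'
#' @param table Ortholog table.
#' @param species_a,species_b Species labels.
#' @param alpha Significance level on the adjusted p-value; default 0.05.
#' @return Tibble: `chr_a`, `chr_b`, `n_shared`, `a`, `b`, `c`, `d`,
#'   `p_value`, `p_adj`, `significant`.
#' @export
significant_blocks <- function(table, species_a, species_b, alpha = 0.05) {
  oo <- one_to_one_ogs(table, species_a, species_b)
  if (nrow(oo) == 0L) abort("no one-to-one orthologs between the species")
  total <- nrow(oo)
  counts <- dplyr::count(oo, .data$chr_a, .data$chr_b, name = "a")
  a_tot <- dplyr::count(oo, .data$chr_a, name = "n_a")
  b_tot <- dplyr::count(oo, .data$chr_b, name = "n_b")
  blocks <- counts |>
    dplyr::left_join(a_tot, by = "chr_a") |>
    dplyr::left_join(b_tot, by = "chr_b") |>
    dplyr::mutate(
      b = .data$n_a - .data$a,
      c = .data$n_b - .data$a,
      d = total - .data$a - .data$b - .data$c
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      p_value = fisher_exact_greater(c(.data$a, .data$b, .data$c, .data$d))
    ) |>
    dplyr::ungroup()
  blocks |>
    dplyr::mutate(
      p_adj = stats::p.adjust(.data$p_value, method = "BH"),
      significant = .data$p_adj <= alpha,
      n_shared = .data$a
    ) |>
    dplyr::select(
      "chr_a", "chr_b", "n_shared", "a", "b", "c", "d",
      "p_value", "p_adj", "significant"
    ) |>
    dplyr::arrange(.data$chr_a, .data$chr_b)
}

#' Call chromosome-scale rearrangement events from synteny blocks
#'
#' Builds the bipartite linkage graph of significant blocks and labels
#' each connected component: one A chromosome linked to exactly one B
#' chromosome is `one_to_one`; one B chromosome absorbing two or more A
#' chromosomes is a `fusion` (in the B genome); one A chromosome split
#' over two or more B chromosomes is a `fission`; anything more tangled is
#' a `translocation_candidate`.
#'
#' @param blocks Output of [significant_blocks()].
#' @return List with `karyotype` (tibble: `genome`, `n_chromosomes`,
#'   counted over linked chromosomes) and `events` (tibble: `event`,
#'   `chrs_a`, `chrs_b`).
#' @export
call_karyotype_events <- function(blocks) {
  sig <- dplyr::filter(blocks, .data$significant)
  if (nrow(sig) == 0L) {
    return(list(
      karyotype = tibble::tibble(
        genome = c("A", "B"), n_chromosomes = c(0L, 0L)
      ),
      events = tibble::tibble(
        event = character(), chrs_a = character(), chrs_b = character()
      )
    ))
  }
  # connected components of the bipartite chromosome graph
  nodes_a <- unique(sig$chr_a)
  nodes_b <- unique(sig$chr_b)
  comp <- setNames(seq_along(c(nodes_a, nodes_b)),
                   c(paste0("A:", nodes_a), paste0("B:", nodes_b)))
  # union-find over chromosome nodes
  parent <- seq_along(comp)
  root_of <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- setNames(seq_along(comp), names(comp))
  for (k in seq_len(nrow(sig))) {
    i <- root_of(idx[[paste0("A:", sig$chr_a[k])]])
    j <- root_of(idx[[paste0("B:", sig$chr_b[k])]])
    if (i != j) parent[j] <- i
  }
  roots <- vapply(seq_along(comp), root_of, integer(1))
  events <- purrr::map_dfr(unique(roots), function(r) {
    members <- names(comp)[roots == r]
    ca <- sub("^A:", "", members[startsWith(members, "A:")])
    cb <- sub("^B:", "", members[startsWith(members, "B:")])
    event <- if (length(ca) == 1L && length(cb) == 1L) {
      "one_to_one"
    } else if (length(ca) >= 2L && length(cb) == 1L) {
      "fusion"
    } else if (length(ca) == 1L && length(cb) >= 2L) {
      "fission"
    } else {
      "translocation_candidate"
    }
    tibble::tibble(
      event = event,
      chrs_a = paste(sort(ca), collapse = "+"),
      chrs_b = paste(sort(cb), collapse = "+")
    )
  })
  list(
    karyotype = tibble::tibble(
      genome = c("A", "B"),
      n_chromosomes = c(length(nodes_a), length(nodes_b))
    ),
    events = dplyr::arrange(events, .data$event, .data$chrs_a)
  )
}

#' Export dot-plot coordinates for a species pair
#'
#' One row per one-to-one ortholog with its chromosome and position in
#' each genome -- the raw material of an Oxford dot plot.
#'
#' @param table Ortholog table.
#' @param species_a,species_b Species labels.
#' @return Tibble: `og_id`, `chr_a`, `pos_a`, `chr_b`, `pos_b`.
#' @export
synteny_dotplot_data <- function(table, species_a, species_b) {
  one_to_one_ogs(table, species_a, species_b)
}
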