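#' Saturation regression slope for one gene
#'
#' For every ingroup taxon pair the gene's alignment yields an observed
#' difference proportion, hence a percent identity and a Poisson-corrected
#' distance. The saturation statistic is the OLS slope of identity (%,
#' response) on corrected distance (predictor) over those pairs. Fast,
#' multiply-hit genes flatten towards 0 (identity stops responding to
#' distance); clean, diverse genes have strongly negative slopes. Pairs
#' involving outgroup taxa are excluded, as are saturated pairs
#' (`p >= 19/20`) and pairs with no comparable columns (both counted in
#' `n_dropped`).
#'
#' @param aln An [aa_alignment()].
#' @param outgroup Taxon labels excluded from all pairs.
#' @param gene_id Identifier; defaults to the alignment's id.
#' @return One-row tibble: `gene_id`, `slope` (`NA` when fewer than two
#'   usable pairs or zero distance variance), `n_pairs`, `n_dropped`,
#'   `retained` (`NA`, filled by [retain_by_slope()]).
#' @export
saturation_slope <- function(aln, outgroup = character(), gene_id = NULL) {
  gene_id <- gene_id %||% aln_id(aln)
  ingroup <- setdiff(rownames(aln), outgroup)
  pairs <- if (length(ingroup) >= 2L) utils::combn(ingroup, 2L) else NULL
  d <- numeric()
  idpc <- numeric()
  dropped <- 0L
  if (!is.null(pairs)) {
    for (k in seq_len(ncol(pairs))) {
      cm <- comparable_mask(aln, pairs[1L, k], pairs[2L, k])
      if (cm$n == 0L) {
        dropped <- dropped + 1L
        next
      }
      p <- 1 - sum(cm$a == cm$b) / cm$n
      if (p >= 19 / 20) {
        dropped <- dropped + 1L
        next
      }
      d <- c(d, poisson_correct(p))
      idpc <- c(idpc, 100 * (1 - p))
    }
  }
  slope <- NA_real_
  if (length(d) >= 2L && stats::var(d) > 0) {
    # closed-form two-variable OLS; lm() is the cross-check in the tests
    slope <- sum((d - mean(d)) * (idpc - mean(idpc))) / sum((d - mean(d))^2)
  }
  tibble::tibble(
    gene_id = gene_id, slope = slope,
    n_pairs = length(d), n_dropped = dropped, retained = NA
  )
}

#' Retain the least saturated half of the genes
#'
#' Sorts genes with a defined slope ascending (most negative = least
#' saturated first, ties broken by gene id, lexicographic) and retains the
#' first `floor(fraction * m)` of the `m` defined-slope genes. Undefined
#' slopes are never retained.
#'
#' @param records Tibble of saturation records (from [saturation_slope()],
#'   row-bound across genes).
#' @param fraction Retention fraction; default 0.5.
#' @return `records` with the `retained` flag filled, original row order.
#' @export
retain_by_slope <- function(records, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  defined <- records[!is.na(records$slope), ]
  if (nrow(defined) == 0L) abort("no gene has a defined slope")
  ord <- order(defined$slope, defined$gene_id)
  n_keep <- floor(fraction * nrow(defined))
  keep_ids <- defined$gene_id[ord][seq_len(n_keep)]
  dplyr::mutate(records, retained = .data$gene_id %in% keep_ids)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Lays the genes out in input order over the union taxon set (or a
#' supplied `taxon_universe`); taxa absent from a gene are filled with
#' gaps across that gene's partition. Partition ranges are 1-based
#' inclusive.
#'
#' @param alignments List of [aa_alignment()]s with unique gene ids
#'   (attribute or list names).
#' @param taxon_universe Optional character vector fixing taxon order;
#'   every alignment's taxa must be contained in it.
#' @return A `supermatrix`: list with `alignment` ([aa_alignment()]),
#'   `partitions` (tibble `gene_id`, `start`, `end`) and `occupancy`
#'   (tibble `taxon`, `occupancy` = fraction of non-gap sites).
#' @export
concatenate_alignments <- function(alignments, taxon_universe = NULL) {
  if (length(alignments) == 0L) abort("no alignments to concatenate")
  ids <- purrr::imap_chr(alignments, function(a, i) {
    id <- aln_id(a)
    if (is.na(id) && is.character(i)) id <- i
    if (is.na(id)) abort("alignment without a gene id")
    id
  })
  if (anyDuplicated(ids)) abort("duplicate gene ids in concatenation")
  taxa <- taxon_universe %||% unique(unlist(lapply(alignments, rownames)))
  extra <- setdiff(unique(unlist(lapply(alignments, rownames))), taxa)
  if (length(extra) > 0L) {
    abort(paste0("taxa outside the universe: ", paste(extra, collapse = ", ")))
  }
  lens <- vapply(alignments, ncol, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  total <- sum(lens)
  mat <- matrix(GAP_CHAR, nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  for (g in seq_along(alignments)) {
    a <- unclass(alignments[[g]])
    mat[rownames(a), starts[g]:ends[g]] <- a
  }
  occupancy <- rowMeans(mat != GAP_CHAR)
  structure(
    list(
      alignment = aa_alignment(mat, id = "supermatrix"),
      partitions = tibble::tibble(gene_id = ids, start = starts, end = ends),
      occupancy = tibble::tibble(taxon = taxa, occupancy = unname(occupancy))
    ),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf(
    "<supermatrix: %d taxa x %d sites, %d partitions>\n",
    nrow(x$alignment), ncol(x$alignment), nrow(x$partitions)
  ))
  invisible(x)
}

#' Extract one gene's alignment back out of a supermatrix
#'
#' Returns the partition's columns restricted to taxa with at least one
#' non-gap site in it (i.e. the taxa the gene originally had, provided no
#' input row was all-gap).
#'
#' @param sm A `supermatrix`.
#' @param gene_id Partition to extract.
#' @return An [aa_alignment()].
#' @export
extract_partition <- function(sm, gene_id) {
  p <- sm$partitions[sm$partitions$gene_id == gene_id, ]
  if (nrow(p) == 0L) abort(paste0("no partition named ", gene_id))
  block <- unclass(sm$alignment)[, p$start:p$end, drop = FALSE]
  keep <- rowSums(block != GAP_CHAR) > 0L
  aa_alignment(block[keep, , drop = FALSE], id = gene_id)
}

#' @describeIn concatenate_alignments `tidy()` returns the partition map.
#' @method tidy supermatrix
#' @param x A `supermatrix`.
#' @param ... Unused.
#' @export
tidy.supermatrix <- function(x, ...) {
  dplyr::mutate(x$partitions, length = .data$end - .data$start + 1L)
}

#' @describeIn concatenate_alignments `glance()` returns a one-row summary
#'   (taxa, sites, partitions, variable/informative sites, mean occupancy).
#' @method glance supermatrix
#' @export
glance.supermatrix <- function(x, ...) {
  counts <- count_parsimony_informative(x$alignment)
  tibble::tibble(
    n_taxa = nrow(x$alignment),
    n_sites = ncol(x$alignment),
    n_partitions = nrow(x$partitions),
    variable_sites = counts$variable_sites,
    informative_sites = counts$informative_sites,
    mean_occupancy = mean(x$occupancy$occupancy)
  )
}

#' Write a RAxML-style partition file
#'
#' One line per partition, `MODEL, name = start-end`, ranges 1-based
#' inclusive. The ranges must be disjoint, contiguous and cover `1..L`.
#'
#' @param partitions Tibble with `gene_id`, `start`, `end` (e.g.
#'   `tidy(sm)` or `sm$partitions`).
#' @param path Output path.
#' @param model Substitution-model token written before each name.
#' @return `path`, invisibly.
#' @export
write_partition_file <- function(partitions, path, model = "LG") {
  p <- dplyr::arrange(tibble::as_tibble(partitions), .data$start)
  if (nrow(p) == 0L) abort("no partitions")
  expected_start <- c(1L, p$end[-nrow(p)] + 1L)
  if (any(p$start != expected_start) || any(p$end < p$start)) {
    abort("partitions must be disjoint, contiguous and cover 1..L")
  }
  writeLines(
    sprintf("%s, %s = %d-%d", model, p$gene_id, p$start, p$end),
    path
  )
  invisible(path)
}
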