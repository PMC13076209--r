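#' Run the full orthogroup curation cascade
#'
#' Stage order: long-terminal-branch screen, clan-monophyly check on the
#' survivors, gap-column trimming, saturation-slope ranking with the
#' retention cut, concatenation of the retained genes into a partitioned
#' supermatrix, and site counting. Each stage only ever shrinks the
#' retained set. Thresholds default to the cascade's canonical values
#' (branch ratio 20, support 50, gap fraction 0.5, retention fraction
#' 0.5); the saturation cut applies to the post-screening survivors.
#'
#' @param genes A tibble with `gene_id`, `tree` and `alignment`
#'   list-columns (e.g. `make_benchmark()$genes`), or an `og_benchmark`.
#' @param clans List of [clan_definition()]s (taken from the benchmark if
#'   one is supplied).
#' @param outgroup Outgroup taxa.
#' @param ratio Long-branch threshold.
#' @param support_threshold Clan-violation support threshold.
#' @param max_gap_fraction Gap-trimming threshold.
#' @param retention_fraction Saturation retention fraction.
#' @param out_dir Optional directory: writes `supermatrix.faa`,
#'   `partitions.txt`, `qc_verdicts.tsv`, `saturation.tsv`,
#'   `summary.json`.
#' @return A `curation_run`: list with `verdicts` (QC tibble),
#'   `saturation` (records tibble), `supermatrix`, and `summary` (named
#'   list of per-stage counts and matrix statistics).
#' @export
run_pipeline <- function(genes, clans = NULL, outgroup = NULL,
                         ratio = 20, support_threshold = 50,
                         max_gap_fraction = 0.5, retention_fraction = 0.5,
                         out_dir = NULL) {
  if (inherits(genes, "og_benchmark")) {
    clans <- clans %||% genes$clans
    outgroup <- outgroup %||% genes$outgroup
    genes <- genes$genes
  }
  outgroup <- outgroup %||% character()
  if (nrow(genes) == 0L) abort("no input genes")
  stopifnot(all(c("gene_id", "tree", "alignment") %in% names(genes)))

  verdicts <- qc_cascade(
    genes, clans, outgroup,
    ratio = ratio, support_threshold = support_threshold
  )
  excluded <- unique(verdicts$gene_id[verdicts$decision == "exclude"])
  survivors <- dplyr::filter(genes, !.data$gene_id %in% excluded)
  if (nrow(survivors) == 0L) abort("no gene survived the QC cascade")

  trimmed <- purrr::map(
    survivors$alignment, trim_gapped_columns,
    max_gap_fraction = max_gap_fraction
  )
  sat <- purrr::map2_dfr(
    trimmed, survivors$gene_id,
    function(a, id) saturation_slope(a, outgroup, gene_id = id)
  )
  sat <- retain_by_slope(sat, fraction = retention_fraction)
  kept_ids <- sat$gene_id[sat$retained]
  kept_alns <- trimmed[match(kept_ids, survivors$gene_id)]
  sm <- concatenate_alignments(kept_alns)
  counts <- count_parsimony_informative(sm$alignment)

  summary <- list(
    n_input = nrow(genes),
    n_after_long_branch = nrow(genes) - sum(
      verdicts$stage == "long_branch" & verdicts$decision == "exclude"
    ),
    n_after_clan_check = nrow(survivors),
    n_retained = length(kept_ids),
    supermatrix_sites = counts$n_sites,
    variable_sites = counts$variable_sites,
    informative_sites = counts$informative_sites,
    thresholds = list(
      ratio = ratio, support_threshold = support_threshold,
      max_gap_fraction = max_gap_fraction,
      retention_fraction = retention_fraction
    )
  )
  run <- structure(
    list(
      verdicts = verdicts, saturation = sat,
      supermatrix = sm, summary = summary
    ),
    class = "curation_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta_alignment(
      sm$alignment, file.path(out_dir, "supermatrix.faa")
    )
    write_partition_file(sm$partitions, file.path(out_dir, "partitions.txt"))
    utils::write.table(
      verdicts, file.path(out_dir, "qc_verdicts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(
      sat, file.path(out_dir, "saturation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    jsonlite::write_json(
      summarize_run(run), file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  run
}

#' Machine-readable summary of a curation run
#'
#' Stable key order; echoes the thresholds verbatim and reports the
#' per-stage gene counts and supermatrix statistics.
#'
#' @param run A `curation_run` from [run_pipeline()].
#' @return A named list (serialize with `jsonlite::write_json`).
#' @export
summarize_run <- function(run) {
  if (!inherits(run, "curation_run")) abort("not a curation_run")
  s <- run$summary
  list(
    package_version = as.character(utils::packageVersion("ogcurator")),
    thresholds = s$thresholds,
    counts = list(
      n_input = s$n_input,
      n_after_long_branch = s$n_after_long_branch,
      n_after_clan_check = s$n_after_clan_check,
      n_retained = s$n_retained
    ),
    supermatrix = list(
      sites = s$supermatrix_sites,
      variable_sites = s$variable_sites,
      informative_sites = s$informative_sites
    )
  )
}

#' @export
print.curation_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<curation_run: %d genes in -> %d after long-branch -> %d after ",
      "clan check -> %d retained; supermatrix %d sites ",
      "(%d variable, %d informative)>\n"
    ),
    s$n_input, s$n_after_long_branch, s$n_after_clan_check, s$n_retained,
    s$supermatrix_sites, s$variable_sites, s$informative_sites
  ))
  invisible(x)
}

#' @describeIn run_pipeline `tidy()` returns the per-gene verdict table
#' @method tidy curation_run
#'   joined with saturation records.
#' @param x A `curation_run`.
#' @param ... Unused.
#' @export
tidy.curation_run <- function(x, ...) {
  dplyr::bind_rows(
    x$verdicts,
    x$saturation |>
      dplyr::transmute(
        gene_id = .data$gene_id, stage = "saturation",
        decision = ifelse(.data$retained, "retain", "exclude"),
        reason = dplyr::case_when(
          is.na(.data$slope) ~ "undefined slope",
          .data$retained ~ "top fraction of lowest slopes",
          TRUE ~ "above the slope cut"
        ),
        statistic = .data$slope
      )
  )
}

#' @describeIn run_pipeline `glance()` returns the one-row run summary.
#' @method glance curation_run
#' @export
glance.curation_run <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_input = s$n_input,
    n_after_long_branch = s$n_after_long_branch,
    n_after_clan_check = s$n_after_clan_check,
    n_retained = s$n_retained,
    supermatrix_sites = s$supermatrix_sites,
    variable_sites = s$variable_sites,
    informative_sites = s$informative_sites
  )
}
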