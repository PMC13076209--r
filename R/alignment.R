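#' Amino-acid multiple alignment container
#'
#' A thin wrapper around a character matrix: one row per taxon (rownames are
#' the taxon labels, input order preserved), one column per alignment site.
#' Legal symbols are the 20 amino acids, the gap `"-"` and the ambiguity
#' `"X"`. Gap and `"X"` are never counted as residue states by any
#' downstream statistic.
#'
#' @param x Character matrix of single residues with unique rownames, or a
#'   named character vector of equal-length sequence strings.
#' @param id Optional orthogroup identifier carried as an attribute.
#' @return An object of class `aa_alignment` (a character matrix).
#' @examples
#' aln <- aa_alignment(c(t1 = "MKL-", t2 = "MKLX"), id = "OG0001")
#' dim(aln)
#' @export
aa_alignment <- function(x, id = NULL) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) abort("sequence vector must be named by taxon")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      abort("alignment rows have unequal lengths (ragged alignment)")
    }
    mat <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(mat) <- names(x)
    x <- mat
  }
  if (!is.matrix(x) || !is.character(x)) {
    abort("`x` must be a character matrix or named character vector")
  }
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    abort("taxon labels must be present and unique")
  }
  if (ncol(x) < 1L) abort("alignment must have at least one column")
  bad <- setdiff(unique(as.vector(x)), c(AA_ALPHABET, GAP_CHAR, AMBIG_CHAR))
  if (length(bad) > 0L) {
    abort(paste0(
      "illegal alignment symbols: ", paste(bad, collapse = ", ")
    ))
  }
  structure(x, id = id, class = c("aa_alignment", "matrix", "array"))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf(
    "<aa_alignment%s: %d taxa x %d sites>\n",
    if (!is.null(attr(x, "id"))) paste0(" ", attr(x, "id")) else "",
    nrow(x), ncol(x)
  ))
  invisible(x)
}

aln_id <- function(aln) attr(aln, "id") %||% NA_character_

#' Read an aligned FASTA file
#'
#' Reads a protein FASTA alignment into an [aa_alignment()]. Input taxon
#' order is preserved. Ragged rows, duplicate labels and empty files are
#' format errors, not warnings.
#'
#' @param path Path to a FASTA file with at least two records.
#' @param id Orthogroup id; defaults to the file name without extension.
#' @return An [aa_alignment()].
#' @export
read_fasta_alignment <- function(path, id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("empty FASTA file")
  starts <- grep("^>", lines)
  if (length(starts) < 2L) abort("FASTA alignment needs >= 2 records")
  if (starts[1] != 1L) abort("malformed FASTA: leading sequence data")
  labels <- sub("^>\\s*", "", lines[starts])
  labels <- vapply(strsplit(labels, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(labels)) abort("duplicate taxon labels in FASTA")
  ends <- c(starts[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(starts), function(i) {
    if (ends[i] < starts[i] + 1L) return("")
    paste(lines[(starts[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  if (any(!nzchar(seqs))) abort("FASTA record with no sequence data")
  if (length(unique(nchar(seqs))) != 1L) {
    abort("alignment rows have unequal lengths (ragged alignment)")
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  aa_alignment(setNames(seqs, labels), id = id)
}

#' Write an alignment as FASTA
#'
#' @param aln An [aa_alignment()] (or any character matrix with rownames).
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, width = 60L) {
  seqs <- apply(aln, 1L, paste, collapse = "")
  out <- unlist(lapply(names(seqs), function(lab) {
    s <- seqs[[lab]]
    chunks <- substring(
      s, seq(1L, nchar(s), by = width),
      pmin(seq(1L, nchar(s), by = width) + width - 1L, nchar(s))
    )
    c(paste0(">", lab), chunks)
  }))
  writeLines(out, path)
  invisible(path)
}

#' Drop gap-rich alignment columns
#'
#' Removes every column in which the gap fraction reaches
#' `max_gap_fraction`: a column is dropped when
#' `gaps / n_taxa >= max_gap_fraction` (so with the default 0.5, a column
#' gapped in half or more of the taxa goes). Row order is untouched. The
#' ambiguity symbol `"X"` is not a gap.
#'
#' @param aln An [aa_alignment()].
#' @param max_gap_fraction Threshold in (0, 1]; default 0.5.
#' @return The trimmed [aa_alignment()] (possibly with zero columns, with a
#'   warning).
#' @export
trim_gapped_columns <- function(aln, max_gap_fraction = 0.5) {
  stopifnot(max_gap_fraction > 0, max_gap_fraction <= 1)
  gap_frac <- colMeans(unclass(aln) == GAP_CHAR)
  keep <- gap_frac < max_gap_fraction
  out <- unclass(aln)[, keep, drop = FALSE]
  if (ncol(out) == 0L) {
    warn(sprintf(
      "all %d columns removed by gap trimming (gene %s)",
      ncol(aln), aln_id(aln)
    ))
    return(structure(out,
      id = attr(aln, "id"),
      class = c("aa_alignment", "matrix", "array")
    ))
  }
  aa_alignment(out, id = attr(aln, "id"))
}

# columns where both rows carry a real residue (no gap, no 'X')
comparable_mask <- function(aln, i, j) {
  a <- unclass(aln)[i, ]
  b <- unclass(aln)[j, ]
  ok <- !(a %in% c(GAP_CHAR, AMBIG_CHAR)) & !(b %in% c(GAP_CHAR, AMBIG_CHAR))
  list(a = a[ok], b = b[ok], n = sum(ok))
}

#' Percent identity between two aligned taxa
#'
#' `100 * matches / comparable columns`, where a column is comparable when
#' both taxa carry a real residue (neither gap nor `"X"`).
#'
#' @param aln An [aa_alignment()].
#' @param taxon_i,taxon_j Taxon labels (exact, case-sensitive).
#' @return A number in \[0, 100\].
#' @export
percent_identity <- function(aln, taxon_i, taxon_j) {
  cm <- comparable_mask(aln, taxon_i, taxon_j)
  if (cm$n == 0L) {
    abort(sprintf(
      "no comparable columns between '%s' and '%s'", taxon_i, taxon_j
    ))
  }
  100 * sum(cm$a == cm$b) / cm$n
}

#' Poisson-corrected amino-acid distance
#'
#' Corrects an observed proportion of differing residues `p` for multiple
#' hits under a 20-state symmetric substitution process:
#' `d = -(19/20) * ln(1 - (20/19) * p)`. Defined for `p < 19/20`; beyond
#' that the pair is saturated and the correction diverges.
#'
#' @param aln An [aa_alignment()].
#' @param taxon_i,taxon_j Taxon labels.
#' @return Non-negative distance (substitutions/site).
#' @export
corrected_distance <- function(aln, taxon_i, taxon_j) {
  p <- 1 - percent_identity(aln, taxon_i, taxon_j) / 100
  poisson_correct(p)
}

poisson_correct <- function(p) {
  if (p >= 19 / 20) {
    abort("saturation overflow: p >= 19/20", class = "ogcurator_saturated")
  }
  -(19 / 20) * log(1 - (20 / 19) * p)
}

#' Count variable and parsimony-informative sites
#'
#' A column is *variable* when it shows at least two distinct residue
#' states; *parsimony-informative* when at least two states each occur in
#' at least two taxa. Gaps and `"X"` are not states.
#'
#' @param aln An [aa_alignment()] (a supermatrix alignment works too).
#' @return A one-row tibble with `n_sites`, `variable_sites`,
#'   `informative_sites`.
#' @export
count_parsimony_informative <- function(aln) {
  m <- unclass(aln)
  var_n <- 0L
  inf_n <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[!(col %in% c(GAP_CHAR, AMBIG_CHAR))]
    if (length(col) == 0L) next
    tab <- table(col)
    if (length(tab) >= 2L) {
      var_n <- var_n + 1L
      if (sum(tab >= 2L) >= 2L) inf_n <- inf_n + 1L
    }
  }
  tibble::tibble(
    n_sites = ncol(m),
    variable_sites = var_n,
    informative_sites = inf_n
  )
}
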