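#' Mean per-site amino-acid diversity (PPA-DIV statistic)
#'
#' The mean over alignment columns of the number of distinct residue
#' states in the column. Gaps and `"X"` are not states; an all-gap column
#' contributes 0. This is the observed side of the posterior-predictive
#' site-diversity test: a model whose simulated replicates reproduce the
#' observed diversity fits in this respect.
#'
#' @param aln An [aa_alignment()].
#' @return A non-negative scalar.
#' @export
ppa_div <- function(aln) {
  m <- unclass(aln)
  mean(apply(m, 2L, function(col) {
    length(unique(col[!(col %in% c(GAP_CHAR, AMBIG_CHAR))]))
  }))
}

#' Maximal compositional heterogeneity (PPA-MAX statistic)
#'
#' For each taxon, the L1 distance between its residue composition and the
#' global composition, summed over the 20 amino acids; the statistic is
#' the maximum over taxa. 0 means perfectly homogeneous composition; the
#' theoretical maximum is 2.
#'
#' @param aln An [aa_alignment()]; every taxon needs at least one residue.
#' @return A scalar in \[0, 2\].
#' @export
ppa_max <- function(aln) {
  m <- unclass(aln)
  comp <- function(chars) {
    chars <- chars[!(chars %in% c(GAP_CHAR, AMBIG_CHAR))]
    if (length(chars) == 0L) return(NULL)
    tab <- table(factor(chars, levels = AA_ALPHABET))
    as.numeric(tab) / length(chars)
  }
  per_taxon <- lapply(seq_len(nrow(m)), function(i) comp(m[i, ]))
  empty <- vapply(per_taxon, is.null, logical(1))
  if (any(empty)) {
    abort(paste0(
      "taxa with no residues: ",
      paste(rownames(m)[empty], collapse = ", ")
    ))
  }
  global <- comp(as.vector(m))
  max(vapply(per_taxon, function(f) sum(abs(f - global)), double(1)))
}

#' Z-score of an observed statistic against a replicate ensemble
#'
#' `Z = (observed - mean(replicates)) / sd(replicates)`. Small `|Z|` means
#' the replicate ensemble (e.g. posterior-predictive simulations) covers
#' the observed value, i.e. the generating model is adequate for that
#' statistic.
#'
#' @param observed Observed statistic value.
#' @param replicates Numeric vector of replicate values (>= 2, non-zero
#'   spread).
#' @param statistic Optional name carried into the result.
#' @return One-row tibble: `statistic`, `observed`, `replicate_mean`,
#'   `replicate_sd`, `n_replicates`, `z`, `abs_z`.
#' @export
ppa_zscore <- function(observed, replicates, statistic = NA_character_) {
  if (length(replicates) < 2L) abort("need at least 2 replicates")
  s <- stats::sd(replicates)
  if (s == 0) abort("degenerate replicate ensemble: zero spread")
  z <- (observed - mean(replicates)) / s
  tibble::tibble(
    statistic = statistic,
    observed = observed,
    replicate_mean = mean(replicates),
    replicate_sd = s,
    n_replicates = length(replicates),
    z = z,
    abs_z = abs(z)
  )
}

#' Assess model adequacy of an alignment against replicate alignments
#'
#' Convenience wrapper computing [ppa_div()] and/or [ppa_max()] on the
#' observed alignment and each replicate, then the Z-scores via
#' [ppa_zscore()]. Replicates are supplied as alignments (from files or
#' from the simulator); no MCMC is run here.
#'
#' @param observed An [aa_alignment()].
#' @param replicates List of [aa_alignment()]s.
#' @param stat `"div"`, `"max"`, or `"both"`.
#' @return A tibble with one row per statistic (see [ppa_zscore()]).
#' @export
ppa_assess <- function(observed, replicates, stat = c("both", "div", "max")) {
  stat <- match.arg(stat)
  pick <- if (stat == "both") c("div", "max") else stat
  purrr::map_dfr(pick, function(s) {
    f <- if (s == "div") ppa_div else ppa_max
    ppa_zscore(
      f(observed),
      vapply(replicates, f, double(1)),
      statistic = paste0("PPA-", toupper(s))
    )
  })
}
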