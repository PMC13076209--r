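#' Pairwise Ka/Ks under the Nei--Gojobori (1986) estimator
#'
#' Computes synonymous (Ks) and non-synonymous (Ka) substitution rates for
#' one pair of aligned coding sequences by pathway counting with
#' Jukes--Cantor correction. Synonymous site counts enumerate the three
#' single-nucleotide changes at every position of every codon against the
#' genetic code: each position contributes one site, split between
#' synonymous and non-synonymous by the fraction of its non-nonsense
#' changes that preserve the amino acid (so `S + N = 3` per codon
#' exactly). Observed synonymous/non-synonymous differences average
#' over all minimal substitution pathways between differing codons, with
#' pathways through stop codons excluded; codon pairs whose pathways all
#' hit stops are skipped, as are codons containing gaps, `N` or stops.
#' Finally `Ks = -(3/4) ln(1 - (4/3) pS)` and likewise Ka.
#'
#' The study-style discard rules are applied after estimation, never
#' silently: a pair is `discarded` when Ks is undefined (JC overflow, no
#' comparable codons), `Ks > 98` or `Ks < 0.01`, with the reason recorded.
#'
#' @param seq1,seq2 Aligned coding sequences: single strings or character
#'   vectors of nucleotides; equal length, divisible by 3.
#' @param pair_id Optional identifier for the pair.
#' @param code Genetic code as a named vector codon -> amino acid (`"*"`
#'   for stops); defaults to the standard code (table 1).
#' @return One-row tibble: `pair_id`, `ka`, `ks`, `omega`, `s_sites`,
#'   `n_sites`, `sd_diff`, `nd_diff`, `n_codons`, `discarded`, `reason`.
#' @export
ng86_rates <- function(seq1, seq2, pair_id = NA_character_,
                       code = standard_genetic_code()) {
  c1 <- split_codons(seq1)
  c2 <- split_codons(seq2)
  if (length(c1) != length(c2)) abort("sequences differ in length")
  usable <- function(cod) {
    !is.na(code[cod]) & code[cod] != "*" & !grepl("[^ACGT]", cod)
  }
  ok <- usable(c1) & usable(c2)
  c1 <- c1[ok]
  c2 <- c2[ok]
  row <- function(ka, ks, s, n, sd_d, nd_d, ncod, reason = NA_character_) {
    discarded <- !is.na(reason)
    tibble::tibble(
      pair_id = pair_id, ka = ka, ks = ks,
      omega = if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_,
      s_sites = s, n_sites = n, sd_diff = sd_d, nd_diff = nd_d,
      n_codons = ncod, discarded = discarded, reason = reason
    )
  }
  if (length(c1) == 0L) {
    return(row(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
               0L, "no comparable codons"))
  }
  syn_sites <- codon_syn_sites(code)
  sd_d <- 0
  nd_d <- 0
  keep <- logical(length(c1))
  for (k in seq_along(c1)) {
    if (c1[k] == c2[k]) {
      keep[k] <- TRUE
      next
    }
    path <- pathway_counts(c1[k], c2[k], code)
    if (is.null(path)) next # every pathway runs through a stop codon
    keep[k] <- TRUE
    sd_d <- sd_d + path$syn
    nd_d <- nd_d + path$nonsyn
  }
  c1 <- c1[keep]
  c2 <- c2[keep]
  ncod <- length(c1)
  if (ncod == 0L) {
    return(row(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
               0L, "no comparable codons"))
  }
  s_bar <- (sum(syn_sites[c1]) + sum(syn_sites[c2])) / 2
  n_bar <- 3 * ncod - s_bar
  ps <- if (s_bar > 0) sd_d / s_bar else 0
  pn <- if (n_bar > 0) nd_d / n_bar else 0
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    -(3 / 4) * log(1 - (4 / 3) * p)
  }
  ks <- jc(ps)
  ka <- jc(pn)
  reason <- if (is.na(ks) || is.na(ka)) {
    "JC overflow"
  } else if (ks > 98) {
    "Ks > 98"
  } else if (ks < 0.01) {
    "Ks < 0.01"
  } else {
    NA_character_
  }
  row(ka, ks, s_bar, n_bar, sd_d, nd_d, ncod, reason)
}

split_codons <- function(x) {
  if (length(x) > 1L) x <- paste(x, collapse = "")
  x <- toupper(gsub("\\s", "", x))
  if (nchar(x) %% 3 != 0) abort("sequence length not divisible by 3")
  substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
}

# Per-codon synonymous site counts: each position contributes one site,
# split S : N by the fraction of its possible single-nucleotide changes
# that are synonymous, nonsense (stop-producing) changes excluded from
# consideration as in the original pathway-counting formulation. S + N
# is exactly 3 per codon.
codon_syn_sites <- function(code) {
  codons <- names(code)[code != "*"]
  out <- setNames(numeric(length(codons)), codons)
  for (cod in codons) {
    s <- 0
    base <- strsplit(cod, "")[[1]]
    for (pos in 1:3) {
      n_syn <- 0L
      n_sense <- 0L
      for (nt in setdiff(DNA_BASES, base[pos])) {
        alt <- base
        alt[pos] <- nt
        alt_aa <- code[paste(alt, collapse = "")]
        if (alt_aa == "*") next
        n_sense <- n_sense + 1L
        if (alt_aa == code[cod]) n_syn <- n_syn + 1L
      }
      if (n_sense > 0L) s <- s + n_syn / n_sense
    }
    out[cod] <- s
  }
  out
}

# Average synonymous/non-synonymous step counts over all minimal pathways
# between two codons, skipping pathways that pass through a stop codon.
# Returns NULL when no stop-free pathway exists.
pathway_counts <- function(cod1, cod2, code) {
  b1 <- strsplit(cod1, "")[[1]]
  b2 <- strsplit(cod2, "")[[1]]
  diff_pos <- which(b1 != b2)
  perms <- permutations_of(diff_pos)
  syn <- 0
  nonsyn <- 0
  n_valid <- 0L
  for (ord in perms) {
    cur <- b1
    steps_syn <- 0L
    steps_non <- 0L
    valid <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- b2[pos]
      aa_from <- code[paste(cur, collapse = "")]
      aa_to <- code[paste(nxt, collapse = "")]
      if (aa_to == "*") {
        valid <- FALSE
        break
      }
      if (aa_from == aa_to) steps_syn <- steps_syn + 1L else steps_non <- steps_non + 1L
      cur <- nxt
    }
    if (valid) {
      n_valid <- n_valid + 1L
      syn <- syn + steps_syn
      nonsyn <- nonsyn + steps_non
    }
  }
  if (n_valid == 0L) return(NULL)
  list(syn = syn / n_valid, nonsyn = nonsyn / n_valid)
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Ka/Ks for a set of codon alignments
#'
#' Applies [ng86_rates()] to each pairwise codon alignment in a list and
#' row-binds the records.
#'
#' @param pairs Named list, each element a length-2 named list/vector of
#'   aligned coding sequences (names = species labels).
#' @return Tibble of [ng86_rates()] rows with `species_a`, `species_b`.
#' @export
ng86_rates_table <- function(pairs) {
  purrr::imap_dfr(pairs, function(p, nm) {
    sp <- names(p)
    if (is.null(sp) || length(sp) != 2L) {
      abort("each pair must hold two sequences named by species")
    }
    rec <- ng86_rates(p[[1L]], p[[2L]], pair_id = nm)
    dplyr::mutate(rec, species_a = sp[1L], species_b = sp[2L], .before = 1L)
  })
}

#' Mean pairwise Ks per lineage
#'
#' For each focal lineage, the mean of non-discarded Ks values over all
#' pairs joining a focal-lineage species to a species of any comparison
#' lineage. All gene-by-pair estimates are pooled (no per-gene averaging
#' first).
#'
#' @param estimates Tibble of estimates with `species_a`, `species_b`,
#'   `ks`, `discarded` (e.g. from [ng86_rates_table()]).
#' @param lineage_map Named character vector: species label -> lineage.
#' @param focal_lineages Lineages to summarize; default all in the map.
#' @param comparison_lineages Lineages admitted on the other side of the
#'   pair; default every lineage except the focal one.
#' @return Tibble: `lineage`, `mean_ks`, `n_pairs` (mean is `NA` with a
#'   warning when every pair is discarded).
#' @export
lineage_mean_ks <- function(estimates, lineage_map,
                            focal_lineages = NULL,
                            comparison_lineages = NULL) {
  focal_lineages <- focal_lineages %||% unique(unname(lineage_map))
  est <- dplyr::mutate(
    estimates,
    lin_a = unname(lineage_map[.data$species_a]),
    lin_b = unname(lineage_map[.data$species_b])
  )
  purrr::map_dfr(focal_lineages, function(foc) {
    others <- comparison_lineages %||% setdiff(unique(unname(lineage_map)), foc)
    hit <- dplyr::filter(
      est,
      (.data$lin_a == foc & .data$lin_b %in% others) |
        (.data$lin_b == foc & .data$lin_a %in% others)
    )
    usable <- dplyr::filter(hit, !.data$discarded & !is.na(.data$ks))
    if (nrow(usable) == 0L) {
      warn(paste0("no usable Ks estimates for lineage ", foc))
      return(tibble::tibble(lineage = foc, mean_ks = NA_real_, n_pairs = 0L))
    }
    tibble::tibble(
      lineage = foc, mean_ks = mean(usable$ks), n_pairs = nrow(usable)
    )
  })
}
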