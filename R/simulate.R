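#' Simulate a random species tree
#'
#' Draws a binary topology uniformly over labelled topologies
#' (`ape::rtopology`) with independent exponential branch lengths.
#' Deterministic under `seed`.
#'
#' @param n_taxa Number of leaves (>= 4).
#' @param branch_scale Mean branch length (substitutions/site).
#' @param seed Integer seed.
#' @param tip_labels Optional labels; default `t01, t02, ...`.
#' @return An unrooted `ape::phylo`.
#' @export
simulate_species_tree <- function(n_taxa, branch_scale = 0.1, seed = 1,
                                  tip_labels = NULL) {
  if (n_taxa < 4L) abort("need at least 4 taxa")
  tip_labels <- tip_labels %||% sprintf("t%02d", seq_len(n_taxa))
  with_seed(seed, {
    tree <- ape::rtopology(n_taxa, rooted = FALSE, tip.label = tip_labels)
    tree$edge.length <- rexp(nrow(tree$edge), rate = 1 / branch_scale)
    as_gene_tree(tree, support_convention = "none")
  })
}

#' Simulate a species tree with monophyletic clans
#'
#' Builds a backbone over one placeholder per clan plus the free and
#' outgroup taxa, then grafts a random subtree of each clan's members onto
#' its placeholder, so every clan is monophyletic by construction --
#' the truth state the clan screen assumes for clean genes.
#'
#' @param clans List of [clan_definition()]s.
#' @param outgroup Outgroup taxon labels (attached like free taxa).
#' @param free_taxa Additional taxa outside any clan.
#' @param branch_scale Mean branch length.
#' @param seed Integer seed.
#' @return An unrooted `ape::phylo` containing every clan as a clade.
#' @export
simulate_clan_species_tree <- function(clans, outgroup = character(),
                                       free_taxa = character(),
                                       branch_scale = 0.1, seed = 1) {
  with_seed(seed, {
    units <- c(
      paste0("..clan_", vapply(clans, `[[`, character(1), "name")),
      free_taxa, outgroup
    )
    if (length(units) < 4L) abort("need at least 4 backbone units")
    bb <- ape::rtopology(length(units), rooted = FALSE, tip.label = units)
    bb$edge.length <- rexp(nrow(bb$edge), rate = 1 / branch_scale)
    for (cl in clans) {
      ph <- paste0("..clan_", cl$name)
      if (length(cl$members) == 1L) {
        bb$tip.label[bb$tip.label == ph] <- cl$members
        next
      }
      sub <- ape::rtopology(
        length(cl$members), rooted = TRUE, tip.label = cl$members
      )
      sub$edge.length <- rexp(nrow(sub$edge), rate = 1 / branch_scale)
      sub$root.edge <- 0
      where <- which(bb$tip.label == ph)
      bb <- ape::bind.tree(bb, sub, where = where, position = 0)
      bb <- ape::drop.tip(bb, ph)
    }
    as_gene_tree(ape::unroot(bb), support_convention = "none")
  })
}

#' Plant a benchmark artifact class into a gene tree
#'
#' Starting from the species tree (with mild lognormal rate jitter so gene
#' trees differ), plants exactly one artifact. Natural terminal branches
#' are first clamped at 10 times the tree's median length so that only a
#' *planted* long branch can cross the screen's 20x threshold -- planted
#' artifacts must be separable from background variation by construction.
#' The planted classes:
#' * `clean`: no change, all internal supports 100;
#' * `long_branch`: one random non-outgroup terminal stretched to
#'   `ratio` times the tree's median branch length (re-checked after the
#'   stretch so the planted ratio always clears the screen's threshold);
#' * `clan_violation_strong` / `clan_violation_weak`: one member of a
#'   random clan pruned and regrafted onto a non-member terminal branch;
#'   all internal supports set to `support_strong` (default 90) or
#'   `support_weak` (default 40);
#' * `saturated`: every branch length multiplied by `rate` (default 5),
#'   supports 100.
#'
#' @param species_tree The species tree (`ape::phylo`).
#' @param class One of `"clean"`, `"long_branch"`,
#'   `"clan_violation_strong"`, `"clan_violation_weak"`, `"saturated"`.
#' @param clans List of [clan_definition()] (required for violation
#'   classes).
#' @param outgroup Outgroup taxa (never stretched or regrafted).
#' @param ratio Long-branch multiple of the median; default 25.
#' @param support_strong,support_weak Planted supports; defaults 90 / 40.
#' @param rate Saturation rate multiplier; default 5.
#' @param jitter_sd sdlog of the lognormal branch-length jitter; 0 for
#'   none.
#' @param seed Integer seed.
#' @return An `ape::phylo` gene tree with supports.
#' @export
plant_artifacts <- function(species_tree, class, clans = NULL,
                            outgroup = character(), ratio = 25,
                            support_strong = 90, support_weak = 40,
                            rate = 5, jitter_sd = 0.2, seed = 1) {
  class <- match.arg(class, c(
    "clean", "long_branch", "clan_violation_strong",
    "clan_violation_weak", "saturated"
  ))
  with_seed(seed, {
    tree <- species_tree
    if (jitter_sd > 0) {
      tree$edge.length <- tree$edge.length *
        rlnorm(nrow(tree$edge), meanlog = 0, sdlog = jitter_sd)
    }
    # contract: only PLANTED long branches may cross the 20x screen.
    # Exponential lengths have heavy ratio tails, so natural terminal
    # branches are clamped at 10x the median -- a two-fold margin below
    # the threshold (clamping values above the median leaves it fixed).
    nt_all <- length(tree$tip.label)
    term_all <- tree$edge[, 2L] <= nt_all
    cap <- 10 * stats::median(tree$edge.length)
    tree$edge.length[term_all & tree$edge.length > cap] <- cap
    support_value <- 100
    if (class == "long_branch") {
      nt <- length(tree$tip.label)
      term_edges <- which(tree$edge[, 2L] <= nt)
      candidates <- term_edges[
        !(tree$tip.label[tree$edge[term_edges, 2L]] %in% outgroup)
      ]
      pick <- candidates[sample.int(length(candidates), 1L)]
      repeat {
        tree$edge.length[pick] <- ratio * stats::median(tree$edge.length)
        m <- stats::median(tree$edge.length)
        if (tree$edge.length[pick] >= (ratio - 1) * m) break
      }
    } else if (class == "saturated") {
      tree$edge.length <- tree$edge.length * rate
    } else if (class %in% c("clan_violation_strong", "clan_violation_weak")) {
      if (is.null(clans) || length(clans) == 0L) {
        abort("clan definitions required for violation classes")
      }
      eligible <- purrr::keep(clans, function(cl) {
        length(intersect(cl$members, tree$tip.label)) >= 2L
      })
      if (length(eligible) == 0L) abort("no clan with >= 2 members in tree")
      cl <- eligible[[sample.int(length(eligible), 1L)]]
      members <- intersect(cl$members, tree$tip.label)
      mover <- members[sample.int(length(members), 1L)]
      hosts <- setdiff(tree$tip.label, c(cl$members, outgroup, mover))
      host <- hosts[sample.int(length(hosts), 1L)]
      tree <- regraft_onto_tip(tree, mover, host)
      support_value <- if (class == "clan_violation_strong") {
        support_strong
      } else {
        support_weak
      }
    }
    tree$support <- rep(support_value, tree$Nnode)
    tree$node.label <- as.character(tree$support)
    tree
  })
}

# Prune `mover` and reattach it halfway along `host`'s terminal branch.
regraft_onto_tip <- function(tree, mover, host) {
  pruned <- ape::drop.tip(tree, mover)
  host_edge <- which(pruned$edge[, 2L] == which(pruned$tip.label == host))
  graft <- structure(
    list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      tip.label = mover,
      edge.length = pruned$edge.length[host_edge] / 2,
      Nnode = 1L
    ),
    class = "phylo"
  )
  out <- ape::bind.tree(
    pruned, graft,
    where = pruned$edge[host_edge, 2L],
    position = pruned$edge.length[host_edge] / 2
  )
  as_gene_tree(ape::unroot(out), support_convention = "none")
}

#' Simulate an amino-acid alignment along a tree
#'
#' Evolves sequences under the 20-state symmetric (uniform-exchangeability)
#' substitution process: on a branch of length `t` (substitutions/site), a
#' site differs from its parent with probability
#' `19/20 * (1 - exp(-20 t / 19))`, the replacement drawn uniformly from
#' the other 19 residues. This keeps a closed-form relation between branch
#' length and expected difference fraction, which the saturation
#' correction inverts exactly.
#'
#' To plant compositional heterogeneity (for the PPA-MAX test), pass
#' `skew_taxon`: after simulation, each of that taxon's sites is resampled
#' with probability `skew_weight` from `skew_freqs` (default: mass
#' concentrated on the first five residues).
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param length Number of columns (>= 1).
#' @param seed Integer seed.
#' @param freqs Root/stationary frequencies over the 20 residues
#'   (default uniform).
#' @param skew_taxon Optional taxon label to make compositionally deviant.
#' @param skew_weight Per-site resampling probability for the skewed
#'   taxon; default 0.5, planting a strong, unambiguous heterogeneity
#'   (the generator's artifact plants are positive controls and must
#'   clear their detector by a wide margin, like the long-branch plant).
#' @param skew_freqs Frequencies used for resampled sites.
#' @param id Gene id attached to the alignment.
#' @return An [aa_alignment()].
#' @export
simulate_alignment <- function(tree, length, seed = 1, freqs = NULL,
                               skew_taxon = NULL, skew_weight = 0.5,
                               skew_freqs = NULL, id = NULL) {
  stopifnot(length >= 1L)
  assert_phylo(tree)
  freqs <- freqs %||% rep(1 / 20, 20)
  with_seed(seed, {
    nt <- length(tree$tip.label)
    tr <- stats::reorder(tree, "postorder")
    root <- setdiff(unique(tr$edge[, 1L]), tr$edge[, 2L])
    seqs <- vector("list", nt + tr$Nnode)
    seqs[[root]] <- sample.int(20L, length, replace = TRUE, prob = freqs)
    # preorder = reversed postorder edge sweep
    for (k in rev(seq_len(nrow(tr$edge)))) {
      p <- tr$edge[k, 1L]
      ch <- tr$edge[k, 2L]
      t_br <- tr$edge.length[k]
      p_change <- (19 / 20) * (1 - exp(-20 * t_br / 19))
      s <- seqs[[p]]
      flip <- runif(length) < p_change
      if (any(flip)) {
        # uniform over the 19 other states
        shift <- sample.int(19L, sum(flip), replace = TRUE)
        s[flip] <- 1L + (s[flip] - 1L + shift) %% 20L
      }
      seqs[[ch]] <- s
    }
    mat <- do.call(rbind, seqs[seq_len(nt)])
    rownames(mat) <- tree$tip.label
    if (!is.null(skew_taxon)) {
      if (!skew_taxon %in% tree$tip.label) abort("skew_taxon not in tree")
      skew_freqs <- skew_freqs %||% c(rep(0.18, 5), rep(0.1 / 15, 15))
      skew_freqs <- skew_freqs / sum(skew_freqs)
      hit <- runif(length) < skew_weight
      if (any(hit)) {
        mat[skew_taxon, hit] <- sample.int(
          20L, sum(hit), replace = TRUE, prob = skew_freqs
        )
      }
    }
    res <- matrix(AA_ALPHABET[mat], nrow = nt,
                  dimnames = list(rownames(mat), NULL))
    aa_alignment(res, id = id)
  })
}

#' Simulate a diverged pair of coding sequences
#'
#' Generates a stop-free ancestral codon sequence and evolves two
#' descendants. Proposed events are single-nucleotide changes at uniform
#' positions; proposals creating stop codons are rejected, synonymous
#' proposals are accepted with probability `min(1, 1/omega)` and
#' non-synonymous ones with `min(1, omega)`, so `omega = 1` is neutral
#' (NG86 Ka/Ks centres on 1), `omega = 0` yields `Ka = 0` exactly.
#'
#' @param divergence Expected proposed mutations per nucleotide site for
#'   the pair (split evenly between the two lineages).
#' @param omega Non-synonymous/synonymous acceptance ratio (> 0, or 0 for
#'   strict purifying).
#' @param length_codons Number of codons.
#' @param seed Integer seed.
#' @param code Genetic code (named codon -> amino-acid vector).
#' @return Named list of two coding strings `seq1`, `seq2`.
#' @export
simulate_codon_pair <- function(divergence, omega, length_codons, seed = 1,
                                code = standard_genetic_code()) {
  stopifnot(omega >= 0, divergence >= 0, length_codons >= 1)
  sense <- names(code)[code != "*"]
  with_seed(seed, {
    anc <- sample(sense, length_codons, replace = TRUE)
    evolve <- function(codons) {
      n_nt <- 3L * length(codons)
      n_prop <- rpois(1L, divergence / 2 * n_nt)
      for (i in seq_len(n_prop)) {
        site <- sample.int(n_nt, 1L)
        cod_i <- (site - 1L) %/% 3L + 1L
        pos <- (site - 1L) %% 3L + 1L
        base <- strsplit(codons[cod_i], "")[[1]]
        alt <- base
        alt[pos] <- sample(setdiff(DNA_BASES, base[pos]), 1L)
        alt_cod <- paste(alt, collapse = "")
        if (code[alt_cod] == "*") next
        syn <- code[alt_cod] == code[codons[cod_i]]
        p_accept <- if (syn) min(1, 1 / max(omega, 1e-12)) else min(1, omega)
        if (omega == 0 && !syn) next
        if (runif(1L) < p_accept) codons[cod_i] <- alt_cod
      }
      codons
    }
    list(
      seq1 = paste(evolve(anc), collapse = ""),
      seq2 = paste(evolve(anc), collapse = "")
    )
  })
}

#' Simulate paired karyotypes with planted rearrangements
#'
#' Creates an ancestral genome of `n_chromosomes` chromosomes carrying
#' `genes_per_chromosome` one-to-one orthologs each. Species A inherits
#' the ancestral karyotype unchanged; species B applies the requested
#' numbers of fusions (two chromosomes merge), fissions (one splits in
#' two) and translocations (a random ~third of one chromosome's genes
#' moves to another). Gene positions are uniform on 1..10 Mb.
#'
#' @param n_chromosomes Ancestral chromosome count; default 46.
#' @param genes_per_chromosome Orthologs per ancestral chromosome.
#' @param events Named list/vector with counts for `fusion`, `fission`,
#'   `translocation` (missing = 0).
#' @param seed Integer seed.
#' @param species Labels for the two species.
#' @return List: `table` (ortholog tibble for both species, see
#'   [read_ortholog_table()] for columns) and `truth` (tibble of planted
#'   events with the chromosomes involved).
#' @export
simulate_karyotypes <- function(n_chromosomes = 46, genes_per_chromosome = 50,
                                events = list(), seed = 1,
                                species = c("spA", "spB")) {
  ev <- function(nm) if (is.null(events[[nm]])) 0L else as.integer(events[[nm]])
  n_fus <- ev("fusion"); n_fis <- ev("fission"); n_tra <- ev("translocation")
  if (n_fis > n_chromosomes) abort("more fissions than chromosomes")
  with_seed(seed, {
    anc_chr <- sprintf("chr%02d", seq_len(n_chromosomes))
    genes <- tibble::tibble(
      og_id = sprintf("OG%05d", seq_len(n_chromosomes * genes_per_chromosome)),
      anc = rep(anc_chr, each = genes_per_chromosome)
    )
    b_chr <- setNames(paste0("B_", anc_chr), anc_chr) # B chromosome of each gene
    genes$chr_b <- unname(b_chr[genes$anc])
    truth <- tibble::tibble(
      event = character(), chrs_a = character(), chrs_b = character()
    )
    pool <- unique(genes$chr_b)
    # fusions: merge two random B chromosomes
    for (i in seq_len(n_fus)) {
      pick <- sample(pool, 2L)
      merged <- paste0("Bfus", i)
      genes$chr_b[genes$chr_b %in% pick] <- merged
      truth <- dplyr::add_row(
        truth, event = "fusion",
        chrs_a = paste(sort(sub("^B_", "A_", pick)), collapse = "+"),
        chrs_b = merged
      )
      pool <- c(setdiff(pool, pick), merged)
    }
    # fissions: split one B chromosome's genes in two halves
    for (i in seq_len(n_fis)) {
      splittable <- setdiff(pool, truth$chrs_b)
      pick <- sample(splittable, 1L)
      idx <- which(genes$chr_b == pick)
      half <- sample(idx, floor(length(idx) / 2))
      new1 <- paste0("Bfis", i, "a")
      new2 <- paste0("Bfis", i, "b")
      genes$chr_b[half] <- new1
      genes$chr_b[setdiff(idx, half)] <- new2
      truth <- dplyr::add_row(
        truth, event = "fission",
        chrs_a = sub("^B_", "A_", pick),
        chrs_b = paste(new1, new2, sep = "+")
      )
      pool <- c(setdiff(pool, pick), new1, new2)
    }
    # translocations: move ~1/3 of one chromosome onto another
    for (i in seq_len(n_tra)) {
      intact <- setdiff(pool, truth$chrs_b)
      pick <- sample(intact, 2L)
      idx <- which(genes$chr_b == pick[1L])
      seg <- sample(idx, max(1L, floor(length(idx) / 3)))
      genes$chr_b[seg] <- pick[2L]
      truth <- dplyr::add_row(
        truth, event = "translocation",
        chrs_a = paste(sort(sub("^B_", "A_", pick)), collapse = "+"),
        chrs_b = pick[2L]
      )
    }
    n_genes <- nrow(genes)
    table <- dplyr::bind_rows(
      tibble::tibble(
        gene_id = paste0(genes$og_id, "_", species[1L]),
        species = species[1L],
        chromosome = paste0("A_", genes$anc),
        start_bp = sample.int(1e7L, n_genes, replace = TRUE),
        og_id = genes$og_id
      ),
      tibble::tibble(
        gene_id = paste0(genes$og_id, "_", species[2L]),
        species = species[2L],
        chromosome = genes$chr_b,
        start_bp = sample.int(1e7L, n_genes, replace = TRUE),
        og_id = genes$og_id
      )
    )
    list(table = table, truth = truth)
  })
}

#' Generate a labelled gene-quality benchmark
#'
#' Builds a clan-respecting species tree, then `n_per_class` genes of each
#' requested artifact class via [plant_artifacts()], simulating an
#' alignment on every gene tree with [simulate_alignment()]. Per-gene
#' seeds are derived from the top-level seed and the gene index, so any
#' subset regenerates identically. When `out_dir` is given, trees
#' (Newick), alignments (FASTA) and a JSON manifest are written; the
#' manifest tibble is always returned in memory.
#'
#' @param clans List of [clan_definition()]s; default: two 3-member and
#'   two 2-member clans over 14 ingroup taxa plus a 2-taxon outgroup.
#' @param outgroup Outgroup labels.
#' @param free_taxa Taxa outside clans and outgroup.
#' @param n_per_class Genes per class; default 50.
#' @param classes Artifact classes to generate.
#' @param aln_length Alignment columns per gene.
#' @param branch_scale Mean species-tree branch length.
#' @param ratio,support_strong,support_weak,rate Artifact parameters
#'   passed to [plant_artifacts()].
#' @param seed Top-level integer seed.
#' @param out_dir Optional output directory.
#' @return An `og_benchmark`: list with `manifest` (tibble: `gene_id`,
#'   `label`, `seed`, `tree_file`, `alignment_file`), `genes` (tibble with
#'   list-columns `tree`, `alignment`), `species_tree`, `clans`,
#'   `outgroup`, `params`.
#' @export
make_benchmark <- function(clans = NULL,
                           outgroup = c("out1", "out2"),
                           free_taxa = c("free1", "free2", "free3", "free4"),
                           n_per_class = 50,
                           classes = c("clean", "long_branch",
                                       "clan_violation_strong",
                                       "clan_violation_weak", "saturated"),
                           aln_length = 300, branch_scale = 0.08,
                           ratio = 25, support_strong = 90, support_weak = 40,
                           rate = 5, seed = 1, out_dir = NULL) {
  clans <- clans %||% default_benchmark_clans()
  species_tree <- simulate_clan_species_tree(
    clans, outgroup, free_taxa,
    branch_scale = branch_scale, seed = derive_seed(seed, 0L)
  )
  spec <- tidyr::expand_grid(
    label = classes,
    rep = seq_len(n_per_class)
  )
  spec$gene_id <- sprintf("OG%04d", seq_len(nrow(spec)))
  genes <- purrr::pmap_dfr(spec, function(label, rep, gene_id) {
    gseed <- derive_seed(seed, match(gene_id, spec$gene_id))
    tree <- plant_artifacts(
      species_tree, label, clans = clans, outgroup = outgroup,
      ratio = ratio, support_strong = support_strong,
      support_weak = support_weak, rate = rate, seed = gseed
    )
    aln <- simulate_alignment(
      tree, aln_length, seed = derive_seed(gseed, 1L), id = gene_id
    )
    tibble::tibble(
      gene_id = gene_id, label = label, seed = gseed,
      tree = list(tree), alignment = list(aln)
    )
  })
  manifest <- dplyr::select(genes, "gene_id", "label", "seed")
  manifest$tree_file <- NA_character_
  manifest$alignment_file <- NA_character_
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "trees"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "alignments"), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(genes))) {
      tf <- file.path(out_dir, "trees", paste0(genes$gene_id[i], ".nwk"))
      af <- file.path(out_dir, "alignments", paste0(genes$gene_id[i], ".faa"))
      ape::write.tree(genes$tree[[i]], tf)
      write_fasta_alignment(genes$alignment[[i]], af)
      manifest$tree_file[i] <- tf
      manifest$alignment_file[i] <- af
    }
    jsonlite::write_json(
      list(
        seed = seed,
        params = list(
          n_per_class = n_per_class, aln_length = aln_length,
          branch_scale = branch_scale, ratio = ratio,
          support_strong = support_strong, support_weak = support_weak,
          rate = rate
        ),
        genes = manifest
      ),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  structure(
    list(
      manifest = manifest, genes = genes, species_tree = species_tree,
      clans = clans, outgroup = outgroup,
      params = list(
        ratio = ratio, support_strong = support_strong,
        support_weak = support_weak, rate = rate, seed = seed
      )
    ),
    class = "og_benchmark"
  )
}

default_benchmark_clans <- function() {
  list(
    clan_definition("Oegopsida", c("oeg1", "oeg2", "oeg3"),
                    c("out1", "out2")),
    clan_definition("Sepiida", c("sep1", "sep2", "sep3"), c("out1", "out2")),
    clan_definition("Myopsida", c("myo1", "myo2"), c("out1", "out2")),
    clan_definition("Sepiolida", c("siol1", "siol2"), c("out1", "out2"))
  )
}

#' @export
print.og_benchmark <- function(x, ...) {
  cat(sprintf(
    "<og_benchmark: %d genes (%s), seed %d>\n",
    nrow(x$manifest),
    paste(unique(x$manifest$label), collapse = ", "),
    x$params$seed
  ))
  invisible(x)
}

#' @describeIn make_benchmark `tidy()` returns the truth-label manifest.
#' @method tidy og_benchmark
#' @param x An `og_benchmark`.
#' @param ... Unused.
#' @export
tidy.og_benchmark <- function(x, ...) x$manifest
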