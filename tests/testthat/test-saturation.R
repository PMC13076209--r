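test_that("gap trimming removes columns at half-or-more gaps", {
  aln <- aa_alignment(c(
    a = "AC-D",
    b = "AC-D",
    c = "A--D",
    d = "A-CD"
  ))
  # column gap fractions: 0, 0.75, 0.75 -> wait: cols are (A,A,A,A),(C,C,-,-),
  # (-,-,-,C),(D,D,D,D); fractions 0, 0.5, 0.75, 0
  trimmed <- trim_gapped_columns(aln, 0.5)
  expect_equal(ncol(trimmed), 2L)
  expect_equal(unname(apply(trimmed, 1, paste, collapse = "")),
               c("AD", "AD", "AD", "AD"))

  one_gap <- aa_alignment(c(a = "AC", b = "AC", c = "A-", d = "AC"))
  expect_equal(ncol(trim_gapped_columns(one_gap, 0.5)), 2L)

  gapless <- aa_alignment(c(a = "ACD", b = "ACD", c = "ACE", d = "ACF"))
  expect_identical(
    unclass(trim_gapped_columns(gapless, 0.5)), unclass(gapless)
  )

  all_gone <- aa_alignment(c(a = "A-", b = "-A", c = "--", d = "--"))
  expect_warning(out <- trim_gapped_columns(all_gone, 0.5), "all")
  expect_equal(ncol(out), 0L)
})

test_that("percent identity counts comparable columns only", {
  aln <- aa_alignment(c(a = "AAAAAAAAAA", b = "AAAAAAACCC"))
  expect_equal(percent_identity(aln, "a", "b"), 70)
  expect_equal(percent_identity(aln, "a", "a"), 100)

  gappy <- aa_alignment(c(a = "AA--XC", b = "A-A-CC"))
  # comparable columns: 1 (A,A) and 6 (C,C) -> 100
  expect_equal(percent_identity(gappy, "a", "b"), 100)

  disjoint <- aa_alignment(c(a = "A--", b = "-AA"))
  expect_error(percent_identity(disjoint, "a", "b"), "comparable")
})

test_that("the Poisson correction matches its closed form and flags saturation", {
  expect_equal(ogcurator:::poisson_correct(0), 0)
  expect_equal(
    ogcurator:::poisson_correct(0.5), 0.95 * log(19 / 9),
    tolerance = 1e-12
  )
  expect_error(ogcurator:::poisson_correct(0.95), "overflow")

  # strictly increasing on its domain
  p <- seq(0, 0.94, by = 0.01)
  d <- vapply(p, ogcurator:::poisson_correct, double(1))
  expect_true(all(diff(d) > 0))
})

test_that("the saturation slope matches OLS on constructed collinear pairs", {
  # Build a 4-taxon alignment whose three taxon pairs land exactly on a
  # line in (distance, identity%): engineered via hamming distances.
  # Simpler check: verify against lm() on the pair data of a simulated
  # alignment (dual-route: closed-form OLS vs stats::lm).
  tr <- simulate_species_tree(8, branch_scale = 0.15, seed = 5)
  aln <- simulate_alignment(tr, 400, seed = 6)
  rec <- saturation_slope(aln, gene_id = "g")
  taxa <- rownames(aln)
  pairs <- combn(taxa, 2)
  d <- id <- numeric(0)
  for (k in seq_len(ncol(pairs))) {
    idpc <- percent_identity(aln, pairs[1, k], pairs[2, k])
    d <- c(d, ogcurator:::poisson_correct(1 - idpc / 100))
    id <- c(id, idpc)
  }
  fit <- stats::lm(id ~ d)
  expect_equal(rec$slope, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(rec$n_pairs, ncol(pairs))
})

test_that("outgroup pairs are excluded from the regression", {
  tr <- simulate_species_tree(8, branch_scale = 0.15, seed = 7)
  aln <- simulate_alignment(tr, 300, seed = 8)
  with_og <- saturation_slope(aln, outgroup = c("t01", "t02"), gene_id = "g")
  expect_equal(with_og$n_pairs, choose(6, 2))
})

test_that("degenerate alignments yield undefined slopes", {
  const <- aa_alignment(c(a = "AAAA", b = "AAAA", c = "AAAA"))
  rec <- saturation_slope(const, gene_id = "g")
  expect_true(is.na(rec$slope))
  records <- dplyr::bind_rows(
    rec,
    tibble::tibble(gene_id = "h", slope = -10, n_pairs = 3L,
                   n_dropped = 0L, retained = NA)
  )
  out <- retain_by_slope(records, 1)
  expect_false(out$retained[out$gene_id == "g"]) # undefined never retained
})

test_that("slope retention keeps the floor of the fraction, ties by gene id", {
  rec <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    slope = c(-60, -40, -20, -10),
    n_pairs = 3L, n_dropped = 0L, retained = NA
  )
  out <- retain_by_slope(rec, 0.5)
  expect_equal(out$gene_id[out$retained], c("g1", "g2"))

  rec5 <- dplyr::add_row(rec, gene_id = "g5", slope = -5,
                         n_pairs = 3L, n_dropped = 0L, retained = NA)
  expect_equal(sum(retain_by_slope(rec5, 0.5)$retained), 2L)

  ties <- tibble::tibble(
    gene_id = c("gB", "gA", "gC", "gD"),
    slope = c(-40, -40, -40, -40),
    n_pairs = 3L, n_dropped = 0L, retained = NA
  )
  out_ties <- retain_by_slope(ties, 0.5)
  expect_equal(sort(out_ties$gene_id[out_ties$retained]), c("gA", "gB"))

  # composability: the retained half halves again
  rec8 <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:8), slope = -(8:1),
    n_pairs = 3L, n_dropped = 0L, retained = NA
  )
  first <- retain_by_slope(rec8, 0.5)
  second <- retain_by_slope(first[first$retained, ], 0.5)
  expect_equal(sum(second$retained), floor(0.25 * 8))
})

test_that("concatenation lays out partitions and occupancy correctly", {
  a1 <- aa_alignment(c(x = paste(rep("A", 100), collapse = ""),
                       y = paste(rep("C", 100), collapse = "")), id = "g1")
  a2 <- aa_alignment(c(x = paste(rep("D", 50), collapse = ""),
                       z = paste(rep("E", 50), collapse = "")), id = "g2")
  sm <- concatenate_alignments(list(a1, a2))
  expect_equal(ncol(sm$alignment), 150L)
  expect_equal(sm$partitions$start, c(1L, 101L))
  expect_equal(sm$partitions$end, c(100L, 150L))
  occ <- setNames(sm$occupancy$occupancy, sm$occupancy$taxon)
  expect_equal(occ[["x"]], 1)
  expect_equal(occ[["y"]], 100 / 150)
  expect_equal(occ[["z"]], 50 / 150)

  # partition extraction returns the inputs exactly
  expect_identical(unclass(extract_partition(sm, "g1")), unclass(a1))
  expect_identical(unclass(extract_partition(sm, "g2")), unclass(a2))

  expect_error(concatenate_alignments(list()), "no alignments")
  expect_error(concatenate_alignments(list(a1, a1)), "duplicate")
})

test_that("site counting matches the definition on crafted columns", {
  crafted <- aa_alignment(c(
    s1 = "AAAA",
    s2 = "AADA",
    s3 = "DAAD",
    s4 = "DD--"
  ))
  # col1 (A,A,D,D) informative; col2 (A,A,A,D) variable only;
  # col3 (A,D,A,-) variable only; col4 (A,A,D,-) variable only
  counts <- count_parsimony_informative(crafted)
  expect_equal(counts$variable_sites, 4L)
  expect_equal(counts$informative_sites, 1L)

  const <- aa_alignment(c(a = "AAA", b = "AAA"))
  expect_equal(count_parsimony_informative(const)$variable_sites, 0L)
})

test_that("informative <= variable <= L on random alignments", {
  for (seed in 1:20) {
    aln <- random_alignment(8, 60, seed, p_gap = 0.2)
    counts <- count_parsimony_informative(aln)
    expect_lte(counts$informative_sites, counts$variable_sites)
    expect_lte(counts$variable_sites, ncol(aln))
  }
})

test_that("supermatrix tidiers expose partitions and summary statistics", {
  bm <- make_benchmark(n_per_class = 3, classes = "clean",
                       aln_length = 50, seed = 2)
  sm <- concatenate_alignments(bm$genes$alignment)
  td <- tidy(sm)
  expect_equal(td$length, rep(50L, 3))
  gl <- glance(sm)
  expect_equal(gl$n_sites, 150L)
  expect_equal(gl$n_partitions, 3L)
  expect_equal(gl$mean_occupancy, 1)
})
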