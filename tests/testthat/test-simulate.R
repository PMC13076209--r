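test_that("tree simulation is seed-deterministic with correct shape", {
  t1 <- simulate_species_tree(16, 0.1, seed = 21)
  t2 <- simulate_species_tree(16, 0.1, seed = 21)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(
    ape::write.tree(simulate_species_tree(16, 0.1, seed = 22)),
    ape::write.tree(t1)
  ))
  # unrooted binary: 2n-3 branches, n-3 internal
  expect_equal(nrow(t1$edge), 2 * 16 - 3)
  nt <- length(t1$tip.label)
  expect_equal(sum(t1$edge[, 2] > nt), 16 - 3)
  expect_error(simulate_species_tree(3), "at least 4")
})

test_that("branch lengths match the requested exponential scale", {
  lens <- unlist(lapply(1:300, function(i) {
    simulate_species_tree(8, branch_scale = 0.1, seed = i)$edge.length
  }))
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 0.1), 3 * se)
})

test_that("planted artifacts are detected by the matching filter", {
  bm_clans <- ogcurator:::default_benchmark_clans()
  st <- simulate_clan_species_tree(
    bm_clans, outgroup = c("out1", "out2"),
    free_taxa = c("f1", "f2"), seed = 31
  )
  for (s in 1:10) {
    lb <- plant_artifacts(st, "long_branch", outgroup = c("out1", "out2"),
                          seed = s)
    expect_equal(
      long_branch_filter(lb, c("out1", "out2"))$decision, "exclude"
    )
    weak <- plant_artifacts(st, "clan_violation_weak", clans = bm_clans,
                            outgroup = c("out1", "out2"), seed = s)
    stats_weak <- vapply(bm_clans, function(cl) {
      clan_check(weak, cl)$status
    }, character(1))
    expect_true("weak_violation" %in% stats_weak)
    expect_false("strong_violation" %in% stats_weak)

    clean <- plant_artifacts(st, "clean", clans = bm_clans,
                             outgroup = c("out1", "out2"), seed = s)
    expect_equal(long_branch_filter(clean, c("out1", "out2"))$decision,
                 "retain")
    expect_true(all(vapply(bm_clans, function(cl) {
      clan_check(clean, cl)$status
    }, character(1)) == "satisfied"))
  }
})

test_that("alignment simulation is deterministic and honours zero lengths", {
  tr <- simulate_species_tree(6, 0.1, seed = 41)
  a1 <- simulate_alignment(tr, 80, seed = 42)
  a2 <- simulate_alignment(tr, 80, seed = 42)
  expect_identical(unclass(a1), unclass(a2))

  frozen <- tr
  frozen$edge.length <- rep(0, nrow(frozen$edge))
  a0 <- simulate_alignment(frozen, 60, seed = 43)
  expect_equal(nrow(unique(unclass(a0))), 1L)
})

test_that("pairwise differences match the closed form of the uniform process", {
  # two-taxon comparison at a known path length
  tr <- tree_from_text("((A:0.15,B:0.25):0.1,(C:0.05,D:0.05):0.1);")
  aln <- simulate_alignment(tr, 10000, seed = 44)
  d_ab <- 0.15 + 0.25
  p_obs <- 1 - percent_identity(aln, "A", "B") / 100
  p_exp <- (19 / 20) * (1 - exp(-20 * d_ab / 19))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("codon pair simulation honours its acceptance rules", {
  p0 <- simulate_codon_pair(0, 1, 50, seed = 51)
  expect_identical(p0$seq1, p0$seq2)

  pp <- simulate_codon_pair(0.3, 0, 100, seed = 52)
  rec <- ng86_rates(pp$seq1, pp$seq2)
  expect_equal(rec$ka, 0) # omega = 0 admits no non-synonymous change
  expect_gt(rec$sd_diff, 0)

  # determinism
  pa <- simulate_codon_pair(0.2, 1, 40, seed = 53)
  pb <- simulate_codon_pair(0.2, 1, 40, seed = 53)
  expect_identical(pa, pb)
})

test_that("karyotype simulation plants the requested events", {
  none <- simulate_karyotypes(46, 5, events = list(), seed = 61)
  expect_equal(
    length(unique(none$table$chromosome[none$table$species == "spA"])), 46L
  )
  expect_equal(
    length(unique(none$table$chromosome[none$table$species == "spB"])), 46L
  )
  expect_equal(nrow(none$truth), 0L)

  fus <- simulate_karyotypes(46, 5, events = list(fusion = 1), seed = 62)
  expect_equal(
    length(unique(fus$table$chromosome[fus$table$species == "spB"])), 45L
  )
  fis <- simulate_karyotypes(46, 5, events = list(fission = 1), seed = 63)
  expect_equal(
    length(unique(fis$table$chromosome[fis$table$species == "spB"])), 47L
  )
  expect_error(
    simulate_karyotypes(4, 5, events = list(fission = 5), seed = 1),
    "more fissions"
  )
})

test_that("benchmarks are fully reproducible, file outputs included", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  bm1 <- make_benchmark(n_per_class = 2, aln_length = 40, seed = 71,
                        out_dir = dir1)
  bm2 <- make_benchmark(n_per_class = 2, aln_length = 40, seed = 71,
                        out_dir = dir2)
  expect_equal(nrow(bm1$manifest), 10L)
  expect_equal(sort(unique(bm1$manifest$label)), sort(c(
    "clean", "long_branch", "clan_violation_strong",
    "clan_violation_weak", "saturated"
  )))
  for (f in list.files(file.path(dir1, "alignments"))) {
    expect_identical(
      readLines(file.path(dir1, "alignments", f)),
      readLines(file.path(dir2, "alignments", f))
    )
  }
  for (f in list.files(file.path(dir1, "trees"))) {
    expect_identical(
      readLines(file.path(dir1, "trees", f)),
      readLines(file.path(dir2, "trees", f))
    )
  }
  expect_true(file.exists(file.path(dir1, "manifest.json")))

  # every generated file appears in the manifest
  man <- jsonlite::read_json(file.path(dir1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_setequal(
    basename(man$genes$alignment_file),
    list.files(file.path(dir1, "alignments"))
  )
})

test_that("seed splitting regenerates single genes identically", {
  bm <- make_benchmark(n_per_class = 3, aln_length = 30, seed = 81)
  g <- bm$genes[4, ]
  regen <- plant_artifacts(
    bm$species_tree, g$label, clans = bm$clans, outgroup = bm$outgroup,
    ratio = bm$params$ratio, support_strong = bm$params$support_strong,
    support_weak = bm$params$support_weak, rate = bm$params$rate,
    seed = g$seed
  )
  expect_identical(ape::write.tree(regen), ape::write.tree(g$tree[[1]]))
})
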