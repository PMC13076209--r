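test_that("median branch length covers all branches with the even-count mean", {
  tr <- tree_from_text("((A:0.1,B:0.1):0.1,(C:0.3,D:0.1):0.1);")
  # branches: 0.1 x5, 0.3 -> median 0.1
  expect_equal(median_branch_length(tr), 0.1)

  tr2 <- tree_from_text("(A:0.1,B:0.2);")
  expect_equal(median_branch_length(tr2), 0.15)

  tr3 <- tree_from_text("(A:0.5);")
  expect_equal(median_branch_length(tr3), 0.5)
})

test_that("long-branch screen is inclusive at the ratio and exempts the outgroup", {
  # nine branches of 0.1 and one ingroup terminal at exactly 2.0 = 20x median
  txt <- "(((A:2.0,B:0.1):0.1,(C:0.1,D:0.1):0.1):0.1,(E:0.1,F:0.1):0.1);"
  tr <- tree_from_text(txt)
  expect_equal(median_branch_length(tr), 0.1)
  v <- long_branch_filter(tr, outgroup = character(), ratio = 20)
  expect_equal(v$decision, "exclude")
  expect_equal(v$statistic, 20)

  # same branch but belonging to the outgroup -> retained
  v_og <- long_branch_filter(tr, outgroup = "A", ratio = 20)
  expect_equal(v_og$decision, "retain")

  # uniform tree retains with ratio statistic 1
  flat <- tree_from_text("((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  v_flat <- long_branch_filter(flat, ratio = 20)
  expect_equal(v_flat$decision, "retain")
  expect_equal(v_flat$statistic, 1)
})

test_that("long-branch screen is invariant under uniform branch scaling", {
  for (seed in 1:10) {
    tr <- simulate_species_tree(8, branch_scale = 0.1, seed = seed)
    v1 <- long_branch_filter(tr, ratio = 20)
    scaled <- tr
    scaled$edge.length <- scaled$edge.length * 137.5
    v2 <- long_branch_filter(scaled, ratio = 20)
    expect_equal(v1$decision, v2$decision)
    expect_equal(v1$statistic, v2$statistic, tolerance = 1e-12)
  }
})

test_that("degenerate medians are handled explicitly", {
  zero <- tree_from_text("((A:0,B:0):0,(C:0,D:0):0);")
  expect_equal(long_branch_filter(zero)$decision, "retain")

  mixed <- tree_from_text("((A:0.4,B:0):0,(C:0,D:0):0);")
  v <- long_branch_filter(mixed)
  expect_equal(v$decision, "exclude")
  expect_match(v$reason, "degenerate median")
})

test_that("weak-branch collapse contracts at the inclusive threshold and is idempotent", {
  txt <- "(((A:1,B:1)40:1,C:1)40:1,(D:1,E:1)40:1);"
  star <- collapse_weak_branches(tree_from_text(txt), 50)
  expect_equal(star$Nnode, 1L) # all internal branches weak -> star tree

  strong_txt <- "(((A:1,B:1)100:1,C:1)100:1,(D:1,E:1)100:1);"
  tr <- tree_from_text(strong_txt)
  kept <- collapse_weak_branches(tr, 50)
  expect_equal(kept$Nnode, tr$Nnode)
  expect_equal(
    as.numeric(ape::dist.topo(ape::unroot(kept), ape::unroot(tr))), 0
  )

  # support exactly 50 collapses (exclusion requires MORE than 50), 90 stays
  mix <- tree_from_text("(((A:1,B:1)90:1,C:1)50:1,(D:1,E:1)90:1);")
  coll <- collapse_weak_branches(mix, 50)
  expect_equal(coll$Nnode, mix$Nnode - 1L)
  sides <- lapply(ogcurator:::tree_bipartitions(coll), `[[`, "tips")
  expect_true(list(c("A", "B")) %in% sides)
  expect_false(list(c("A", "B", "C")) %in% sides)

  # idempotence
  twice <- collapse_weak_branches(coll, 50)
  expect_equal(twice$edge, coll$edge)
  expect_equal(twice$support, coll$support)
})

test_that("clan check distinguishes satisfied, weak and strong violations", {
  # unrooted AB|CD with clan {A,B}
  quartet <- tree_from_text("((A:1,B:1)95:1,(C:1,D:1)95:1);")
  ab <- clan_definition("AB", c("A", "B"))
  expect_equal(clan_check(quartet, ab)$status, "satisfied")
  expect_true(is.na(clan_check(quartet, ab)$max_conflicting_support))

  # clan {C,D} broken by C grouping with E at support 40 -> weak
  broken40 <- tree_from_text("(((C:1,E:1)40:1,D:1)90:1,(A:1,B:1)90:1);")
  cd <- clan_definition("CD", c("C", "D"))
  v_weak <- clan_check(broken40, cd)
  expect_equal(v_weak$status, "weak_violation")
  expect_equal(v_weak$max_conflicting_support, 40)

  broken90 <- tree_from_text("(((C:1,E:1)90:1,D:1)90:1,(A:1,B:1)90:1);")
  v_strong <- clan_check(broken90, cd)
  expect_equal(v_strong$status, "strong_violation")
  expect_equal(v_strong$max_conflicting_support, 90)

  expect_error(
    clan_check(quartet, clan_definition("XY", c("X", "Y"))),
    "absent"
  )
  # partially missing members: drops them with a warning
  expect_warning(
    v <- clan_check(quartet, clan_definition("AX", c("A", "X"))),
    "missing"
  )
  expect_equal(v$status, "satisfied") # single present member is vacuous
})

test_that("clan satisfaction is invariant to rerooting", {
  for (seed in 1:8) {
    cl <- list(clan_definition("grp", c("m1", "m2", "m3")))
    tr <- simulate_clan_species_tree(
      cl, free_taxa = c("f1", "f2", "f3", "f4"), seed = seed
    )
    tr$support <- rep(100, tr$Nnode)
    base <- clan_check(tr, cl[[1]])$status
    expect_equal(base, "satisfied")
    for (tip in c("f1", "f4")) {
      rerooted <- ogcurator:::as_gene_tree_if_needed(
        ape::root(tr, outgroup = tip)
      )
      rerooted$support <- rep(100, rerooted$Nnode)
      expect_equal(clan_check(rerooted, cl[[1]])$status, "satisfied")
    }
  }
})

test_that("raising conflicting support never improves a violation verdict", {
  cd <- clan_definition("CD", c("C", "D"))
  statuses <- vapply(c(10, 30, 50, 50.1, 70, 100), function(s) {
    txt <- sprintf("(((C:1,E:1)%g:1,D:1)100:1,(A:1,B:1)100:1);", s)
    clan_check(tree_from_text(txt), cd)$status
  }, character(1))
  expect_equal(
    statuses,
    c(rep("weak_violation", 3), rep("strong_violation", 3))
  )
})

test_that("the cascade short-circuits and recovers planted classes", {
  bm <- make_benchmark(n_per_class = 6, seed = 11)
  verdicts <- qc_cascade(bm$genes, bm$clans, bm$outgroup)
  truth <- tidy(bm)

  excluded <- unique(verdicts$gene_id[verdicts$decision == "exclude"])
  by_label <- split(truth$gene_id %in% excluded, truth$label)
  expect_true(all(by_label$long_branch))
  expect_true(all(by_label$clan_violation_strong))
  expect_false(any(by_label$clean))
  expect_false(any(by_label$clan_violation_weak))
  expect_false(any(by_label$saturated))

  # short-circuit: genes excluded at the long-branch stage get no clan verdict
  lb_excluded <- verdicts$gene_id[
    verdicts$stage == "long_branch" & verdicts$decision == "exclude"
  ]
  expect_false(any(
    verdicts$gene_id %in% lb_excluded & verdicts$stage == "clan_check"
  ))

  # order preserved, one long-branch verdict per gene
  expect_equal(
    unique(verdicts$gene_id), truth$gene_id
  )

  empty <- qc_cascade(list(), bm$clans, bm$outgroup)
  expect_equal(nrow(empty), 0L)
})
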