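test_that("read_trees computes tip/node ages and preserves order", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("((A:1,B:1):1,C:2);",
               "((A:1,B:0.5):1,C:2);",
               "((A:1,B:1):1,C:2);"), f)
  trees <- read_trees(f)
  expect_length(trees, 3)
  expect_equal(unname(tip_ages(trees[[1]])), c(0, 0, 0))
  expect_equal(node_ages(trees[[1]])[4], 2)  # root age
  a <- tip_ages(trees[[2]])
  expect_equal(unname(a[c("A", "C")]), c(0, 0))
  expect_equal(unname(a["B"]), 0.5)
  expect_equal(extinct_tips(trees[[2]]), "B")
})

test_that("read_trees rejects broken input and resolves polytomies", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A,B,C);", f)  # no branch lengths
  expect_error(read_trees(f), "tree 1")
  writeLines("(A:1,B:1,C:1.5);", f)
  trees <- read_trees(f)
  expect_true(ape::is.binary(trees[[1]]))
  expect_match(attr(trees, "polytomy_log"), "tree 1")
  expect_equal(sort(unname(tip_ages(trees[[1]]))), c(0, 0.5, 0.5))
})

test_that("timescale_mbl applies the cascading minimum-branch rule", {
  # parent age 10, grandparent 10.5; forcing the tip to age 10 must push the
  # parent to 11 and cascade the grandparent to 12
  phy <- ape::read.tree(text = "((F:1,A:10):0.5,B:10.5);")
  out <- timescale_mbl(phy, tip_ages = c(F = 10), min_bl = 1)
  ages <- node_ages(out)
  expect_equal(ages[5], 11)        # parent of F
  expect_equal(ages[4], 12)        # root
  expect_true(all(out$edge.length >= 1 - 1e-12))
  sh <- attr(out, "mbl_shifts")
  expect_setequal(sh$node, c(4, 5))

  # already-valid tree: no-op, including at min_bl = 0
  phy2 <- tree3()
  expect_equal(timescale_mbl(phy2, min_bl = 1)$edge.length, phy2$edge.length)
  expect_equal(timescale_mbl(phy2, min_bl = 0)$edge.length, phy2$edge.length)
  expect_equal(nrow(attr(timescale_mbl(phy2, min_bl = 1), "mbl_shifts")), 0)
})

test_that("timescale_mbl output always satisfies the floor; valid trees unchanged", {
  for (s in 1:5) {
    phy <- random_tree(20, seed = s, fossils = TRUE)
    fa <- tip_ages(phy)
    fos <- names(fa)[fa > 1e-8]
    set.seed(s)
    shift <- stats::setNames(fa[fos] + runif(length(fos), 0, 5), fos)
    out <- timescale_mbl(phy, tip_ages = shift, min_bl = 1)
    expect_true(all(out$edge.length >= 1 - 1e-9))
    # with an epsilon floor and unchanged tip ages nothing moves
    out2 <- timescale_mbl(phy, min_bl = 1e-12)
    expect_equal(out2$edge.length, phy$edge.length, tolerance = 1e-9)
  }
})

test_that("sample_fossil_tip_ages respects ranges, seeds and degenerate intervals", {
  phy <- tree3_fossil()
  rg <- data.frame(taxon = "B", fad = 1.2, lad = 0.9)
  reps <- sample_fossil_tip_ages(phy, rg, n_trees = 40, seed = 7, min_bl = 0.1)
  ages <- vapply(reps, function(tr) tip_ages(tr)[["B"]], numeric(1))
  expect_true(all(ages >= 0.9 & ages <= 1.2))
  reps2 <- sample_fossil_tip_ages(phy, rg, n_trees = 40, seed = 7, min_bl = 0.1)
  expect_identical(lapply(reps, `[[`, "edge.length"),
                   lapply(reps2, `[[`, "edge.length"))
  # degenerate interval
  rg0 <- data.frame(taxon = "B", fad = 1, lad = 1)
  reps3 <- sample_fossil_tip_ages(phy, rg0, n_trees = 5, seed = 1, min_bl = 0.1)
  expect_true(all(abs(vapply(reps3, function(tr) tip_ages(tr)[["B"]],
                             numeric(1)) - 1) < 1e-12))
  # missing range errors with the tip named
  expect_error(sample_fossil_tip_ages(phy, rg[0, ], 1, 1), "B")
})

test_that("sampled fossil ages have the uniform mean over [lad, fad]", {
  phy <- tree3_fossil()
  rg <- data.frame(taxon = "B", fad = 120, lad = 110)
  reps <- sample_fossil_tip_ages(phy, rg, n_trees = 1000, seed = 3, min_bl = 0.1)
  ages <- vapply(reps, function(tr) tip_ages(tr)[["B"]], numeric(1))
  se <- sqrt((120 - 110)^2 / 12 / 1000)
  expect_lt(abs(mean(ages) - 115), 3 * se)
})

test_that("prune_to_taxa preserves root-to-tip distances", {
  phy <- tree3()
  pr <- prune_to_taxa(phy, c("A", "B"))
  expect_equal(sort(pr$tip.label), c("A", "B"))
  expect_equal(unname(node_depths(pr)[1:2]), c(1, 1))
  expect_equal(prune_to_taxa(phy, phy$tip.label)$edge.length, phy$edge.length)
  big <- random_tree(20, seed = 11, fossils = TRUE)
  keep <- sample(big$tip.label, 8)
  d0 <- node_depths(big)[match(keep, big$tip.label)]
  pr2 <- prune_to_taxa(big, keep)
  d1 <- node_depths(pr2)[match(keep, pr2$tip.label)]
  expect_equal(d1, d0, tolerance = 1e-10)
  expect_error(prune_to_taxa(phy, c("A", "Z")), "Z")
  expect_error(prune_to_taxa(phy, "A"), "at least 2")
})

test_that("rescale_unit_height normalizes, preserves depth ratios, idempotent", {
  phy <- random_tree(15, seed = 2, fossils = TRUE)
  h <- tree_height(phy)
  u <- rescale_unit_height(phy)
  expect_equal(tree_height(u), 1, tolerance = 1e-12)
  expect_equal(u$edge.length, phy$edge.length / h)
  expect_equal(rescale_unit_height(u)$edge.length, u$edge.length)
  # a tip at depth h/2 lands at depth 0.5
  expect_equal(node_depths(u), node_depths(phy) / h)
})

test_that("phylo_covariance matches hand paths and is PSD", {
  pc <- phylo_covariance(tree3())
  expect_equal(unname(diag(pc$S)), c(2, 2, 2))
  expect_equal(pc$S["A", "B"], 1)
  expect_equal(pc$S["A", "C"], 0)
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  star <- ape::multi2di(star, random = FALSE)
  Ss <- phylo_covariance(star)$S
  expect_equal(max(abs(Ss[upper.tri(Ss)])), 0)
  for (s in 1:5) {
    phy <- random_tree(10, seed = 100 + s, fossils = (s %% 2 == 0))
    pc <- phylo_covariance(phy)
    expect_true(isSymmetric(pc$S))
    expect_gte(min(eigen(pc$S, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    # shared path never exceeds either depth
    expect_true(all(pc$S <= outer(pc$depths, pc$depths, pmin) + 1e-10))
    if (ape::is.ultrametric(phy)) {
      expect_lt(diff(range(pc$depths)), 1e-8)
    }
  }
})

test_that("child_seed is deterministic and in 32-bit range", {
  s <- vapply(1:1000, function(i) child_seed(123456789, i), integer(1))
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(child_seed(5, 7), child_seed(5, 7))
  expect_false(child_seed(5, 7) == child_seed(5, 8))
})
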