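test_that("simulate_tree honours the stated world and its invariants", {
  w <- small_world()
  expect_equal(sum(tip_ages(w$tree) <= 1e-8), 128)   # extant
  expect_equal(length(extinct_tips(w$tree)), 30)     # sampled fossils
  validate_dated_tree(w$tree)
  # fad >= true age >= lad for every fossil
  expect_true(all(w$ranges$fad >= w$ranges$true_age - 1e-9))
  expect_true(all(w$ranges$lad <= w$ranges$true_age + 1e-9))
  expect_true(all(w$ranges$lad >= 0))
})

test_that("pure-birth configuration yields an ultrametric fossil-free tree", {
  cfg <- synth_config(n_extant = 20, death_rate = 0, n_fossils = 0, seed = 3)
  tr <- simulate_tree(cfg)
  expect_length(extinct_tips(tr$tree), 0)
  expect_true(ape::is.ultrametric(tr$tree, tol = 1e-6))
  expect_equal(nrow(tr$ranges), 0)
})

test_that("simulate_tree is deterministic given the seed", {
  cfg <- synth_config(n_extant = 15, n_fossils = 4, seed = 11)
  t1 <- simulate_tree(cfg)
  t2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
  expect_identical(t1$ranges, t2$ranges)
})

test_that("trait tables carry counts, ranges and the truth attribute", {
  w <- small_world()
  tab <- w$table
  expect_s3_class(tab, "trait_table")
  expect_equal(nrow(tab), length(w$tree$tip.label))
  expect_true(all(tab$count_min <= tab$count_mean))
  expect_true(all(tab$count_mean <= tab$count_max))
  expect_true(all(tab$count_min >= 0))
  expect_equal(sum(tab$extinct), 30)
  truth <- attr(tab, "truth")
  expect_equal(truth$model, "EB")
  expect_named(truth$params, c("theta0", "sigma2", "beta"))
  expect_length(truth$raw_values, nrow(tab))
  # degenerate generator: zero variance puts every species at the root count
  cfg0 <- synth_config(n_extant = 10, n_fossils = 0, death_rate = 0, seed = 2,
                       trait_model = "BM", range_frac = 0,
                       trait_params = list(theta0 = 7, sigma2 = 0))
  tab0 <- simulate_trait_table(simulate_tree(cfg0), cfg0)
  expect_true(all(tab0$count_mean == 7))
})

test_that("strong early bursts concentrate divergence among deep splits", {
  # deep-vs-shallow mean-squared-contrast ratio (on the BM-scaled tree) is
  # ~1 under BM and inflated under EB(beta = -5); the EB replicates should
  # exceed their BM-matched controls in >= 90% of draws and sit above 1
  base <- synth_config(n_extant = 64, n_fossils = 0, death_rate = 0, seed = 9)
  u <- rescale_unit_height(simulate_tree(base)$tree)
  deep_shallow_ratio <- function(x) {
    cs <- pic_contrasts(u, x)
    qs <- quantile(cs$node_heights, c(0.25, 0.75))
    mean(cs$contrasts[cs$node_heights >= qs[2]]^2) /
      mean(cs$contrasts[cs$node_heights <= qs[1]]^2)
  }
  sig2_eb <- 60
  sig2_bm <- sig2_eb * (1 - exp(-5)) / 5  # same expected tip variance
  meb <- simulate_traits("EB", list(theta0 = 0, sigma2 = sig2_eb, beta = -5),
                         u, 30, seed = 4)
  mbm <- simulate_traits("BM", list(theta0 = 0, sigma2 = sig2_bm), u, 30,
                         seed = 5)
  reb <- apply(meb, 2, function(x) deep_shallow_ratio(stats::setNames(x, u$tip.label)))
  rbm <- apply(mbm, 2, function(x) deep_shallow_ratio(stats::setNames(x, u$tip.label)))
  expect_gte(mean(reb > rbm), 0.9)
  expect_gte(mean(reb > 1), 0.9)
  expect_gt(median(reb), median(rbm))
})

test_that("make_fixture writes a loadable, self-describing bundle", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_extant = 16, n_fossils = 4, seed = 8,
                      trait_params = list(theta0 = 8, sigma2 = 40, beta = -3))
  out <- make_fixture(file.path(dir, "tiny"), cfg)
  trees <- read_trees(file.path(dir, "tiny", "trees.tre"))
  tab <- read_trait_table(file.path(dir, "tiny", "traits.csv"))
  truth <- jsonlite::read_json(file.path(dir, "tiny", "truth.json"),
                               simplifyVector = TRUE)
  expect_length(trees, 1)
  expect_equal(sort(trees[[1]]$tip.label), sort(tab$species))
  expect_equal(truth$model, "EB")
  expect_equal(truth$n_fossils, 4)
  expect_equal(truth$params$beta, -3)
  # the whole pipeline runs on the bundle
  v <- map_to_tips(tab, trees[[1]], "mean")
  f <- fit_ml("EB", rescale_unit_height(trees[[1]]), v)
  expect_true(is.finite(f$lnL))
})

test_that("the generating model wins model selection on its own fixtures", {
  # identifiability at desk scale: EB with a strong burst should be selected
  # by Akaike weight in nearly all replicates
  base <- synth_config(n_extant = 128, n_fossils = 0, death_rate = 0, seed = 31)
  u <- rescale_unit_height(simulate_tree(base)$tree)
  m <- simulate_traits("EB", list(theta0 = 6, sigma2 = 60, beta = -5), u, 10,
                       seed = 7)
  wins <- apply(m, 2, function(x) {
    # the TREND fit legitimately warns on this ultrametric tree
    fits <- suppressWarnings(
      lapply(c("BM", "OU", "EB", "TREND", "WN"), fit_ml, phy = u,
             traits = stats::setNames(x, u$tip.label)))
    cmp <- akaike_compare(fits)
    cmp$model[which.max(cmp$akaike_weight)]
  })
  expect_gte(mean(wins == "EB"), 0.8)
})
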