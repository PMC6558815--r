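test_that("model specs carry the documented parameter counts", {
  k <- vapply(c("BM", "OU", "EB", "TREND", "WN"),
              function(m) cont_model_spec(m)$k, numeric(1))
  expect_equal(unname(k), c(2, 4, 3, 3, 2))
})

test_that("model_moments match hand computations and limits", {
  phy <- tree3()
  mm <- model_moments("BM", list(theta0 = 0, sigma2 = 2), phy)
  expect_equal(unname(mm$cov), 2 * rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  expect_equal(mm$mean, rep(0, 3))

  # TREND shifts the mean by trend * depth
  mt <- model_moments("TREND", list(theta0 = 1, sigma2 = 1, trend = -0.5), phy)
  expect_equal(mt$mean, 1 - 0.5 * c(2, 2, 2))
  expect_equal(mt$cov, model_moments("BM", list(theta0 = 1, sigma2 = 1), phy)$cov)

  # OU at alpha -> 0 reproduces BM moments
  mo <- model_moments("OU", list(theta0 = 3, theta1 = 9, sigma2 = 2,
                                 alpha = 1e-10), phy)
  mb <- model_moments("BM", list(theta0 = 3, sigma2 = 2), phy)
  expect_equal(mo$cov, mb$cov, tolerance = 1e-6)
  expect_equal(mo$mean, mb$mean, tolerance = 1e-6)

  # EB tip variance on a unit-height tree: sigma2 (1 - exp(beta)) / (-beta)
  u <- rescale_unit_height(tree3())
  me <- model_moments("EB", list(theta0 = 0, sigma2 = 4708.20, beta = -5.04), u)
  expect_equal(unname(diag(me$cov)),
               rep(4708.20 * (1 - exp(-5.04)) / 5.04, 3), tolerance = 1e-10)

  # WN ignores the phylogeny
  mw <- model_moments("WN", list(theta0 = 7, sigma2 = 18), phy)
  expect_equal(unname(mw$cov), 18 * diag(3))
})

test_that("cont_loglik reproduces closed-form densities", {
  phy <- tree3()
  expect_equal(cont_loglik("WN", list(theta0 = 2, sigma2 = 2 / 3), phy,
                           c(A = 1, B = 2, C = 3)),
               -3.648618, tolerance = 1e-6)
  star <- cherry()
  expect_equal(cont_loglik("BM", list(theta0 = 1, sigma2 = 1), star,
                           c(A = 0, B = 2)),
               -log(2 * pi) - 1, tolerance = 1e-12)
})

test_that("EB at beta=0 and TREND at trend=0 collapse to BM", {
  phy <- random_tree(40, seed = 5, fossils = TRUE)
  set.seed(9)
  x <- stats::setNames(rnorm(length(phy$tip.label), 10, 3), phy$tip.label)
  pb <- list(theta0 = 10, sigma2 = 2.5)
  lbm <- cont_loglik("BM", pb, phy, x)
  expect_equal(cont_loglik("EB", c(pb, beta = 0), phy, x), lbm)
  expect_equal(cont_loglik("TREND", c(pb, trend = 0), phy, x), lbm)
})

test_that("cont_loglik is invariant under tip permutation", {
  phy <- random_tree(25, seed = 8)
  set.seed(2)
  x <- stats::setNames(rnorm(25, 5, 2), phy$tip.label)
  p <- list(theta0 = 5, sigma2 = 1.7, beta = -1.2)
  l1 <- cont_loglik("EB", p, phy, x)
  l2 <- cont_loglik("EB", p, phy, sample(x))
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("WN fit is the closed-form sample mean / ML variance", {
  phy <- tree3()
  f <- fit_ml("WN", phy, c(A = 1, B = 2, C = 3))
  expect_equal(f$params$theta0, 2)
  expect_equal(f$params$sigma2, 2 / 3)        # divisor n
  expect_equal(f$lnL, -3.648618, tolerance = 1e-6)
  expect_equal(f$aic, 2 * 2 - 2 * f$lnL)
})

test_that("fit_ml recovers BM parameters and satisfies nesting", {
  phy <- rescale_unit_height(random_tree(200, seed = 3, fossils = TRUE))
  x <- simulate_traits("BM", list(theta0 = 0, sigma2 = 4), phy, 1, seed = 4)[, 1]
  f <- fit_ml("BM", phy, stats::setNames(x, phy$tip.label))
  expect_lt(abs(f$params$sigma2 - 4) / 4, 0.25)
  # theta0 within 3 SE (SE from the GLS information: sigma2 / sum(V^-1))
  V <- phylo_covariance(phy)$S * f$params$sigma2
  se <- sqrt(1 / sum(solve(V)))
  expect_lt(abs(f$params$theta0 - 0), 3 * se)
  feb <- fit_ml("EB", phy, x)
  ftr <- fit_ml("TREND", phy, x)
  expect_gte(feb$lnL, f$lnL - 1e-6)
  expect_gte(ftr$lnL, f$lnL - 1e-6)
  expect_equal(feb$aic, 2 * 3 - 2 * feb$lnL, tolerance = 1e-9)
})

test_that("constant traits warn and return the sigma2 floor", {
  phy <- tree3()
  expect_warning(f <- fit_ml("BM", phy, c(A = 5, B = 5, C = 5)), "constant")
  expect_equal(f$params$sigma2, 1e-10)
})

test_that("akaike_compare normalizes, orders and survives huge deltas", {
  cmp <- akaike_compare(c(BM = 100, EB = 100))
  expect_equal(cmp$akaike_weight, c(0.5, 0.5))
  expect_equal(akaike_compare(c(only = 42))$akaike_weight, 1)
  cmp2 <- akaike_compare(c(a = 0, b = 800))
  expect_equal(sum(cmp2$akaike_weight), 1, tolerance = 1e-12)
  expect_gt(cmp2$akaike_weight[1], cmp2$akaike_weight[2])
  expect_gt(cmp2$akaike_weight[2], 0)  # no underflow to exactly zero at 1e-174
  expect_equal(min(cmp2$delta_aic), 0)
})

test_that("simulate_traits matches analytic variances and is seed-stable", {
  phy <- random_tree(50, seed = 12, fossils = TRUE)
  m <- simulate_traits("BM", list(theta0 = 0, sigma2 = 1), phy, 2000, seed = 5)
  d <- phylo_covariance(phy)$depths
  sv <- apply(m, 1, var)
  se <- d * sqrt(2 / 2000)  # var of a sample variance of N(0, d)
  expect_true(all(abs(sv - d) < 4 * se + 1e-12))
  m2 <- simulate_traits("BM", list(theta0 = 0, sigma2 = 1), phy, 2000, seed = 5)
  expect_identical(m, m2)
  m0 <- simulate_traits("WN", list(theta0 = 3, sigma2 = 0), phy, 3, seed = 1)
  expect_true(all(m0 == 3))
})

test_that("ancestral_states: GLS root, constant invariance, EB(0) == BM", {
  star <- cherry()
  f <- fit_ml("BM", star, c(A = 0, B = 2))
  est <- ancestral_states(f, star, c(A = 0, B = 2))
  expect_equal(unname(est["3"]), 1)
  phy <- random_tree(20, seed = 21)
  expect_warning(fc <- fit_ml("BM", phy,
    stats::setNames(rep(7, 20), phy$tip.label)))
  estc <- ancestral_states(fc, phy, stats::setNames(rep(7, 20), phy$tip.label))
  expect_equal(unname(estc), rep(7, phy$Nnode), tolerance = 1e-6)
  set.seed(1)
  x <- stats::setNames(rnorm(20, 5), phy$tip.label)
  fb <- fit_ml("BM", phy, x)
  feb <- fb; feb$model <- "EB"; feb$params$beta <- 0
  expect_equal(ancestral_states(feb, phy, x), ancestral_states(fb, phy, x))
  fw <- fit_ml("WN", phy, x)
  expect_error(ancestral_states(fw, phy, x), "BM, EB and TREND")
})

test_that("OU fit recovers the optimum on a fossil tree", {
  phy <- rescale_unit_height(random_tree(150, seed = 31, fossils = TRUE))
  x <- simulate_traits("OU", list(theta0 = 5, theta1 = 8, sigma2 = 2,
                                  alpha = 3), phy, 1, seed = 6)[, 1]
  f <- fit_ml("OU", phy, x)
  expect_lt(abs(f$params$theta1 - 8), 1.5)
  expect_gt(f$params$alpha, 0.5)
})
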