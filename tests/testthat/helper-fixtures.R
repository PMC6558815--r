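# Fixtures are built in code; the larger synthetic worlds are memoized so
# several test files can share one simulation.

tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
tree3_fossil <- function() ape::read.tree(text = "((A:1,B:0.5):1,C:2);")
cherry <- function() ape::read.tree(text = "(A:1,B:1);")
balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

random_tree <- function(n, seed, fossils = FALSE, birth = 0.1, death = 0.04) {
  set.seed(seed)
  ape::rphylo(n, birth = birth, death = if (fossils) death else 0,
              fossils = fossils)
}

.world_cache <- new.env(parent = emptyenv())

memo_world <- function(key, builder) {
  if (!exists(key, envir = .world_cache)) {
    assign(key, builder(), envir = .world_cache)
  }
  get(key, envir = .world_cache)
}

# Stand-in for the empirical dataset, stated at the analysed conditions:
# 440 extant + 66 fossil species, counts generated under EB with the
# unit-height-scale parameters estimated from the real data. Synthetic.
paper_world <- function() {
  memo_world("paper", function() {
    cfg <- synth_config(n_extant = 440, n_fossils = 66, seed = 20190610,
                        birth_rate = 0.05, death_rate = 0.025,
                        strat_window = 10, trait_model = "EB",
                        trait_params = list(theta0 = 5.8, sigma2 = 4708.2,
                                            beta = -5.04))
    tr <- simulate_tree(cfg)
    tab <- simulate_trait_table(tr, cfg)
    list(tree = tr$tree, ranges = tr$ranges, table = tab, cfg = cfg)
  })
}

# Desk-scale world for the jackknife and pipeline tests: 128 extant + 30
# fossils, EB with a strong early burst.
small_world <- function() {
  memo_world("small", function() {
    cfg <- synth_config(n_extant = 128, n_fossils = 30, seed = 42,
                        birth_rate = 0.08, death_rate = 0.04,
                        strat_window = 8, trait_model = "EB",
                        trait_params = list(theta0 = 8, sigma2 = 60,
                                            beta = -5))
    tr <- simulate_tree(cfg)
    tab <- simulate_trait_table(tr, cfg)
    list(tree = tr$tree, ranges = tr$ranges, table = tab, cfg = cfg)
  })
}
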