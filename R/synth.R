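# Synthetic-data generator: birth-death trees with sampled fossil tips and
# meristic count tables with the statistical structure the pipeline assumes.
# Defaults state the analysed world: 440 extant + 66 fossil species, root a
# few hundred My deep, counts generated under the early-burst model with the
# unit-height-scale parameters reported for the empirical data.

#' Synthetic-world configuration
#'
#' @param n_extant number of surviving tips the birth-death simulation is
#'   conditioned on.
#' @param birth_rate,death_rate per-lineage rates (per My).
#' @param n_fossils exact number of extinct lineages retained as sampled
#'   fossil tips (`NULL` to use `fossil_keep_prob` instead).
#' @param fossil_keep_prob independent retention probability per extinct
#'   lineage when `n_fossils` is `NULL`.
#' @param strat_window full width (My) of the stratigraphic interval drawn
#'   around each fossil's true age (`fad >= true age >= lad` always).
#' @param trait_model `"BM"`, `"OU"`, `"EB"`, `"TREND"`, `"WN"`, or `"MK"`.
#' @param trait_params named list of generating parameters. Continuous models
#'   are simulated on the unit-height rescaling of the tree (where the
#'   empirical parameter scale lives); ordered-Mk traits are simulated by
#'   exact event sampling on the time tree.
#' @param range_frac fraction of species reported as polymorphic ranges.
#' @param range_halfwidths integer half-widths sampled for reported ranges.
#' @param seed integer run seed.
#' @export
synth_config <- function(n_extant = 440, birth_rate = 0.05, death_rate = 0.025,
                         n_fossils = 66, fossil_keep_prob = 0.5,
                         strat_window = 10,
                         trait_model = "EB",
                         trait_params = list(theta0 = 5.8, sigma2 = 4708.2,
                                             beta = -5.04),
                         range_frac = 0.25, range_halfwidths = 1:2,
                         seed = 1) {
  stopifnot(n_extant >= 2, birth_rate >= 0, death_rate >= 0,
            fossil_keep_prob >= 0, fossil_keep_prob <= 1,
            strat_window >= 0, range_frac >= 0, range_frac <= 1)
  list(n_extant = n_extant, birth_rate = birth_rate, death_rate = death_rate,
       n_fossils = n_fossils, fossil_keep_prob = fossil_keep_prob,
       strat_window = strat_window, trait_model = toupper(trait_model),
       trait_params = trait_params, range_frac = range_frac,
       range_halfwidths = range_halfwidths, seed = seed)
}

#' Simulate a dated birth-death tree with sampled fossil tips
#'
#' A birth-death tree conditioned on `cfg$n_extant` survivors is simulated
#' (with extinct lineages kept), extinct tips are subsampled as fossils, and
#' each fossil gets a stratigraphic interval bracketing its true age within
#' `cfg$strat_window`. Retries (up to 100, logged) when too few extinct
#' lineages are produced.
#'
#' @param cfg a [synth_config()].
#' @return list with `tree` (a dated `phylo`; fossil tips relabelled
#'   `fos_*`, extant `sp_*`) and `ranges` (data frame `taxon`, `fad`, `lad`,
#'   `true_age`).
#' @export
simulate_tree <- function(cfg) {
  need <- if (is.null(cfg$n_fossils)) 0L else cfg$n_fossils
  for (try in seq_len(100)) {
    set.seed(child_seed(cfg$seed, try))
    phy <- tryCatch(
      ape::rphylo(cfg$n_extant, birth = cfg$birth_rate,
                  death = cfg$death_rate, fossils = TRUE),
      error = function(e) NULL)
    if (is.null(phy)) next
    ages <- tip_ages(phy)
    fossils <- names(ages)[ages > 1e-8]
    if (length(fossils) >= need) {
      keep_f <- if (!is.null(cfg$n_fossils)) {
        if (cfg$n_fossils == 0) character(0) else
          sample(fossils, cfg$n_fossils)
      } else {
        fossils[stats::runif(length(fossils)) < cfg$fossil_keep_prob]
      }
      extant <- names(ages)[ages <= 1e-8]
      phy2 <- ape::keep.tip(phy, c(extant, keep_f))
      a2 <- tip_ages(phy2)
      new_lab <- phy2$tip.label
      is_f <- a2 > 1e-8
      new_lab[!is_f] <- sprintf("sp_%03d", seq_len(sum(!is_f)))
      new_lab[is_f] <- sprintf("fos_%03d", seq_len(sum(is_f)))
      phy2$tip.label <- new_lab
      a2 <- tip_ages(phy2)
      fa <- a2[a2 > 1e-8]
      w <- cfg$strat_window
      ranges <- data.frame(
        taxon = names(fa),
        fad = fa + stats::runif(length(fa), 0, w / 2),
        lad = pmax(0, fa - stats::runif(length(fa), 0, w / 2)),
        true_age = unname(fa))
      attr(phy2, "n_retries") <- try - 1L
      return(list(tree = phy2, ranges = ranges))
    }
  }
  stop("failed to simulate a tree with ", need, " fossil lineages in 100 tries")
}

#' Simulate a meristic count table on a tree
#'
#' Continuous models are simulated on the unit-height rescaling of the tree
#' and mapped to counts by rounding half up and flooring at 0; `"MK"`
#' simulates integer states directly by exact event sampling. A configured
#' fraction of species get a reported polymorphic range around their value;
#' the rest are point records. The pre-rounding values and generating
#' parameters are kept in the `"truth"` attribute for recovery tests.
#'
#' @param tree_and_ranges result of [simulate_tree()] (or a list with
#'   elements `tree` and `ranges`).
#' @param cfg a [synth_config()].
#' @return a validated `trait_table` data frame.
#' @export
simulate_trait_table <- function(tree_and_ranges, cfg) {
  phy <- tree_and_ranges$tree
  ranges <- tree_and_ranges$ranges
  n <- length(phy$tip.label)
  if (cfg$trait_model == "MK") {
    p <- cfg$trait_params
    spec <- ordered_mk_spec(p$n_states, p$q_gain, p$q_loss)
    states <- simulate_mk(phy, spec, p$root_state, child_seed(cfg$seed, 211))
    raw <- as.numeric(states)
  } else {
    ut <- rescale_unit_height(phy)
    raw <- as.numeric(simulate_traits(cfg$trait_model, cfg$trait_params, ut,
                                      1, child_seed(cfg$seed, 211)))
  }
  counts <- pmax(0, floor(raw + 0.5))
  set.seed(child_seed(cfg$seed, 212))
  poly <- stats::runif(n) < cfg$range_frac
  hw <- sample(cfg$range_halfwidths, n, replace = TRUE)
  cmin <- ifelse(poly, pmax(0, counts - hw), counts)
  cmax <- ifelse(poly, counts + hw, counts)
  ext <- phy$tip.label %in% ranges$taxon
  ri <- match(phy$tip.label, ranges$taxon)
  df <- data.frame(
    species = phy$tip.label,
    old_label = phy$tip.label,
    count_min = cmin,
    count_max = cmax,
    count_mean = (cmin + cmax) / 2,
    polymorphism_reported = poly,
    extinct = ext,
    fad = ifelse(ext, ranges$fad[ri], NA_real_),
    lad = ifelse(ext, ranges$lad[ri], NA_real_))
  df <- validate_trait_table(df)
  attr(df, "truth") <- list(model = cfg$trait_model,
                            params = cfg$trait_params,
                            raw_values = stats::setNames(raw, phy$tip.label))
  df
}

#' Write a self-describing synthetic fixture bundle
#'
#' Creates `<dir>/trees.tre` (Newick), `<dir>/traits.csv` (trait-table
#' schema) and `<dir>/truth.json` (generating parameters), so recovery tests
#' can compare estimates to the truth. All synthetic.
#'
#' @param dir output directory (created).
#' @param cfg a [synth_config()].
#' @return the directory path, invisibly; the generated objects as the
#'   `"bundle"` attribute.
#' @export
make_fixture <- function(dir, cfg) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- simulate_tree(cfg)
  tab <- simulate_trait_table(tr, cfg)
  ape::write.tree(tr$tree, file.path(dir, "trees.tre"))
  write_trait_table(tab, file.path(dir, "traits.csv"))
  truth <- attr(tab, "truth")
  jsonlite::write_json(
    list(model = truth$model, params = truth$params,
         n_extant = cfg$n_extant, n_fossils = sum(tab$extinct),
         seed = cfg$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  out <- structure(dir, bundle = list(tree = tr$tree, ranges = tr$ranges,
                                      traits = tab))
  invisible(out)
}
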