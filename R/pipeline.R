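# Run configuration, command entry points and the reproduction harness.
# Configuration is a JSON file (same keys as the documented schema) merged
# over defaults; every command is deterministic given (inputs, config, seed)
# and writes TSV + JSON outputs plus a manifest into the output directory.

run_config_defaults <- function() {
  list(
    trees = NULL, traits = NULL, out_dir = "meristevo_out",
    variant = "mean",
    models = c("BM", "OU", "EB", "TREND", "WN"),
    seed = 1,
    ensemble = list(n_trees = NULL, min_bl = 1, resample_tip_ages = FALSE),
    adequacy = list(n_sim = 1000, model = "EB"),
    jackknife = list(group = "fossil", steps = 10, reps = 20, cap = NULL),
    mk = list(root_prior = "uniform", n_states = NULL, alpha = 0.05),
    correct_lepidosiren = FALSE)
}

#' Load a run configuration
#'
#' @param config path to a JSON file, or a named list of overrides; missing
#'   keys take their documented defaults.
#' @return the merged configuration list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  merge_cfg <- function(def, ov) {
    for (k in names(ov)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(ov[[k]])) {
        merge_cfg(def[[k]], ov[[k]])
      } else ov[[k]]
    }
    def
  }
  merge_cfg(run_config_defaults(), config)
}

load_inputs <- function(cfg) {
  if (is.null(cfg$trees) || is.null(cfg$traits)) {
    stop("config must name 'trees' (Newick) and 'traits' (CSV) inputs")
  }
  trees <- read_trees(cfg$trees)
  if (!is.null(cfg$ensemble$n_trees)) {
    trees <- trees[seq_len(min(length(trees), cfg$ensemble$n_trees))]
  }
  tab <- read_trait_table(cfg$traits)
  if (isTRUE(cfg$correct_lepidosiren)) {
    i <- which(tab$species == "Lepidosiren_paradoxa")
    if (length(i)) {
      tab$count_min[i] <- 0; tab$count_max[i] <- 0; tab$count_mean[i] <- 0
    }
  }
  # analyses run on the taxa shared by tree and table
  keep <- intersect(trees[[1]]$tip.label, tab$species)
  if (length(keep) < 3) stop("fewer than 3 taxa shared by tree and traits")
  trees <- lapply(trees, prune_to_taxa, taxa = keep)
  if (isTRUE(cfg$ensemble$resample_tip_ages) && length(trees) >= 1) {
    trees <- sample_fossil_tip_ages(trees[[1]], strat_ranges(tab),
                                    n_trees = max(1, length(trees)),
                                    seed = cfg$seed,
                                    min_bl = cfg$ensemble$min_bl)
  }
  list(trees = trees, table = tab, taxa = keep)
}

write_manifest <- function(cfg, out_dir, stage) {
  hash_file <- function(p) {
    if (is.null(p) || !file.exists(p)) return(NA_character_)
    as.character(tools::md5sum(p))
  }
  jsonlite::write_json(
    list(stage = stage, config = cfg, seed = cfg$seed,
         input_md5 = list(trees = hash_file(cfg$trees),
                          traits = hash_file(cfg$traits)),
         package_version = as.character(utils::packageVersion("meristevo")),
         r_version = R.version.string),
    file.path(out_dir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE, digits = NA)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Continuous-model comparison over the tree ensemble
#'
#' Reads the inputs, rescales every tree to unit height, fits the configured
#' models on every tree, and writes a table-style report (per-model mean and
#' SD of parameters and lnL across trees, mean AIC, Akaike weights).
#'
#' @param config path or list, see [run_config()].
#' @return the `ensemble_result`, invisibly; outputs under `cfg$out_dir`:
#'   `fit_long.tsv`, `fit_summary.tsv`, `fit_summary.json`.
#' @export
cmd_fit <- function(config) {
  cfg <- run_config(config)
  inp <- load_inputs(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  traits <- map_to_tips(inp$table, inp$trees[[1]], cfg$variant)
  trees <- lapply(inp$trees, rescale_unit_height)
  res <- run_ensemble(trees, traits, cfg$models, variant = cfg$variant)
  write_tsv(res$long, file.path(cfg$out_dir, "fit_long.tsv"))
  write_tsv(res$summary, file.path(cfg$out_dir, "fit_summary.tsv"))
  jsonlite::write_json(res$summary, file.path(cfg$out_dir, "fit_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_manifest(cfg, cfg$out_dir, "fit")
  invisible(res)
}

#' Ordered Mk model comparison with likelihood-ratio test
#'
#' Fits the symmetric and asymmetric ordered Mk models to the discretized
#' counts on every tree, for the mean, soft-minimum and soft-maximum state
#' assignments; reports medians across trees and the LRT on the median
#' likelihoods, plus the per-tree LRT verdicts.
#'
#' @inheritParams cmd_fit
#' @return data frame report, invisibly; output `mk_report.tsv`.
#' @export
cmd_mk <- function(config) {
  cfg <- run_config(config)
  inp <- load_inputs(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (variant in c("discrete", "min", "max")) {
    states <- map_to_tips(inp$table, inp$trees[[1]], variant)
    n_states <- cfg$mk$n_states %||% (max(states) + 1)
    per_tree <- lapply(inp$trees, function(tr) {
      tru <- rescale_unit_height(tr)
      sym <- fit_mk(tru, states, symmetric = TRUE, n_states = n_states,
                    root_prior = cfg$mk$root_prior)
      asym <- fit_mk(tru, states, symmetric = FALSE, n_states = n_states,
                     root_prior = cfg$mk$root_prior)
      c(rate_sym = sym$spec$q_gain, lnL_sym = sym$lnL,
        gain = asym$spec$q_gain, loss = asym$spec$q_loss,
        lnL_asym = asym$lnL,
        lrt_stat = mk_lrt(sym, asym)$statistic,
        lrt_p = mk_lrt(sym, asym)$p_value)
    })
    med <- apply(do.call(rbind, per_tree), 2, stats::median)
    stat <- max(0, 2 * (med["lnL_asym"] - med["lnL_sym"]))
    rows[[variant]] <- data.frame(
      variant = variant, n_states = n_states,
      rate_sym_median = med["rate_sym"], lnL_sym_median = med["lnL_sym"],
      gain_median = med["gain"], loss_median = med["loss"],
      lnL_asym_median = med["lnL_asym"],
      lrt_stat = stat,
      lrt_p = stats::pchisq(stat, 1, lower.tail = FALSE),
      lrt_p_median_per_tree = med["lrt_p"],
      significant = stats::pchisq(stat, 1, lower.tail = FALSE) < cfg$mk$alpha)
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  write_tsv(rep, file.path(cfg$out_dir, "mk_report.tsv"))
  write_manifest(cfg, cfg$out_dir, "mk")
  invisible(rep)
}

#' Contrast-based adequacy test of the configured model
#'
#' Fits the configured model (default EB) on each tree, runs the
#' posterior-predictive adequacy test on the first tree of the ensemble, and
#' writes the observed statistics, null moments and p-values.
#'
#' @inheritParams cmd_fit
#' @return the `pp_result`, invisibly; output `adequacy_report.tsv`.
#' @export
cmd_adequacy <- function(config) {
  cfg <- run_config(config)
  inp <- load_inputs(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  traits <- map_to_tips(inp$table, inp$trees[[1]], cfg$variant)
  tr <- rescale_unit_height(inp$trees[[1]])
  fit <- fit_ml(cfg$adequacy$model, tr, traits)
  pp <- pp_test(fit, tr, traits, n_sim = cfg$adequacy$n_sim, seed = cfg$seed)
  rep <- data.frame(
    statistic = names(pp$p_values),
    observed = unlist(pp$observed[names(pp$p_values)]),
    null_mean = colMeans(pp$null_distribution),
    null_sd = apply(pp$null_distribution, 2, stats::sd),
    p_value = pp$p_values, tail = pp$tails, row.names = NULL)
  write_tsv(rep, file.path(cfg$out_dir, "adequacy_report.tsv"))
  write_manifest(cfg, cfg$out_dir, "adequacy")
  invisible(pp)
}

#' Taxon jackknife sensitivity analysis
#'
#' @inheritParams cmd_fit
#' @return the `jackknife_result`, invisibly; outputs `jackknife_long.tsv`,
#'   `jackknife_summary.tsv`.
#' @export
cmd_jackknife <- function(config) {
  cfg <- run_config(config)
  inp <- load_inputs(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  traits <- map_to_tips(inp$table, inp$trees[[1]], cfg$variant)
  trees <- lapply(inp$trees, rescale_unit_height)
  plan <- make_jackknife_plan(inp$trees[[1]], inp$table,
                              group = cfg$jackknife$group,
                              n_steps = cfg$jackknife$steps,
                              n_reps = cfg$jackknife$reps,
                              cap = cfg$jackknife$cap, seed = cfg$seed)
  res <- run_jackknife(trees, traits, plan, cfg$models)
  write_tsv(res$long, file.path(cfg$out_dir, "jackknife_long.tsv"))
  write_tsv(res$summary, file.path(cfg$out_dir, "jackknife_summary.tsv"))
  write_manifest(cfg, cfg$out_dir, "jackknife")
  invisible(res)
}

#' Generate a synthetic fixture from a config
#'
#' @param config list or JSON path with an element `synth` of
#'   [synth_config()] arguments and an `out_dir`.
#' @export
cmd_simulate <- function(config) {
  cfg <- run_config(config)
  scfg <- do.call(synth_config, cfg$synth %||% list())
  make_fixture(cfg$out_dir, scfg)
}

#' Re-time-scale trees against stratigraphic ranges
#'
#' Applies MBL time-scaling with resampled fossil tip ages and writes the
#' resulting tree ensemble as Newick.
#'
#' @inheritParams cmd_fit
#' @export
cmd_timescale <- function(config) {
  cfg <- run_config(config)
  inp <- load_inputs(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- cfg$ensemble$n_trees %||% 50
  trees <- sample_fossil_tip_ages(inp$trees[[1]], strat_ranges(inp$table),
                                  n_trees = n, seed = cfg$seed,
                                  min_bl = cfg$ensemble$min_bl)
  out <- file.path(cfg$out_dir, "trees_rescaled.tre")
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, out)
  write_manifest(cfg, cfg$out_dir, "timescale")
  invisible(out)
}

#' Command-line dispatcher
#'
#' Usage from a shell: `Rscript -e 'meristevo::meristevo_cli()' fit cfg.json`
#' (subcommands: fit, mk, adequacy, jackknife, simulate, timescale).
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @export
meristevo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 2) {
    stop("usage: <fit|mk|adequacy|jackknife|simulate|timescale> <config.json>")
  }
  fn <- switch(args[1],
               fit = cmd_fit, mk = cmd_mk, adequacy = cmd_adequacy,
               jackknife = cmd_jackknife, simulate = cmd_simulate,
               timescale = cmd_timescale,
               stop("unknown subcommand: ", args[1]))
  fn(args[2])
}
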