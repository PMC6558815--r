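# Ensemble analysis over the resampled-tree set and taxon jackknife
# sensitivity experiments.

#' Fit a set of continuous models over a tree ensemble
#'
#' Every model is fitted on every tree; the summary reports per-model mean
#' and SD of each parameter and lnL across trees, the mean AIC, and Akaike
#' weights computed from the mean AICs (which reproduces table-style weights
#' computed from printed mean AICs). Per-tree weights are kept in the long
#' table. Single-fit failures are recorded and excluded with a warning.
#'
#' @param trees list of dated `phylo` objects sharing one tip set.
#' @param traits named numeric vector covering that tip set.
#' @param models character vector of continuous model names.
#' @param variant label recorded in the output (e.g. `"mean"`).
#' @param ... passed to [fit_ml()].
#' @return list of class `ensemble_result`: `long` (one row per tree x
#'   model) and `summary` (one row per model).
#' @export
run_ensemble <- function(trees, traits, models = cont_model_names,
                         variant = "mean", ...) {
  rows <- list()
  failures <- character(0)
  for (ti in seq_along(trees)) {
    fits <- list()
    for (m in models) {
      f <- tryCatch(fit_ml(m, trees[[ti]], traits, tree_id = ti, ...),
                    error = function(e) e)
      if (inherits(f, "error")) {
        failures <- c(failures, sprintf("tree %d, %s: %s", ti, m, conditionMessage(f)))
      } else fits[[m]] <- f
    }
    if (length(fits) == 0) next
    cmp <- akaike_compare(fits)
    for (m in names(fits)) {
      f <- fits[[m]]
      p <- f$params
      rows[[length(rows) + 1L]] <- data.frame(
        tree_id = ti, model = m, variant = variant,
        theta0 = p$theta0, theta1 = p$theta1 %||% NA_real_,
        sigma2 = p$sigma2, alpha = p$alpha %||% NA_real_,
        beta = p$beta %||% NA_real_, trend = p$trend %||% NA_real_,
        lnL = f$lnL, aic = f$aic,
        akaike_weight = cmp$akaike_weight[cmp$model == m])
    }
  }
  if (length(failures)) {
    warning("fit failures excluded: ", paste(failures, collapse = "; "))
  }
  long <- do.call(rbind, rows)
  summ <- ensemble_summary(long)
  structure(list(long = long, summary = summ, failures = failures),
            class = "ensemble_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ensemble_summary <- function(long) {
  pars <- c("theta0", "theta1", "sigma2", "alpha", "beta", "trend", "lnL")
  out <- lapply(split(long, long$model), function(d) {
    row <- data.frame(model = d$model[1], n_trees = nrow(d))
    for (p in pars) {
      row[[paste0(p, "_mean")]] <- mean(d[[p]])
      row[[paste0(p, "_sd")]] <- if (nrow(d) > 1) stats::sd(d[[p]]) else 0
    }
    row$aic_mean <- mean(d$aic)
    row
  })
  summ <- do.call(rbind, out)
  cmp <- akaike_compare(stats::setNames(summ$aic_mean, summ$model))
  summ$delta_aic <- cmp$delta_aic[match(summ$model, cmp$model)]
  summ$akaike_weight <- cmp$akaike_weight[match(summ$model, cmp$model)]
  rownames(summ) <- NULL
  summ
}

#' Plan a taxon jackknife experiment
#'
#' Removal counts are a rounded linear ramp from `cap / n_steps` up to `cap`.
#' By analogy with the empirical design, the fossil group's cap defaults to
#' the whole fossil pool and the extant group's to 15% of the extant pool.
#'
#' @param phy a dated `phylo` (defines which tips are extinct).
#' @param trait_df trait table giving the removable pools.
#' @param group `"fossil"` or `"extant"`.
#' @param n_steps number of removal steps.
#' @param n_reps replicates per step.
#' @param cap maximum number removed (default per group, see above).
#' @param seed integer seed for the removal draws.
#' @return list of class `jackknife_plan`: `group`, `pool`, `step_sizes`,
#'   `n_reps`, `seed`.
#' @export
make_jackknife_plan <- function(phy, trait_df, group = c("fossil", "extant"),
                                n_steps = 10, n_reps = 500, cap = NULL,
                                seed = 1) {
  group <- match.arg(group)
  if (n_steps < 1 || n_reps < 1) stop("n_steps and n_reps must be >= 1")
  on_tree <- trait_df$species %in% phy$tip.label
  pool <- if (group == "fossil") {
    trait_df$species[trait_df$extinct & on_tree]
  } else {
    trait_df$species[!trait_df$extinct & on_tree]
  }
  if (length(pool) == 0) stop("empty removable pool for group ", group)
  if (is.null(cap)) {
    cap <- if (group == "fossil") length(pool) else round(0.15 * length(pool))
  }
  if (cap > length(pool)) stop("cap exceeds pool size")
  step_sizes <- unique(round(seq(cap / n_steps, cap, length.out = n_steps)))
  step_sizes <- step_sizes[step_sizes >= 1]
  structure(list(group = group, pool = pool, step_sizes = step_sizes,
                 n_reps = n_reps, seed = seed), class = "jackknife_plan")
}

#' Run a taxon jackknife over a tree ensemble
#'
#' For each removal step and replicate: draw the removal set without
#' replacement, prune every tree, refit all models, and record estimates and
#' Akaike weights. A baseline row block with 0 removals (the full data) is
#' always included. The summary reports per-step medians keyed by the number
#' of pool taxa retained.
#'
#' @param trees list of dated `phylo` objects (the ensemble).
#' @param traits named numeric vector over the full tip set.
#' @param plan a [make_jackknife_plan()].
#' @param models continuous model names.
#' @param progress emit a message per (step, replicate) cell.
#' @param ... passed to [fit_ml()].
#' @return list of class `jackknife_result`: `long` (per tree x rep x step x
#'   model) and `summary` (per step x model medians and quartiles).
#' @export
run_jackknife <- function(trees, traits, plan, models = cont_model_names,
                          progress = FALSE, ...) {
  cells <- list()
  base <- run_ensemble(trees, traits, models, ...)
  b <- base$long
  b$n_removed <- 0L
  b$rep <- 1L
  cells[[1]] <- b
  for (si in seq_along(plan$step_sizes)) {
    s <- plan$step_sizes[si]
    for (r in seq_len(plan$n_reps)) {
      set.seed(child_seed(plan$seed, si * 100000 + r))
      removed <- sample(plan$pool, s)
      kept_tips <- setdiff(trees[[1]]$tip.label, removed)
      sub_trees <- lapply(trees, prune_to_taxa, taxa = kept_tips)
      res <- run_ensemble(sub_trees, traits[kept_tips], models, ...)
      d <- res$long
      if (is.null(d) || !all(models %in% unique(d$model))) next
      d$n_removed <- s
      d$rep <- r
      cells[[length(cells) + 1L]] <- d
      if (progress) {
        message(sprintf("jackknife %s: removed %d, rep %d done",
                        plan$group, s, r))
      }
    }
  }
  long <- do.call(rbind, cells)
  long$n_retained <- length(plan$pool) - long$n_removed
  summ <- jackknife_summary(long)
  structure(list(long = long, summary = summ, plan = plan),
            class = "jackknife_result")
}

jackknife_summary <- function(long) {
  key <- interaction(long$n_removed, long$model, drop = TRUE)
  out <- lapply(split(long, key), function(d) {
    data.frame(
      n_removed = d$n_removed[1], n_retained = d$n_retained[1],
      model = d$model[1], n_fits = nrow(d),
      weight_median = stats::median(d$akaike_weight),
      weight_q25 = stats::quantile(d$akaike_weight, 0.25, names = FALSE),
      weight_q75 = stats::quantile(d$akaike_weight, 0.75, names = FALSE),
      sigma2_median = stats::median(d$sigma2),
      theta0_median = stats::median(d$theta0),
      theta1_median = stats::median(d$theta1),
      alpha_median = stats::median(d$alpha),
      beta_median = stats::median(d$beta),
      trend_median = stats::median(d$trend),
      lnL_median = stats::median(d$lnL))
  })
  summ <- do.call(rbind, out)
  summ <- summ[order(summ$n_removed, summ$model), ]
  rownames(summ) <- NULL
  summ
}
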