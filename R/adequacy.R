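# Phylogenetic independent contrasts and contrast-based model adequacy.
#
# If the fitted model is the true generating process, contrasts computed on
# the model-rescaled ("unit") tree are iid standard normal. Departures are
# summarized by:
#   m_sig  mean squared contrast (overall rate check)
#   c_var  coefficient of variation of |contrasts| (rate heterogeneity)
#   s_asr  OLS slope of |contrast| on the nodal ancestral value
#          (state-dependent rates)
#   d_cdf  Kolmogorov-Smirnov distance of the contrasts from
#          Normal(0, sqrt(m_sig)) (non-normality / jumps)
# and calibrated by posterior-predictive simulation under the fitted model.

#' Rescale a tree so a fitted model becomes unit-rate Brownian motion
#'
#' BM: every branch times `sigma2`; EB: branch over depths `[t1, t2]` gets
#' `sigma2 (exp(beta t2) - exp(beta t1)) / beta`; TREND: as BM (the trend
#' enters the mean only). On the returned tree, contrasts of adequate data
#' are standard normal.
#'
#' @param fit a `cont_fit` for BM, EB or TREND.
#' @param phy the tree the model was fitted on.
#' @export
unit_tree <- function(fit, phy) {
  if (!fit$model %in% c("BM", "EB", "TREND")) {
    stop("unit_tree supports BM, EB and TREND fits only")
  }
  beta <- if (fit$model == "EB") fit$params$beta else 0
  model_rescaled_tree(phy, beta = beta, sigma2 = fit$params$sigma2)
}

#' Phylogenetic independent contrasts (Felsenstein recursion)
#'
#' At each internal node of the binary tree, the standardized contrast is
#' `(x_i - x_j) / sqrt(v_i + v_j)`, the nodal value is the
#' precision-weighted average of the daughter values, and the branch above
#' the node is extended by `v_i v_j / (v_i + v_j)`. Zero-length cherries get
#' the configured variance floor.
#'
#' @param phy a rooted binary `phylo` with branch lengths.
#' @param traits named numeric vector aligned to the tips.
#' @param var_floor lower bound on the contrast variance denominator.
#' @return list of class `contrast_set`: `contrasts`, `nodal_values`,
#'   `expected_variances`, `node_heights` (node ages), each of length
#'   `Ntip - 1`, named by internal node number.
#' @export
pic_contrasts <- function(phy, traits, var_floor = 1e-12) {
  if (!ape::is.binary(phy)) stop("tree must be binary; resolve polytomies first")
  x <- align_traits(traits, phy)
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  val <- numeric(n_all); val[seq_len(n_tip)] <- x
  extra <- numeric(n_all)   # accumulated variance above each node
  contrast <- numeric(phy$Nnode)
  nodal <- numeric(phy$Nnode)
  evar <- numeric(phy$Nnode)
  eo <- ape::reorder.phylo(phy, "postorder")
  ed <- eo$edge; el <- eo$edge.length
  floored <- 0L
  # a parent is processed once both its child edges have been seen; postorder
  # guarantees children's subtrees are complete by then
  first_child <- integer(n_all)
  first_len <- numeric(n_all)
  for (k in seq_len(nrow(ed))) {
    p <- ed[k, 1L]
    if (first_child[p] == 0L) {
      first_child[p] <- ed[k, 2L]
      first_len[p] <- el[k]
      next
    }
    c1 <- first_child[p]; c2 <- ed[k, 2L]
    v1 <- first_len[p] + extra[c1]
    v2 <- el[k] + extra[c2]
    vsum <- v1 + v2
    if (vsum < var_floor) { vsum <- var_floor; floored <- floored + 1L }
    j <- p - n_tip
    contrast[j] <- (val[c1] - val[c2]) / sqrt(vsum)
    w1 <- if (v1 <= 0 && v2 <= 0) 0.5 else v2 / vsum
    nodal[j] <- w1 * val[c1] + (1 - w1) * val[c2]
    evar[j] <- vsum
    val[p] <- nodal[j]
    extra[p] <- if (vsum <= 0) 0 else v1 * v2 / vsum
  }
  if (floored > 0) {
    warning(floored, " contrast variance denominator(s) floored at ", var_floor)
  }
  ages <- node_ages(phy)[(n_tip + 1L):n_all]
  nm <- as.character((n_tip + 1L):n_all)
  structure(list(contrasts = stats::setNames(contrast, nm),
                 nodal_values = stats::setNames(nodal, nm),
                 expected_variances = stats::setNames(evar, nm),
                 node_heights = stats::setNames(ages, nm)),
            class = "contrast_set")
}

#' Adequacy statistics of a contrast set
#'
#' @param cs a [pic_contrasts()] result.
#' @param sqrt_transform compute `s_asr` on square-root-transformed
#'   `|contrasts|` instead of raw values.
#' @return list with `m_sig`, `c_var`, `s_asr`, `d_cdf` and `s_asr_p` (the
#'   OLS t-test p-value of the slope); `s_asr` is `NA` with fewer than 3
#'   contrasts.
#' @export
adequacy_stats <- function(cs, sqrt_transform = FALSE) {
  cc <- cs$contrasts
  m <- length(cc)
  m_sig <- mean(cc^2)
  ac <- abs(cc)
  c_var <- if (mean(ac) > 0) stats::sd(ac) / mean(ac) else 0
  if (m >= 3) {
    y <- if (sqrt_transform) sqrt(ac) else ac
    sl <- stats::lm(y ~ cs$nodal_values)
    s_asr <- unname(stats::coef(sl)[2])
    s_asr_p <- tryCatch(
      suppressWarnings(summary(sl)$coefficients[2, 4]),  # constant |contrasts|
      error = function(e) NA_real_)
  } else {
    s_asr <- NA_real_
    s_asr_p <- NA_real_
  }
  # sup distance between the contrast ECDF and Normal(0, sqrt(m_sig)),
  # evaluated on both sides of every step
  z <- sort(cc)
  Fi <- stats::pnorm(z, mean = 0, sd = sqrt(m_sig))
  d_cdf <- max(abs(seq_len(m) / m - Fi), abs((seq_len(m) - 1) / m - Fi))
  list(m_sig = m_sig, c_var = c_var, s_asr = s_asr, d_cdf = d_cdf,
       s_asr_p = s_asr_p)
}

#' Posterior-predictive adequacy test of a fitted continuous model
#'
#' Simulates `n_sim` datasets under the fitted model on the original tree,
#' recomputes the adequacy statistics of each on the same unit tree, and
#' returns a two-tailed Monte-Carlo p-value per statistic with the +1
#' correction: `p = min(1, 2 * min(p_low, p_high))` where
#' `p_low = (1 + #{sim <= obs}) / (n_sim + 1)`.
#'
#' @param fit a `cont_fit` for BM, EB or TREND.
#' @param phy the tree the model was fitted on.
#' @param traits the observed trait vector.
#' @param n_sim number of simulations (>= 100).
#' @param seed integer seed.
#' @param sqrt_transform passed to [adequacy_stats()].
#' @return list of class `pp_result`: `observed`, `null_distribution`
#'   (matrix `n_sim x 4`), `p_values`, `tails`, `n_sim`.
#' @export
pp_test <- function(fit, phy, traits, n_sim = 1000, seed = 1,
                    sqrt_transform = FALSE) {
  if (n_sim < 100) stop("n_sim must be >= 100")
  ut <- unit_tree(fit, phy)
  x <- align_traits(traits, phy)
  detrend <- function(v) {
    if (fit$model == "TREND") {
      v - fit$params$trend * node_depths(phy)[seq_along(v)]
    } else v
  }
  obs_cs <- pic_contrasts(ut, stats::setNames(detrend(x), phy$tip.label))
  obs <- adequacy_stats(obs_cs, sqrt_transform)
  sims <- simulate_traits(fit$model, fit$params, phy, n_sim, seed)
  stat_names <- c("m_sig", "c_var", "s_asr", "d_cdf")
  null <- matrix(NA_real_, n_sim, 4, dimnames = list(NULL, stat_names))
  for (i in seq_len(n_sim)) {
    cs <- pic_contrasts(ut, stats::setNames(detrend(sims[, i]), phy$tip.label))
    st <- adequacy_stats(cs, sqrt_transform)
    null[i, ] <- unlist(st[stat_names])
  }
  p <- numeric(4); names(p) <- stat_names
  tails <- character(4); names(tails) <- stat_names
  for (s in stat_names) {
    o <- obs[[s]]
    if (is.na(o)) { p[s] <- NA_real_; tails[s] <- "undefined"; next }
    p_low <- (1 + sum(null[, s] <= o, na.rm = TRUE)) / (n_sim + 1)
    p_high <- (1 + sum(null[, s] >= o, na.rm = TRUE)) / (n_sim + 1)
    p[s] <- min(1, 2 * min(p_low, p_high))
    tails[s] <- if (p_high < p_low) "upper" else "lower"
  }
  structure(list(observed = obs, null_distribution = null, p_values = p,
                 tails = tails, n_sim = n_sim), class = "pp_result")
}
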