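# Exact Gaussian machinery for the five continuous trait models.
#
# Every model is multivariate normal over the tips:
#   BM:    mean_i = theta0;                    Cov_ij = sigma2 * S_ij
#   TREND: mean_i = theta0 + trend * T_i;      Cov as BM
#   EB:    mean_i = theta0;                    Cov_ij = sigma2 * (exp(beta*S_ij)-1)/beta
#   OU:    mean_i = theta1 + (theta0-theta1)*exp(-alpha*T_i)
#          Cov_ij = sigma2/(2 alpha) * exp(-alpha*(T_i+T_j-2 S_ij)) * (1-exp(-2 alpha S_ij))
#   WN:    mean_i = theta0;                    Cov = sigma2 * I
# with S_ij the shared root-to-MRCA path and T_i the root-to-tip depth.
# The OU variant is the fixed-root, non-stationary one (theta0 free), which is
# well defined on non-ultrametric fossil trees.

cont_model_names <- c("BM", "OU", "EB", "TREND", "WN")
cont_model_k <- c(BM = 2, OU = 4, EB = 3, TREND = 3, WN = 2)

#' Continuous-model specification
#'
#' @param name one of `"BM"`, `"OU"`, `"EB"`, `"TREND"`, `"WN"`.
#' @return list with the model name and its parameter count `k`
#'   (BM 2, OU 4, EB 3, TREND 3, WN 2).
#' @export
cont_model_spec <- function(name) {
  name <- match.arg(toupper(name), cont_model_names)
  list(name = name, k = unname(cont_model_k[name]))
}

# Covariance shape V0 such that Cov = sigma2 * V0; `shape` is alpha (OU) or
# beta (EB), ignored otherwise.
cont_cov_shape <- function(name, S, depths, shape = 0) {
  n <- length(depths)
  switch(name,
    BM = ,
    TREND = S,
    WN = diag(n),
    EB = if (abs(shape) < 1e-12) S else (exp(shape * S) - 1) / shape,
    OU = {
      a <- shape
      if (a < 1e-10) return(S)
      D <- outer(depths, depths, "+") - 2 * S
      exp(-a * D) * (1 - exp(-2 * a * S)) / (2 * a)
    },
    stop("unknown model ", name))
}

# Design matrix for the GLS-profiled location parameters.
cont_design <- function(name, depths, shape = 0) {
  n <- length(depths)
  switch(name,
    BM = ,
    EB = ,
    WN = matrix(1, n, 1, dimnames = list(NULL, "theta0")),
    TREND = cbind(theta0 = rep(1, n), trend = depths),
    OU = {
      if (shape < 1e-10) {
        matrix(1, n, 1, dimnames = list(NULL, "theta0"))
      } else {
        w <- exp(-shape * depths)
        cbind(theta0 = w, theta1 = 1 - w)
      }
    })
}

#' Model mean vector and covariance matrix over the tips
#'
#' @param spec a [cont_model_spec()].
#' @param params named list/vector with the relevant entries among `theta0`,
#'   `theta1`, `sigma2`, `alpha`, `beta`, `trend`.
#' @param phy a rooted dated `phylo`.
#' @return list with `mean` (vector) and `cov` (matrix), in tip order.
#' @export
model_moments <- function(spec, params, phy) {
  if (is.character(spec)) spec <- cont_model_spec(spec)
  p <- as.list(params)
  if (is.null(p$sigma2) || !is.finite(p$sigma2) || p$sigma2 < 0) {
    stop("sigma2 must be finite and >= 0")
  }
  pc <- phylo_covariance(phy)
  shape <- switch(spec$name, OU = p$alpha, EB = p$beta, 0)
  if (is.null(shape) || !is.finite(shape)) stop("non-finite shape parameter")
  V0 <- cont_cov_shape(spec$name, pc$S, pc$depths, shape)
  mu <- switch(spec$name,
    BM = ,
    EB = ,
    WN = rep(p$theta0, length(pc$depths)),
    TREND = p$theta0 + p$trend * pc$depths,
    OU = if (p$alpha < 1e-10) rep(p$theta0, length(pc$depths)) else
      p$theta1 + (p$theta0 - p$theta1) * exp(-p$alpha * pc$depths))
  list(mean = unname(mu), cov = p$sigma2 * V0)
}

# Cholesky with an optional one-shot diagonal jitter; errors carry condition
# diagnostics.
chol_safe <- function(V, jitter = 1e-10) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    R <- tryCatch(chol(V + diag(jitter * mean(diag(V)), nrow(V))),
                  error = function(e) NULL)
    if (is.null(R)) {
      stop(sprintf("covariance not positive definite (n=%d, diag range [%g, %g])",
                   nrow(V), min(diag(V)), max(diag(V))))
    }
    attr(R, "jittered") <- TRUE
  }
  R
}

#' Log-likelihood of a trait vector under a continuous model
#'
#' Multivariate-normal log density computed through a Cholesky factorization
#' of the model covariance.
#'
#' @inheritParams model_moments
#' @param traits named numeric vector aligned to `phy$tip.label`.
#' @export
cont_loglik <- function(spec, params, phy, traits) {
  mm <- model_moments(spec, params, phy)
  x <- align_traits(traits, phy)
  R <- chol_safe(mm$cov)
  z <- backsolve(R, x - mm$mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

align_traits <- function(traits, phy) {
  if (!is.null(names(traits))) {
    idx <- match(phy$tip.label, names(traits))
    if (anyNA(idx)) {
      stop("traits missing for tips: ",
           paste(phy$tip.label[is.na(idx)], collapse = ", "))
    }
    traits <- traits[idx]
  } else if (length(traits) != length(phy$tip.label)) {
    stop("unnamed trait vector of wrong length")
  }
  as.numeric(traits)
}

# Profile lnL for a given covariance shape: location parameters by GLS,
# sigma2 in closed form (ML, divisor n).
cont_profile <- function(V0, X, x, sigma2_floor = 1e-10) {
  n <- length(x)
  R <- chol_safe(V0)
  Xi <- backsolve(R, X, transpose = TRUE)
  xi <- backsolve(R, x, transpose = TRUE)
  qrX <- qr(Xi)
  beta <- qr.coef(qrX, xi)
  beta[is.na(beta)] <- 0
  r <- xi - Xi %*% beta
  s2 <- sum(r^2) / n
  degenerate <- s2 < sigma2_floor
  if (degenerate) s2 <- sigma2_floor
  lnL <- -0.5 * n * (log(2 * pi) + log(s2)) - sum(log(diag(R))) -
    0.5 * sum(r^2) / s2
  list(lnL = lnL, beta = beta, sigma2 = s2, degenerate = degenerate)
}

#' Maximum-likelihood fit of a continuous trait model
#'
#' Location parameters (`theta0`, `theta1`, `trend`) are profiled by
#' generalized least squares and `sigma2` analytically, so only the
#' covariance-shape parameter (OU `alpha`, EB `beta`) is searched
#' numerically: a grid of candidate values followed by 1-D refinement with
#' [stats::optimize()]. BM, TREND and WN are closed form.
#'
#' @inheritParams model_moments
#' @param traits named numeric vector aligned to `phy$tip.label`.
#' @param beta_bounds EB bounds on `beta * height` (default `c(-10, 0)`;
#'   positive upper bound allowed via `allow_positive_beta`).
#' @param alpha_max OU upper bound on `alpha * height` (default 500).
#' @param allow_positive_beta permit accelerating-rate EB fits.
#' @param n_grid number of grid restarts for the shape search.
#' @param tol convergence tolerance on the shape parameter.
#' @param tree_id identifier stored in the result.
#' @return object of class `cont_fit`: list with `model`, `k`, `params`,
#'   `lnL`, `aic`, `converged`, `n_restarts_used`, `tree_id`.
#' @export
fit_ml <- function(spec, phy, traits, beta_bounds = c(-10, 0),
                   alpha_max = 500, allow_positive_beta = FALSE,
                   n_grid = 12, tol = 1e-8, tree_id = NA) {
  if (is.character(spec)) spec <- cont_model_spec(spec)
  x <- align_traits(traits, phy)
  n <- length(x)
  min_n <- 3L
  if (n < min_n && !(spec$name %in% c("BM", "WN") && n >= 2)) {
    stop("too few tips (", n, ") for model ", spec$name)
  }
  pc <- phylo_covariance(phy)
  h <- max(pc$depths)
  # on an ultrametric tree all tip depths are equal, so theta0/theta1 (OU)
  # and theta0/trend (TREND) are collinear: only fossils separate them
  ultrametric <- diff(range(pc$depths)) < 1e-8 * h
  if (ultrametric && spec$name == "TREND") {
    warning("trend parameter is not identifiable on an ultrametric tree; ",
            "fit reduces to BM")
  }
  obj <- function(shape) {
    X <- if (ultrametric && spec$name %in% c("OU", "TREND")) {
      matrix(1, n, 1, dimnames = list(NULL, "theta0"))
    } else {
      cont_design(spec$name, pc$depths, shape)
    }
    V0 <- cont_cov_shape(spec$name, pc$S, pc$depths, shape)
    cont_profile(V0, X, x)
  }
  shape_hat <- 0
  n_restarts <- 1L
  converged <- TRUE
  if (spec$name == "OU") {
    ub <- alpha_max / h
    grid <- c(1e-8, exp(seq(log(1e-3), log(ub), length.out = n_grid)))
    lls <- vapply(grid, function(a) obj(a)$lnL, numeric(1))
    best <- which.max(lls)
    lo <- grid[max(1, best - 1)]; hi <- grid[min(length(grid), best + 1)]
    o <- stats::optimize(function(a) obj(a)$lnL, c(lo, hi),
                         maximum = TRUE, tol = tol)
    shape_hat <- if (o$objective >= lls[best]) o$maximum else grid[best]
    n_restarts <- length(grid)
  } else if (spec$name == "EB") {
    lb <- beta_bounds[1] / h
    ub <- if (allow_positive_beta) abs(beta_bounds[1]) / h else 0
    grid <- unique(c(seq(lb, ub, length.out = n_grid), 0))
    lls <- vapply(grid, function(b) obj(b)$lnL, numeric(1))
    best <- which.max(lls)
    lo <- grid[max(1, best - 1)]; hi <- grid[min(length(grid), best + 1)]
    if (lo < hi) {
      o <- stats::optimize(function(b) obj(b)$lnL, c(lo, hi),
                           maximum = TRUE, tol = tol)
      shape_hat <- if (o$objective >= lls[best]) o$maximum else grid[best]
    } else shape_hat <- grid[best]
    n_restarts <- length(grid)
  }
  pr <- obj(shape_hat)
  if (pr$degenerate) {
    warning("constant or near-constant traits: sigma2 at lower bound")
  }
  params <- list(theta0 = unname(pr$beta[1]), sigma2 = pr$sigma2)
  if (spec$name == "OU") {
    params$alpha <- shape_hat
    params$theta1 <- if (length(pr$beta) > 1) unname(pr$beta[2]) else
      unname(pr$beta[1])  # ultrametric: only the common level is identified
    if (ultrametric) {
      # the intercept-only profile fits the one identified mean level; report
      # it for both the root state and the optimum
      params$theta1 <- params$theta0
    }
  }
  if (spec$name == "EB") params$beta <- shape_hat
  if (spec$name == "TREND") {
    params$trend <- if (ultrametric) NA_real_ else unname(pr$beta[2])
  }
  structure(list(
    model = spec$name, k = spec$k, params = params,
    lnL = pr$lnL, aic = 2 * spec$k - 2 * pr$lnL,
    converged = converged, n_restarts_used = n_restarts,
    tree_id = tree_id), class = "cont_fit")
}

#' @export
print.cont_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, AIC = %.4f\n", x$model, x$lnL, x$aic))
  cat("  ", paste(sprintf("%s = %.6g", names(x$params), unlist(x$params)),
                  collapse = ", "), "\n")
  invisible(x)
}

#' Akaike weights across a set of model fits
#'
#' `delta_aic = aic - min(aic)`; weights `exp(-delta/2)` normalized in
#' log-space so differences of several hundred AIC units survive.
#'
#' @param fits list of `cont_fit` objects, or a named numeric vector of AICs.
#' @return data frame with `model`, `aic`, `delta_aic`, `akaike_weight`,
#'   sorted as given.
#' @export
akaike_compare <- function(fits) {
  if (is.numeric(fits)) {
    aic <- fits
    model <- names(fits)
    if (is.null(model)) model <- paste0("model", seq_along(fits))
  } else {
    aic <- vapply(fits, function(f) f$aic, numeric(1))
    model <- vapply(fits, function(f) f$model, character(1))
  }
  if (length(aic) < 1) stop("no fits")
  delta <- aic - min(aic)
  logw <- -delta / 2
  logw <- logw - (max(logw) + log(sum(exp(logw - max(logw)))))
  data.frame(model = model, aic = aic, delta_aic = delta,
             akaike_weight = exp(logw), row.names = NULL)
}

#' Simulate trait datasets under a continuous model
#'
#' Independent multivariate-normal draws with the model's tip moments.
#'
#' @inheritParams model_moments
#' @param n_reps number of replicate datasets.
#' @param seed integer seed (reproducible).
#' @return numeric matrix, `Ntip x n_reps`, rownames = tip labels.
#' @export
simulate_traits <- function(spec, params, phy, n_reps, seed) {
  mm <- model_moments(spec, params, phy)
  n <- length(mm$mean)
  if (all(mm$cov == 0)) {
    out <- matrix(mm$mean, n, n_reps)
  } else {
    R <- chol_safe(mm$cov)
    set.seed(child_seed(seed, 1L))
    z <- matrix(stats::rnorm(n * n_reps), n, n_reps)
    out <- mm$mean + crossprod(R, z)
  }
  rownames(out) <- phy$tip.label
  out
}

#' Generalized-least-squares ancestral state estimates
#'
#' Supported for BM, EB and TREND fits (OU and WN excluded). The tree is
#' rescaled so the fitted model becomes constant-rate BM (EB branch segment
#' `[t1, t2]` gets length `(exp(beta t2) - exp(beta t1)) / beta`), and each
#' internal node's state is the GLS conditional expectation given the tips;
#' the root estimate equals the fitted `theta0`.
#'
#' @param fit a `cont_fit` for BM, EB or TREND.
#' @param phy the tree the model was fitted on.
#' @param traits the trait vector used for the fit.
#' @return numeric vector of internal-node estimates, named by node number
#'   (root first, `Ntip + 1`).
#' @export
ancestral_states <- function(fit, phy, traits) {
  if (!fit$model %in% c("BM", "EB", "TREND")) {
    stop("ancestral_states supports BM, EB and TREND fits only")
  }
  x <- align_traits(traits, phy)
  n_tip <- length(phy$tip.label)
  beta <- if (fit$model == "EB") fit$params$beta else 0
  ut <- model_rescaled_tree(phy, beta = beta, sigma2 = 1)
  d <- node_depths(ut)
  # shared path (on the rescaled tree) between every internal node and tip =
  # depth of their MRCA
  M <- ape::mrca(ut, full = TRUE)
  nodes <- (n_tip + 1L):(n_tip + phy$Nnode)
  Snt <- matrix(d[M[nodes, seq_len(n_tip)]], nrow = length(nodes))
  V <- phylo_covariance(ut)$S
  mu_tip <- if (fit$model == "TREND") {
    fit$params$theta0 + fit$params$trend * node_depths(phy)[seq_len(n_tip)]
  } else rep(fit$params$theta0, n_tip)
  mu_node <- if (fit$model == "TREND") {
    fit$params$theta0 + fit$params$trend * node_depths(phy)[nodes]
  } else rep(fit$params$theta0, length(nodes))
  R <- chol_safe(V)
  w <- backsolve(R, backsolve(R, x - mu_tip, transpose = TRUE))
  est <- as.numeric(mu_node + Snt %*% w)
  names(est) <- nodes
  est
}

# Rescale branches so the fitted model is unit-rate BM; a branch spanning
# depths [t1, t2] gets sigma2 * (exp(beta t2) - exp(beta t1)) / beta
# (limit sigma2 * (t2 - t1) at beta = 0).
model_rescaled_tree <- function(phy, beta = 0, sigma2 = 1) {
  d <- node_depths(phy)
  t1 <- d[phy$edge[, 1L]]
  t2 <- d[phy$edge[, 2L]]
  phy$edge.length <- if (abs(beta) < 1e-12) {
    sigma2 * (t2 - t1)
  } else {
    sigma2 * (exp(beta * t2) - exp(beta * t1)) / beta
  }
  phy
}
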