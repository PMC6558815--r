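# Ordered single-step Markov models for meristic counts: states 0..S-1, the
# only transitions allowed are +1 (gain) and -1 (loss). The symmetric model
# (MkS) has one rate; the asymmetric model (MkA) has separate gain and loss
# rates. Likelihood by Felsenstein pruning with an eigendecomposition of the
# tridiagonal rate matrix (computed once per likelihood evaluation, so
# per-branch transition matrices are cheap).

#' Ordered Mk model specification
#'
#' @param n_states number of states `S` (states are `0..S-1`).
#' @param q_gain rate of +1 transitions (>= 0).
#' @param q_loss rate of -1 transitions (>= 0); forced equal to `q_gain` when
#'   `symmetric`.
#' @param symmetric single shared rate for gains and losses.
#' @export
ordered_mk_spec <- function(n_states, q_gain, q_loss = q_gain,
                            symmetric = FALSE) {
  if (n_states < 2) stop("need at least 2 states")
  if (q_gain < 0 || q_loss < 0) stop("rates must be >= 0")
  if (symmetric) q_loss <- q_gain
  list(n_states = as.integer(n_states), q_gain = q_gain, q_loss = q_loss,
       symmetric = symmetric)
}

#' Tridiagonal rate matrix of an ordered Mk model
#'
#' `Q[i, i+1] = q_gain`, `Q[i, i-1] = q_loss`, rows sum to zero.
#'
#' @param spec an [ordered_mk_spec()].
#' @export
build_q <- function(spec) {
  S <- spec$n_states
  Q <- matrix(0, S, S)
  for (i in seq_len(S - 1)) {
    Q[i, i + 1] <- spec$q_gain
    Q[i + 1, i] <- spec$q_loss
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Transition-matrix factory: one eigendecomposition of Q, then P(t) per
# branch. Birth-death chains have real spectra; tiny imaginary parts from the
# general solver are dropped and rows renormalized.
mk_transition_factory <- function(Q) {
  if (all(Q == 0)) {
    S <- nrow(Q)
    return(function(t) diag(S))
  }
  eg <- eigen(Q)
  U <- eg$vectors
  Ui <- solve(U)
  lam <- eg$values
  function(t) {
    P <- Re(U %*% (exp(lam * t) * Ui))
    P[P < 0] <- 0
    P / rowSums(P)
  }
}

#' Pruning log-likelihood of tip states under an ordered Mk model
#'
#' @param phy a rooted `phylo` with branch lengths.
#' @param states integer vector of tip states in `0..S-1`, named by tip label
#'   (or in tip order).
#' @param spec an [ordered_mk_spec()].
#' @param root_prior `"uniform"` (1/S, the default of standard Mk fitting
#'   functions), `"equilibrium"` (stationary distribution of Q), or a numeric
#'   vector of length S.
#' @export
mk_loglik <- function(phy, states, spec, root_prior = "uniform") {
  S <- spec$n_states
  st <- align_traits(states, phy)
  bad <- st < 0 | st > S - 1 | st != round(st)
  if (any(bad)) {
    stop("states out of range 0..", S - 1, " for tips: ",
         paste(phy$tip.label[bad], collapse = ", "))
  }
  prior <- mk_root_prior(root_prior, spec)
  Q <- build_q(spec)
  Pt <- mk_transition_factory(Q)
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  part <- matrix(1, n_all, S)
  part[seq_len(n_tip), ] <- 0
  part[cbind(seq_len(n_tip), st + 1L)] <- 1
  eo <- ape::reorder.phylo(phy, "postorder")
  ed <- eo$edge
  el <- eo$edge.length
  loglik <- 0
  for (k in seq_len(nrow(ed))) {
    p <- ed[k, 1L]; ch <- ed[k, 2L]
    v <- Pt(el[k]) %*% part[ch, ]
    part[p, ] <- part[p, ] * v
    m <- max(part[p, ])
    if (m < 1e-100) stop("numerical underflow in pruning")
    if (m < 1e-6) {  # rescale partials to avoid underflow
      part[p, ] <- part[p, ] / m
      loglik <- loglik + log(m)
    }
  }
  root <- n_tip + 1L
  loglik + log(sum(prior * part[root, ]))
}

mk_root_prior <- function(root_prior, spec) {
  S <- spec$n_states
  if (is.numeric(root_prior)) {
    if (length(root_prior) != S || any(root_prior < 0)) {
      stop("numeric root prior must be a length-S non-negative vector")
    }
    return(root_prior / sum(root_prior))
  }
  switch(match.arg(root_prior, c("uniform", "equilibrium")),
    uniform = rep(1 / S, S),
    equilibrium = {
      if (spec$q_loss <= 0 || spec$q_gain <= 0) return(rep(1 / S, S))
      pi0 <- (spec$q_gain / spec$q_loss)^(0:(S - 1))
      pi0 / sum(pi0)
    })
}

#' Maximum-likelihood fit of an ordered Mk model
#'
#' Rates are optimized in log space; the symmetric model by 1-D
#' [stats::optimize()], the asymmetric model by L-BFGS-B from several starts
#' (including a warm start at the symmetric optimum).
#'
#' @inheritParams mk_loglik
#' @param symmetric fit the single-rate model.
#' @param n_states state count S; default `max(states) + 1` (logged in the
#'   result because the uniform root prior makes the likelihood depend on S).
#' @param rate_bounds search bounds for each rate.
#' @return object of class `mk_fit`: `spec`, `lnL`, `k`, `aic`, `n_states`.
#' @export
fit_mk <- function(phy, states, symmetric = TRUE, n_states = NULL,
                   root_prior = "uniform", rate_bounds = c(1e-8, 1e3)) {
  st <- align_traits(states, phy)
  if (length(st) < 3) stop("need at least 3 tips")
  if (length(unique(st)) < 2) {
    warning("all tips share one state: rates driven to the lower bound")
  }
  if (is.null(n_states)) n_states <- max(st) + 1L
  lb <- log(rate_bounds[1]); ub <- log(rate_bounds[2])
  ll_sym <- function(lr) {
    mk_loglik(phy, st, ordered_mk_spec(n_states, exp(lr), symmetric = TRUE),
              root_prior)
  }
  o_sym <- stats::optimize(ll_sym, c(lb, ub), maximum = TRUE, tol = 1e-8)
  if (symmetric) {
    r <- exp(o_sym$maximum)
    spec <- ordered_mk_spec(n_states, r, symmetric = TRUE)
    lnL <- o_sym$objective
    k <- 1L
  } else {
    ll_asym <- function(lr) {
      val <- tryCatch(
        -mk_loglik(phy, st, ordered_mk_spec(n_states, exp(lr[1]), exp(lr[2])),
                   root_prior),
        error = function(e) NA_real_)
      # keep L-BFGS-B away from rate regions where the pruning underflows
      if (!is.finite(val)) 1e10 else val
    }
    starts <- list(c(o_sym$maximum, o_sym$maximum),
                   c(o_sym$maximum + 1, o_sym$maximum - 1),
                   c(o_sym$maximum - 1, o_sym$maximum + 1))
    best <- NULL
    for (s0 in starts) {
      o <- tryCatch(
        stats::optim(pmin(pmax(s0, lb), ub), ll_asym, method = "L-BFGS-B",
                     lower = lb, upper = ub,
                     control = list(factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("asymmetric Mk optimization failed from all starts")
    spec <- ordered_mk_spec(n_states, exp(best$par[1]), exp(best$par[2]))
    lnL <- -best$value
    # the symmetric optimum is a feasible point of the asymmetric model
    if (o_sym$objective > lnL) {
      spec <- ordered_mk_spec(n_states, exp(o_sym$maximum), exp(o_sym$maximum))
      lnL <- o_sym$objective
    }
    k <- 2L
  }
  structure(list(spec = spec, lnL = lnL, k = k, aic = 2 * k - 2 * lnL,
                 n_states = n_states, root_prior = root_prior),
            class = "mk_fit")
}

#' Likelihood-ratio test between symmetric and asymmetric ordered Mk fits
#'
#' Statistic `2 (lnL_asym - lnL_sym)` (clamped at 0), 1 degree of freedom,
#' chi-square upper-tail p-value.
#'
#' @param sym symmetric `mk_fit`.
#' @param asym asymmetric `mk_fit` on the same tree and states.
#' @param alpha significance level for the verdict flag.
#' @export
mk_lrt <- function(sym, asym, alpha = 0.05) {
  if (sym$n_states != asym$n_states) stop("fits use different state spaces")
  stat <- 2 * (asym$lnL - sym$lnL)
  if (stat < -1e-6) stop("asymmetric lnL below symmetric: inconsistent fits")
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, df = 1L, p_value = p,
       significant = p < alpha, alpha = alpha)
}

#' Simulate an ordered Mk character along a tree (exact event sampling)
#'
#' Gillespie-style simulation: along each branch, waiting times are
#' exponential with the total available rate and the step is +1 or -1 with
#' probability proportional to the gain/loss rate; states reflect at 0 and
#' S-1 (only the feasible move is available there).
#'
#' @inheritParams mk_loglik
#' @param root_state starting state at the root.
#' @param seed integer seed.
#' @return integer vector of tip states named by tip label; the attribute
#'   `"n_events"` holds the total number of simulated jumps.
#' @export
simulate_mk <- function(phy, spec, root_state, seed) {
  S <- spec$n_states
  if (root_state < 0 || root_state > S - 1) stop("root_state out of range")
  set.seed(child_seed(seed, 1L))
  n_tip <- length(phy$tip.label)
  state <- integer(n_tip + phy$Nnode)
  state[n_tip + 1L] <- as.integer(root_state)
  eo <- ape::reorder.phylo(phy, "postorder")
  ed <- eo$edge; el <- eo$edge.length
  n_events <- 0L
  for (k in rev(seq_len(nrow(ed)))) {  # preorder: parent before child
    s <- state[ed[k, 1L]]
    t_left <- el[k]
    repeat {
      rg <- if (s < S - 1) spec$q_gain else 0
      rl <- if (s > 0) spec$q_loss else 0
      rtot <- rg + rl
      if (rtot <= 0) break
      w <- stats::rexp(1, rtot)
      if (w > t_left) break
      t_left <- t_left - w
      s <- if (stats::runif(1) < rg / rtot) s + 1L else s - 1L
      n_events <- n_events + 1L
    }
    state[ed[k, 2L]] <- s
  }
  out <- state[seq_len(n_tip)]
  names(out) <- phy$tip.label
  attr(out, "n_events") <- n_events
  out
}
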