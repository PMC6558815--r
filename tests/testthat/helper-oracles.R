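# Independent oracle: likelihood by exhaustive enumeration over all internal
# node states, with transition matrices from ape::matexpo (a code path fully
# separate from the package's eigendecomposition pruning).
enumerate_mk_loglik <- function(phy, states, spec, prior = NULL) {
  S <- spec$n_states
  Q <- build_q(spec)
  if (is.null(prior)) prior <- rep(1 / S, S)
  n_tip <- length(phy$tip.label)
  nodes <- (n_tip + 1):(n_tip + phy$Nnode)
  st <- states[phy$tip.label]
  grid <- expand.grid(rep(list(0:(S - 1)), phy$Nnode))
  P <- lapply(seq_len(nrow(phy$edge)),
              function(k) ape::matexpo(Q * phy$edge.length[k]))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign_state <- c(st, as.numeric(grid[g, ]))
    lik <- prior[assign_state[n_tip + 1] + 1]
    for (k in seq_len(nrow(phy$edge))) {
      a <- assign_state[phy$edge[k, 1]] + 1
      b <- assign_state[phy$edge[k, 2]] + 1
      lik <- lik * P[[k]][a, b]
    }
    total <- total + lik
  }
  log(total)
}

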