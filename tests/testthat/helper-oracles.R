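# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed forms, brute-force enumeration, and
# normal equations.

# closed-form solution of the irreversible sequential first-order system
# A -> B -> C with rates ka, kb (A = FlH2, B = FlSQ, C = Flox under
# pseudo-first-order oxidant excess)
sequentialDecayOracle <- function(A0, ka, kb, t) {
  A <- A0 * exp(-ka * t)
  B <- if (abs(ka - kb) < 1e-12) A0 * ka * t * exp(-ka * t)
       else A0 * ka / (kb - ka) * (exp(-ka * t) - exp(-kb * t))
  list(A = A, B = B, C = A0 - A - B)
}

# ordinary least squares through the normal equations
normalEquationsOracle <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# brute-force Mk likelihood: sum over all internal-node state assignments
enumMkLikelihood <- function(tree, tip_states, alpha,
                             states = operonStates()) {
  k <- length(states)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  edge <- tree$edge
  bl <- tree$edge.length
  tipidx <- match(tip_states[tree$tip.label], states)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  Pe <- lapply(seq_len(nrow(edge)),
               function(e) mkTransitionMatrix(alpha, bl[e], k))
  tot <- 0
  for (r in seq_len(nrow(combos))) {
    st <- c(tipidx, combos[r, ])
    p <- 1 / k
    for (e in seq_len(nrow(edge)))
      p <- p * Pe[[e]][st[edge[e, 1]], st[edge[e, 2]]]
    tot <- tot + p
  }
  tot
}

# brute-force marginal ancestral probabilities by enumeration
enumMkMarginals <- function(tree, tip_states, alpha,
                            states = operonStates()) {
  k <- length(states)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  edge <- tree$edge
  bl <- tree$edge.length
  tipidx <- match(tip_states[tree$tip.label], states)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  Pe <- lapply(seq_len(nrow(edge)),
               function(e) mkTransitionMatrix(alpha, bl[e], k))
  M <- matrix(0, nint, k)
  for (r in seq_len(nrow(combos))) {
    st <- c(tipidx, combos[r, ])
    p <- 1 / k
    for (e in seq_len(nrow(edge)))
      p <- p * Pe[[e]][st[edge[e, 1]], st[edge[e, 2]]]
    for (j in seq_len(nint))
      M[j, combos[r, j]] <- M[j, combos[r, j]] + p
  }
  M <- M / rowSums(M)
  dimnames(M) <- list(paste0("n", ntip + seq_len(nint)), states)
  M
}

# random tip-state map over a tree
randomTipStates <- function(tree, states = operonStates()) {
  stats::setNames(sample(states, length(tree$tip.label), replace = TRUE),
                  tree$tip.label)
}

# log-spaced simulation grid for a single-exponential process
logGrid <- function(k_app, n = 400L, horizons = 7) {
  c(0, exp(seq(log(1 / (50 * k_app)), log(horizons / k_app),
               length.out = n - 1L)))
}
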