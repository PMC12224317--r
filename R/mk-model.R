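# Equal-rates multistate Markov (Mk) model on a rooted tree: likelihood by
# Felsenstein pruning, marginal ancestral states by the standard two-pass
# algorithm, ML rate estimation, and transition counting.

#' Default operon-category state space
#' @return character vector \code{c("black", "blue", "green", "red")}.
#' @export
operonStates <- function() c("black", "blue", "green", "red")

#' Mk transition probability matrix
#'
#' Closed form for the equal-rates k-state model in which \code{alpha} is
#' the total rate of leaving the current state (so each of the k-1 target
#' states is entered at rate \code{alpha/(k-1)}):
#' \deqn{P_{ii}(t) = 1/k + (k-1)/k \, e^{-\alpha k t/(k-1)}}
#' with all off-diagonal entries equal.
#'
#' @param alpha transition rate (> 0), per unit branch length.
#' @param t branch length (>= 0).
#' @param k number of states (default 4).
#' @return k x k row-stochastic matrix.
#' @examples
#' mkTransitionMatrix(1, 0)        # identity
#' mkTransitionMatrix(1, 1e6)      # stationary: all 1/4
#' @export
mkTransitionMatrix <- function(alpha, t, k = 4L) {
  if (!isScalarNumber(alpha) || alpha <= 0) stopf("alpha must be > 0")
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stopf("branch length must be >= 0")
  e <- exp(-alpha * k * t / (k - 1))
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) / k * e
  P
}

# normalize tip states to a named character vector over the tree's tips
#' @noRd
normalizeTipStates <- function(tree, tip_states, states) {
  if (is.data.frame(tip_states))
    tip_states <- stats::setNames(tip_states$category, tip_states$tip_label)
  if (is.null(names(tip_states)))
    stopf("tip_states must be named by tip label (or a tip_label/category data.frame)")
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing))
    stopf("tips missing a state: %s", paste(missing, collapse = ", "))
  ts <- tip_states[tree$tip.label]
  bad <- setdiff(unique(ts), states)
  if (length(bad))
    stopf("unknown states: %s", paste(bad, collapse = ", "))
  ts
}

# postorder pruning pass; returns list(partials = matrix[node, state] on a
# scaled basis, logscale = per-node accumulated log scaling)
#' @noRd
pruningPass <- function(tree, tip_states, alpha, states) {
  k <- length(states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  L <- matrix(0, nnode, k)
  logscale <- numeric(nnode)
  for (i in seq_len(ntip))
    L[i, match(tip_states[i], states)] <- 1
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge; blen <- tr$edge.length
  internal <- unique(edge[, 1])
  # postorder edge ordering guarantees children are complete before parents
  done <- rep(FALSE, nnode)
  Lwork <- L
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; child <- edge[e, 2]
    if (!done[par]) { Lwork[par, ] <- 1; logscale[par] <- 0; done[par] <- TRUE }
    P <- mkTransitionMatrix(alpha, blen[e], k)
    contrib <- as.numeric(P %*% Lwork[child, ])
    Lwork[par, ] <- Lwork[par, ] * contrib
    logscale[par] <- logscale[par] + logscale[child]
    m <- max(Lwork[par, ])
    if (m > 0 && (m < 1e-100 || m > 1e100)) {
      Lwork[par, ] <- Lwork[par, ] / m
      logscale[par] <- logscale[par] + log(m)
    }
  }
  list(partials = Lwork, logscale = logscale, edge = edge, blen = blen)
}

#' Mk log-likelihood of tip states on a rooted tree
#'
#' Felsenstein pruning under the equal-rates Mk model with a uniform root
#' prior over the k states.
#'
#' @param tree rooted \code{ape::phylo} with branch lengths.
#' @param tip_states named character vector (names = tip labels) or
#'   data.frame with columns \code{tip_label}, \code{category}.
#' @param alpha transition rate (> 0).
#' @param states state space (default \code{\link{operonStates}}).
#' @return log-likelihood (numeric scalar).
#' @export
mkLogLikelihood <- function(tree, tip_states, alpha,
                            states = operonStates()) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stopf("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stopf("negative branch length")
  ts <- normalizeTipStates(tree, tip_states, states)
  pp <- pruningPass(tree, ts, alpha, states)
  root <- length(tree$tip.label) + 1L
  lik <- sum(pp$partials[root, ] / length(states))
  log(lik) + pp$logscale[root]
}

#' Maximum-likelihood Mk rate
#'
#' One-dimensional ML optimization of \code{\link{mkLogLikelihood}} over
#' \code{alpha} on the log scale within \code{[1e-6, 1e3]}. If all tips
#' share one state the likelihood is maximized at the boundary; the lower
#' bound is returned with a warning and \code{attr(, "boundary") = TRUE}.
#'
#' @inheritParams mkLogLikelihood
#' @return \code{alpha_hat} with attributes \code{logLik} and
#'   \code{boundary}.
#' @export
estimateMkRate <- function(tree, tip_states, states = operonStates()) {
  ts <- normalizeTipStates(tree, tip_states, states)
  if (length(unique(ts)) < 2L) {
    warnf("all tips share one state; rate is at the lower boundary")
    ll <- mkLogLikelihood(tree, ts, 1e-6, states)
    return(structure(1e-6, logLik = ll, boundary = TRUE))
  }
  negll <- function(la) -mkLogLikelihood(tree, ts, exp(la), states)
  opt <- stats::optimize(negll, lower = log(1e-6), upper = log(1e3),
                         tol = 1e-10)
  structure(exp(opt$minimum), logLik = -opt$objective, boundary = FALSE)
}

#' Marginal ancestral state probabilities
#'
#' Standard two-pass algorithm: a postorder (pruning) pass collects the
#' likelihood of the data below each node, a preorder pass propagates the
#' likelihood of the data outside each node's subtree; their product,
#' normalized, is the marginal posterior over states at every internal node
#' under the Mk model with uniform root prior.
#'
#' @inheritParams mkLogLikelihood
#' @return matrix (rows = internal nodes in \code{ape} numbering, labelled
#'   \code{"n<id>"}; columns = states); each row sums to 1.
#' @export
marginalAncestralProbs <- function(tree, tip_states, alpha,
                                   states = operonStates()) {
  stopifnot(inherits(tree, "phylo"))
  ts <- normalizeTipStates(tree, tip_states, states)
  k <- length(states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  pp <- pruningPass(tree, ts, alpha, states)
  L <- pp$partials
  edge <- pp$edge; blen <- pp$blen

  # preorder "outside" pass; G[root] = uniform prior
  G <- matrix(0, nnode, k)
  root <- ntip + 1L
  G[root, ] <- 1 / k
  children <- split(seq_len(nrow(edge)), edge[, 1])
  # preorder: reverse postorder edge order visits parents before children
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1]; child <- edge[e, 2]
    sibs <- setdiff(children[[as.character(par)]], e)
    outer <- G[par, ]
    for (se in sibs) {
      P <- mkTransitionMatrix(alpha, blen[se], k)
      outer <- outer * as.numeric(P %*% L[edge[se, 2], ])
    }
    P <- mkTransitionMatrix(alpha, blen[e], k)
    g <- as.numeric(crossprod(P, outer))   # sum_i P_ij * outer_i
    m <- max(g)
    G[child, ] <- if (m > 0) g / m else g
  }

  internal <- (ntip + 1L):nnode
  probs <- G[internal, , drop = FALSE] * L[internal, , drop = FALSE]
  probs <- probs / rowSums(probs)
  dimnames(probs) <- list(paste0("n", internal), states)
  probs
}

#' Most-probable states at every node
#'
#' Tips keep their observed state; each internal node takes the argmax of
#' its marginal probabilities. Ties are broken toward the parent's state
#' (visited preorder, so the parent is always resolved first), then
#' lexicographically, making the output deterministic.
#'
#' @inheritParams mkLogLikelihood
#' @param probs matrix from \code{\link{marginalAncestralProbs}}.
#' @param tol numerical tolerance for calling a tie.
#' @return named character vector of states for nodes 1..(ntip + nnode) in
#'   \code{ape} numbering.
#' @export
maxProbStates <- function(tree, tip_states, probs, states = operonStates(),
                          tol = 1e-12) {
  ts <- normalizeTipStates(tree, tip_states, states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  out <- character(nnode)
  out[seq_len(ntip)] <- ts
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  parent_of <- integer(nnode)
  parent_of[edge[, 2]] <- edge[, 1]
  root <- ntip + 1L
  pick <- function(p, parent_state) {
    best <- max(p)
    cand <- states[p >= best - tol]
    if (!is.na(parent_state) && parent_state %in% cand) return(parent_state)
    sort(cand)[1]
  }
  # preorder over internal nodes: parents before children
  for (e in c(0L, rev(seq_len(nrow(edge))))) {
    node <- if (e == 0L) root else edge[e, 2]
    if (node <= ntip) next
    ps <- if (node == root) NA_character_ else out[parent_of[node]]
    out[node] <- pick(probs[paste0("n", node), ], ps)
  }
  names(out) <- c(tree$tip.label, paste0("n", (ntip + 1L):nnode))
  out
}

#' Count state transitions along the tree
#'
#' Counts edges whose parent and child states differ, keyed by the ordered
#' pair (parent state, child state). Applied to marginal argmax states this
#' approximates the number of independent origins of each category.
#'
#' @param tree rooted \code{ape::phylo}.
#' @param node_states state vector over all nodes in \code{ape} numbering,
#'   as from \code{\link{maxProbStates}}.
#' @return data.frame with columns \code{from}, \code{to}, \code{count}.
#' @export
countTransitions <- function(tree, node_states) {
  stopifnot(inherits(tree, "phylo"))
  nnode <- length(tree$tip.label) + tree$Nnode
  if (length(node_states) != nnode)
    stopf("node_states must cover all %d nodes", nnode)
  from <- node_states[tree$edge[, 1]]
  to <- node_states[tree$edge[, 2]]
  changed <- from != to
  if (!any(changed))
    return(data.frame(from = character(0), to = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  tab <- table(from = from[changed], to = to[changed])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("from", "to", "count")
  df <- df[df$count > 0, , drop = FALSE]
  rownames(df) <- NULL
  df[order(df$from, df$to), , drop = FALSE]
}

#' Annotate a tree's nodes with reconstructed states
#'
#' Writes the argmax state into \code{node.label} so the annotated tree can
#' be exported as Newick with state comments.
#'
#' @param tree rooted \code{ape::phylo}.
#' @param node_states vector from \code{\link{maxProbStates}}.
#' @return the tree with \code{node.label} set.
#' @export
annotateTreeStates <- function(tree, node_states) {
  ntip <- length(tree$tip.label)
  tree$node.label <- unname(node_states[(ntip + 1L):length(node_states)])
  tree
}
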