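test_that("transition matrix has the equal-rates closed form", {
  expect_equal(mkTransitionMatrix(0.7, 0), diag(4))
  expect_equal(mkTransitionMatrix(0.7, 1e9), matrix(0.25, 4, 4),
               tolerance = 1e-12)
  P <- mkTransitionMatrix(1.3, 0.8, k = 4)
  expect_equal(rowSums(P), rep(1, 4))
  off <- P[row(P) != col(P)]
  expect_lt(max(off) - min(off), 1e-15)
})

test_that("transition matrix matches the matrix exponential of the rate matrix", {
  skip_if_not_installed("Matrix")
  k <- 4
  for (prm in list(c(0.3, 0.5), c(2, 0.1), c(0.05, 7))) {
    alpha <- prm[1]; t <- prm[2]
    Q <- matrix(alpha / (k - 1), k, k); diag(Q) <- -alpha
    Pref <- as.matrix(Matrix::expm(Q * t))
    expect_equal(mkTransitionMatrix(alpha, t, k), unname(Pref),
                 tolerance = 1e-10)
  }
})

test_that("pruning likelihood matches textbook limits on two-tip trees", {
  tree <- ape::read.tree(text = "(a:0,b:0);")
  ts <- c(a = "blue", b = "blue")
  expect_equal(mkLogLikelihood(tree, ts, 1), log(1 / 4), tolerance = 1e-12)

  tree_inf <- ape::read.tree(text = "(a:1e9,b:1e9);")
  for (st in list(c(a = "blue", b = "blue"), c(a = "red", b = "green")))
    expect_equal(mkLogLikelihood(tree_inf, st, 1), log(1 / 16),
                 tolerance = 1e-9)
})

test_that("pruning equals brute-force enumeration on random small trees", {
  set.seed(101)
  for (n in c(3, 4, 5, 6)) {
    tree <- ape::rphylo(n, 1, 0)
    ts <- randomTipStates(tree)
    alpha <- runif(1, 0.1, 2)
    expect_equal(mkLogLikelihood(tree, ts, alpha),
                 log(enumMkLikelihood(tree, ts, alpha)),
                 tolerance = 1e-10)
  }
})

test_that("marginal probabilities equal enumeration and are valid distributions", {
  set.seed(202)
  for (n in c(4, 5, 6)) {
    tree <- ape::rphylo(n, 1, 0)
    ts <- randomTipStates(tree)
    alpha <- runif(1, 0.2, 1.5)
    mp <- marginalAncestralProbs(tree, ts, alpha)
    em <- enumMkMarginals(tree, ts, alpha)
    expect_equal(mp, em, tolerance = 1e-10)
    expect_equal(unname(rowSums(mp)), rep(1, nrow(mp)), tolerance = 1e-9)
    expect_true(all(mp >= 0))
  }
})

test_that("marginals are invariant to tip input order and symmetric under label permutation", {
  set.seed(77)
  tree <- ape::rphylo(6, 1, 0)
  ts <- randomTipStates(tree)
  mp1 <- marginalAncestralProbs(tree, ts, 0.6)
  mp2 <- marginalAncestralProbs(tree, ts[rev(names(ts))], 0.6)
  expect_equal(mp1, mp2)

  # permuting state labels permutes the output columns identically
  states <- operonStates()
  perm <- c(blue = "red", red = "blue", black = "green", green = "black")
  ts_p <- stats::setNames(unname(perm[ts]), names(ts))
  mp3 <- marginalAncestralProbs(tree, ts_p, 0.6)
  expect_equal(unname(mp3[, perm[states]]), unname(mp1[, states]),
               tolerance = 1e-12)
})

test_that("zero-length star tree concentrates the root on the shared tip state", {
  tree <- ape::read.tree(text = "(a:0,b:0,c:0,d:0);")
  ts <- c(a = "blue", b = "blue", c = "blue", d = "blue")
  mp <- marginalAncestralProbs(tree, ts, 1)
  expect_equal(unname(mp[1, "blue"]), 1, tolerance = 1e-12)
})

test_that("rate estimation recovers the simulating rate and flags boundaries", {
  g <- genCharacterTree(64, birth_rate = 1, alpha = 0.5, seed = 11)
  ah <- estimateMkRate(g$tree, g$tip_states)
  expect_gt(as.numeric(ah), 0.25)
  expect_lt(as.numeric(ah), 1.0)
  expect_false(attr(ah, "boundary"))

  # optimality: no improvement at half or double the estimate
  ll <- function(a) mkLogLikelihood(g$tree, g$tip_states, a)
  expect_gte(attr(ah, "logLik"), ll(as.numeric(ah) / 2))
  expect_gte(attr(ah, "logLik"), ll(as.numeric(ah) * 2))

  uni <- genCharacterTree(16, alpha = 0, seed = 5)
  expect_warning(ah0 <- estimateMkRate(uni$tree, uni$tip_states), "boundary")
  expect_equal(as.numeric(ah0), 1e-6)
  expect_true(attr(ah0, "boundary"))
})

test_that("argmax states break ties deterministically and count transitions", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  ts <- c(a = "blue", b = "blue", c = "black", d = "black")
  mp <- marginalAncestralProbs(tree, ts, 0.3)
  st <- maxProbStates(tree, ts, mp)
  expect_identical(unname(st[c("a", "b", "c", "d")]),
                   c("blue", "blue", "black", "black"))

  tc <- countTransitions(tree, st)
  expect_true(all(tc$count > 0))
  # all nodes one state: zero transitions
  same <- stats::setNames(rep("blue", 7), names(st))
  expect_identical(nrow(countTransitions(tree, same)), 0L)

  # hand-built single planted change: one blue -> black edge
  tree2 <- ape::read.tree(text = "((a:1,b:1)x:1,(c:1,d:1)y:1)r;")
  st2 <- stats::setNames(c("blue", "blue", "black", "black",
                           "blue", "blue", "black"),
                         c("a", "b", "c", "d", "n5", "n6", "n7"))
  tc2 <- countTransitions(tree2, st2)
  expect_identical(tc2$from, "blue")
  expect_identical(tc2$to, "black")
  expect_identical(tc2$count, 1L)
})

test_that("counted transitions never exceed the simulated change events", {
  for (seed in 1:5) {
    g <- genCharacterTree(24, alpha = 0.4, seed = seed)
    if (length(unique(g$tip_states$category)) < 2L) next
    ah <- estimateMkRate(g$tree, g$tip_states)
    mp <- marginalAncestralProbs(g$tree, g$tip_states, as.numeric(ah))
    st <- maxProbStates(g$tree, g$tip_states, mp)
    tc <- countTransitions(g$tree, st)
    expect_lte(sum(tc$count), g$n_changes)
  }
})
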