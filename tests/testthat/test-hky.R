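# HKY substitution model and pruning likelihood.

test_that("rate matrix is a proper normalized generator", {
  p <- c(0.33, 0.16, 0.14, 0.37)
  Q <- hky_rate_matrix(4, p)
  expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(drop(p %*% Q)), rep(0, 4),
               tolerance = 1e-12) # stationary
  expect_equal(-sum(p * diag(Q)), 1, tolerance = 1e-12)     # unit rate
  # detailed balance (reversibility)
  expect_equal(p * Q, t(p * Q), tolerance = 1e-12)
})

test_that("transition probabilities behave and collapse to Jukes-Cantor", {
  p <- rep(0.25, 4)
  for (t in c(0.01, 0.1, 1)) {
    P <- hky_transition_prob(t, kappa = 1, base_freqs = p)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
    jc_same <- 0.25 + 0.75 * exp(-4 / 3 * t)
    jc_diff <- 0.25 - 0.25 * exp(-4 / 3 * t)
    expect_equal(diag(P), rep(jc_same, 4), tolerance = 1e-10)
    expect_equal(P[1, 2], jc_diff, tolerance = 1e-10)
  }
  P0 <- hky_transition_prob(0, kappa = 3, base_freqs = c(.3, .2, .2, .3))
  expect_equal(P0, diag(4), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("two-taxon likelihood equals the closed form", {
  set.seed(6)
  for (rep in 1:20) {
    kappa <- runif(1, 0.5, 10)
    p <- runif(4, 0.1, 1); p <- p / sum(p)
    b1 <- runif(1, 0.001, 0.3); b2 <- runif(1, 0.001, 0.3)
    L <- 120
    # random pair of sequences
    s1 <- sample.int(4, L, replace = TRUE, prob = p)
    s2 <- s1
    flip <- runif(L) < 0.2
    s2[flip] <- sample.int(4, sum(flip), replace = TRUE)
    chars <- rbind(c("A", "C", "G", "T")[s1], c("A", "C", "G", "T")[s2])
    rownames(chars) <- c("t1", "t2")
    tr <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                         edge.length = c(b1, b2),
                         tip.label = c("t1", "t2"), Nnode = 1L),
                    class = "phylo")
    ll <- hky_likelihood(tr, chars, kappa = kappa, base_freqs = p)
    # closed form by reversibility: pi_a P_{ab}(b1 + b2) per site
    P <- hky_transition_prob(b1 + b2, kappa = kappa, base_freqs = p)
    ll_cf <- sum(log(p[s1] * P[cbind(s1, s2)]))
    expect_equal(ll, ll_cf, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant under leaf reordering", {
  d <- simulate_dataset(demography_constant(4, 6, L = 150), seed = 15)
  tr <- d$genealogy
  tr$edge.length <- tr$edge.length * attr(tr, "mut_scale")
  aln <- as.matrix(d$alignment)
  ll1 <- hky_likelihood(tr, aln, kappa = 4)
  ll2 <- hky_likelihood(tr, aln[sample(nrow(aln)), ], kappa = 4)
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("pruning agrees with an independent implementation", {
  set.seed(44)
  d <- simulate_dataset(demography_constant(5, 8, L = 300), seed = 44)
  tr <- d$genealogy
  tr$edge.length <- tr$edge.length * attr(tr, "mut_scale")
  p <- c(A = 0.33, C = 0.16, G = 0.14, T = 0.37)
  ll <- hky_likelihood(tr, d$alignment, kappa = 4, base_freqs = p)
  dat <- phangorn::phyDat(as.character(as.matrix(d$alignment)))
  fit <- phangorn::pml(tr, dat, bf = p / sum(p),
                       Q = c(1, 4, 1, 1, 4, 1)) # AG and CT transitions
  expect_equal(ll, fit$logLik, tolerance = 1e-6)
})

test_that("the sampler's C++ pruning matches the R reference", {
  set.seed(20)
  st <- phylodem:::sim_structured_state(4, 4, 1, 2)
  d <- simulate_dataset(demography_constant(4, 8, L = 200), seed = 20)
  chars <- phylodem:::aln_chars(as.matrix(d$alignment))
  rownames(chars) <- paste0("s", 1:8)
  coded <- phylodem:::aln_coded(chars)
  pat <- phylodem:::site_patterns(coded)
  eig <- phylodem:::hky_eigen(3, phylodem:::base_freqs_empirical(chars))
  for (mu in c(0.001, 0.01, 0.05)) {
    llR <- phylodem:::state_loglik(st, pat$patterns, pat$weights, eig, mu)
    llC <- phylodem:::cpp_state_loglik(st$time, st$parent, st$child,
                                       st$root, 8L, pat$patterns,
                                       pat$weights, eig$U, eig$Uinv,
                                       eig$lambda, eig$freqs, mu)
    expect_equal(llR, llC, tolerance = 1e-10)
  }
})

test_that("zero-length degenerate trees with conflicting sites give -Inf", {
  chars <- char_aln(c(t1 = "AAAA", t2 = "CCCC"))
  tr <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                       edge.length = c(0, 0),
                       tip.label = c("t1", "t2"), Nnode = 1L),
                  class = "phylo")
  expect_equal(hky_likelihood(tr, chars, kappa = 2,
                              base_freqs = rep(0.25, 4)), -Inf)
})
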