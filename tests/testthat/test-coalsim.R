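# Coalescent simulator: genealogies and sequence evolution.

test_that("genealogies are valid and reproducible", {
  m <- demography_constant(5, 12, L = 100)
  g1 <- simulate_genealogy(m, seed = 7)
  g2 <- simulate_genealogy(m, seed = 7)
  expect_identical(g1$edge, g2$edge)
  expect_identical(g1$edge.length, g2$edge.length)
  chk <- capture.output(ape::checkValidPhylo(g1))
  expect_false(any(grepl("FATAL|MODERATE", chk)))
  expect_equal(length(g1$tip.label), 12L)
  expect_true(all(g1$edge.length >= 0))
})

test_that("pairwise coalescence matches the closed-form expectation", {
  # n = 2, constant theta: pairwise differences are geometric with mean
  # theta (mutational units; exact under infinite sites)
  set.seed(5)
  theta <- 5
  m <- demography_constant(theta, 2, L = 596)
  roots <- vapply(1:3000, function(i) {
    max(attr(simulate_genealogy(m), "node_times"))
  }, numeric(1))
  # pair coalescence time (mutational units) is Exp(1/theta): the pair
  # path then carries Poisson(root) mutations, so E[k] = theta
  expect_equal(mean(roots), theta, tolerance = 0.06)
})

test_that("split model respects migration structure", {
  m0 <- demography_split(4, 0, 2, 5, 5, L = 50)
  for (s in 1:5) {
    g <- simulate_genealogy(m0, seed = s)
    expect_equal(attr(g, "n_migrations"), 0L) # M = 0: never migrate
    expect_gte(max(attr(g, "node_times")), 2) # root above the split
  }
  mm <- demography_split(4, 8, 2, 5, 5, L = 50)
  nm <- vapply(1:10, function(s)
    attr(simulate_genealogy(mm, seed = s), "n_migrations"), integer(1))
  expect_gt(mean(nm), 0)
  # deep split without migration: between >> within differences
  d <- simulate_dataset(demography_split(5, 0, 10, 6, 6, L = 400),
                        seed = 11)
  dm <- phylodem:::pairwise_diff_matrix(phylodem:::aln_coded(d$alignment))
  within <- c(dm[1:6, 1:6][upper.tri(dm[1:6, 1:6])],
              dm[7:12, 7:12][upper.tri(dm[7:12, 7:12])])
  between <- dm[1:6, 7:12]
  expect_gt(mean(between), 3 * mean(within))
})

test_that("sequence evolution follows the HKY process", {
  # zero-length branches: all sequences identical
  m <- demography_constant(1e-8, 6, L = 100)
  d <- simulate_dataset(m, seed = 3)
  expect_equal(length(collapse_haplotypes(d$alignment)$counts), 1L)

  # large kappa: substitutions are (almost) all transitions
  tr <- ape::rtree(8)
  tr$edge.length <- rep(0.05, nrow(tr$edge))
  aln <- evolve_sequences(tr, L = 2000, kappa = 500,
                          base_freqs = rep(0.25, 4), seed = 9)
  km <- kappa_moments(aln)
  expect_gt(km$ts, 0)
  expect_lt(km$tv / max(km$ts, 1), 0.05)

  # moment estimate tracks the simulating kappa at moderate divergence
  aln2 <- evolve_sequences(tr, L = 5000, kappa = 4,
                           base_freqs = rep(0.25, 4), seed = 10)
  expect_equal(kappa_moments(aln2)$kappa, 4, tolerance = 0.35)
})

test_that("expansion spectra are unimodal with mode near tau", {
  set.seed(12)
  for (tau in c(3, 4.56, 6)) {
    acc <- NULL
    for (r in 1:40) {
      sp <- phylodem:::sim_mismatch_spectrum(40, tau, 0, 16.98)
      v <- numeric(40)
      v[as.integer(names(sp)) + 1L] <- sp
      acc <- if (is.null(acc)) v else acc + v
    }
    expect_lte(abs(which.max(acc) - 1 - tau), 1)
  }
})

test_that("simulate_dataset writes a reproducible file set", {
  out <- file.path(tempdir(), "simout")
  d <- simulate_dataset(demography_constant(3, 5, L = 60), seed = 8,
                        write_to = out)
  expect_true(file.exists(file.path(out, "alignment.fasta")))
  expect_true(file.exists(file.path(out, "popmap.tsv")))
  prov <- readLines(file.path(out, "provenance.txt"))
  expect_match(prov[1], "constant")
  expect_match(prov[3], "seed: 8")
  back <- read_alignment(file.path(out, "alignment.fasta"))
  expect_identical(as.character(as.matrix(back)),
                   as.character(as.matrix(d$alignment)))
})
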