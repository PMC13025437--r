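# Neutrality statistics against independently coded oracles, plus the
# simulation p-value machinery.

test_that("statistics are undefined (flagged) without polymorphism", {
  same <- char_aln(setNames(rep("ACGTAA", 5), paste0("s", 1:5)))
  expect_false(tajimas_d(same)$defined)
  expect_false(fu_li_d(same)$defined)
  expect_false(r2_stat(same)$defined)
  expect_false(fus_fs(same)$defined) # single haplotype boundary
})

test_that("Tajima's D, Fu & Li's D* and R2 match the oracles exactly", {
  for (seed in c(42, 43, 44)) {
    aln <- fixture_alignment(n = 8, theta = 4, L = 200, seed = seed)
    expect_equal(tajimas_d(aln)$value, oracle_tajima(aln),
                 tolerance = 1e-12)
    expect_equal(fu_li_d(aln)$value, oracle_fuli_dstar(aln),
                 tolerance = 1e-12)
    expect_equal(r2_stat(aln)$value, oracle_r2(aln), tolerance = 1e-12)
  }
})

test_that("Fu & Li's D with outgroup counts derived singletons", {
  # alignment with known ancestral states: outgroup all-A
  aln <- char_aln(c(s1 = "AAAACA", s2 = "AAAAAA", s3 = "GAAAAA",
                    s4 = "GATAAA", s5 = "AAAAAA"))
  og <- char_aln(c(out = "AAAAAA"))
  res <- fu_li_d(aln, outgroup = og)
  expect_equal(res$variant, "D")
  # by hand: eta = 3 (cols 1, 3, 5); external singletons (derived state
  # seen once): col3 T(s4) yes, col5 C(s1) yes; col1 G appears twice, no
  n <- 5; eta <- 3; eta_e <- 2
  an <- sum(1 / (1:4)); bn <- sum(1 / (1:4)^2)
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + an^2 / (bn + an^2) * (cn - (n + 1) / (n - 1))
  uD <- an - 1 - vD
  expect_equal(res$value,
               (eta - an * eta_e) / sqrt(uD * eta + vD * eta^2),
               tolerance = 1e-12)
  expect_error(fu_li_d(aln, outgroup = char_aln(c(out = "AAAA"))),
               "length")
})

test_that("Ewens haplotype-number pmf matches exact enumeration at n=4", {
  th <- 1.7
  lp <- phylodem:::log_pmf_K(th, 4)
  thn <- th * (th + 1) * (th + 2) * (th + 3)
  # unsigned Stirling numbers |s(4,k)| = 6, 11, 6, 1
  exact <- c(6 * th, 11 * th^2, 6 * th^3, th^4) / thn
  expect_equal(exp(lp[2:5]), exact, tolerance = 1e-12)
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-12)
  # stays normalized for large samples (log-space stability)
  expect_equal(sum(exp(phylodem:::log_pmf_K(12, 150))), 1,
               tolerance = 1e-9)
})

test_that("Fu's Fs follows the Ewens tail probability", {
  aln <- fixture_alignment(n = 6, theta = 3, L = 150, seed = 7)
  res <- fus_fs(aln)
  h <- collapse_haplotypes(aln)
  K <- length(h$counts)
  k <- nucleotide_diversity(aln)$k
  lp <- phylodem:::log_pmf_K(k, 6)
  Sp <- sum(exp(lp[(K + 1):7]))
  expect_equal(res$value, log(Sp / (1 - Sp)), tolerance = 1e-9)
})

test_that("statistics are invariant under sequence reordering", {
  aln <- fixture_alignment(n = 10, theta = 5, L = 150, seed = 13)
  m <- as.matrix(aln)
  perm <- m[sample(nrow(m)), ]
  for (f in list(tajimas_d, fu_li_d, fus_fs, r2_stat)) {
    expect_equal(f(perm)$value, f(m)$value, tolerance = 1e-12)
  }
})

test_that("null simulation p-values behave sensibly", {
  set.seed(2)
  aln <- fixture_alignment(n = 12, theta = 4, L = 300, seed = 31)
  res <- neutrality_pvalue("tajima_d", aln, n_sims = 800, seed = 5)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_equal(res$n_sims, 800)
  expect_equal(res$conditioning, "S")
  # neutral data should not be extreme
  expect_gt(res$p_value, 0.01)

  # p is monotone in the observed value for a fixed null sample
  nulls <- phylodem:::sim_null_statistics("tajima_d", 12, S = 10,
                                          n_sims = 500)
  obs <- sort(stats::quantile(nulls, c(0.2, 0.5, 0.8), na.rm = TRUE))
  ps <- vapply(obs, function(o) mean(nulls <= o, na.rm = TRUE),
               numeric(1))
  expect_true(all(diff(ps) >= 0))
  # observed at the simulated median -> p about one half
  expect_equal(unname(ps[2]), 0.5, tolerance = 0.05)

  # undefined statistic propagates
  same <- char_aln(setNames(rep("ACGTAA", 5), paste0("s", 1:5)))
  expect_false(neutrality_pvalue("tajima_d", same,
                                 n_sims = 200)$defined)
  expect_error(neutrality_pvalue("tajima_d", aln, n_sims = 50),
               "n_sims")
})

test_that("expansion data push Fs negative and R2 down", {
  set.seed(4)
  fs_exp <- r2_exp <- fs_con <- r2_con <- numeric(12)
  for (i in 1:12) {
    de <- simulate_dataset(
      demography_expansion(4.56, 0, 16.98, n = 30, L = 596),
      seed = 400 + i, infinite_sites = TRUE)
    dc <- simulate_dataset(demography_constant(5, 30, L = 596),
                           seed = 400 + i, infinite_sites = TRUE)
    fs_exp[i] <- fus_fs(de$alignment)$value
    fs_con[i] <- fus_fs(dc$alignment)$value
    r2_exp[i] <- r2_stat(de$alignment)$value
    r2_con[i] <- r2_stat(dc$alignment)$value
  }
  expect_lt(mean(fs_exp), -2)          # markedly negative under growth
  expect_lt(mean(fs_exp), mean(fs_con))
  expect_lt(mean(r2_exp), mean(r2_con)) # smaller R2 under expansion
})
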