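# Isolation-with-migration machinery: prior density, moves, conversion.

test_that("the structured-coalescent prior rejects invalid states", {
  set.seed(3)
  st <- phylodem:::sim_structured_state(3, 3, 2, 1.5)
  lp <- phylodem:::log_prior_state(st, 2, 1.5)
  expect_true(is.finite(lp))
  # migration event at/above T is invalid
  st2 <- st
  v <- which(st2$parent > 0)[1]
  st2$mig[[v]] <- c(st2$mig[[v]], 2.0) # >= T
  expect_equal(phylodem:::log_prior_state(st2, 2, 1.5), -Inf)
  # migration on the root edge is invalid
  st3 <- st
  st3$mig[[st3$root]] <- 0.5
  expect_equal(phylodem:::log_prior_state(st3, 2, 1.5), -Inf)
  # M = 0 with migration events present has zero density
  st4 <- phylodem:::sim_structured_state(3, 3, 6, 3)
  if (sum(lengths(st4$mig)) > 0) {
    expect_equal(phylodem:::log_prior_state(st4, 0, 3), -Inf)
  }
})

test_that("C++ prior matches the R reference over random states", {
  set.seed(9)
  for (i in 1:60) {
    M <- runif(1, 0, 8); Ts <- runif(1, 0.2, 5)
    st <- phylodem:::sim_structured_state(sample(2:5, 1),
                                          sample(2:5, 1), M, Ts)
    a <- phylodem:::log_prior_state(st, M, Ts)
    b <- phylodem:::cpp_log_prior(st$time, st$parent, st$child,
                                  st$tip_pop, st$mig, st$n_tip, M, Ts)
    if (is.finite(a) || is.finite(b)) {
      expect_equal(a, b, tolerance = 1e-10)
    }
  }
})

test_that("lineage threading preserves the structured-coalescent law", {
  # chain of threading moves only, compared against direct simulation
  set.seed(15)
  M <- 3; Ts <- 1.5
  K <- 1200
  direct <- t(replicate(K, {
    st <- phylodem:::sim_structured_state(3, 3, M, Ts)
    c(st$time[st$root], sum(lengths(st$mig)))
  }))
  st <- phylodem:::sim_structured_state(3, 3, M, Ts)
  out <- matrix(NA_real_, K, 2)
  for (i in seq_len(K * 10)) {
    cand <- seq_len(2 * st$n_tip - 1)[-st$root]
    v <- cand[sample.int(length(cand), 1)]
    det <- phylodem:::detach_node(st, v)
    ds <- det$state
    att <- phylodem:::cpp_thread_lineage(ds$time, ds$parent, ds$child,
                                         ds$tip_pop, ds$mig, ds$n_tip,
                                         ds$root, v, M, Ts, 1e6, 1000L)
    if (!is.null(att)) {
      st <- phylodem:::attach_node(ds, v, det$spare, att)
    }
    if (i %% 10 == 0) {
      out[i / 10, ] <- c(st$time[st$root], sum(lengths(st$mig)))
    }
  }
  expect_equal(mean(out[, 1]), mean(direct[, 1]), tolerance = 0.1)
  expect_equal(mean(out[, 2]), mean(direct[, 2]), tolerance = 0.12)
})

test_that("chains are bit-reproducible under a fixed seed", {
  d <- simulate_dataset(demography_split(4, 0, 2, 4, 4, L = 200),
                        seed = 31)
  a1 <- d$alignment[d$map$haplogroup == "POP1", ]
  a2 <- d$alignment[d$map$haplogroup == "POP2", ]
  cfg <- im_config(chain_length = 4000, burn_in = 1000, thinning = 10,
                   seed = 77, n_chains = 1)
  r1 <- im_mcmc(a1, a2, cfg)
  r2 <- im_mcmc(a1, a2, cfg)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$T_mode, r2$T_mode)
  # input validation
  expect_error(im_mcmc(a1, as.matrix(a2)[, 1:100], cfg), "lengths")
  expect_error(im_mcmc(a1[1, , drop = FALSE], a2, cfg), "sample-size")
})

test_that("posterior summaries expose histograms, modes and diagnostics", {
  d <- simulate_dataset(demography_split(5, 0, 2, 5, 5, L = 300),
                        seed = 41)
  a1 <- d$alignment[d$map$haplogroup == "POP1", ]
  a2 <- d$alignment[d$map$haplogroup == "POP2", ]
  cfg <- im_config(chain_length = 6000, burn_in = 2000, thinning = 10,
                   seed = 5, n_chains = 2)
  r <- im_mcmc(a1, a2, cfg)
  expect_s3_class(r, "divergence_estimate")
  expect_equal(nrow(r$chain_modes), 2L)
  expect_true(all(c("theta", "M", "T", "TMRCA") %in%
                    names(r$histograms)))
  h <- r$histograms$T
  expect_equal(nrow(h), 100L) # T_max/100 bins
  expect_equal(sum(h$mass), 1, tolerance = 1e-9)
  expect_true(all(r$samples[, "T"] <= cfg$T_max))
  expect_true(all(r$samples[, "M"] <= cfg$M_max))
  expect_output(print(r), "Isolation-with-migration")
})

test_that("unit conversion matches the stated formula", {
  # theta = 2 L mu_gen means Ne = 1
  L <- 596; rate <- 1.1e-8; g <- 1.5
  mu_gen <- rate * g
  cv <- convert_divergence(2 * L * mu_gen, T_mode = 1, TMRCA_mode = 2,
                           L = L, rate_per_site_per_year = rate, g = g)
  expect_equal(cv$Ne_female, 1, tolerance = 1e-12)
  # doubling the rate halves Ne and T_pop exactly
  cv1 <- convert_divergence(2.86, 8.95, 9.5, L, rate, g)
  cv2 <- convert_divergence(2.86, 8.95, 9.5, L, 2 * rate, g)
  expect_equal(cv2$Ne_female, cv1$Ne_female / 2, tolerance = 1e-12)
  expect_equal(cv2$T_pop_years, cv1$T_pop_years / 2, tolerance = 1e-12)
  # hand evaluation of T_pop = (T theta / 2L) / rate
  expect_equal(cv1$T_pop_years, 8.95 * 2.86 / (2 * 596) / 1.1e-8,
               tolerance = 1e-12)
  expect_gt(cv1$TMRCA_years, cv1$T_pop_years)
})
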