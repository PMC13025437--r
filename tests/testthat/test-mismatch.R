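# Stepwise-expansion mismatch analysis.

test_that("expected spectrum reduces to the equilibrium geometric law", {
  th <- 3
  f <- expected_mismatch(0, th, th, 40)
  geo <- th^(0:40) / (th + 1)^(1:41)
  expect_equal(f, geo / sum(geo), tolerance = 1e-12)
  # also via tau = 0 with differing theta0 (start at theta0 equilibrium)
  f2 <- expected_mismatch(0, 2, 8, 40)
  geo2 <- 2^(0:40) / 3^(1:41)
  expect_equal(f2, geo2 / sum(geo2), tolerance = 1e-12)
})

test_that("expected spectrum is a probability vector with mode near tau", {
  for (tau in c(3, 4.56, 6)) {
    f <- expected_mismatch(tau, 0, 16.98, 60)
    expect_equal(sum(f), 1, tolerance = 1e-9)
    expect_true(all(f >= 0))
    expect_lte(abs(which.max(f) - 1 - tau), 1.6) # unimodal near tau
  }
  expect_error(expected_mismatch(Inf, 0, 1, 10), "domain error")
  expect_error(expected_mismatch(-1, 0, 1, 10), "domain error")
})

test_that("expected spectrum matches a forward pairwise simulation", {
  set.seed(31)
  cases <- list(c(4.56, 0, 16.98), c(3, 1, 8), c(0, 2, 2))
  for (cs in cases) {
    tau <- cs[1]; th0 <- cs[2]; th1 <- cs[3]
    nrep <- 40000
    w <- stats::rexp(nrep, 1 / th1)
    xc <- ifelse(w < tau | tau == 0, w, if (th0 > 0)
      tau + stats::rexp(nrep, 1 / th0) else tau)
    if (tau == 0 && th0 > 0) xc <- stats::rexp(nrep, 1 / th0)
    diffs <- stats::rpois(nrep, xc)
    emp <- tabulate(diffs + 1, nbins = 31) / nrep
    thr <- expected_mismatch(tau, th0, th1, 120)[1:31]
    expect_lt(max(abs(emp - thr)), 0.01)
  }
})

test_that("raggedness follows Harpending's squared-step sum", {
  # uniform spectrum: only the trailing boundary step remains
  expect_equal(raggedness(rep(1, 5)), (1 / 5)^2)
  # interior spike: one step up, one step down
  expect_equal(raggedness(c(0, 0, 10, 0)), 2)
  # a smooth unimodal curve is less ragged than its permutation
  f <- expected_mismatch(5, 0, 10, 20)
  set.seed(2)
  expect_lt(raggedness(f), raggedness(sample(f)))
  expect_error(raggedness(numeric(0)), "empty")
})

test_that("fitting recovers parameters and flags degenerate input", {
  set.seed(17)
  sp <- phylodem:::sim_mismatch_spectrum(100, 4.56, 0, 16.98)
  fit <- fit_expansion(sp, 100, n_boot = 120, seed = 3)
  expect_s3_class(fit, "expansion_fit")
  expect_gte(fit$tau, 1)
  expect_lte(fit$tau, 9)
  expect_true(fit$converged)
  expect_true(all(fit$p_SSD >= 0 & fit$p_SSD <= 1))
  # CIs contain the point estimates
  expect_gte(fit$tau, fit$CI95["tau", 1] - 1e-9)
  expect_lte(fit$tau, fit$CI95["tau", 2] + 1e-9)
  expect_gte(fit$theta1, fit$theta0)

  # all-identical sequences: boundary fit at tau = 0, flagged degenerate
  sp0 <- c(`0` = 45)
  fit0 <- fit_expansion(sp0, 10, n_boot = 100, seed = 1)
  expect_equal(fit0$tau, 0)
  expect_equal(fit0$theta0, 0)
  expect_match(fit0$diagnostics, "degenerate")
  expect_error(fit_expansion(sp, 100, n_boot = 50), "n_boot")
  expect_error(fit_expansion(sp, 2, n_boot = 100), "sample-size")
})

test_that("fitted SSD is locally optimal on a surrounding grid", {
  set.seed(23)
  sp <- phylodem:::sim_mismatch_spectrum(60, 4, 1, 10)
  obs <- c(sp, rep(0, 10)) / sum(sp)
  fit <- phylodem:::fit_expansion_point(sp)
  for (dtau in c(-0.5, 0, 0.5)) for (dth in c(-0.5, 0, 0.5)) {
    tau2 <- max(fit$tau + dtau, 0)
    th12 <- max(fit$theta1 + dth, fit$theta0)
    expect_gte(phylodem:::mismatch_ssd(obs, tau2, fit$theta0, th12),
               fit$SSD - 1e-9)
  }
})

test_that("expansion-time conversion follows tau = 2ut", {
  et <- expansion_time(4.56, L = 596, rate_per_site_per_year = 1.1e-8,
                       g = 1.5)
  # by hand: u = 596 * 1.1e-8 * 1.5 per generation;
  # t = 4.56/(2u) generations * 1.5 years
  expect_equal(et$t_years, 4.56 / (2 * 596 * 1.1e-8 * 1.5) * 1.5,
               tolerance = 1e-12)
  expect_equal(et$t_years, 3.48e5, tolerance = 0.01)
  # doubling the rate halves the time exactly
  et2 <- expansion_time(4.56, 596, 2.2e-8, 1.5)
  expect_equal(et2$t_years, et$t_years / 2, tolerance = 1e-12)
  # round trip: time -> tau -> time
  tau_back <- 2 * et$u * et$t_generations
  expect_equal(tau_back, 4.56, tolerance = 1e-12)
  # pairwise-rate reading halves the per-lineage rate
  etp <- expansion_time(4.56, 596, 1.1e-8, 1.5, pairwise_rate = TRUE)
  expect_equal(etp$t_years, et$t_years * 2, tolerance = 1e-12)
})
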