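# Sudden (stepwise) demographic-expansion analysis of the mismatch
# distribution: closed-form expected spectrum, least-squares estimation of
# (tau, theta0, theta1), SSD and Harpending's raggedness with parametric
# bootstrap p-values and percentile confidence intervals, and conversion
# of tau into calendar time.

#' Expected mismatch distribution under stepwise expansion
#'
#' Probability that a random sequence pair differs at i sites when the
#' population grew suddenly from theta0 to theta1 at tau mutational units
#' (2ut) in the past. Computed from the classic closed form for pairwise
#' coalescence through a two-epoch history, written with regularized
#' gamma/Poisson terms so large tau and theta stay numerically stable; the
#' vector is truncated at \code{max_diff} and renormalized.
#'
#' @param tau Expansion age in mutational units, >= 0.
#' @param theta0,theta1 Pre-/post-expansion theta (>= 0).
#' @param max_diff Largest difference class retained (>= 1).
#' @return Numeric probability vector over 0..max_diff summing to one.
#' @export
expected_mismatch <- function(tau, theta0, theta1, max_diff) {
  if (!all(is.finite(c(tau, theta0, theta1))) ||
      any(c(tau, theta0, theta1) < 0)) {
    stop("domain error: parameters must be finite and non-negative")
  }
  stopifnot(max_diff >= 1)
  i <- 0:max_diff
  if (theta1 <= 1e-12) {
    # recent epoch collapses instantly: all pairs identical
    f <- c(1, rep(0, max_diff))
    return(f)
  }
  beta <- (theta1 + 1) / theta1
  # equilibrium geometric spectra, in logs
  lg1 <- i * log(theta1) - (i + 1) * log(theta1 + 1)
  part1 <- exp(lg1) * stats::pgamma(tau, shape = i + 1, rate = beta)
  # convolution term: e^{-beta tau} sum_j tau^j/j! Fhat_{i-j}(theta0)
  w <- exp(-beta * tau + tau) * stats::dpois(i, tau) # e^{-beta tau} tau^i/i!
  if (theta0 <= 1e-12) {
    part2 <- w
  } else {
    f0 <- exp(i * log(theta0) - (i + 1) * log(theta0 + 1))
    part2 <- vapply(i, function(ii) {
      sum(w[1:(ii + 1)] * f0[(ii + 1):1])
    }, numeric(1))
  }
  f <- part1 + part2
  f[f < 0] <- 0
  f / sum(f)
}

#' Harpending's raggedness index
#'
#' \eqn{rg = \sum_{i=1}^{d+1} (x_i - x_{i-1})^2} over the relative
#' mismatch frequencies \eqn{x_0..x_d} (d = largest difference class),
#' with \eqn{x_{d+1} = 0}. Smooth unimodal spectra — the signature of
#' sudden expansion — give small values.
#'
#' @param spectrum Numeric vector of mismatch counts or relative
#'   frequencies for difference classes 0, 1, ..., d.
#' @return Raggedness index (>= 0).
#' @export
raggedness <- function(spectrum) {
  if (!length(spectrum)) stop("input error: empty spectrum")
  x <- spectrum / sum(spectrum)
  x <- c(x, 0)
  sum(diff(x)^2)
}

# Sum of squared deviations between an observed relative spectrum and the
# model expectation over the same classes.
mismatch_ssd <- function(obs_rel, tau, theta0, theta1) {
  ex <- expected_mismatch(tau, theta0, theta1, length(obs_rel) - 1L)
  sum((obs_rel - ex)^2)
}

#' Fit the sudden-expansion model to a mismatch spectrum
#'
#' Least-squares estimation of (tau, theta0, theta1) by minimizing the sum
#' of squared deviations (SSD) between the observed relative
#' pairwise-difference spectrum and the stepwise-expansion expectation,
#' with multi-start bounded optimization. Goodness-of-fit p-values for SSD
#' and Harpending's raggedness, and percentile confidence intervals for
#' the parameters, come from a parametric bootstrap: data are re-simulated
#' under the fitted model (coalescent with the fitted demography) and
#' re-fit for every replicate.
#'
#' @param spectrum Observed mismatch counts (vector over classes 0..d),
#'   e.g. from \code{\link{pairwise_spectrum}}.
#' @param n Number of sequences behind the spectrum (>= 3).
#' @param n_boot Bootstrap replicates (>= 100; default 10000 matches the
#'   usual randomization count of this analysis).
#' @param seed Optional integer seed for the bootstrap.
#' @param extend Number of extra difference classes appended beyond the
#'   observed maximum when evaluating the expected spectrum (tail mass is
#'   negligible at fitted parameters).
#' @return Object of class \code{expansion_fit}: tau, theta0, theta1, SSD,
#'   rg, p_SSD, p_rg, CI95 (rows tau/theta0/theta1), bootstrap draws,
#'   convergence flag and diagnostics.
#' @export
fit_expansion <- function(spectrum, n, n_boot = 10000L, seed = NULL,
                          extend = 10L) {
  if (n < 3L) stop("sample-size error: spectrum must come from >= 3 sequences")
  if (n_boot < 100L) stop("input error: n_boot must be >= 100")
  fit <- fit_expansion_point(spectrum, extend = extend)
  if (!is.null(seed)) set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 5L,
                 dimnames = list(NULL, c("tau", "theta0", "theta1",
                                         "SSD", "rg")))
  boot_starts <- rbind(c(fit$tau, fit$theta0,
                         max(fit$theta1 - fit$theta0, 0.1)),
                       c(1, 0, max(fit$theta1, 1)))
  for (b in seq_len(n_boot)) {
    sp <- sim_mismatch_spectrum(n, fit$tau, fit$theta0, fit$theta1)
    bf <- fit_expansion_point(sp, extend = extend, starts = boot_starts)
    boot[b, ] <- c(bf$tau, bf$theta0, bf$theta1, bf$SSD,
                   raggedness(sp))
  }
  obs_rg <- raggedness(spectrum)
  ci <- t(apply(boot[, 1:3, drop = FALSE], 2L, stats::quantile,
                probs = c(0.025, 0.975), na.rm = TRUE))
  structure(list(
    tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
    SSD = fit$SSD, rg = obs_rg,
    p_SSD = mean(boot[, "SSD"] >= fit$SSD, na.rm = TRUE),
    p_rg = mean(boot[, "rg"] >= obs_rg, na.rm = TRUE),
    CI95 = ci, n = n, n_boot = n_boot,
    seed = if (is.null(seed)) NA_integer_ else seed,
    boot = boot, converged = fit$converged,
    diagnostics = fit$diagnostics,
    spectrum = spectrum / sum(spectrum),
    expected = expected_mismatch(fit$tau, fit$theta0, fit$theta1,
                                 length(spectrum) - 1L + extend)),
    class = "expansion_fit")
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat(sprintf(
    "Sudden-expansion fit (n = %d):\n  tau = %.3f (95%% CI %.2f-%.2f)\n",
    x$n, x$tau, x$CI95["tau", 1], x$CI95["tau", 2]))
  cat(sprintf("  theta0 = %.3f (%.2f-%.2f), theta1 = %.3f (%.2f-%.2f)\n",
              x$theta0, x$CI95["theta0", 1], x$CI95["theta0", 2],
              x$theta1, x$CI95["theta1", 1], x$CI95["theta1", 2]))
  cat(sprintf("  SSD = %.4f (p = %.3f), rg = %.4f (p = %.3f), %d bootstraps\n",
              x$SSD, x$p_SSD, x$rg, x$p_rg, x$n_boot))
  if (!x$converged) cat("  WARNING: optimizer did not converge cleanly\n")
  invisible(x)
}

# Point estimate only: multi-start bounded minimization of SSD. `starts`
# (rows of tau, theta0, theta1-theta0) overrides the default start grid;
# bootstrap refits pass the original fit to keep the refit cheap.
fit_expansion_point <- function(spectrum, extend = 10L, starts = NULL) {
  counts <- as.numeric(spectrum)
  d <- length(counts) - 1L
  obs <- c(counts, rep(0, extend)) / sum(counts)
  khat <- sum((0:d) * counts) / sum(counts)
  if (khat == 0) {
    return(list(tau = 0, theta0 = 0, theta1 = 0, SSD = 0,
                converged = TRUE,
                diagnostics = "degenerate: all pairs identical (boundary fit)"))
  }
  mode_cl <- which.max(counts) - 1L
  upper <- c(4 * (d + extend), 10 * khat + 10, 20 * khat + 20)
  objective <- function(p) mismatch_ssd(obs, p[1], p[2], p[2] + p[3])
  if (is.null(starts)) {
    starts <- expand.grid(tau = unique(c(1, max(mode_cl, 1))),
                          theta0 = c(0, khat / 2),
                          dtheta = c(khat, 5 * khat))
  }
  starts <- as.matrix(starts)
  best <- NULL
  codes <- integer(0)
  for (s in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[s, ]), c(0, 0, 0)), upper)
    o <- tryCatch(
      stats::optim(p0, objective,
                   method = "L-BFGS-B", lower = c(0, 0, 0),
                   upper = upper),
      error = function(e) NULL)
    if (is.null(o)) next
    codes <- c(codes, o$convergence)
    if (is.null(best) || o$value < best$value - 1e-12 ||
        (abs(o$value - best$value) <= 1e-12 && o$par[1] < best$par[1])) {
      best <- o
    }
  }
  if (is.null(best)) {
    return(list(tau = NA_real_, theta0 = NA_real_, theta1 = NA_real_,
                SSD = NA_real_, converged = FALSE,
                diagnostics = "all optimizer starts failed"))
  }
  list(tau = best$par[1], theta0 = best$par[2],
       theta1 = best$par[2] + best$par[3], SSD = best$value,
       converged = any(codes == 0L),
       diagnostics = sprintf("starts: %d, convergence codes: %s",
                             nrow(starts),
                             paste(unique(codes), collapse = ",")))
}

# Simulate one mismatch spectrum under the stepwise-expansion coalescent
# (mutational units; infinite-sites mutation counts per branch), without
# building sequences: pairwise differences are path sums of per-branch
# mutation counts.
sim_mismatch_spectrum <- function(n, tau, theta0, theta1) {
  g <- coal_times_piecewise(n, breaks = tau, thetas = c(theta1, theta0))
  n_nodes <- 2L * n - 1L
  br <- seq_len(n_nodes - 1L)
  len <- g$time[g$parent[br]] - g$time[br]
  m <- stats::rpois(length(br), len / 2)
  Mb <- matrix(0, n, length(br))
  desc <- vector("list", n_nodes)
  for (i in seq_len(n)) desc[[i]] <- i
  for (p in (n + 1L):n_nodes) {
    kids <- which(g$parent == p)
    desc[[p]] <- c(desc[[kids[1L]]], desc[[kids[2L]]])
  }
  for (b in br) Mb[desc[[b]], b] <- 1
  s <- drop(Mb %*% m)
  Dm <- outer(s, s, "+") - 2 * (Mb %*% (m * t(Mb)))
  spectrum_from_diffs(round(Dm[upper.tri(Dm)]))
}

#' Convert an expansion age tau to calendar time
#'
#' tau = 2ut with u the whole-locus mutation rate per generation; u is
#' assembled as \code{L * rate_per_site_per_year * g}. The substitution
#' rate is interpreted as a per-lineage rate by default (the usual reading
#' of "percent per million years" calibrations for arthropod mtDNA); set
#' \code{pairwise_rate = TRUE} when the calibration is a pairwise
#' divergence rate (this halves the per-lineage rate).
#'
#' @param tau Expansion age in mutational units.
#' @param L Locus length in sites.
#' @param rate_per_site_per_year Substitution rate per site per year
#'   (default 1.1e-8, i.e. 1.1% per Myr).
#' @param g Generation time in years (default 1.5).
#' @param pairwise_rate Interpret the rate as pairwise divergence.
#' @return Object of class \code{expansion_time}: tau, u (locus rate per
#'   generation), t_generations, t_years, and the rate interpretation.
#' @export
expansion_time <- function(tau, L = 596, rate_per_site_per_year = 1.1e-8,
                           g = 1.5, pairwise_rate = FALSE) {
  stopifnot(tau >= 0, L > 0, rate_per_site_per_year > 0, g > 0)
  rate <- if (pairwise_rate) rate_per_site_per_year / 2
          else rate_per_site_per_year
  u <- L * rate * g
  t_gen <- tau / (2 * u)
  structure(list(tau = tau, u = u, g = g,
                 rate_per_site_per_year = rate,
                 rate_interpretation = if (pairwise_rate) "pairwise"
                                       else "per-lineage",
                 t_generations = t_gen, t_years = t_gen * g),
            class = "expansion_time")
}

#' @export
print.expansion_time <- function(x, ...) {
  cat(sprintf(
    "tau = %.3f -> %.0f generations = %.3g years (u = %.3g/locus/gen, %s rate)\n",
    x$tau, x$t_generations, x$t_years, x$u, x$rate_interpretation))
  invisible(x)
}
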