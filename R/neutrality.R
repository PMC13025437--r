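# Neutrality tests: Tajima's D, Fu & Li's D (outgroup) and D* (without),
# Fu's Fs, Ramos-Onsins & Rozas's R2 — each available with an empirical
# p-value from neutral constant-size coalescent simulation.
#
# The statistic formulas live in small *_from() functions operating on
# sufficient summaries (n, S, eta, k, singleton tallies, haplotype count),
# so the observed-data path and the null-simulation path share one
# implementation.

# ---- sufficient summaries --------------------------------------------------

# Summaries from a coded alignment matrix (integers; any number of
# states). outgroup_row: optional coded vector giving the ancestral state
# per column (for Fu & Li's D with outgroup).
seq_summaries <- function(coded, outgroup_row = NULL) {
  n <- nrow(coded)
  L <- ncol(coded)
  k_states <- apply(coded, 2L, function(col) length(unique(col)))
  seg <- k_states > 1L
  S <- sum(seg)
  eta <- sum(k_states - 1L)
  d <- pairwise_diff_matrix(coded)
  k <- mean(d[upper.tri(d)])
  # singleton tallies over segregating columns
  eta_s <- 0L
  eta_e <- 0L
  U <- integer(n)
  for (j in which(seg)) {
    col <- coded[, j]
    tab <- table(col)
    singles <- names(tab)[tab == 1L]
    for (sv in singles) {
      carrier <- which(col == as.integer(sv))
      eta_s <- eta_s + 1L
      U[carrier] <- U[carrier] + 1L
      if (!is.null(outgroup_row) && as.integer(sv) != outgroup_row[j]) {
        eta_e <- eta_e + 1L
      }
    }
  }
  K <- length(unique(apply(coded, 1L, paste, collapse = "."))) # haplotypes
  list(n = n, L = L, S = S, eta = eta, k = k, eta_s = eta_s,
       eta_e = if (is.null(outgroup_row)) NA_integer_ else eta_e,
       U = U, K = K)
}

summaries_from_alignment <- function(aln, outgroup = NULL,
                                     site_policy = "complete") {
  if (!is.null(outgroup)) {
    og <- aln_chars(outgroup)
    m <- aln_chars(aln)
    if (ncol(og) != ncol(m)) {
      stop("input error: outgroup length differs from alignment")
    }
    both <- rbind(m, og[1L, , drop = FALSE])
    coded_all <- aln_coded(both, site_policy)
    coded <- coded_all[seq_len(nrow(m)), , drop = FALSE]
    attr(coded, "n_states") <- attr(coded_all, "n_states")
    seq_summaries(coded, outgroup_row = coded_all[nrow(both), ])
  } else {
    seq_summaries(aln_coded(aln, site_policy))
  }
}

# ---- statistic formulas ----------------------------------------------------

harmonic <- function(n, power = 1) sum(1 / (seq_len(n)^power))

tajima_constants <- function(n) {
  a1 <- harmonic(n - 1)
  a2 <- harmonic(n - 1, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

tajima_d_from <- function(n, S, k) {
  if (S < 1L) return(NA_real_)
  cc <- tajima_constants(n)
  (k - S / cc$a1) / sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
}

fuli_constants <- function(n) {
  an <- harmonic(n - 1)
  bn <- harmonic(n - 1, 2)
  an1 <- an + 1 / n
  cn <- if (n == 2L) 1 else 2 * (n * an - 2 * (n - 1)) /
    ((n - 1) * (n - 2))
  # D (with outgroup)
  vD <- 1 + an^2 / (bn + an^2) * (cn - (n + 1) / (n - 1))
  uD <- an - 1 - vD
  # D* (without outgroup); dn per Fu & Li (1993) with the published
  # correction, as implemented in the standard population-genetics
  # libraries
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vDs <- ((n / (n - 1))^2 * bn + an^2 * dn -
            2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uDs <- n / (n - 1) * (an - n / (n - 1)) - vDs
  list(an = an, bn = bn, cn = cn, dn = dn,
       vD = vD, uD = uD, vDs = vDs, uDs = uDs)
}

fuli_d_from <- function(n, eta, eta_e) {
  if (eta < 1L) return(NA_real_)
  cc <- fuli_constants(n)
  (eta - cc$an * eta_e) / sqrt(cc$uD * eta + cc$vD * eta^2)
}

fuli_dstar_from <- function(n, eta, eta_s) {
  if (eta < 1L) return(NA_real_)
  cc <- fuli_constants(n)
  (n / (n - 1) * eta - cc$an * eta_s) /
    sqrt(cc$uDs * eta + cc$vDs * eta^2)
}

r2_from <- function(n, U, k, S) {
  if (S < 1L) return(NA_real_)
  sqrt(mean((U - k / 2)^2)) / S
}

# log P(K = 0..n | theta, n) under the Ewens sampling formula, via the
# Poisson-binomial representation K = sum_i Bern(theta/(theta+i-1)),
# computed entirely in log space (no underflow for n in the hundreds).
log_pmf_K <- function(theta, n) {
  stopifnot(theta > 0, n >= 1)
  lp <- c(0, rep(-Inf, n)) # P(K=0)=1 before any draw
  for (i in seq_len(n)) {
    p <- theta / (theta + i - 1)
    lsucc <- c(-Inf, lp[seq_len(n)] + log(p))
    lfail <- if (p < 1) lp + log1p(-p) else rep(-Inf, n + 1L) # p==1 at i=1
    lp <- pmax(lsucc, lfail) +
      log1p(exp(pmin(lsucc, lfail) - pmax(lsucc, lfail)))
    lp[is.nan(lp)] <- -Inf
  }
  lp # index k+1 = log P(K = k)
}

logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

fs_from <- function(n, k, K) {
  if (!is.finite(k) || k <= 0) return(NA_real_)
  lp <- log_pmf_K(k, n)
  lS <- logsumexp(lp[(K + 1L):(n + 1L)])     # log P(K >= K_obs)
  l1mS <- if (K >= 2L) logsumexp(lp[seq_len(K)]) else -Inf
  if (!is.finite(lS) && !is.finite(l1mS)) {
    stop("numerical error: Ewens probability underflow for n = ", n)
  }
  if (!is.finite(l1mS)) return(Inf)  # S' = 1 (K_obs at/below minimum)
  if (!is.finite(lS)) return(-Inf)
  lS - l1mS
}

# ---- user-facing statistics ------------------------------------------------

neutrality_result <- function(statistic, value, n = NA_integer_,
                              p_value = NA_real_, n_sims = 0L,
                              conditioning = NA_character_,
                              seed = NA_integer_, variant = NULL) {
  structure(list(statistic = statistic, value = value, n = n,
                 defined = is.finite(value), p_value = p_value,
                 n_sims = n_sims, conditioning = conditioning,
                 seed = seed, variant = variant),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(x$statistic,
      if (!is.null(x$variant)) sprintf("(%s)", x$variant) else "",
      "=", if (x$defined) format(x$value, digits = 6) else "undefined")
  if (!is.na(x$p_value)) {
    cat(sprintf("  p = %.4g (%d sims, conditional on %s)",
                x$p_value, x$n_sims, x$conditioning))
  }
  cat("\n")
  invisible(x)
}

#' Tajima's D
#'
#' \eqn{D = (k - S/a_1)/\sqrt{e_1 S + e_2 S (S-1)}} with the canonical
#' constants derived from the sample size. Negative values indicate an
#' excess of rare variants, as after a recent demographic expansion.
#'
#' @param aln Alignment.
#' @param site_policy Site filtering policy.
#' @return A \code{neutrality_result}; \code{value} is \code{NA} (flagged
#'   undefined) when there are no segregating sites.
#' @export
tajimas_d <- function(aln, site_policy = "complete") {
  ss <- summaries_from_alignment(aln, site_policy = site_policy)
  if (ss$n < 4L) stop("sample-size error: need n >= 4")
  neutrality_result("Tajima's D", tajima_d_from(ss$n, ss$S, ss$k),
                    n = ss$n)
}

#' Fu and Li's D / D*
#'
#' With an outgroup sequence, external (derived singleton) mutations are
#' identified and Fu & Li's D is returned; without one the singleton-based
#' D* variant is computed. The variant used is recorded in the result.
#'
#' @param aln Alignment.
#' @param outgroup Optional outgroup sequence (same length), used to
#'   polarize singletons.
#' @param site_policy Site filtering policy.
#' @return A \code{neutrality_result} with \code{variant} "D" or "D*".
#' @export
fu_li_d <- function(aln, outgroup = NULL, site_policy = "complete") {
  ss <- summaries_from_alignment(aln, outgroup = outgroup,
                                 site_policy = site_policy)
  if (ss$n < 4L) stop("sample-size error: need n >= 4")
  if (is.null(outgroup)) {
    neutrality_result("Fu and Li's D", fuli_dstar_from(ss$n, ss$eta,
                                                       ss$eta_s),
                      n = ss$n, variant = "D*")
  } else {
    neutrality_result("Fu and Li's D", fuli_d_from(ss$n, ss$eta,
                                                   ss$eta_e),
                      n = ss$n, variant = "D")
  }
}

#' Fu's Fs
#'
#' \eqn{F_s = \ln(S'/(1-S'))} where \eqn{S' = P(K \ge K_{obs} \mid
#' \theta = \hat k)} under the Ewens sampling formula. The probability is
#' computed in log space through the sequential (Chinese-restaurant)
#' representation of the Ewens distribution, stable for samples of
#' hundreds of sequences.
#'
#' @inheritParams tajimas_d
#' @return A \code{neutrality_result}; infinite/undefined values (e.g. a
#'   single haplotype) are flagged via \code{defined = FALSE}.
#' @export
fus_fs <- function(aln, site_policy = "complete") {
  ss <- summaries_from_alignment(aln, site_policy = site_policy)
  if (ss$n < 2L) stop("sample-size error: need n >= 2")
  neutrality_result("Fu's Fs", fs_from(ss$n, ss$k, ss$K), n = ss$n)
}

#' Ramos-Onsins and Rozas's R2
#'
#' \eqn{R_2 = \sqrt{\frac{1}{n}\sum_i (U_i - k/2)^2} / S} with \eqn{U_i}
#' the number of singletons carried by sequence i. Small values indicate
#' the excess of singletons expected after population growth.
#'
#' @inheritParams tajimas_d
#' @return A \code{neutrality_result}.
#' @export
r2_stat <- function(aln, site_policy = "complete") {
  ss <- summaries_from_alignment(aln, site_policy = site_policy)
  if (ss$n < 4L) stop("sample-size error: need n >= 4")
  neutrality_result("R2", r2_from(ss$n, ss$U, ss$k, ss$S), n = ss$n)
}

# ---- null simulation -------------------------------------------------------

# One neutral constant-size genealogy for n samples; returns branch
# lengths (coalescent units) and, per branch, the tips it subtends.
null_genealogy <- function(n) {
  g <- coal_times_piecewise(n, breaks = numeric(0), thetas = 1)
  n_nodes <- 2L * n - 1L
  desc <- vector("list", n_nodes)
  for (i in seq_len(n)) desc[[i]] <- i
  for (p in (n + 1L):n_nodes) {
    kids <- which(g$parent == p)
    desc[[p]] <- c(desc[[kids[1L]]], desc[[kids[2L]]])
  }
  br <- seq_len(n_nodes - 1L) # all non-root nodes have a branch above
  list(len = g$time[g$parent[br]] - g$time[br], desc = desc[br], n = n)
}

# Simulated null values of one statistic, conditional on S (mutations
# dropped multinomially on branches, infinite sites) or on theta
# (Poisson mutation numbers with locus rate theta/2 per coalescent unit).
sim_null_statistics <- function(statistic, n, S = NULL, theta = NULL,
                                n_sims = 1000L,
                                conditioning = c("S", "theta")) {
  conditioning <- match.arg(conditioning)
  need_matrix <- statistic %in% c("fus_fs")
  out <- numeric(n_sims)
  for (r in seq_len(n_sims)) {
    g <- null_genealogy(n)
    nm <- if (conditioning == "S") {
      as.integer(stats::rmultinom(1L, S, g$len))
    } else {
      stats::rpois(length(g$len), g$len * theta / 2)
    }
    tot <- sum(nm)
    if (tot == 0L) { out[r] <- NA_real_; next }
    f <- vapply(g$desc, length, integer(1L))
    k <- sum(nm * 2 * f * (n - f)) / (n * (n - 1))
    out[r] <- switch(statistic,
      tajima_d = tajima_d_from(n, tot, k),
      fu_li_d = fuli_d_from(n, tot, sum(nm[f == 1L])),
      fu_li_dstar = fuli_dstar_from(n, tot,
                                    sum(nm[f == 1L | f == n - 1L])),
      r2 = {
        U <- integer(n)
        one <- which(f == 1L & nm > 0L)
        for (b in one) U[g$desc[[b]]] <- U[g$desc[[b]]] + nm[b]
        nm1 <- which(f == n - 1L & nm > 0L)
        for (b in nm1) {
          odd <- setdiff(seq_len(n), g$desc[[b]])
          U[odd] <- U[odd] + nm[b]
        }
        r2_from(n, U, k, tot)
      },
      fus_fs = {
        live <- which(nm > 0L)
        pat <- matrix(0L, n, sum(nm[live]))
        col <- 0L
        for (b in live) for (m in seq_len(nm[b])) {
          col <- col + 1L
          pat[g$desc[[b]], col] <- 1L
        }
        K <- length(unique(apply(pat, 1L, paste, collapse = "")))
        fs_from(n, k, K)
      },
      stop("unknown statistic: ", statistic))
  }
  out
}

#' Simulation p-value for a neutrality statistic
#'
#' Simulates the statistic's null distribution under selective neutrality
#' and constant population size (coalescent genealogies; mutations placed
#' under infinite sites, conditional on the observed number of segregating
#' sites by default, or on Watterson's theta), and reports the one-tailed
#' empirical p-value in each statistic's conventional rejection direction
#' (lower tail for D, D*, Fs and R2).
#'
#' @param statistic One of \code{"tajima_d"}, \code{"fu_li_d"} (needs
#'   \code{outgroup}), \code{"fu_li_dstar"}, \code{"fus_fs"}, \code{"r2"}.
#' @param aln Alignment.
#' @param n_sims Number of null simulations (>= 100).
#' @param seed Integer seed recorded in the result.
#' @param conditioning \code{"S"} (default) or \code{"theta"}.
#' @param outgroup Optional outgroup for \code{fu_li_d}.
#' @param site_policy Site filtering policy.
#' @return A \code{neutrality_result} with the observed value and p-value.
#' @export
neutrality_pvalue <- function(statistic, aln, n_sims = 10000L,
                              seed = NULL,
                              conditioning = c("S", "theta"),
                              outgroup = NULL,
                              site_policy = "complete") {
  conditioning <- match.arg(conditioning)
  if (n_sims < 100L) stop("input error: n_sims must be >= 100")
  statistic <- match.arg(statistic, c("tajima_d", "fu_li_d",
                                      "fu_li_dstar", "fus_fs", "r2"))
  if (statistic == "fu_li_d" && is.null(outgroup)) statistic <- "fu_li_dstar"
  ss <- summaries_from_alignment(aln, outgroup = outgroup,
                                 site_policy = site_policy)
  obs <- switch(statistic,
    tajima_d = tajima_d_from(ss$n, ss$S, ss$k),
    fu_li_d = fuli_d_from(ss$n, ss$eta, ss$eta_e),
    fu_li_dstar = fuli_dstar_from(ss$n, ss$eta, ss$eta_s),
    fus_fs = fs_from(ss$n, ss$k, ss$K),
    r2 = r2_from(ss$n, ss$U, ss$k, ss$S))
  if (!is.finite(obs)) {
    return(neutrality_result(statistic, obs, n = ss$n,
                             conditioning = conditioning))
  }
  if (!is.null(seed)) set.seed(seed)
  nulls <- sim_null_statistics(statistic, ss$n, S = ss$S,
                               theta = ss$S / harmonic(ss$n - 1),
                               n_sims = n_sims,
                               conditioning = conditioning)
  nulls <- nulls[is.finite(nulls)]
  p <- mean(nulls <= obs)
  neutrality_result(statistic, obs, n = ss$n, p_value = p,
                    n_sims = n_sims, conditioning = conditioning,
                    seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Significance stars for p-values
#' @param p Numeric vector of p-values.
#' @return Character vector: \code{***} p<0.001, \code{**} p<0.01,
#'   \code{*} p<0.05, empty otherwise.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}
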