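# Two-population isolation-with-migration (IM) estimation in the MDIV
# style: Metropolis-Hastings MCMC over genealogies with migration
# histories and the parameters (theta, M, T) under a finite-sites HKY
# likelihood, followed by posterior-mode extraction and conversion to
# demographic units.
#
# Units: time in coalescent units of Ne generations (pair coalescence
# rate 1 within a population; both daughter populations and the ancestor
# share the same size). Backward migration rate per lineage is M/2 per
# unit. theta = 2 Ne u (locus-wide), so the mutation rate is theta/(2L)
# substitutions per site per coalescent unit.

#' Configuration for the isolation-with-migration sampler
#'
#' @param M_max,T_max Upper bounds of the uniform priors on the scaled
#'   migration rate and divergence time (defaults 10 and 5).
#' @param theta_max Upper bound of the uniform prior on theta; \code{NULL}
#'   sets it at run time to five times the pooled Watterson estimate.
#' @param chain_length Total MCMC steps (default 5e6).
#' @param burn_in Steps discarded (default 1e6; must be < chain_length).
#' @param thinning Record every this-many steps (default 500).
#' @param seed Integer seed; chain i uses \code{seed + i - 1}.
#' @param kappa HKY kappa; \code{NULL} fixes it from the data by the
#'   pairwise transition/transversion moment estimate.
#' @param n_chains Replicate chains for the convergence check (default 3).
#' @param prior_only Switch the likelihood off (samples the joint prior;
#'   used to validate the sampler).
#' @return List of class \code{im_config}.
#' @export
im_config <- function(M_max = 10, T_max = 5, theta_max = NULL,
                      chain_length = 5e6, burn_in = 1e6, thinning = 500,
                      seed = 1L, kappa = NULL, n_chains = 3L,
                      prior_only = FALSE) {
  stopifnot(M_max > 0, T_max > 0, burn_in < chain_length, thinning >= 1)
  structure(list(M_max = M_max, T_max = T_max, theta_max = theta_max,
                 chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning), seed = as.integer(seed),
                 kappa = kappa, n_chains = as.integer(n_chains),
                 prior_only = isTRUE(prior_only)),
            class = "im_config")
}

# ---- genealogy state -------------------------------------------------------
# state: list(n_tip, time, parent (0 = root), child (n x 2, 0 for tips),
#             tip_pop, mig (list of ascending event times on the edge
#             above each node), root)

# Simulate a structured two-population genealogy from the prior, keeping
# per-edge migration events. Also the chain initializer.
sim_structured_state <- function(n1, n2, M, T_split) {
  n <- n1 + n2
  n_nodes <- 2L * n - 1L
  time <- numeric(n_nodes)
  parent <- integer(n_nodes)
  child <- matrix(0L, n_nodes, 2L)
  mig <- rep(list(numeric(0)), n_nodes)
  tip_pop <- c(rep(1L, n1), rep(2L, n2))
  active <- seq_len(n)
  pop <- tip_pop
  nxt <- n + 1L
  t <- 0
  repeat {
    k <- length(active)
    if (k == 1L) break
    if (t < T_split) {
      k1 <- sum(pop == 1L); k2 <- k - k1
      rc <- k1 * (k1 - 1) / 2 + k2 * (k2 - 1) / 2
      rm <- M / 2 * k
      if (rc + rm <= 0) { t <- T_split; next }
      wait <- stats::rexp(1L, rc + rm)
      if (t + wait >= T_split) { t <- T_split; next }
      t <- t + wait
      if (stats::runif(1L) < rm / (rc + rm)) {
        i <- sample(k, 1L)
        mig[[active[i]]] <- c(mig[[active[i]]], t)
        pop[i] <- 3L - pop[i]
      } else {
        p <- if (stats::runif(1L) <
               (k1 * (k1 - 1) / 2) / rc) 1L else 2L
        idx <- which(pop == p)
        pick <- idx[sample(length(idx), 2L)]
        parent[active[pick]] <- nxt
        child[nxt, ] <- active[pick]
        time[nxt] <- t
        active <- c(active[-pick], nxt)
        pop <- c(pop[-pick], p)
        nxt <- nxt + 1L
      }
    } else {
      wait <- stats::rexp(1L, k * (k - 1) / 2)
      t <- t + wait
      pick <- sample(k, 2L)
      parent[active[pick]] <- nxt
      child[nxt, ] <- active[pick]
      time[nxt] <- t
      active <- c(active[-pick], nxt)
      pop <- c(pop[-pick], 1L)
      nxt <- nxt + 1L
    }
  }
  list(n_tip = n, time = time, parent = parent, child = child,
       tip_pop = tip_pop, mig = mig, root = n_nodes)
}

# Population of the lineage above node v at time t (t within v's edge,
# i.e. time[v] <= t < time[parent[v]] or v is the root).
pop_at <- function(state, v, t) {
  p <- pop_base(state, v)
  flips <- sum(state$mig[[v]] <= t)
  if (flips %% 2L == 1L) 3L - p else p
}

# Population of the lineage at node v exactly at time[v] (before any of
# v's own-edge events). Derived from a descendant tip.
pop_base <- function(state, v) {
  if (v <= state$n_tip) return(state$tip_pop[v])
  c1 <- state$child[v, 1L]
  p <- pop_base(state, c1)
  flips <- length(state$mig[[c1]])
  if (flips %% 2L == 1L) 3L - p else p
}

# Joint log-density of (genealogy, migration events) given M and T under
# the structured coalescent, or -Inf when the configuration is invalid
# (cross-population coalescence below T, migration at/above T, event
# outside its edge span).
log_prior_state <- function(state, M, T_split) {
  n <- state$n_tip
  n_nodes <- 2L * n - 1L
  # event lists: coalescences and migrations
  ev_t <- state$time[(n + 1L):n_nodes]
  ev_type <- rep(1L, n - 1L)
  ev_node <- (n + 1L):n_nodes
  for (v in seq_len(n_nodes)) {
    mg <- state$mig[[v]]
    if (length(mg)) {
      if (state$parent[v] == 0L) return(-Inf)
      if (any(mg >= T_split) || any(mg <= state$time[v]) ||
          any(mg >= state$time[state$parent[v]])) return(-Inf)
      ev_t <- c(ev_t, mg)
      ev_type <- c(ev_type, rep(2L, length(mg)))
      ev_node <- c(ev_node, rep(v, length(mg)))
    }
  }
  o <- order(ev_t)
  ev_t <- ev_t[o]; ev_type <- ev_type[o]; ev_node <- ev_node[o]
  cur_pop <- integer(n_nodes)
  alive <- logical(n_nodes)
  cur_pop[seq_len(n)] <- state$tip_pop
  alive[seq_len(n)] <- TRUE
  lp <- 0
  t <- 0
  for (e in seq_along(ev_t)) {
    te <- ev_t[e]
    # integrate rate over [t, te), splitting at T
    lp <- lp - rate_integral(sum(alive & cur_pop == 1L),
                             sum(alive & cur_pop == 2L),
                             M, T_split, t, te)
    t <- te
    v <- ev_node[e]
    if (ev_type[e] == 2L) {
      if (te >= T_split) return(-Inf)
      cur_pop[v] <- 3L - cur_pop[v]
      lp <- lp + log(M / 2)
      if (!is.finite(lp)) return(-Inf)
    } else {
      k1 <- state$child[v, 1L]; k2 <- state$child[v, 2L]
      if (te < T_split && cur_pop[k1] != cur_pop[k2]) return(-Inf)
      alive[k1] <- FALSE; alive[k2] <- FALSE
      alive[v] <- TRUE
      cur_pop[v] <- if (te < T_split) cur_pop[k1] else 1L
    }
  }
  lp
}

# Integral of the total event rate over [t0, t1) given k1/k2 lineages per
# population (below T: within-pop coalescence + migration; above: single
# pool of k1+k2 lineages).
rate_integral <- function(k1, k2, M, T_split, t0, t1) {
  below <- max(0, min(t1, T_split) - t0)
  above <- max(0, t1 - max(t0, T_split))
  r_below <- k1 * (k1 - 1) / 2 + k2 * (k2 - 1) / 2 + M / 2 * (k1 + k2)
  k <- k1 + k2
  r_above <- k * (k - 1) / 2
  below * r_below + above * r_above
}

# ---- likelihood ------------------------------------------------------------

# Full pruning likelihood of the state's genealogy. patterns: 4 x P tip
# partials are implied by pattern_idx (n_tip x P integer states).
state_loglik <- function(state, pattern_idx, weights, eig, mu_scale) {
  n <- state$n_tip
  n_nodes <- 2L * n - 1L
  P <- ncol(pattern_idx)
  internal <- (n + 1L):n_nodes
  ord <- internal[order(state$time[internal])]
  partial <- vector("list", n_nodes)
  lsc <- vector("list", n_nodes)
  for (v in ord) {
    acc <- NULL
    sc <- rep(0, P)
    for (ci in 1:2) {
      ch <- state$child[v, ci]
      b <- (state$time[v] - state$time[ch]) * mu_scale
      Pm <- hky_transition_prob(b, eig = eig)
      contrib <- if (ch <= n) {
        Pm[, pattern_idx[ch, ], drop = FALSE]
      } else {
        sc <- sc + lsc[[ch]]
        Pm %*% partial[[ch]]
      }
      acc <- if (is.null(acc)) contrib else acc * contrib
    }
    mx <- .colMax(acc)
    if (any(mx <= 0)) return(-Inf)
    partial[[v]] <- acc / rep(mx, each = 4L)
    lsc[[v]] <- sc + log(mx)
  }
  lik <- colSums(eig$freqs * partial[[state$root]])
  if (any(lik <= 0)) return(-Inf)
  sum(weights * (log(lik) + lsc[[state$root]]))
}

.colMax <- function(m) {
  do.call(pmax, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}

# ---- MCMC moves ------------------------------------------------------------

# Detach node v (and its subtree) from its parent; returns modified state
# plus the sibling-merge bookkeeping. v must not be the root.
detach_node <- function(state, v) {
  p <- state$parent[v]
  sib <- setdiff(state$child[p, ], v)
  q <- state$parent[p]
  if (q != 0L) {
    state$child[q, which(state$child[q, ] == p)] <- sib
    state$parent[sib] <- q
    state$mig[[sib]] <- sort(c(state$mig[[sib]], state$mig[[p]]))
  } else {
    state$parent[sib] <- 0L
    state$mig[[sib]] <- numeric(0) # segment above the root carries no events
    state$root <- sib
  }
  state$parent[v] <- 0L
  state$parent[p] <- 0L
  state$child[p, ] <- 0L
  state$mig[[p]] <- numeric(0)
  list(state = state, spare = p)
}

# Rest-tree edges alive at time t (excluding the detached subtree, which
# is disconnected): nodes with parent != 0 whose edge spans t, plus the
# rest root as an open-ended edge.
alive_edges <- function(state, t) {
  n_nodes <- 2L * state$n_tip - 1L
  out <- integer(0)
  for (w in seq_len(n_nodes)) {
    pw <- state$parent[w]
    if (pw != 0L) {
      if (state$time[w] <= t && t < state$time[pw]) out <- c(out, w)
    } else if (w == state$root && state$time[w] <= t) {
      out <- c(out, w)
    }
  }
  out
}

# Thread the detached lineage (starting at node v, time t_v) back through
# the rest tree: migrate at M/2 below T, coalesce at rate 1 per same-pop
# contemporary edge; above the rest root the remaining ancestral lineage
# is also allowed to migrate. When the detachment point lies above the
# rest root, the rest-root lineage's migration path on the segment below
# t_v is regenerated too (rejection-sampled against non-coalescence with
# the detached subtree's lineages), so the proposal is the exact
# conditional prior of everything the move erases. Returns the attachment
# (target edge, time) and the new migration paths, or NULL when the
# rejection loop or time cap gives up (counted as a rejected move).
thread_lineage <- function(state, v, M, T_split, t_cap = Inf,
                           max_retry = 1000L) {
  t <- state$time[v]
  cur_pop <- pop_base(state, v)
  new_self <- numeric(0)
  new_other <- numeric(0)
  rootR <- state$root
  other_pop_flip <- 0L
  if (state$time[rootR] < t) {
    pre <- sim_root_segment(state, v, M, T_split,
                            a = state$time[rootR], b = t,
                            max_retry = max_retry)
    if (is.null(pre)) return(NULL)
    new_other <- pre
    other_pop_flip <- length(pre)
  }
  # breakpoints of the rest interval structure
  n_nodes <- 2L * state$n_tip - 1L
  bps <- c(state$time[state$parent != 0L | seq_len(n_nodes) == rootR],
           unlist(state$mig), T_split)
  bps <- sort(unique(bps[bps > t & is.finite(bps)]))
  bps <- c(bps, Inf)
  repeat {
    b <- bps[which(bps > t)[1L]]
    al <- alive_edges(state, t)
    only_root <- length(al) == 1L && al[1L] == rootR &&
      state$time[rootR] <= t
    pops <- vapply(al, function(w) {
      if (w == rootR) {
        p0 <- pop_base(state, rootR)
        if (other_pop_flip %% 2L == 1L) 3L - p0 else p0
      } else pop_at(state, w, t)
    }, integer(1L))
    below <- t < T_split
    same <- if (below) al[pops == cur_pop] else al
    r_coal <- length(same)
    r_mig <- if (below) M / 2 else 0
    r_mig_other <- if (below && only_root) M / 2 else 0
    total <- r_coal + r_mig + r_mig_other
    if (total <= 0) { t <- b; next }
    wait <- stats::rexp(1L, total)
    if (t + wait >= b) { t <- b; next }
    t <- t + wait
    u <- stats::runif(1L) * total
    if (u < r_coal) {
      target <- same[sample.int(length(same), 1L)]
      return(list(target = target, time = t, new_self = new_self,
                  new_other = new_other))
    } else if (u < r_coal + r_mig) {
      new_self <- c(new_self, t)
      cur_pop <- 3L - cur_pop
    } else {
      new_other <- c(new_other, t)
      other_pop_flip <- other_pop_flip + 1L
    }
    if (t > t_cap) return(NULL)
  }
}

# Migration path of the rest-root lineage on [a, b] (b = detachment
# time), conditional on not coalescing with the detached subtree's
# lineages: flips are a Poisson(M/2) process below T, accepted with
# probability exp(-integral of the same-population subtree-lineage count)
# — a rejection sampler for the exactly tilted conditional.
sim_root_segment <- function(state, v, M, T_split, a, b, max_retry) {
  rootR <- state$root
  z0 <- pop_base(state, rootR)
  sub <- subtree_nodes(state, v)
  end <- min(b, T_split)
  lam <- M / 2 * max(end - a, 0)
  for (i in seq_len(max_retry)) {
    ev <- if (lam > 0) sort(stats::runif(stats::rpois(1L, lam), a, end))
          else numeric(0)
    integ <- forbidden_integral(state, sub, z0, ev, a, b, T_split)
    if (stats::runif(1L) < exp(-integ)) return(ev)
  }
  NULL
}

# Nodes strictly below v (v's subtree, excluding v itself).
subtree_nodes <- function(state, v) {
  if (v <= state$n_tip) return(integer(0))
  out <- integer(0)
  stack <- state$child[v, ]
  while (length(stack)) {
    w <- stack[1L]; stack <- stack[-1L]
    out <- c(out, w)
    if (w > state$n_tip) stack <- c(stack, state$child[w, ])
  }
  out
}

# Integral over [a, b] of the coalescence rate between the rest-root
# lineage (population path z0 flipped at `ev`) and the alive edges of the
# detached subtree (same population below T, any population above).
forbidden_integral <- function(state, sub, z0, ev, a, b, T_split) {
  if (!length(sub)) return(0)
  lo <- state$time[sub]
  hi <- state$time[ifelse(state$parent[sub] > 0L, state$parent[sub], sub)]
  bps <- sort(unique(c(a, b, T_split, ev, lo, hi,
                       unlist(state$mig[sub]))))
  bps <- bps[bps >= a & bps <= b]
  if (length(bps) < 2L) return(0)
  total <- 0
  for (i in seq_len(length(bps) - 1L)) {
    s <- (bps[i] + bps[i + 1L]) / 2
    len <- bps[i + 1L] - bps[i]
    alive <- which(lo <= s & s < hi)
    if (!length(alive)) next
    if (s < T_split) {
      zpop <- if (sum(ev <= s) %% 2L == 1L) 3L - z0 else z0
      cnt <- sum(vapply(sub[alive], function(w)
        pop_at(state, w, s), integer(1L)) == zpop)
    } else {
      cnt <- length(alive)
    }
    total <- total + len * cnt
  }
  total
}

# Reattach: create node `spare` at `att$time` on edge `att$target`.
attach_node <- function(state, v, spare, att) {
  tg <- att$target
  tt <- att$time
  state$time[spare] <- tt
  state$child[spare, ] <- c(v, tg)
  state$parent[v] <- spare
  state$mig[[v]] <- att$new_self
  if (tg == state$root) {
    state$parent[spare] <- 0L
    state$mig[[spare]] <- numeric(0)
    state$parent[tg] <- spare
    state$mig[[tg]] <- sort(att$new_other)
    state$root <- spare
  } else {
    q <- state$parent[tg]
    state$parent[spare] <- q
    state$child[q, which(state$child[q, ] == tg)] <- spare
    mg <- state$mig[[tg]]
    state$mig[[spare]] <- mg[mg > tt]
    state$mig[[tg]] <- mg[mg <= tt]
    state$parent[tg] <- spare
  }
  state
}

# ---- the sampler -----------------------------------------------------------

#' Isolation-with-migration MCMC for two populations
#'
#' Jointly samples the genealogy (topology, node times, migration paths)
#' and the parameters theta (locus-scaled 2 Ne u), M (scaled migration)
#' and T (scaled divergence time) with uniform priors on
#' \code{[0, theta_max]}, \code{[0, M_max]}, \code{[0, T_max]}, under a
#' finite-sites HKY likelihood. Genealogy updates use node-time slides and
#' a lineage-threading (Wilson-Balding style) move whose proposal is the
#' conditional structured-coalescent prior, so its acceptance reduces to
#' the likelihood ratio.
#'
#' @param aln1,aln2 Alignments of the two populations (equal lengths).
#' @param config An \code{\link{im_config}}.
#' @return Object of class \code{divergence_estimate} with posterior
#'   samples and histograms of theta, M, T, TMRCA; their modes;
#'   per-move acceptance rates; and a multi-chain mode-agreement
#'   diagnostic. Boundary-mode warnings are flagged.
#' @export
im_mcmc <- function(aln1, aln2, config = im_config()) {
  stopifnot(inherits(config, "im_config"))
  m1 <- as.matrix(as_dnabin(aln1)); m2 <- as.matrix(as_dnabin(aln2))
  if (ncol(m1) != ncol(m2)) {
    stop("input error: alignments have different lengths")
  }
  if (nrow(m1) < 2L || nrow(m2) < 2L) {
    stop("sample-size error: need >= 2 sequences per population")
  }
  pooled <- rbind(aln_chars(m1), aln_chars(m2))
  rownames(pooled) <- c(paste0("p1_", seq_len(nrow(m1))),
                        paste0("p2_", seq_len(nrow(m2))))
  coded <- aln_coded(pooled, "complete")
  L <- attr(coded, "n_retained")
  n1 <- nrow(m1); n2 <- nrow(m2)
  kap <- if (is.null(config$kappa)) kappa_moments(pooled)$kappa
         else config$kappa
  freqs <- base_freqs_empirical(pooled)
  eig <- hky_eigen(kap, freqs)
  pat <- site_patterns(coded)
  theta_w <- watterson_theta(coded)
  theta_max <- if (is.null(config$theta_max)) max(5 * theta_w, 1)
               else config$theta_max
  chains <- lapply(seq_len(config$n_chains), function(ci) {
    run_im_chain(pat, n1, n2, L, eig, config,
                 seed = config$seed + ci - 1L,
                 theta_init = max(theta_w, 0.1), theta_max = theta_max)
  })
  samples <- do.call(rbind, lapply(chains, `[[`, "samples"))
  modes <- list(
    theta = hist_mode(samples[, "theta"], 0, theta_max, 100L),
    M = hist_mode(samples[, "M"], 0, config$M_max, 100L),
    T = hist_mode(samples[, "T"], 0, config$T_max, 100L),
    TMRCA = hist_mode(samples[, "TMRCA"], 0,
                      max(samples[, "TMRCA"]) * 1.001, 100L))
  chain_modes <- t(vapply(chains, function(ch) c(
    theta = hist_mode(ch$samples[, "theta"], 0, theta_max, 100L)$mode,
    M = hist_mode(ch$samples[, "M"], 0, config$M_max, 100L)$mode,
    T = hist_mode(ch$samples[, "T"], 0, config$T_max, 100L)$mode),
    numeric(3L)))
  boundary <- c(
    M = modes$M$mode > config$M_max * 0.97,
    T = modes$T$mode > config$T_max * 0.97,
    theta = modes$theta$mode > theta_max * 0.97)
  structure(list(
    samples = samples, chains = lapply(chains, `[[`, "samples"),
    theta_mode = modes$theta$mode, M_mode = modes$M$mode,
    T_mode = modes$T$mode, TMRCA_mode = modes$TMRCA$mode,
    histograms = lapply(modes, `[[`, "hist"),
    acceptance = Reduce(`+`, lapply(chains, `[[`, "acc")) /
      config$n_chains,
    chain_modes = chain_modes,
    mode_spread = apply(chain_modes, 2L, function(x) diff(range(x))),
    boundary_flags = boundary, kappa = kap, base_freqs = freqs,
    L = L, n1 = n1, n2 = n2, theta_max = theta_max, config = config),
    class = "divergence_estimate")
}

watterson_theta <- function(coded) {
  n <- nrow(coded)
  S <- sum(apply(coded, 2L, function(col) length(unique(col))) > 1L)
  max(S, 1) / harmonic(n - 1)
}

hist_mode <- function(x, lo, hi, nbins) {
  br <- seq(lo, hi, length.out = nbins + 1L)
  x <- x[x >= lo & x <= hi]
  idx <- pmin(nbins, pmax(1L, findInterval(x, br, rightmost.closed = TRUE)))
  counts <- tabulate(idx, nbins)
  i <- which.max(counts) # ties: which.max takes the first = smaller value
  list(mode = (br[i] + br[i + 1L]) / 2,
       hist = data.frame(bin_left = br[-length(br)], bin_right = br[-1L],
                         mass = counts / max(sum(counts), 1L)))
}

run_im_chain <- function(pat, n1, n2, L, eig, config, seed, theta_init,
                         theta_max) {
  set.seed(seed)
  Mmax <- config$M_max; Tmax <- config$T_max
  Tcur <- Tmax / 2
  Mcur <- min(Mmax / 10, 1)
  theta <- min(theta_init, theta_max)
  state <- sim_structured_state(n1, n2, Mcur, Tcur)
  pattern_idx <- pat$patterns
  weights <- pat$weights
  n <- n1 + n2
  use_cpp <- exists("cpp_state_loglik", mode = "function")
  ll_fun <- function(st, th) {
    if (config$prior_only) return(0)
    if (use_cpp) {
      cpp_state_loglik(st$time, st$parent, st$child, st$root, n,
                       pattern_idx, weights, eig$U, eig$Uinv,
                       eig$lambda, eig$freqs, th / (2 * L))
    } else {
      state_loglik(st, pattern_idx, weights, eig, th / (2 * L))
    }
  }
  lp_fun <- if (use_cpp) {
    function(st, M, Ts) cpp_log_prior(st$time, st$parent, st$child,
                                      st$tip_pop, st$mig, st$n_tip,
                                      M, Ts)
  } else {
    log_prior_state
  }
  thread_fun <- if (use_cpp) {
    function(st, v, M, Ts, t_cap) {
      cpp_thread_lineage(st$time, st$parent, st$child, st$tip_pop,
                         st$mig, st$n_tip, st$root, v, M, Ts, t_cap,
                         1000L)
    }
  } else {
    thread_lineage
  }
  lp <- lp_fun(state, Mcur, Tcur)
  ll <- ll_fun(state, theta)
  n_keep <- (config$chain_length - config$burn_in) %/% config$thinning
  samples <- matrix(NA_real_, n_keep, 5L,
                    dimnames = list(NULL, c("theta", "M", "T", "TMRCA",
                                            "n_mig")))
  kept <- 0L
  acc <- c(theta = 0, M = 0, T = 0, time = 0, thread = 0, scale = 0)
  tries <- c(theta = 0, M = 0, T = 0, time = 0, thread = 0, scale = 0)
  internal_nodes <- (n + 1L):(2L * n - 1L)
  for (step in seq_len(config$chain_length)) {
    mv <- sample.int(6L, 1L, prob = c(1, 1, 1, n - 1, n, 2))
    if (mv == 1L && !config$prior_only) {
      tries["theta"] <- tries["theta"] + 1
      th2 <- theta * exp(0.5 * (stats::runif(1L) - 0.5))
      if (th2 <= theta_max) {
        ll2 <- ll_fun(state, th2)
        if (log(stats::runif(1L)) < ll2 - ll + log(th2 / theta)) {
          theta <- th2; ll <- ll2; acc["theta"] <- acc["theta"] + 1
        }
      }
    } else if (mv == 1L) {
      # prior-only: theta has no likelihood; sample uniformly
      theta <- stats::runif(1L, 0, theta_max)
      acc["theta"] <- acc["theta"] + 1; tries["theta"] <- tries["theta"] + 1
    } else if (mv == 2L) {
      tries["M"] <- tries["M"] + 1
      M2 <- reflect(Mcur + (stats::runif(1L) - 0.5) * Mmax / 4, 0, Mmax)
      lp2 <- lp_fun(state, M2, Tcur)
      if (log(stats::runif(1L)) < lp2 - lp) {
        Mcur <- M2; lp <- lp2; acc["M"] <- acc["M"] + 1
      }
    } else if (mv == 3L) {
      tries["T"] <- tries["T"] + 1
      T2 <- reflect(Tcur + (stats::runif(1L) - 0.5) * Tmax / 4, 0, Tmax)
      lp2 <- lp_fun(state, Mcur, T2)
      if (log(stats::runif(1L)) < lp2 - lp) {
        Tcur <- T2; lp <- lp2; acc["T"] <- acc["T"] + 1
      }
    } else if (mv == 4L) {
      tries["time"] <- tries["time"] + 1
      v <- internal_nodes[sample.int(n - 1L, 1L)]
      lower <- max(state$time[state$child[v, ]])
      if (state$parent[v] == 0L) {
        gap <- state$time[v] - lower
        gap2 <- gap * exp(0.7 * (stats::runif(1L) - 0.5))
        t2 <- lower + gap2
        lhr <- log(gap2 / gap)
      } else {
        upper <- state$time[state$parent[v]]
        t2 <- stats::runif(1L, lower, upper)
        lhr <- 0
      }
      st2 <- state
      st2$time[v] <- t2
      if (edge_events_ok(st2, v)) {
        lp2 <- lp_fun(st2, Mcur, Tcur)
        if (is.finite(lp2)) {
          ll2 <- ll_fun(st2, theta)
          if (log(stats::runif(1L)) < (lp2 - lp) + (ll2 - ll) + lhr) {
            state <- st2; lp <- lp2; ll <- ll2
            acc["time"] <- acc["time"] + 1
          }
        }
      }
    } else if (mv == 6L) {
      # joint rescale of T, node times and migration times: traverses the
      # T axis quickly, which otherwise mixes slowly because T is pinned
      # by the genealogy's cross-population structure
      tries["scale"] <- tries["scale"] + 1
      cc <- exp(0.7 * (stats::runif(1L) - 0.5))
      T2 <- Tcur * cc
      if (T2 <= Tmax) {
        st2 <- state
        st2$time <- state$time * cc
        st2$mig <- lapply(state$mig, function(m) m * cc)
        n_mig <- sum(lengths(state$mig))
        lp2 <- lp_fun(st2, Mcur, T2)
        if (is.finite(lp2)) {
          ll2 <- ll_fun(st2, theta)
          ljac <- (n - 1L + n_mig + 1L) * log(cc)
          if (log(stats::runif(1L)) < (lp2 - lp) + (ll2 - ll) + ljac) {
            state <- st2; Tcur <- T2; lp <- lp2; ll <- ll2
            acc["scale"] <- acc["scale"] + 1
          }
        }
      }
    } else {
      tries["thread"] <- tries["thread"] + 1
      cand <- seq_len(2L * n - 1L)[-state$root]
      v <- cand[sample.int(length(cand), 1L)]
      det <- detach_node(state, v)
      att <- thread_fun(det$state, v, Mcur, Tcur, 1e6)
      if (!is.null(att)) {
        st2 <- attach_node(det$state, v, det$spare, att)
        ll2 <- ll_fun(st2, theta)
        if (log(stats::runif(1L)) < ll2 - ll) {
          lp2 <- lp_fun(st2, Mcur, Tcur)
          state <- st2; lp <- lp2; ll <- ll2
          acc["thread"] <- acc["thread"] + 1
        }
      }
    }
    if (step > config$burn_in &&
        (step - config$burn_in) %% config$thinning == 0L &&
        kept < n_keep) {
      kept <- kept + 1L
      samples[kept, ] <- c(theta, Mcur, Tcur, state$time[state$root],
                           sum(lengths(state$mig)))
    }
  }
  list(samples = samples[seq_len(kept), , drop = FALSE],
       acc = acc / pmax(tries, 1))
}

reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

# All migration events on the edges adjacent to v still inside their
# spans after v's time changed.
edge_events_ok <- function(state, v) {
  chk <- function(w) {
    mg <- state$mig[[w]]
    pw <- state$parent[w]
    !length(mg) ||
      (all(mg > state$time[w]) &&
         (pw == 0L || all(mg < state$time[pw])))
  }
  all(vapply(c(v, state$child[v, ]), chk, logical(1L)))
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf(
    "Isolation-with-migration posterior (n = %d + %d, L = %d, kappa = %.2f):\n",
    x$n1, x$n2, x$L, x$kappa))
  cat(sprintf("  theta = %.3f  M = %.3f  T = %.3f  TMRCA = %.3f (modes)\n",
              x$theta_mode, x$M_mode, x$T_mode, x$TMRCA_mode))
  cat(sprintf("  chain mode spread: theta %.3f, M %.3f, T %.3f (%d chains)\n",
              x$mode_spread["theta"], x$mode_spread["M"],
              x$mode_spread["T"], nrow(x$chain_modes)))
  if (any(x$boundary_flags)) {
    cat("  WARNING: posterior mode at prior boundary for:",
        paste(names(x$boundary_flags)[x$boundary_flags], collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Convert scaled IM estimates to demographic units
#'
#' Implements the conversion used with MDIV output: with theta = 2 Ne u
#' (locus-wide) and mu the per-site per-generation mutation rate
#' (\code{rate_per_site_per_year * g}), the female effective size is
#' \eqn{N_e = \theta / (2 L \mu)} and the population divergence time is
#' \eqn{T_{pop} = T \theta / (2L) \times 1/\mathrm{rate}} years
#' (equivalently \eqn{T N_e} generations times g). The same transform is
#' applied to TMRCA. Every factor is echoed for auditability.
#'
#' @param theta_mode,T_mode,TMRCA_mode Posterior modes from
#'   \code{\link{im_mcmc}}.
#' @param L Locus length (sites).
#' @param rate_per_site_per_year Substitution rate per site per year.
#' @param g Generation time in years.
#' @param pairwise_rate Interpret the rate as a pairwise divergence rate
#'   (halves the per-lineage rate).
#' @return List with Ne_female, T_pop_years, T_pop_Myr, TMRCA_years,
#'   TMRCA_Myr and the factors used.
#' @export
convert_divergence <- function(theta_mode, T_mode, TMRCA_mode = NA_real_,
                               L = 596, rate_per_site_per_year = 1.1e-8,
                               g = 1.5, pairwise_rate = FALSE) {
  stopifnot(theta_mode > 0, T_mode >= 0, L > 0,
            rate_per_site_per_year > 0, g > 0)
  rate <- if (pairwise_rate) rate_per_site_per_year / 2
          else rate_per_site_per_year
  mu_gen <- rate * g # per site per generation
  ne <- theta_mode / (2 * L * mu_gen)
  tpop_years <- T_mode * theta_mode / (2 * L) / rate
  tmrca_years <- if (is.na(TMRCA_mode)) NA_real_
                 else TMRCA_mode * theta_mode / (2 * L) / rate
  list(Ne_female = ne, T_pop_years = tpop_years,
       T_pop_Myr = tpop_years / 1e6, TMRCA_years = tmrca_years,
       TMRCA_Myr = tmrca_years / 1e6,
       factors = list(L = L, rate_per_site_per_year = rate,
                      g = g, mu_per_site_per_generation = mu_gen,
                      rate_interpretation = if (pairwise_rate) "pairwise"
                                            else "per-lineage"))
}
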