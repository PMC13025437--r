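# Coalescent simulator: genealogies under constant size, stepwise
# (sudden) expansion and two-population isolation-with-migration, plus HKY
# sequence evolution. This is the synthetic stand-in for real mtDNA data
# and the engine behind simulation p-values and parametric bootstraps.
#
# Time units:
#   * constant / stepwise_expansion: mutational units x = 2ut (u = whole-
#     locus mutation rate per generation). A pair of lineages coalesces at
#     rate 1/theta per unit x, and a branch of length x carries on average
#     x/2 mutations over the locus, i.e. x/(2L) substitutions per site.
#     This makes tau and theta directly comparable with the mismatch
#     estimators.
#   * split_with_migration: coalescent units of Ne generations (pair
#     coalescence rate 1 within a population, migration rate M/2 per
#     lineage, split at time T). Mutation scale is theta/(2L) substitutions
#     per site per unit, matching the isolation-with-migration estimator.

AT_RICH_FREQS <- c(A = 0.33, C = 0.16, G = 0.14, T = 0.37)

#' Demography model constructors
#'
#' Build a demography description consumed by
#' \code{\link{simulate_genealogy}} and \code{\link{simulate_dataset}}.
#'
#' @param theta Scaled population-mutation parameter (2 Ne u per locus for
#'   mtDNA).
#' @param n,n1,n2 Sample sizes.
#' @param L Number of sites (default 596, a typical COI fragment).
#' @param kappa HKY transition/transversion ratio (default 4, an
#'   insect-mtDNA-like value; configurable).
#' @param base_freqs Stationary base frequencies (default AT-rich).
#' @return A list of class \code{demography}.
#' @name demography
NULL

#' @rdname demography
#' @export
demography_constant <- function(theta, n, L = 596, kappa = 4,
                                base_freqs = AT_RICH_FREQS) {
  stopifnot(theta >= 0, n >= 2, L >= 1)
  structure(list(kind = "constant", theta = theta, n = as.integer(n),
                 L = as.integer(L), kappa = kappa,
                 base_freqs = base_freqs / sum(base_freqs)),
            class = "demography")
}

#' @rdname demography
#' @param tau Expansion age in mutational units (2ut).
#' @param theta0,theta1 Pre- and post-expansion values of theta
#'   (\code{theta1 >= theta0}; looking forward in time the population grew
#'   from N0 to N1 at tau/2u generations ago).
#' @export
demography_expansion <- function(tau, theta0, theta1, n, L = 596,
                                 kappa = 4, base_freqs = AT_RICH_FREQS) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 >= theta0, n >= 2, L >= 1)
  structure(list(kind = "stepwise_expansion", tau = tau, theta0 = theta0,
                 theta1 = theta1, n = as.integer(n), L = as.integer(L),
                 kappa = kappa, base_freqs = base_freqs / sum(base_freqs)),
            class = "demography")
}

#' @rdname demography
#' @param M Scaled migration rate between the two descendant populations
#'   (per-lineage backward migration rate M/2 per coalescent unit).
#' @param T_split Divergence time in coalescent units (Ne generations).
#' @export
demography_split <- function(theta, M, T_split, n1, n2, L = 596,
                             kappa = 4, base_freqs = AT_RICH_FREQS) {
  stopifnot(theta > 0, M >= 0, T_split >= 0, n1 >= 1, n2 >= 1, L >= 1)
  structure(list(kind = "split_with_migration", theta = theta, M = M,
                 T_split = T_split, n1 = as.integer(n1),
                 n2 = as.integer(n2), L = as.integer(L), kappa = kappa,
                 base_freqs = base_freqs / sum(base_freqs)),
            class = "demography")
}

#' Simulate a coalescent genealogy
#'
#' @param model A \code{demography} object.
#' @param seed Optional integer seed (uses and advances R's RNG when
#'   \code{NULL}).
#' @return An \code{ape::phylo} tree (tips \code{seq1..seqn}) with
#'   attributes: \code{mut_scale} (expected substitutions per site per
#'   branch-length unit), \code{node_times} (time of every node, tips at
#'   0), \code{n_migrations} and \code{tip_pop} (split model only).
#' @export
simulate_genealogy <- function(model, seed = NULL) {
  stopifnot(inherits(model, "demography"))
  if (!is.null(seed)) set.seed(seed)
  g <- switch(model$kind,
    constant = coal_times_piecewise(model$n,
      breaks = numeric(0), thetas = model$theta),
    stepwise_expansion = coal_times_piecewise(model$n,
      breaks = model$tau, thetas = c(model$theta1, model$theta0)),
    split_with_migration = coal_split(model),
    stop("unknown demography kind"))
  mut_scale <- if (model$kind == "split_with_migration") {
    model$theta / (2 * model$L)
  } else {
    1 / (2 * model$L)
  }
  tr <- genealogy_to_phylo(g$parent, g$time, n_tip = g$n_tip)
  attr(tr, "mut_scale") <- mut_scale
  attr(tr, "n_migrations") <- g$n_migrations %||% 0L
  attr(tr, "tip_pop") <- g$tip_pop %||% NULL
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single-population coalescent with piecewise-constant theta(x):
# theta = thetas[i] on [breaks[i-1], breaks[i]); pair rate 1/theta.
# theta = 0 in an epoch means instantaneous coalescence at its start.
coal_times_piecewise <- function(n, breaks, thetas) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0
  epoch <- 1L
  bounds <- c(breaks, Inf)
  while (length(active) > 1L) {
    k <- length(active)
    th <- thetas[epoch]
    if (th <= 0) {
      # instantaneous coalescence of everything at current epoch start
      while (length(active) > 1L) {
        pick <- sample(length(active), 2L)
        parent[active[pick]] <- nxt
        time[nxt] <- t
        active <- c(active[-pick], nxt)
        nxt <- nxt + 1L
      }
      break
    }
    rate <- k * (k - 1) / 2 / th
    wait <- stats::rexp(1L, rate)
    if (t + wait >= bounds[epoch]) {
      t <- bounds[epoch]
      epoch <- epoch + 1L
      next
    }
    t <- t + wait
    pick <- sample(k, 2L)
    parent[active[pick]] <- nxt
    time[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, time = time, n_tip = n)
}

# Two-population isolation-with-migration coalescent (coalescent units).
coal_split <- function(model) {
  n <- model$n1 + model$n2
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  active <- seq_len(n)
  pop <- c(rep(1L, model$n1), rep(2L, model$n2))
  tip_pop <- pop
  nxt <- n + 1L
  t <- 0
  n_mig <- 0L
  Tsplit <- model$T_split
  M <- model$M
  while (length(active) > 1L) {
    k1 <- sum(pop == 1L); k2 <- sum(pop == 2L)
    if (t < Tsplit) {
      rc <- k1 * (k1 - 1) / 2 + k2 * (k2 - 1) / 2
      rm <- M / 2 * (k1 + k2)
      total <- rc + rm
      if (total <= 0) { t <- Tsplit; next }
      wait <- stats::rexp(1L, total)
      if (t + wait >= Tsplit) { t <- Tsplit; next }
      t <- t + wait
      if (stats::runif(1L) < rm / total) {
        i <- sample(length(active), 1L)
        pop[i] <- 3L - pop[i]
        n_mig <- n_mig + 1L
      } else {
        p <- if (stats::runif(1L) < k1 * (k1 - 1) / 2 / rc) 1L else 2L
        idx <- which(pop == p)
        pick <- idx[sample(length(idx), 2L)]
        parent[active[pick]] <- nxt
        time[nxt] <- t
        active <- c(active[-pick], nxt)
        pop <- c(pop[-pick], p)
        nxt <- nxt + 1L
      }
    } else {
      k <- length(active)
      wait <- stats::rexp(1L, k * (k - 1) / 2)
      t <- t + wait
      pick <- sample(k, 2L)
      parent[active[pick]] <- nxt
      time[nxt] <- t
      active <- c(active[-pick], nxt)
      pop <- c(pop[-pick], 1L)
      nxt <- nxt + 1L
    }
  }
  list(parent = parent, time = time, n_tip = n, n_migrations = n_mig,
       tip_pop = tip_pop)
}

# Convert parent/time vectors (tips 1..n at time 0, internals n+1..2n-1 in
# coalescence order, root = 2n-1) into a valid ape phylo with the root
# renumbered to n+1 (internal ids in decreasing age).
genealogy_to_phylo <- function(parent, time, n_tip) {
  n_nodes <- length(parent)
  # preorder from the true root (created last) so the root gets id n+1
  # regardless of tied node times (e.g. star genealogies)
  kids <- vector("list", n_nodes)
  for (i in which(parent > 0L)) {
    kids[[parent[i]]] <- c(kids[[parent[i]]], i)
  }
  ord <- integer(0)
  stack <- n_nodes # root
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    if (v > n_tip) {
      ord <- c(ord, v)
      stack <- c(kids[[v]], stack)
    }
  }
  new_id <- integer(n_nodes)
  new_id[seq_len(n_tip)] <- seq_len(n_tip)
  new_id[ord] <- n_tip + seq_along(ord)
  child <- which(parent > 0L)
  edge <- cbind(new_id[parent[child]], new_id[child])
  elen <- time[parent[child]] - time[child]
  nt <- numeric(n_nodes)
  nt[new_id] <- time
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = paste0("seq", seq_len(n_tip)),
                       Nnode = n_tip - 1L),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "node_times") <- nt
  tr
}

#' Evolve sequences along a genealogy under HKY
#'
#' Draws the root sequence from the stationary base frequencies and
#' mutates it along every branch with HKY transition probabilities
#' (finite sites: multiple hits are allowed).
#'
#' @param genealogy \code{phylo} from \code{\link{simulate_genealogy}} (or
#'   any phylo; then \code{mut_scale} defaults to 1, i.e. branch lengths in
#'   substitutions per site).
#' @param L Sequence length.
#' @param kappa HKY transition/transversion ratio.
#' @param base_freqs Stationary frequencies (A,C,G,T).
#' @param seed Optional integer seed.
#' @return \code{DNAbin} matrix of tip sequences.
#' @export
evolve_sequences <- function(genealogy, L = 596, kappa = 4,
                             base_freqs = AT_RICH_FREQS, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(L >= 1)
  mut_scale <- attr(genealogy, "mut_scale") %||% 1
  eig <- hky_eigen(kappa, base_freqs)
  n_tip <- length(genealogy$tip.label)
  n_node <- n_tip + genealogy$Nnode
  pre <- ape::reorder.phylo(genealogy, "cladewise", index.only = TRUE)
  edge <- genealogy$edge[pre, , drop = FALSE]
  elen <- genealogy$edge.length[pre] * mut_scale
  seqs <- matrix(0L, n_node, L)
  p <- base_freqs / sum(base_freqs)
  seqs[n_tip + 1L, ] <- sample.int(4L, L, replace = TRUE, prob = p)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    Pm <- hky_transition_prob(elen[e], eig = eig)
    out <- integer(L)
    parent_states <- seqs[par, ]
    for (s in 1:4) {
      idx <- which(parent_states == s)
      if (length(idx)) {
        out[idx] <- sample.int(4L, length(idx), replace = TRUE,
                               prob = Pm[s, ])
      }
    }
    seqs[ch, ] <- out
  }
  tipseq <- matrix(c("a", "c", "g", "t")[seqs[seq_len(n_tip), ,
                                              drop = FALSE]],
                   n_tip, L)
  rownames(tipseq) <- genealogy$tip.label
  ape::as.DNAbin(tipseq)
}

#' Simulate a full dataset (alignment + population map)
#'
#' Convenience wrapper composing \code{\link{simulate_genealogy}} and
#' \code{\link{evolve_sequences}}; optionally writes FASTA, map TSV and a
#' provenance sidecar so every simulated dataset is reproducible.
#'
#' @param model A \code{demography} object.
#' @param seed Optional integer seed.
#' @param write_to Optional directory; when given, writes
#'   \code{alignment.fasta}, \code{popmap.tsv} and \code{provenance.txt}.
#' @param infinite_sites When \code{TRUE}, mutations are placed under the
#'   infinite-sites model (each mutation at a fresh site drawn without
#'   replacement from L sites, derived state flipped) instead of HKY;
#'   useful as an oracle where multiple hits would blur expectations.
#' @return List with \code{alignment} (\code{DNAbin}), \code{map}
#'   (data.frame), \code{genealogy}, \code{model}.
#' @export
simulate_dataset <- function(model, seed = NULL, write_to = NULL,
                             infinite_sites = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  g <- simulate_genealogy(model)
  aln <- if (infinite_sites) {
    infinite_sites_alignment(g, model)
  } else {
    evolve_sequences(g, L = model$L, kappa = model$kappa,
                     base_freqs = model$base_freqs)
  }
  ids <- rownames(as.matrix(aln))
  pops <- attr(g, "tip_pop")
  map <- data.frame(
    id = ids,
    locality = if (is.null(pops)) "simulated" else paste0("pop", pops),
    haplogroup = if (is.null(pops)) "SIM" else paste0("POP", pops),
    stringsAsFactors = FALSE)
  if (!is.null(write_to)) {
    dir.create(write_to, showWarnings = FALSE, recursive = TRUE)
    write_alignment(aln, file.path(write_to, "alignment.fasta"))
    write_population_map(map, file.path(write_to, "popmap.tsv"))
    prov <- c(kind = model$kind,
              params = paste(names(unlist(model[!vapply(model, is.character,
                                                        logical(1))])),
                             unlist(model[!vapply(model, is.character,
                                                  logical(1))]),
                             sep = "=", collapse = " "),
              seed = if (is.null(seed)) "NA" else as.character(seed))
    writeLines(sprintf("%s: %s", names(prov), prov),
               file.path(write_to, "provenance.txt"))
  }
  list(alignment = aln, map = map, genealogy = g, model = model)
}

# Infinite-sites mutation onto nucleotide sequences: Poisson(len/2 * ...)
# mutations per branch at distinct sites (root state from base_freqs, the
# derived state drawn among the other three).
infinite_sites_alignment <- function(genealogy, model) {
  L <- model$L
  mut_scale <- attr(genealogy, "mut_scale") # subs/site/unit
  n_tip <- length(genealogy$tip.label)
  pre <- ape::reorder.phylo(genealogy, "cladewise", index.only = TRUE)
  edge <- genealogy$edge[pre, , drop = FALSE]
  elen <- genealogy$edge.length[pre] * mut_scale * L # locus-wide mean
  n_node <- n_tip + genealogy$Nnode
  seqs <- matrix(0L, n_node, L)
  p <- model$base_freqs
  seqs[n_tip + 1L, ] <- sample.int(4L, L, replace = TRUE, prob = p)
  free_sites <- sample.int(L) # mutation order over fresh sites
  used <- 0L
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    m <- stats::rpois(1L, elen[e])
    s <- seqs[par, ]
    if (m > 0L) {
      take <- min(m, L - used)
      if (take > 0L) {
        sites <- free_sites[used + seq_len(take)]
        used <- used + take
        for (site in sites) {
          s[site] <- sample(setdiff(1:4, s[site]), 1L)
        }
      }
    }
    seqs[ch, ] <- s
  }
  tipseq <- matrix(c("a", "c", "g", "t")[seqs[seq_len(n_tip), ,
                                              drop = FALSE]],
                   n_tip, L)
  rownames(tipseq) <- genealogy$tip.label
  ape::as.DNAbin(tipseq)
}
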