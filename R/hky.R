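# HKY85 substitution model: rate matrix, transition probabilities,
# Felsenstein pruning likelihood and a moment estimator for kappa.
# State order throughout: A, C, G, T. Transitions: A<->G, C<->T.

#' HKY rate matrix
#'
#' Instantaneous rate matrix for the HKY85 model, scaled so that the mean
#' substitution rate at stationarity is one (branch lengths are then
#' expected substitutions per site).
#'
#' @param kappa Transition/transversion rate ratio (kappa = 1 collapses to
#'   F81; with equal base frequencies as well, to Jukes-Cantor).
#' @param base_freqs Stationary base frequencies, length 4 (A,C,G,T);
#'   normalized internally.
#' @return 4x4 rate matrix with rows summing to zero.
#' @export
hky_rate_matrix <- function(kappa, base_freqs) {
  stopifnot(is.finite(kappa), kappa > 0, length(base_freqs) == 4L,
            all(base_freqs > 0))
  p <- base_freqs / sum(base_freqs)
  is_transition <- matrix(FALSE, 4, 4)
  is_transition[1, 3] <- is_transition[3, 1] <- TRUE # A<->G
  is_transition[2, 4] <- is_transition[4, 2] <- TRUE # C<->T
  Q <- matrix(rep(p, each = 4), 4, 4)
  Q[is_transition] <- Q[is_transition] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(p * diag(Q))
  Q <- Q / rate
  dimnames(Q) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  Q
}

# Eigen-decomposition of the HKY generator via the symmetrizing similarity
# transform (Q reversible), so transition probabilities are cheap per branch.
hky_eigen <- function(kappa, base_freqs) {
  p <- base_freqs / sum(base_freqs)
  Q <- hky_rate_matrix(kappa, p)
  sp <- sqrt(p)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  U <- diag(1 / sp) %*% e$vectors
  Uinv <- t(e$vectors) %*% diag(sp)
  list(U = U, Uinv = Uinv, lambda = e$values, freqs = p)
}

#' HKY transition-probability matrix
#'
#' @param t Branch length in expected substitutions per site.
#' @param kappa Transition/transversion rate ratio.
#' @param base_freqs Stationary base frequencies (A,C,G,T).
#' @param eig Optional precomputed \code{hky_eigen} object (kappa and
#'   base_freqs are then ignored).
#' @return 4x4 matrix of P(child state | parent state, t).
#' @export
hky_transition_prob <- function(t, kappa = NULL, base_freqs = NULL,
                                eig = NULL) {
  if (is.null(eig)) eig <- hky_eigen(kappa, base_freqs)
  P <- eig$U %*% (exp(eig$lambda * t) * eig$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Method-of-moments estimate of kappa
#'
#' Estimates the HKY transition/transversion rate ratio from the pooled
#' pairwise transition and transversion counts: under HKY the expected
#' instantaneous ts/tv ratio is
#' \eqn{\kappa (\pi_A \pi_G + \pi_C \pi_T) / (\pi_R \pi_Y)}, which is
#' inverted at the observed ratio. Multiple hits are ignored, so the
#' estimate is slightly downward biased at high divergence.
#'
#' @param aln Alignment.
#' @param max_kappa Cap returned when no transversions are observed.
#' @return List with \code{kappa}, \code{base_freqs}, \code{ts}, \code{tv}.
#' @export
kappa_moments <- function(aln, max_kappa = 100) {
  coded <- aln_coded(aln, "complete")
  n <- nrow(coded)
  p <- base_freqs_empirical(aln)
  ts <- 0; tv <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- coded[i, ]; b <- coded[j, ]
      diff <- a != b
      if (!any(diff)) next
      pur <- (a %in% c(1L, 3L)) & (b %in% c(1L, 3L))
      pyr <- (a %in% c(2L, 4L)) & (b %in% c(2L, 4L))
      ts <- ts + sum(diff & (pur | pyr))
      tv <- tv + sum(diff & !(pur | pyr))
    }
  }
  piR <- p[1] + p[3]; piY <- p[2] + p[4]
  denom <- p[1] * p[3] + p[2] * p[4]
  kappa <- if (tv == 0 || ts == 0) {
    if (ts > 0) max_kappa else 1
  } else {
    min(max_kappa, max(1e-3, (ts / tv) * piR * piY / denom))
  }
  list(kappa = as.numeric(kappa), base_freqs = p, ts = ts, tv = tv)
}

#' Empirical base frequencies of an alignment
#' @param aln Alignment.
#' @param floor Minimum frequency assigned to any base to keep transition
#'   matrices non-degenerate.
#' @return Numeric vector of length 4 (A,C,G,T) summing to one.
#' @export
base_freqs_empirical <- function(aln, floor = 1e-4) {
  coded <- aln_coded(aln, "complete")
  cnt <- tabulate(coded[coded >= 1L & coded <= 4L], nbins = 4L)
  p <- pmax(cnt / sum(cnt), floor)
  stats::setNames(p / sum(p), c("A", "C", "G", "T"))
}

#' HKY log-likelihood of an alignment on a genealogy
#'
#' Felsenstein pruning over compressed site patterns with HKY transition
#' probabilities. Branch lengths are taken as \code{edge.length *
#' mu_scale}, i.e. \code{mu_scale} converts the tree's time unit into
#' expected substitutions per site.
#'
#' @param tree \code{ape::phylo} genealogy whose tip labels match the
#'   alignment row names.
#' @param aln Alignment containing all tips.
#' @param kappa Transition/transversion rate ratio; \code{NULL} uses the
#'   moment estimate from the alignment.
#' @param mu_scale Multiplier from branch-length units to substitutions per
#'   site (default 1: lengths already in substitutions/site).
#' @param base_freqs Stationary frequencies; default empirical.
#' @return Log-likelihood (numeric scalar); \code{-Inf} when conflicting
#'   site patterns meet a zero-length path.
#' @export
hky_likelihood <- function(tree, aln, kappa = NULL, mu_scale = 1,
                           base_freqs = NULL) {
  coded <- aln_coded(aln, "complete")
  if (is.null(base_freqs)) base_freqs <- base_freqs_empirical(aln)
  if (is.null(kappa)) kappa <- kappa_moments(aln)$kappa
  if (!setequal(tree$tip.label, rownames(coded))) {
    stop("input error: tree tips and alignment ids differ")
  }
  if (any(tree$edge.length < 0)) stop("input error: negative branch length")
  eig <- hky_eigen(kappa, base_freqs)
  pat <- site_patterns(coded[tree$tip.label, , drop = FALSE])
  ll <- pruning_loglik(tree, pat$patterns, pat$weights, eig,
                       mu_scale = mu_scale)
  ll
}

# Compress alignment columns into unique patterns with multiplicities.
site_patterns <- function(coded) {
  key <- apply(coded, 2L, paste, collapse = ".")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(patterns = coded[, first, drop = FALSE], weights = w)
}

# Core pruning. patterns: n_tips x P integer matrix (1..4); returns total
# log-likelihood including pattern weights. Postorder traversal with
# per-node rescaling so deep trees do not underflow.
pruning_loglik <- function(tree, patterns, weights, eig, mu_scale = 1) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  P <- ncol(patterns)
  ord <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  edge <- tree$edge[ord, , drop = FALSE]
  elen <- tree$edge.length[ord] * mu_scale
  partial <- vector("list", n_node)
  logscale <- numeric(P)
  for (i in seq_len(n_tip)) {
    m <- matrix(0, 4, P)
    m[cbind(patterns[i, ], seq_len(P))] <- 1
    partial[[i]] <- m
  }
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    Pm <- hky_transition_prob(elen[e], eig = eig)
    contrib <- Pm %*% partial[[ch]]
    if (is.null(partial[[par]])) {
      partial[[par]] <- contrib
    } else {
      partial[[par]] <- partial[[par]] * contrib
      mx <- apply(partial[[par]], 2L, max)
      if (all(mx > 0)) {
        partial[[par]] <- sweep(partial[[par]], 2L, mx, "/")
        logscale <- logscale + log(mx)
      }
    }
  }
  root <- n_tip + 1L
  lik <- colSums(eig$freqs * partial[[root]])
  if (any(lik <= 0)) return(-Inf)
  sum(weights * (log(lik) + logscale))
}
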