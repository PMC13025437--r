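# Independent brute-force oracles for the neutrality statistics, coded
# directly from the published definitions and kept separate from the
# package implementation.

oracle_tajima <- function(aln) {
  m <- toupper(as.character(as.matrix(aln)))
  n <- nrow(m)
  S <- sum(apply(m, 2, function(cl) length(unique(cl)) > 1))
  k <- mean(combn(n, 2, function(ij) sum(m[ij[1], ] != m[ij[2], ])))
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracle_singletons <- function(aln) {
  m <- toupper(as.character(as.matrix(aln)))
  n <- nrow(m)
  eta <- 0; eta_s <- 0
  U <- integer(n)
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    eta <- eta + length(tab) - 1L
    for (st in names(tab)[tab == 1]) {
      eta_s <- eta_s + 1L
      U[which(m[, j] == st)] <- U[which(m[, j] == st)] + 1L
    }
  }
  list(n = n, eta = eta, eta_s = eta_s, U = U)
}

oracle_fuli_dstar <- function(aln) {
  o <- oracle_singletons(aln)
  n <- o$n; eta <- o$eta; eta_s <- o$eta_s
  an <- sum(1 / (1:(n - 1))); bn <- sum(1 / (1:(n - 1))^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vDs <- ((n / (n - 1))^2 * bn + an^2 * dn -
            2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uDs <- n / (n - 1) * (an - n / (n - 1)) - vDs
  (n / (n - 1) * eta - an * eta_s) / sqrt(uDs * eta + vDs * eta^2)
}

oracle_r2 <- function(aln) {
  o <- oracle_singletons(aln)
  m <- toupper(as.character(as.matrix(aln)))
  k <- mean(combn(o$n, 2, function(ij) sum(m[ij[1], ] != m[ij[2], ])))
  S <- sum(apply(m, 2, function(cl) length(unique(cl)) > 1))
  sqrt(mean((o$U - k / 2)^2)) / S
}

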