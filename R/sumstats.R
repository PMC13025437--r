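# Diversity summaries: segregating sites, haplotype diversity, nucleotide
# diversity and the pairwise-difference spectrum reused by the neutrality
# and mismatch modules. All statistics operate on the sites retained by the
# chosen site policy (complete deletion by default).

# Integer-coded alignment restricted to retained columns. Under the
# complete-deletion policy states are 1..4 (A,C,G,T); under the strict
# policy all columns are kept and every distinct symbol (including gaps)
# is its own state. Attribute n_retained carries the column count.
aln_coded <- function(aln, site_policy = c("complete", "strict")) {
  site_policy <- match.arg(site_policy)
  m <- aln_chars(aln)
  keep <- retained_columns(m, site_policy)
  if (length(keep) == 0L) {
    stop("degenerate-input error: no columns retained under complete-deletion")
  }
  mm <- m[, keep, drop = FALSE]
  states <- union(c("A", "C", "G", "T"), sort(unique(as.vector(mm))))
  coded <- matrix(match(mm, states), nrow(mm), ncol(mm))
  rownames(coded) <- rownames(m)
  structure(coded, n_retained = length(keep), n_states = length(states))
}

#' Number of segregating sites
#'
#' Counts alignment columns with at least two distinct nucleotide states
#' among the sites retained under the site policy.
#'
#' @param aln Alignment (\code{DNAbin} matrix or character).
#' @param site_policy Site filtering, see \code{\link{collapse_haplotypes}}.
#' @return Integer count S.
#' @export
segregating_sites <- function(aln, site_policy = "complete") {
  coded <- aln_coded(aln, site_policy)
  if (nrow(coded) < 2L) stop("sample-size error: need n >= 2")
  sum(matrixStats_col_distinct(coded) > 1L)
}

# distinct states per column, no external dependency
matrixStats_col_distinct <- function(coded) {
  apply(coded, 2L, function(col) length(unique(col)))
}

# Minimum number of mutations (eta): sum over columns of (#alleles - 1).
eta_mutations <- function(aln, site_policy = "complete") {
  coded <- aln_coded(aln, site_policy)
  sum(matrixStats_col_distinct(coded) - 1L)
}

#' Pairwise-difference spectrum (mismatch distribution)
#'
#' Exact histogram of Hamming differences over all unordered sequence
#' pairs, computed on retained sites.
#'
#' @inheritParams segregating_sites
#' @return Integer vector of class counts; element \code{i+1} is the number
#'   of pairs differing at exactly \code{i} sites (names "0", "1", ...).
#' @export
pairwise_spectrum <- function(aln, site_policy = "complete") {
  d <- pairwise_diff_matrix(aln_coded(aln, site_policy))
  spectrum_from_diffs(d[upper.tri(d)])
}

# n x n matrix of pairwise Hamming differences from a coded alignment.
pairwise_diff_matrix <- function(coded) {
  n <- nrow(coded)
  if (n < 2L) stop("sample-size error: need n >= 2")
  L <- ncol(coded)
  n_states <- attr(coded, "n_states")
  if (is.null(n_states)) n_states <- max(coded)
  match_count <- matrix(0, n, n)
  for (s in seq_len(n_states)) {
    ind <- matrix(as.numeric(coded == s), n, L)
    match_count <- match_count + tcrossprod(ind)
  }
  L - match_count
}

spectrum_from_diffs <- function(diffs) {
  mx <- max(diffs)
  counts <- tabulate(diffs + 1L, nbins = mx + 1L)
  stats::setNames(as.integer(counts), 0:mx)
}

#' Nucleotide diversity and mean pairwise differences
#'
#' @inheritParams segregating_sites
#' @return List with \code{k} (mean number of pairwise nucleotide
#'   differences per locus), \code{pi} (per-site diversity, k divided by
#'   the number of retained sites), \code{pi_sd} (Nei's sampling standard
#'   deviation of pi) and \code{n_retained_sites}.
#' @export
nucleotide_diversity <- function(aln, site_policy = "complete") {
  coded <- aln_coded(aln, site_policy)
  n <- nrow(coded)
  if (n < 2L) stop("sample-size error: need n >= 2")
  L <- attr(coded, "n_retained")
  d <- pairwise_diff_matrix(coded)
  k <- mean(d[upper.tri(d)])
  pi <- k / L
  # Nei (1987) eq. 10.7 sampling variance of pi (per site)
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(k = k, pi = pi, pi_sd = sqrt(v), n_retained_sites = L)
}

#' Haplotype (gene) diversity
#'
#' \eqn{Hd = n (1 - \sum p_i^2) / (n - 1)} with \eqn{p_i} the haplotype
#' relative frequencies, plus Nei's sampling standard error.
#'
#' @param counts Positive integer vector of haplotype counts.
#' @param n Sample size; defaults to \code{sum(counts)}.
#' @return List with \code{Hd} and \code{SE}.
#' @export
haplotype_diversity <- function(counts, n = sum(counts)) {
  counts <- as.numeric(counts)
  if (any(counts <= 0)) stop("input error: counts must be positive")
  if (abs(sum(counts) - n) > 1e-9) {
    stop("input error: counts must sum to n")
  }
  if (n < 2) stop("sample-size error: need n >= 2")
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  hd <- n * (1 - s2) / (n - 1)
  # Nei (1987) eq. 8.12
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(Hd = hd, SE = sqrt(max(v, 0)))
}

#' Per-haplogroup diversity summary
#'
#' Computes, for each haplogroup and for the pooled sample, the sample
#' size, segregating sites S, haplotype number Nhap, haplotype diversity
#' Hd (with SE), nucleotide diversity pi (with SD) and mean pairwise
#' differences k.
#'
#' @param aln Alignment.
#' @param map Optional population map (data.frame with \code{id},
#'   \code{haplogroup}); when \code{NULL} only the pooled row is returned.
#' @param site_policy Site filtering policy.
#' @return data.frame with one row per haplogroup plus \code{"ALL"}.
#' @export
diversity_summary <- function(aln, map = NULL, site_policy = "complete") {
  aln <- as_dnabin(aln)
  groups <- if (is.null(map)) character(0) else sort(unique(map$haplogroup))
  one <- function(sub, label) {
    if (nrow(as.matrix(sub)) < 2L) {
      return(data.frame(haplogroup = label, n = nrow(as.matrix(sub)),
                        S = NA_integer_, Nhap = NA_integer_,
                        Hd = NA_real_, Hd_SE = NA_real_, pi = NA_real_,
                        pi_SD = NA_real_, k = NA_real_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    hap <- collapse_haplotypes(sub, site_policy)
    nd <- nucleotide_diversity(sub, site_policy)
    hd <- haplotype_diversity(hap$counts)
    data.frame(haplogroup = label, n = nrow(as.matrix(sub)),
               S = segregating_sites(sub, site_policy),
               Nhap = length(hap$counts),
               Hd = hd$Hd, Hd_SE = hd$SE, pi = nd$pi, pi_SD = nd$pi_sd,
               k = nd$k, flagged = FALSE, stringsAsFactors = FALSE)
  }
  rows <- lapply(groups, function(g) one(subset_by_group(aln, g, map), g))
  rows <- c(rows, list(one(aln, "ALL")))
  do.call(rbind, rows)
}

#' Write a diversity summary as TSV
#'
#' Columns (Haplogroup, n, S, Nhap, Hd, pi, k) with Hd/pi to 3 decimals and
#' k to 1, mirroring the usual print precision of such tables; full
#' precision stays available from \code{\link{diversity_summary}}.
#'
#' @param summary data.frame from \code{\link{diversity_summary}}.
#' @param path Output path.
#' @param provenance Optional named character vector written as
#'   \code{# key: value} header lines.
#' @return \code{path}, invisibly.
#' @export
write_summary_table <- function(summary, path, provenance = NULL) {
  out <- data.frame(Haplogroup = summary$haplogroup, n = summary$n,
                    S = summary$S, Nhap = summary$Nhap,
                    Hd = sprintf("%.3f", summary$Hd),
                    pi = sprintf("%.3f ± %.3f", summary$pi,
                                 summary$pi_SD),
                    k = sprintf("%.1f", summary$k),
                    stringsAsFactors = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
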