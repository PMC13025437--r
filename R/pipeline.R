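# Pipeline orchestration: per-haplogroup diversity and demographic-
# expansion reports and pairwise divergence-time reports from an
# alignment + population map (or a haplotype-frequency table), with
# key=value configs, provenance headers and seeded reproducibility.

#' Build a run configuration
#'
#' @param alignment Path to a FASTA alignment (or \code{NULL} when only a
#'   haplotype table is analysed).
#' @param popmap Path to the population-map TSV.
#' @param haplotype_table Path to a haplotype-frequency table TSV.
#' @param site_policy Site filtering policy.
#' @param n_sims Null simulations per neutrality p-value.
#' @param n_boot Parametric-bootstrap replicates for the mismatch fit.
#' @param im Settings list from \code{\link{im_config}}.
#' @param rate_per_site_per_year,generation_time Calibration constants
#'   (defaults: 1.1e-8 per site per year; 1.5 years).
#' @param seed Master seed; stage sub-seeds are derived from it by a
#'   fixed counter scheme so stages are independently reproducible.
#' @param out_dir Output directory for report files.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(alignment = NULL, popmap = NULL,
                       haplotype_table = NULL,
                       site_policy = "complete", n_sims = 10000L,
                       n_boot = 10000L, im = im_config(),
                       rate_per_site_per_year = 1.1e-8,
                       generation_time = 1.5, seed = 1L,
                       out_dir = ".") {
  stopifnot(rate_per_site_per_year > 0, generation_time > 0)
  for (p in c(alignment, popmap, haplotype_table)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input error: path not found: ", p)
    }
  }
  structure(list(alignment = alignment, popmap = popmap,
                 haplotype_table = haplotype_table,
                 site_policy = site_policy, n_sims = as.integer(n_sims),
                 n_boot = as.integer(n_boot), im = im,
                 rate_per_site_per_year = rate_per_site_per_year,
                 generation_time = generation_time,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a key=value configuration file
#'
#' Plain-text lines \code{key = value}; unknown keys are rejected. Paths
#' are resolved relative to the file's directory.
#'
#' @param path Configuration file.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1L)) != 2L
  if (any(bad)) stop("input error: malformed config line: ",
                     lines[bad][1L])
  keys <- vapply(kv, `[`, character(1L), 1L)
  vals <- vapply(kv, `[`, character(1L), 2L)
  known <- c("alignment", "popmap", "haplotype_table", "site_policy",
             "n_sims", "n_boot", "rate_per_site_per_year",
             "generation_time", "seed", "out_dir", "M_max", "T_max",
             "chain_length", "burn_in", "thinning", "n_chains")
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("input error: unknown config keys: ",
                            paste(unknown, collapse = ", "))
  get <- function(k, default = NULL) {
    if (k %in% keys) vals[keys == k][1L] else default
  }
  num <- function(k, default) as.numeric(get(k, default))
  dirn <- dirname(path)
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(dirn, p)
  }
  run_config(
    alignment = resolve(get("alignment")),
    popmap = resolve(get("popmap")),
    haplotype_table = resolve(get("haplotype_table")),
    site_policy = get("site_policy", "complete"),
    n_sims = num("n_sims", 10000), n_boot = num("n_boot", 10000),
    im = im_config(M_max = num("M_max", 10), T_max = num("T_max", 5),
                   chain_length = num("chain_length", 5e6),
                   burn_in = num("burn_in", 1e6),
                   thinning = num("thinning", 500),
                   seed = as.integer(num("seed", 1)),
                   n_chains = as.integer(num("n_chains", 3))),
    rate_per_site_per_year = num("rate_per_site_per_year", 1.1e-8),
    generation_time = num("generation_time", 1.5),
    seed = as.integer(num("seed", 1)),
    out_dir = get("out_dir", dirn))
}

# Deterministic stage sub-seeds from the master seed (kept below 2^31).
stage_seed <- function(config, stage) {
  offsets <- c(summary = 11L, neutrality = 23L, mismatch = 37L,
               divergence = 53L, simulate = 71L)
  (config$seed * 1009L + offsets[[stage]]) %% 2147483629L
}

provenance_header <- function(config, stage) {
  cfg_string <- paste(vapply(
    Filter(Negate(is.null),
           config[c("alignment", "popmap", "haplotype_table",
                    "site_policy", "n_sims", "n_boot",
                    "rate_per_site_per_year", "generation_time",
                    "seed")]),
    as.character, character(1L)), collapse = "|")
  tf <- tempfile()
  writeLines(cfg_string, tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  c(stage = stage, config_md5 = h, seed = as.character(config$seed),
    package = paste0("phylodem ",
                     as.character(utils::packageVersion("phylodem"))))
}

load_inputs <- function(config) {
  aln <- if (!is.null(config$alignment)) read_alignment(config$alignment)
  map <- if (!is.null(config$popmap)) read_population_map(config$popmap)
  ht <- if (!is.null(config$haplotype_table)) {
    parse_haplotype_table(config$haplotype_table, on_mismatch = "declared")
  }
  if (is.null(aln) && is.null(ht)) {
    stop("input error: need an alignment or a haplotype table")
  }
  list(aln = aln, map = map, ht = ht)
}

#' Per-haplogroup diversity report
#'
#' One row per haplogroup plus ALL with n, S, Nhap, Hd, pi, k and Fu &
#' Li's D (D* without an outgroup). When only a haplotype-frequency table
#' is available, sequence-based columns are reported as NA rather than
#' imputed. Groups with n < 2 are flagged, not fatal.
#'
#' @param config A \code{\link{run_config}}.
#' @param write When TRUE, writes \code{summary.tsv} to the output
#'   directory.
#' @return The report data.frame, invisibly when written.
#' @export
run_summary <- function(config, write = TRUE) {
  inp <- load_inputs(config)
  if (!is.null(inp$aln)) {
    out <- diversity_summary(inp$aln, inp$map, config$site_policy)
    fl <- vapply(seq_len(nrow(out)), function(i) {
      if (out$flagged[i] || is.na(out$S[i]) || out$S[i] < 1L ||
          out$n[i] < 4L) return(NA_real_)
      sub <- if (out$haplogroup[i] == "ALL") inp$aln
             else subset_by_group(inp$aln, out$haplogroup[i], inp$map)
      fu_li_d(sub, site_policy = config$site_policy)$value
    }, numeric(1L))
    out$FuLiD <- fl
  } else {
    ht <- inp$ht
    groups <- sort(unique(ht$rows$haplogroup))
    rows <- lapply(c(groups, "ALL"), function(g) {
      cnt <- haplotype_counts(ht, if (g == "ALL") NULL else g)
      n <- sum(if (g == "ALL") ht$rows$n
               else ht$rows$n[ht$rows$haplogroup == g])
      hd <- if (n >= 2L) haplotype_diversity(cnt, sum(cnt))
            else list(Hd = NA_real_, SE = NA_real_)
      data.frame(haplogroup = g, n = n, S = NA_integer_,
                 Nhap = length(cnt), Hd = hd$Hd, Hd_SE = hd$SE,
                 pi = NA_real_, pi_SD = NA_real_, k = NA_real_,
                 flagged = n < 2L, FuLiD = NA_real_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(config$out_dir, "summary.tsv")
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(sprintf("# %s: %s", names(provenance_header(config,
                                                           "summary")),
                       provenance_header(config, "summary")), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    return(invisible(out))
  }
  out
}

#' Per-haplogroup neutrality and expansion report
#'
#' Tajima's D, Fu's Fs and R2 with simulation p-values and significance
#' stars, plus the sudden-expansion fit (SSD, raggedness, tau/theta0/
#' theta1 with 95 percent bootstrap CIs) and the derived expansion time.
#'
#' @inheritParams run_summary
#' @return Report data.frame (one row per haplogroup plus ALL).
#' @export
run_demography <- function(config, write = TRUE) {
  inp <- load_inputs(config)
  if (is.null(inp$aln)) {
    stop("input error: demographic analysis needs sequence data")
  }
  aln <- inp$aln
  groups <- if (is.null(inp$map)) character(0)
            else sort(unique(inp$map$haplogroup))
  sd0 <- stage_seed(config, "neutrality")
  rows <- lapply(seq_along(c(groups, "ALL")), function(i) {
    g <- c(groups, "ALL")[i]
    sub <- if (g == "ALL") aln else subset_by_group(aln, g, inp$map)
    n <- nrow(as.matrix(sub))
    if (n < 4L) {
      return(data.frame(haplogroup = g, n = n, TajimaD = NA, p_D = NA,
                        FuFs = NA, p_Fs = NA, R2 = NA, p_R2 = NA,
                        SSD = NA, p_SSD = NA, rg = NA, p_rg = NA,
                        tau = NA, tau_lo = NA, tau_hi = NA,
                        theta0 = NA, theta0_lo = NA, theta0_hi = NA,
                        theta1 = NA, theta1_lo = NA, theta1_hi = NA,
                        t_years = NA, flagged = TRUE))
    }
    seed_g <- (sd0 + i) %% 2147483629L
    td <- neutrality_pvalue("tajima_d", sub, n_sims = config$n_sims,
                            seed = seed_g,
                            site_policy = config$site_policy)
    fs <- neutrality_pvalue("fus_fs", sub, n_sims = config$n_sims,
                            seed = seed_g + 1L,
                            site_policy = config$site_policy)
    r2 <- neutrality_pvalue("r2", sub, n_sims = config$n_sims,
                            seed = seed_g + 2L,
                            site_policy = config$site_policy)
    sp <- pairwise_spectrum(sub, config$site_policy)
    fit <- fit_expansion(sp, n, n_boot = config$n_boot,
                         seed = seed_g + 3L)
    et <- expansion_time(fit$tau, L = ncol(as.matrix(sub)),
                         rate_per_site_per_year =
                           config$rate_per_site_per_year,
                         g = config$generation_time)
    data.frame(haplogroup = g, n = n,
               TajimaD = td$value, p_D = td$p_value,
               FuFs = fs$value, p_Fs = fs$p_value,
               R2 = r2$value, p_R2 = r2$p_value,
               SSD = fit$SSD, p_SSD = fit$p_SSD,
               rg = fit$rg, p_rg = fit$p_rg,
               tau = fit$tau, tau_lo = fit$CI95["tau", 1],
               tau_hi = fit$CI95["tau", 2],
               theta0 = fit$theta0, theta0_lo = fit$CI95["theta0", 1],
               theta0_hi = fit$CI95["theta0", 2],
               theta1 = fit$theta1, theta1_lo = fit$CI95["theta1", 1],
               theta1_hi = fit$CI95["theta1", 2],
               t_years = et$t_years, flagged = !fit$converged)
  })
  out <- do.call(rbind, rows)
  out$stars_D <- p_stars(out$p_D)
  out$stars_Fs <- p_stars(out$p_Fs)
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(config$out_dir, "demography.tsv")
    con <- file(path, "w", encoding = "UTF-8")
    hd <- provenance_header(config, "demography")
    writeLines(sprintf("# %s: %s", names(hd), hd), con)
    writeLines(paste("# one-tailed p (lower) for D, Fs, R2;",
                     "stars: * p<0.05 ** p<0.01 *** p<0.001"), con)
    utils::write.table(format(out, digits = 6), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    close(con)
    return(invisible(out))
  }
  out
}

#' Pairwise divergence-time report
#'
#' Runs the isolation-with-migration sampler for every unordered pair of
#' haplogroups with at least two sequences each (others are skipped with
#' a message) and converts the posterior modes into female effective
#' sizes and calendar divergence times.
#'
#' @inheritParams run_summary
#' @return Report data.frame, one row per pair.
#' @export
run_divergence <- function(config, write = TRUE) {
  inp <- load_inputs(config)
  if (is.null(inp$aln) || is.null(inp$map)) {
    stop("input error: divergence analysis needs alignment + map")
  }
  groups <- sort(unique(inp$map$haplogroup))
  if (length(groups) < 2L) stop("input error: need >= 2 haplogroups")
  L <- ncol(as.matrix(inp$aln))
  pairs <- utils::combn(groups, 2L)
  sd0 <- stage_seed(config, "divergence")
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    a1 <- subset_by_group(inp$aln, g1, inp$map)
    a2 <- subset_by_group(inp$aln, g2, inp$map)
    if (nrow(a1) < 2L || nrow(a2) < 2L) {
      message("skipping pair ", g1, "-", g2, ": fewer than 2 sequences")
      next
    }
    cfg <- config$im
    cfg$seed <- as.integer((sd0 + 10L * j) %% 2147483629L)
    est <- im_mcmc(a1, a2, cfg)
    conv <- convert_divergence(est$theta_mode, est$T_mode,
                               est$TMRCA_mode, L = L,
                               rate_per_site_per_year =
                                 config$rate_per_site_per_year,
                               g = config$generation_time)
    rows[[length(rows) + 1L]] <- data.frame(
      Haplogroup1 = g1, Haplogroup2 = g2,
      theta = est$theta_mode, Ne_female = conv$Ne_female,
      T = est$T_mode, T_MRCA = est$TMRCA_mode,
      T_pop_Myr = conv$T_pop_Myr, TMRCA_Myr = conv$TMRCA_Myr,
      boundary = paste(names(est$boundary_flags)[est$boundary_flags],
                       collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(config$out_dir, "divergence.tsv")
    con <- file(path, "w", encoding = "UTF-8")
    hd <- provenance_header(config, "divergence")
    writeLines(sprintf("# %s: %s", names(hd), hd), con)
    utils::write.table(format(out, digits = 6), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    close(con)
    return(invisible(out))
  }
  out
}

#' Run the full pipeline
#'
#' \code{\link{run_summary}}, \code{\link{run_demography}} and
#' \code{\link{run_divergence}} in sequence, writing all three reports.
#'
#' @param config A \code{\link{run_config}}.
#' @return List with the three reports.
#' @export
run_all <- function(config) {
  list(summary = run_summary(config),
       demography = run_demography(config),
       divergence = run_divergence(config))
}
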