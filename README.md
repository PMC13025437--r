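# phylodem

Single-locus phylogeography and demographic inference from mtDNA
alignments, for population geneticists working with geographically
structured samples (the motivating setting: mountain-system haplogroups
of a bark beetle sampled across its range, sequenced at a 596-bp COI
fragment).

Given an aligned FASTA plus a population map (sequence → locality →
haplogroup), or a per-locality haplotype-frequency table, the package
computes:

- **Diversity summaries** per haplogroup: segregating sites *S*,
  haplotype number *Nhap*, haplotype diversity
  *Hd* = *n*(1 − Σ*p*ᵢ²)/(*n* − 1) with Nei's SE, nucleotide diversity
  *π* (± SD) and mean pairwise differences *k*.
- **Neutrality tests**: Tajima's *D*, Fu & Li's *D*/*D**, Fu's *Fs*
  (Ewens sampling formula, log-space, stable for hundreds of
  sequences), Ramos-Onsins & Rozas's *R*₂ — each with one-tailed
  p-values from coalescent simulation under neutral equilibrium,
  conditional on the observed *S*.
- **Mismatch analysis**: least-squares fit of the stepwise
  (sudden-expansion) model — *θ*₀ = 2*μN*₀, *θ*₁ = 2*μN*₁,
  *τ* = 2*ut* — with SSD and Harpending's raggedness goodness-of-fit
  via parametric bootstrap, percentile CIs, and conversion of *τ* to
  calendar time from a substitution-rate/generation-time calibration.
- **Divergence dating**: a two-population isolation-with-migration
  MCMC in the MDIV style (uniform priors on *θ*, *M*, *T*; finite-sites
  HKY likelihood; genealogy-and-parameter Metropolis–Hastings with an
  exact-conditional lineage-threading move), returning posterior
  histograms and modes plus conversions to female effective size and
  population divergence time *T*pop = *Tθ*/(2*L*) × 1/rate.
- **A coalescent simulator** (constant size, stepwise expansion,
  split-with-migration) with HKY sequence evolution — the engine for
  all significance tests and a generator of fully synthetic datasets.

## Worked example

Simulate a sample of 60 sequences from a population that expanded
suddenly (τ = 4.56, θ₀ = 0, θ₁ = 16.98 — the fitted values of a
strongly expanded mountain haplogroup), then analyse it:

```r
library(phylodem)

model <- demography_expansion(tau = 4.56, theta0 = 0, theta1 = 16.98,
                              n = 60, L = 596)
dat <- simulate_dataset(model, seed = 7)

diversity_summary(dat$alignment)[, c("n", "S", "Nhap", "Hd", "pi", "k")]
#>    n  S Nhap    Hd      pi    k
#> 1 60 27   20 0.926 0.00654 3.89

neutrality_pvalue("fus_fs", dat$alignment, n_sims = 1000, seed = 11)
#> fus_fs = -6.06587  p = 0.042 (1000 sims, conditional on S)

fit <- fit_expansion(pairwise_spectrum(dat$alignment), n = 60,
                     n_boot = 500, seed = 13)
fit
#> Sudden-expansion fit (n = 60):
#>   tau = 4.708 (95% CI 2.16-7.24)
#>   theta0 = 0.000 (0.00-2.12), theta1 = 22.231 (10.85-127.04)
#>   SSD = 0.0047 (p = 0.376), rg = 0.0159 (p = 0.632), 500 bootstraps

expansion_time(fit$tau)
#> tau = 4.708 -> 239358 generations = 3.59e+05 years
#>   (u = 9.83e-06/locus/gen, per-lineage rate)
```

Reading: the sample carries the signature of expansion (high *Hd* with
low *π*; strongly negative *Fs*, p < 0.05), the mismatch fit recovers
an expansion age near the simulating τ with θ₀ pinned at zero, and the
calibration (1.1%/Myr per lineage, 1.5-year generations) dates the
expansion to roughly 360 kyr — consistent with the ~350 kyr implied by
the true τ = 4.56.

For real data, replace the simulation with
`read_alignment("coi.fasta")` and `read_population_map("map.tsv")`, and
run `run_summary()` / `run_demography()` / `run_divergence()` with a
`run_config()` to produce the three tab-separated reports (diversity,
neutrality-plus-expansion, pairwise divergence), each with a seeded
provenance header.

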