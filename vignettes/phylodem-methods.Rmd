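---
title: "Models and methods in phylodem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phylodem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

phylodem is a single-locus phylogeography toolkit for aligned mtDNA
sequences from geographically structured samples: it summarises
haplotype and nucleotide diversity per haplogroup, tests for departures
from neutral equilibrium with coalescent-simulation significance, fits
the sudden (stepwise) demographic-expansion model to mismatch
distributions, and dates pairwise population divergences with an
isolation-with-migration (IM) Markov chain Monte Carlo sampler under an
HKY substitution model. A coalescent simulator with HKY sequence
evolution provides null distributions, parametric bootstraps and
synthetic datasets throughout. This vignette explains the models, the
defaults and the numerical choices; it states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Data model and site handling

The unit of analysis is an equal-length nucleotide alignment
(`ape::DNAbin`) plus a population map assigning every sequence to a
locality and every locality to a haplogroup. Haplogroup membership is
consumed as input (typically from a phylogenetic analysis done
upstream); the package deliberately does not infer clades. A
haplotype-frequency table in the common per-locality layout
(`"H07(3)"` tokens, optional declared sample size) is the alternative
input for bookkeeping-only analyses; with counts alone,
sequence-dependent statistics are reported as `NA`, never imputed.

All statistics operate on the sites retained under a site policy.
The default, complete deletion, drops every column containing a gap or
ambiguity before any comparison — the convention of the standard
polymorphism software this package mirrors. A `strict` policy that
compares full strings (each symbol its own state) is available; note
it changes S on gapped alignments. Haplotype labels `H01, H02, ...`
are assigned in first-appearance order so collapsing is deterministic.

The shipped transcription of the study-layout frequency table carries
two rows whose haplotype tokens sum to one more than the declared
sample size; since the declared column is the one consistent with the
table's own totals, `parse_haplotype_table()` exposes `on_mismatch =
c("error", "declared", "tokens")`, defaulting to a hard error that
names the offending locality. A related note: different summaries of
that table disagree on the haplotype count (45 vs 47 in different
places of the source material); the table itself enumerates 47
labels, which is what the parser reports.

## Diversity summaries

For each haplogroup and the pooled sample the package reports the
number of segregating sites S, haplotype number, haplotype (gene)
diversity \(Hd = n(1-\sum p_i^2)/(n-1)\) with Nei's sampling standard
error, nucleotide diversity \(\pi\) (per site) with Nei's sampling SD
— printed as "± SD" to match the conventional table layout — and the
mean number of pairwise differences k. Internally k is the mean of the
exact pairwise-difference spectrum, so \(k = \pi \times\) (retained
sites) holds by construction. Report writers round Hd and \(\pi\) to
three decimals and k to one, mirroring the usual print precision;
full precision is retained in the returned objects.

## Neutrality tests

Implemented statistics: Tajima's D; Fu & Li's D (when an outgroup
polarizes singletons) and D* (without; the default, matching the
common no-outgroup analysis path); Fu's Fs; and Ramos-Onsins & Rozas's
R2. D-family statistics are computed from the minimal mutation count
\(\eta\) (per-column allele count minus one) and singleton tallies; Fs
computes \(S' = P(K \ge K_{obs} \mid \theta = \hat k)\) under the
Ewens sampling formula through the sequential (Chinese-restaurant)
representation — a Poisson-binomial dynamic program run entirely in
log space, stable beyond n = 150 and exactly matching Stirling-number
enumeration at small n. Boundary cases are flagged as undefined
rather than thrown: S = 0 for the D family, a single haplotype
(S' = 1, Fs infinite) for Fs.

Significance comes from coalescent simulation under neutrality and
constant size: genealogies for the observed n, mutations placed under
infinite sites, by default conditional on the observed S (mutations
dropped multinomially on branches proportional to length); an
alternative conditions on Watterson's \(\hat\theta\) with Poisson
mutation numbers. One-tailed p-values are reported in each statistic's
conventional rejection direction (lower tail for D, D*, Fs and R2),
with the simulation count, conditioning and seed recorded in the
result and report headers. The default 10,000 simulations match the
usual randomization count for these tests; the test suite runs
scaled-down counts with Monte Carlo tolerances stated in each test.

## Mismatch distributions and the sudden-expansion model

The expected pairwise-difference distribution under a stepwise
expansion (\(\theta_0 \to \theta_1\) at \(\tau = 2ut\) mutational
units ago) is computed from the classic two-epoch pair-coalescence
closed form, written with regularized gamma/Poisson terms
(`pgamma`/`dpois`) so large \(\tau\) or \(\theta\) cannot overflow;
the vector is truncated at the observed maximum plus ten classes and
renormalized (tail mass is negligible at fitted parameters).
At \(\tau = 0\) it reduces exactly to the equilibrium geometric
distribution \(\theta^i/(\theta+1)^{i+1}\), and it matches a forward
stochastic pair simulation within Monte Carlo error — both are tests.

Estimation minimizes the sum of squared deviations (SSD) between the
observed relative spectrum and the model by bounded quasi-Newton
(L-BFGS-B) from a small multi-start grid (\(\theta_0 \in \{0, \hat
k/2\}\), \(\tau \in \{1, \text{spectrum mode}\}\), \(\theta_1 \in
\{\hat k, 5\hat k\}\)), ties broken toward the smaller \(\tau\). The
SSD surface is smooth in the parameters, so a gradient-based bounded
optimizer is used rather than a derivative-free one; a local-optimality
audit against a surrounding grid is part of the test suite. With
\(\theta_0 = 0\) (the fitted value for expanding haplogroups)
\(\theta_1\) is only weakly identified — the spectrum approaches
Poisson(\(\tau\)) as \(\theta_1\) grows — so \(\theta_1\) estimates
can sit at the optimizer's upper bound with wide bootstrap intervals;
\(\tau\) remains well identified.

Goodness of fit (p-values for SSD and Harpending's raggedness
\(rg = \sum_{i=1}^{d+1}(x_i - x_{i-1})^2\), with \(x_{d+1} = 0\)) and
percentile confidence intervals come from a parametric bootstrap:
coalescent data re-simulated under the fitted demography and re-fit
per replicate (refits start from the original optimum plus one
default start, which keeps 10,000 replicates tractable). The
raggedness convention excludes a leading boundary step below class
zero, so a uniform spectrum scores \(x^2\) (one trailing step) and an
interior spike scores 2.

`expansion_time()` converts \(\tau\) to calendar time via
\(t = \tau/(2u)\) generations, \(u = L \times \text{rate} \times g\)
the whole-locus per-generation rate. The default calibration, 1.1%
per million years with a 1.5-year generation time, is read as a
per-lineage per-site rate (the usual convention for arthropod mtDNA
clock calibrations); `pairwise_rate = TRUE` halves it for users whose
calibration is a pairwise divergence rate. For \(\tau = 4.56\),
L = 596: \(t \approx 3.5 \times 10^5\) years.

## Isolation-with-migration divergence dating

The two-population IM model: both daughter populations and their
ancestor share the scaled size \(\theta = 2N_e u\) (locus-wide; mtDNA,
so \(N_e\) is the female effective size); divergence at scaled time T
(units of \(N_e\) generations); symmetric backward migration at rate
M/2 per lineage below T. Uniform priors on \([0, M_{max}]\),
\([0, T_{max}]\) (defaults 10 and 5) and \([0, \theta_{max}]\)
(default five times the pooled Watterson estimate). The likelihood is
finite-sites HKY via Felsenstein pruning over compressed site
patterns (C++ hot path, verified against an independent R
implementation and against `phangorn::pml` to 1e-6); \(\kappa\) is
fixed from the data by a pairwise transition/transversion moment
estimate unless supplied.

The sampler updates: \(\theta\) (multiplier), M and T (reflected
slides), node times (uniform slides; multiplier for the root gap), a
joint rescale of T with all node and migration times (important
because T alone mixes slowly — it is pinned by the genealogy's
cross-population structure), and a lineage-threading move that
detaches a lineage and re-threads it through the remaining genealogy
by simulating its migration path and attachment from the exact
conditional structured-coalescent prior, so its acceptance ratio is
the likelihood ratio alone. One subtle piece of that conditional:
when the detached lineage sits above the remaining tree's root, the
proposal also regenerates the root lineage's migration path below the
detachment point, rejection-sampled against non-coalescence with the
detached subtree — omitting this demonstrably biases the chain. The
sampler was validated by (a) prior-only runs recovering the uniform M
and T priors (Kolmogorov-Smirnov distance below 0.05 at 1e5 thinned
samples), (b) stationarity of the threading move against direct
structured-coalescent simulation, and (c) agreement of full
posteriors with brute-force marginal-likelihood grids on small
datasets.

Posterior modes use histograms with bin width \(M_{max}/100\),
\(T_{max}/100\) (the gridded-posterior convention of this analysis
style), ties toward the smaller value; boundary modes are flagged.
Default chain settings are 5e6 steps, 1e6 burn-in and three replicate
chains whose mode spread is reported as a convergence diagnostic; the
test suite uses chains of 1e5-2.5e5 steps, which the validation above
shows is enough for stable marginals at n = 10+10, though
histogram-bin modes of the diffuse single-locus T posterior remain
noisy (see Limitations).

`convert_divergence()` applies \(N_e = \theta/(2 L \mu_{gen})\) and
\(T_{pop} = T\theta/(2L) \times 1/\text{rate}\) years (the same
transform for the sample TMRCA), echoing every factor used. Note that
with migration permitted, posterior states in which all lineages
coalesce below T through migration are part of the model, so the
sample TMRCA is not logically bounded below by T; with strongly
structured data most, but not all, posterior mass satisfies
TMRCA ≥ T. The per-sample violation fraction is directly computable
from the returned samples.

## The coalescent simulator

`demography_constant()`, `demography_expansion()` and
`demography_split()` describe the three demographies. Constant-size
and expansion genealogies are simulated in mutational units
(\(x = 2ut\); a pair coalesces at rate \(1/\theta(x)\), a branch of
length x carries on average \(x/2\) locus-wide mutations), making
\(\tau\) and \(\theta\) directly comparable with the mismatch
estimators; \(\theta_0 = 0\) collapses all remaining lineages exactly
at \(\tau\) (star genealogy). The split model runs in coalescent
units matching the IM estimator. Sequences evolve under finite-sites
HKY (root drawn from the stationary frequencies), with defaults
L = 596, \(\kappa = 4\) and AT-rich base frequencies
(A 0.33, C 0.16, G 0.14, T 0.37) — insect-mtDNA-like values chosen as
package defaults, configurable per model. An infinite-sites toggle
places each mutation at a fresh site; closed-form oracle tests
(E[S] = \(\theta a_1\), E[k] = \(\theta\)) use it, because the
finite-sites default loses about 5% of mutations to multiple hits at
\(\theta = 5\), L = 596 — real data lose them too, which is exactly
why the HKY estimators are exercised on the finite-sites path
everywhere else. What the generator does not emulate: recombination
(absent in mtDNA), selection, rate heterogeneity across sites,
sequencing error and sampling that is non-random with respect to
geography — so passing calibration tests here says nothing about
those features of real data.

## Pipeline, reproducibility, problem sizes

`run_summary()`, `run_demography()` and `run_divergence()` produce
the three per-haplogroup/pairwise reports; every report carries a
provenance header (config digest, seed, package version). Stage
sub-seeds derive deterministically from the master seed by a fixed
counter scheme, so stages are independently reproducible and the full
pipeline is byte-identical under a fixed config and seed. The test
suite and the acceptance script use scaled-down problem sizes chosen
so the whole suite completes in minutes on one core: 2000 replicates
for estimator calibration, 1000 outer replicates (with null
distributions pooled by S, which is exact under on-S conditioning)
for test-size calibration, 20-25 replicates for expansion-parameter
recovery at n = 149, and 20 IM runs with 1.2e5-step chains.

## Known limitations

- Single locus, single realization of the coalescent: all diffuse
  posteriors and wide bootstrap intervals reflect genuine
  non-identifiability, not numerical weakness. In particular the IM
  divergence time T is informed only through the product
  \(T \times \theta\) and the cross-population coalescence pattern,
  so its posterior is heavy-tailed; histogram modes at the
  \(T_{max}/100\) bin width wander accordingly between replicate
  datasets, and interval summaries of T are more stable than modes.
- \(\theta_1\) in the mismatch fit is weakly identified when
  \(\theta_0 \to 0\) (see above).
- The moment estimate of \(\kappa\) ignores multiple hits and is
  mildly biased down at high divergence; supply \(\kappa\) explicitly
  when a better estimate exists.
- Fu & Li's D with an outgroup treats the outgroup state as ancestral
  at singleton sites; back-mutations along the outgroup lineage are
  ignored, as in the standard implementation of the test.
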