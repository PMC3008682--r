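---
title: "Phylogenetic comparative analysis of leaf physiognomy and temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic comparative analysis of leaf physiognomy and temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Leaf-margin analysis and related leaf-physiognomic paleoclimate proxies rest
on one assumption: that the correlation between leaf traits and temperature
in modern floras reflects adaptive convergence, so that the same
trait-temperature relation held in the past. If instead closely related
species resemble each other because of shared descent — phylogenetic signal
— then part of the modern correlation is biogeographic history, species-site
records are not independent data points, and quantitative paleotemperature
inference is less certain than ordinary regression suggests.

`leafphylo` implements the comparative machinery needed to test this on a
species-site trait table: a dated phylogeny over species-site pairs,
Blomberg's *K* with a tip-shuffling permutation test, and ordinary versus
λ-scaled phylogenetic generalized least squares (GLS vs pGLS) compared by
AIC, plus a binomial PQL model for margin state. A seeded synthetic
community generator reproduces the structure of the empirical calibration
data so that every stage is testable without the (undeposited) original
measurements.

## Tree assembly and dating

Field datasets of this kind come with taxonomy, not molecular trees. The
assembly module mirrors the standard toolchain:

* `graft_taxa()` places genera as polytomies within families on a
  family-level backbone, species as polytomies within genera, and each
  species-site pair as a tip (`Genus_species@site`), pruning unsampled
  families and suppressing unary nodes.
* `smooth_ages()` dates the result: nodes named in the age table are pinned
  exactly, tips sit at age 0, and every undated node is placed by even
  spacing along the chain from its nearest dated ancestor to each nearest
  dated (or tip) descendant.

Even spacing is ambiguous when one undated node lies on several such
chains. We compute the even-spacing candidate per chain and assign the
**maximum**, then verify strict parent-older-than-child monotonicity and
fail loudly if it is violated. Taking the maximum is the only choice of the
simple per-path rules that can never push a node below an older dated
descendant (e.g. ancestor at 100 Myr above an undated node with a dated
descendant at 40 Myr and a tip: candidates 70 and 50; only 70 leaves the
40-Myr node reachable with positive branches).

**Duplicate tips and the ε policy.** A species sampled at *k* sites
contributes *k* tips whose covariance rows would be identical if their
terminal branches were 0, making the GLS covariance matrix exactly singular
at λ = 1. `smooth_ages()` therefore pins species-level polytomy nodes at a
small positive age, `epsilon_frac × root age` (default 1e-6). The
regression module deliberately refuses to jitter a singular matrix itself:
near-duplicate structure is a property of the data and must be introduced
explicitly and visibly at assembly time.

## Phylogenetic signal

`blomberg_k()` implements the ratio statistic directly from its matrix
definition. With tip covariance `V`, phylogenetic mean
`â = (1'V⁻¹x)/(1'V⁻¹1)`, `MSE0 = (x−â)'(x−â)/(n−1)` and
`MSE = (x−â)'V⁻¹(x−â)/(n−1)`,

K = (MSE0/MSE) / [(tr(V) − n/(1'V⁻¹1)) / (n−1)].

*K* = 1 is the Brownian-motion expectation; *K* > 1 means relatives are
more similar than Brownian motion predicts. The acceptance suite verifies
the calibration: the mean of *K* over 500 Brownian traits on a 64-tip
pure-birth tree must lie within 1.0 ± 0.1. *K* is exactly affine-invariant
and exactly 1 on a star phylogeny, both of which are tested.

`signal_test()` assesses significance non-parametrically: the observed
statistic is the variance of the standardized independent contrasts
(computed by Felsenstein's pruning recursion in `independent_contrasts()`);
the null distribution comes from shuffling trait values across tips with
the tree fixed; the one-tailed add-one P-value is
`(1 + #{null ≤ observed})/(1 + n_perm)`, so 999 shuffles give an attainable
floor of 0.001. Polytomies are resolved to a seeded arbitrary bifurcation
with zero-length internal branches before the recursion; this leaves the
implied covariance unchanged and makes runs reproducible. Low contrast
variance — not high — is the signal direction, hence the one-tailed rule.

## Regression models

All Gaussian fits use the **ML parameterization** (σ̂² = RSS/n), not REML:
the point of the analysis is AIC comparison across models with different
covariance structures, and only ML log-likelihoods are comparable. The
parameter counts are k = 3 for ordinary GLS (intercept, slope, σ²) and
k = 4 for pGLS (+λ); a fixed-λ pGLS counts k = 3. Standard errors use the
ML σ̂² for internal consistency, so they are smaller than `lm()`'s by a
factor √((n−p)/n); the coverage consequences are measured, not assumed (see
below).

`fit_pgls()` profiles Pagel's λ over [0, 1] with a bounded scalar search
(tolerance 1e-6), evaluating the boundary values explicitly and resolving
ties within 1e-8 log-likelihood units toward a boundary. A flat profile —
the star-tree case, where off-diagonal covariances vanish and λ has no
effect — is flagged (`lambda_identifiable = FALSE`) rather than reported as
a meaningful estimate. All likelihoods are computed through the Cholesky
factor of the covariance; no matrix is explicitly inverted.

`fit_binomial_pql()` handles the binary margin coding with a logit-link
penalized quasi-likelihood scheme: each cycle regresses the IRLS working
response on the design under total covariance `W⁻¹ + τ²C` (C scaled to
unit height), re-estimating τ² by a one-dimensional profile search, until
coefficients change by less than 1e-6 (at most 100 cycles). PQL's working
likelihood is not a marginal likelihood, so `logL` and `AIC` are reported
as `NA` and the comparison helpers refuse to use them — the binomial row of
a report is interpretable through its coefficients and SEs only.

## The synthetic community generator

`simulate_community()` is first-class, tested code that realizes the data
structure the analysis targets, with defaults fixed at the study
conditions: 17 sites spanning 5.6–25.8 °C of mean annual temperature and
569 species-site pairs, of which 156 belong to the warmest (tropical) site,
so excluding it leaves 413.

The generative mechanism, stage by stage:

* **Species pool.** A seeded pure-birth tree (default 300 species, root age
  100 Myr). Pure birth is the simplest seeded ultrametric generator; the
  methods only need *an* ultrametric shape, not a realistic diversification
  model.
* **Occupancy.** A Brownian "temperature preference" trait fixes a
  phylogenetically conserved ordering of species along the gradient; ranks
  are mapped through the quota- and fidelity-weighted site-MAT distribution,
  and each site fills its quota with the nearest-preference species. The
  per-site fidelity (default: 3 adjacent sites for temperate species, 1 for
  the tropical site) encodes that the tropical flora is largely endemic.
  MAT, viewed as a species trait, thereby inherits phylogenetic signal from
  conserved occupancy — it is never simulated on the tree directly.
* **Duplicate tips.** Species at several sites become ε-branch polytomies
  (`epsilon_frac` default 0.02, i.e. 2 Myr at a 100-Myr root). This is
  deliberately larger than the dating module's numerical ε: conspecific
  populations a fraction of a Myr apart would make within-species
  site-to-site temperature differences dominate the contrast variance and
  erase MAT's signal, which is not how evenly-spaced dating places species
  nodes in real assemblies.
* **Continuous traits.** Each of the 20 continuous leaf traits is
  `a + b·log10(MAT)` plus a λ-structured multivariate-normal residual
  (σ = 0.3 on the log10 scale); the per-trait `a`, `b`, λ defaults are
  realistic values for eastern-North-American leaf-physiognomy calibration
  data. Tooth traits are set missing on fully untoothed rows, reproducing
  the per-trait sample-size pattern of real tables.
* **Margin state.** A Brownian liability plus an optional direct MAT effect
  (default 0 — under the default conditions tooth presence is *not* driven
  by temperature) is thresholded at the quantile giving a 0.43 untoothed
  fraction; each of 5 specimens is scored untoothed with a logistic
  probability around the threshold, and `code_margin()` produces the
  ternary (1 / 0.5 / 0) and binomial (1 = all specimens untoothed) codes.

What the generator does **not** emulate: measurement error in the digital
trait measurements, taphonomic filtering, real diversification dynamics,
and spatial autocorrelation beyond the one-dimensional temperature
gradient. Passing tests therefore show that the estimators do what they
claim under the stated generative model — not that any particular empirical
dataset satisfies that model.

## What the test suite establishes

* Exact algebra: the covariance matrix equals an edge-set-intersection
  oracle; GLS equals the normal equations; the GLS likelihood equals a
  dense multivariate-normal evaluation; pGLS at λ = 0 equals OLS on
  ultrametric trees; PQL at τ² = 0 equals logistic IRLS; contrasts match
  an independent pruning implementation.
* Calibration: mean *K* = 1.0 ± 0.1 under Brownian motion (500 traits,
  64 tips); permutation type-I error at the nominal level on signal-free
  data; a strong-signal Brownian trait on 128 tips reaches the 0.001 floor
  with 999 shuffles.
* Recovery: λ ∈ {0, 0.5, 1} recovered within ±0.1 and the slope within
  ±0.05 (200 replicates each, n = 128); 95% CI coverage of the pGLS slope
  within 95% ± 3% (500 replicates).
* The qualitative headline, in silico: with margin state generated from a
  conserved liability and **zero** true temperature effect, ordinary GLS
  frequently reports a significant margin–MAT slope while the pGLS slope CI
  covers zero in ≥ 90% of replicates; and when residuals are truly
  Brownian, pGLS beats GLS on AIC in ≥ 90% of replicates.

Problem sizes in the suite (64–128 tips for calibration and recovery, a
~120-pair community for the paired-model replicates, 200–500 replicates
per property) were chosen as the smallest at which the binomial bands
above are meaningful; they are the package's own desk-scale choices.

## Numerical choices and limitations

* Covariance factorizations use Cholesky throughout; a non-positive-definite
  matrix raises an error naming the smallest eigenvalue instead of being
  silently regularized.
* λ and τ² searches are bounded scalar optimizations; boundary optima are
  legitimate results, and flat profiles are flagged.
* Zero-length branches are allowed structurally but the contrast engine
  refuses to standardize a contrast over a zero summed branch length —
  the assembly ε policy exists precisely to prevent that state.
* The ternary margin code is analyzed as a continuous response in GLS/pGLS.
  That is the field's convention for this variable and is what the report
  tables do; it remains a coded ordinal proportion, which is why the
  binomial PQL row accompanies it.
* Single-realization *K* on community-structured data is long-tailed: a
  few deep contrasts dominate, so individual synthetic communities can show
  weak *K* for MAT even though the permutation test detects the signal.
  Level statements about *K* in the tests are therefore averaged over
  communities.
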