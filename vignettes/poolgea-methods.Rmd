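---
title: "Models and methods behind poolgea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolgea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

poolgea scans pooled-sequencing (Pool-Seq) allele counts for association
with environmental covariates while correcting for shared population
history. This vignette is the package's account of the underlying models,
the choices that were genuinely open, and what the simulation-based tests
do and do not establish.

## The hierarchical model

For SNP $i$ and population $j$ the data are reference read counts
$r_{ij}$ out of coverage $c_{ij}$, sequenced from a pool of $n_j$
haploid genomes. The generative hierarchy is

$$
\pi_i \sim \mathrm{Beta}(a, b), \qquad
\alpha_{i\cdot} \sim \mathcal N\!\big(\pi_i \mathbf 1 + \delta_i \beta_i
\mathbf z,\; \pi_i (1-\pi_i)\, \Omega\big),
$$
$$
y_{ij} \sim \mathrm{Binomial}\big(n_j,\, g(\alpha_{ij})\big), \qquad
r_{ij} \sim \mathrm{Binomial}\big(c_{ij},\, y_{ij}/n_j\big),
$$

where $\pi_i$ is the across-population allele frequency, $\alpha_{ij}$
the population allele frequency, $y_{ij}$ the latent count of reference
alleles in the sequenced pool, $\Omega$ the scaled covariance matrix of
population allele frequencies (the structure correction), and
$g(\alpha) = \min(\max(\alpha, 0), 1)$ a censored link. The covariate
term $\delta_i \beta_i \mathbf z$ exists only in the association (AUX)
model: $\delta_i \in \{0, 1\}$ is a per-SNP inclusion indicator with
shared prior inclusion probability $P \sim \mathrm{Beta}(1,1)$, and
$\beta_i$ has a uniform prior on $(-0.3, 0.3)$ — comfortably wider than
effect sizes of practical interest on the frequency scale.

**Why the censored link.** Across-population frequencies drawn from a
Beta with shapes near $(2.78, 0.71)$ put many SNPs close to fixation.
If $\alpha$ were confined to $[0,1]$, the Gaussian drift distribution of
those SNPs would be truncated asymmetrically and any sampler — however
long it runs — would attribute the missing variance to the read and pool
binomials, collapsing $\hat\Omega$ toward zero. With the censored link
$\alpha$ is unbounded: a population pinned at frequency 1 carries its
full Gaussian tail, exactly mirroring how the simulator clips its latent
frequencies at the boundary. Recovery experiments in
`tests/testthat/test-acceptance.R` show the difference is dramatic, not
cosmetic.

## Sampling

Metropolis-within-Gibbs, all randomness through R's RNG so `set.seed()`
reproduces a run bit for bit:

* $y_{ij}$: ±1 random-walk proposals (two passes per sweep) against the
  product of the pool and read binomials, with per-population lookup
  tables for the combinatorial terms;
* $\alpha_{ij}$: component-wise Gaussian random walks; the multivariate
  prior ratio is evaluated in $O(J)$ by tracking $\Lambda e$ where
  $\Lambda = \Omega^{-1}$ and $e$ is the current residual;
* $\pi_i$: reflected Gaussian random walk on $(10^{-4}, 1-10^{-4})$
  under the Beta$(a, b)$ prior; the default shapes are $(2.78, 0.710)$,
  held fixed rather than sampled;
* $\Omega$: conjugate inverse-Wishart step on the standardized residuals
  $\bar\alpha_i = (\alpha_i - \pi_i \mathbf 1)/\sqrt{\pi_i(1-\pi_i)}$,
  with identity prior scale and $J + 2$ degrees of freedom;
* $(\delta_i, \beta_i)$: exact Gibbs. Given the residual, the
  conditional density of $\beta_i$ is a Gaussian truncated to
  $(-0.3, 0.3)$ whose normalizing constant is available in closed form,
  so the marginal likelihood ratio for $\delta_i = 1$ versus $0$ is
  exact, and $\beta_i \mid \delta_i = 1$ is drawn from the truncated
  normal by inverse-CDF. A random-walk update with a grid or Laplace
  approximation for the marginal would work, but the conjugate draw
  mixes better and removes two tuning constants, so it is the design
  used here;
* $P$: conjugate Beta update from the current count of included SNPs.

Proposal widths are tuned per SNP during pilot runs toward a 25–45%
acceptance window. The full-scale default schedule is 15 pilot runs of
500 iterations, 2,500 burn-in, and 1,000 retained samples thinned by 20;
the desk-scale schedule used throughout the tests
(`mcmc_settings_desk()`) is 4 pilots of 100, 400 burn-in, and 400
samples thinned by 2, which the recovery and calibration experiments
show is adequate at a few thousand SNPs and $J \le 32$.

## Derived statistics

**XtX.** The differentiation statistic of SNP $i$ is the posterior mean
of $\bar\alpha_i^\top \Omega^{-1} \bar\alpha_i$, computed from per-SNP
posterior second-moment matrices against a fixed $\hat\Omega$
(`compute_xtx()`), or per draw against the current $\Omega$ draw inside
the sampler. Its neutral expectation is the number of populations $J$;
on 10,000 neutral desk-scale SNPs the mean lands within a fraction of a
percent of $J$. The *distribution* of the posterior-mean estimator is
narrower than the asymptotic $\chi^2_J$ reference because at 25×
coverage the posterior shrinks each SNP's standardized frequencies; the
package's documented calibration tolerance for the Kolmogorov–Smirnov
distance to $\chi^2_J$ is therefore 0.25 — loose enough to admit this
finite-information shrinkage, tight enough to catch scaling errors in
$\Omega$ or the standardization.

**Bayes factors.** Per SNP the scan reports the posterior inclusion
probability (PIP), the effect estimate (posterior mean of
$\delta_i\beta_i$), and a Bayes factor computed as posterior odds from
the PIP over prior odds from the posterior mean of $P$, reported in
deciban ($10\log_{10}$). With $S$ retained samples the PIP is clamped to
$[1/(2S),\, 1 - 1/(2S)]$ so the BF stays finite; the cap is recorded in
the scan object. No hard BF significance cutoff is baked in — tail-based
selection (upper 0.5%) and the region rule live downstream.

**FMD distance.** Covariance estimates are compared with the
Förstner–Moonen metric, $\sqrt{\sum_k \log^2 \lambda_k}$ over the
generalized eigenvalues of the pair — zero iff equal, symmetric, and
invariant to joint rescaling.

## The simulator and what it emulates

`simulate_dataset()` draws data from the hierarchy above: truncated-Beta
across-population frequencies (shapes 2.78/0.710, minor-frequency floor
0.01), $\Omega$-structured Gaussian population frequencies clipped to
$[0,1]$ (clipping events are counted and returned), binomial pool
sampling, and binomial read sampling. Defaults are the power-study
design: 168 populations, 10,000 SNPs of which 100 carry a regression
coefficient of 0.1 on the standardized covariate, haploid pool sizes of
30 (about fifteen diploid plants per pool), and constant 25× coverage —
near the empirical mean of the study design this emulates; a vector of
empirical coverages can be supplied instead and is resampled per cell
(whether the original design redrew coverages per SNP or per cell is not
documented; per cell is the choice here). The effect
$\beta \mathbf z$ applies on the natural frequency scale before
clipping.

`simulate_pc_correlated_covariate()` builds covariates with a controlled
Spearman correlation to the leading eigenvector of $\Omega$ by mixing
the rank-transformed eigenvector with Gaussian noise,
$v = w\,u^\ast + \sqrt{1-w^2}\,\varepsilon$, and bisecting on $w$ until
the achieved correlation is within 0.02 of the target (fresh noise is
drawn if a target is unreachable, and the best achieved value is
reported on failure).

What the simulator does **not** emulate: linkage disequilibrium between
SNPs (SNPs are independent, as in the power design it reproduces),
mapping and calling artifacts, reference bias, or spatially explicit
demography. Passing tests therefore establish correctness of the
*inference machinery* under the model's own assumptions, not robustness
to the full messiness of real Pool-Seq data — which is precisely what
the filter cascade upstream is for.

**Desk-scale $\Omega$.** Real regional datasets show one dominant axis
of structure (PC1 explaining most of the genomic variance). The
desk-scale stand-in `omega_structured(J)` is
$s\,(I + \lambda_1 u u^\top)$ with $u$ a standardized linear gradient —
distinct loadings, so a rank correlation against PC1 is well defined —
$\lambda_1$ set so PC1 explains 50% of the variance, and overall scale
$s = 0.15$, a moderate-to-strong drift intensity typical of selfing
plants at regional scale. These two constants were fixed once when the
study conditions were chosen. Compound-symmetry and identity matrices
are kept for analytic checks (their eigenvalues are closed-form), but
note the compound-symmetry leading eigenvector is constant, so it cannot
anchor a rank-correlated covariate.

## Filtering, enrichment, regions, spatial analysis

The five-step filter cascade applies, strictly in order: zero coverage
in at least 8 (of a declared 168; rescaled proportionally for other
panel sizes) populations; mean relative coverage above 1.5 (collapsed
paralogs); allele-frequency standard deviation below 0.004; mean
relative coverage below 0.5 (presence/absence variation); monomorphic —
read-based frequency exactly 0 or 1 — in more than 90% (strict) of the
covered populations. Frequency statistics ignore zero-coverage cells,
which are missing, not zero. A SNP is charged to the first step it
fails, so the audit report depends on step order by design.

Fold enrichments use tail counts: for annotation categories
$FE = (s_a/s)/(S_a/S)$, for the two-statistic overlap
$FE = (n_a/n)/(N_a/N)$; tails are the `floor(0.005 N)` largest values
with ties broken by genome order. Significance comes from circular
permutations: the tail-membership indicator is rotated along the
concatenated genome (chromosomes in declared order) by offsets drawn
uniformly without replacement from $1..N-1$ (with replacement, with a
warning, if more permutations than offsets are requested); rotating the
indicator rather than the labels is an arbitrary but fixed choice —
the two are equivalent in distribution. Rotation preserves runs of
linked SNPs, which is the point: on clustered data the rotation null is
strictly wider than an independent shuffle. The add-one estimator
$p = (1 + \#\{FE^{null} \ge FE^{obs}\})/(1 + n_{perm})$ never returns
zero. Benjamini–Hochberg correction is applied per family of tests
(e.g. categories × covariates).

Candidate regions are maximal runs of top-BF SNPs (the 50 highest per
covariate by default) in which successive SNPs are separated by strictly
less than 10 kb, kept when supported by at least 3 SNPs; the span runs
from the first to the last supporting SNP and the length is
`end - start` bp. Overlapping regions from different covariates merge
into one record listing all supporting covariates. Gene overlap is
1-based inclusive interval intersection: touching at a shared base pair
counts, adjacency at +1 does not.

Spatial structure uses PCNM (principal coordinates of neighbor
matrices) via `vegan::pcnm()` — Euclidean distances truncated at the
longest minimum-spanning-tree edge, beyond-threshold distances replaced
by four times the threshold, positive-eigenvalue principal coordinates
kept in decreasing order — checked in the tests against a direct
eigen-decomposition oracle. Covariate pruning is greedy in a
user-supplied preference order (the stand-in for ecological judgement),
retaining a candidate iff its absolute Spearman correlation with every
already-retained covariate is at most 0.8. Coordinates are treated as
planar; for the ~100 km extents this workflow targets the distortion is
negligible relative to the PCNM truncation.

## Power evaluation

`power_study()` runs the full loop: simulate a covariate at each target
correlation $\rho$ with PC1, simulate replicate datasets, scan each
under the AUX model **with the generating $\Omega$** (matching the
original power design, which reused the estimated matrix rather than
re-estimating it per replicate), pool replicate scores by concatenation,
and sweep thresholds. ROC plots TPR against FPR; the PR curve plots
precision $1 - FDR$ against TPR; both areas use the trapezoid rule on
the achieved-threshold grid (interpolation conventions differ between
tools; trapezoid is the declared one). When nothing is called, FDR is
reported as 0 and flagged. The desk-scale grid is $J = 32$, 2,500 SNPs,
25 associated, 3–5 replicates per $\rho$; at these sizes ROC AUC is
above 0.9 for a structure-independent covariate and collapses as
$\rho \to 0.9$, reproducing the qualitative trade-off the method is
known for: the structure correction absorbs true signal exactly when
the environment mirrors the demography.

## Numerical and degenerate-input choices

* Zero-coverage cells: missing frequencies; a whole population with
  zero median coverage is an error.
* Tail size: `floor(fraction * N)`, ties by genome order.
* Constant covariates cannot be standardized (error) and are excluded
  from pruning with a warning.
* The PIP clamp above; the maximum reportable |BF| is set by the number
  of retained samples and recorded in the scan object.
* $\pi$ is sampled inside $(10^{-4}, 1 - 10^{-4})$; XtX standardization
  is therefore guarded against division by zero.
* `upper_tail` on fewer than $1/f$ SNPs returns an empty set; enrichment
  on an empty tail is flagged undefined rather than silently zero.

## Known limitations

* $\hat\Omega$ carries a mild downward bias at small $J$ because each
  SNP's $\pi_i$ absorbs part of the shared frequency shift
  (a $\approx 1 - 1/J$ factor); comparisons against reference matrices
  should use the FMD scale, not element-wise equality.
* The Bayes factor is a posterior/prior-odds construction from the PIP
  and the estimated inclusion probability; alternative Monte Carlo BF
  estimators exist and will differ in finite samples, though they share
  units (deciban) and ranking behavior.
* The Beta shapes of the $\pi$ prior are fixed, not estimated; analyses
  of data with a very different site-frequency spectrum should set them
  explicitly.
* Spatial analyses assume planar coordinates; great-circle distances are
  not computed internally.
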