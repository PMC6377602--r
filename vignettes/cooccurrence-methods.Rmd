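---
title: "Null models, spatial occupancy regression and variance partitioning for soil animal co-occurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null models, spatial occupancy regression and variance partitioning for soil animal co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooccurspat)
```

## The inferential problem

When two species are found together less often than chance allows, the
pattern may reflect a negative biotic interaction (competition, predation),
opposing responses to environmental gradients, or spatially structured
processes such as dispersal — and usually all three at once. `cooccurspat`
implements a chain of methods designed to separate these sources for
site-by-species survey data in strongly abiotically-structured landscapes,
with polar-desert soil nematode communities (three dominant species over
hundreds of sites) as the motivating scale:

1. **Co-occurrence null models.** The C-score over species pairs, tested
   against the SIM9 fixed–fixed randomization, asks whether the observed
   arrangement is compatible with random placement given each species'
   prevalence and each site's richness.
2. **Spatial occupancy GLMMs.** Per-species binomial regressions with
   spatially correlated residuals estimate the effect of each other
   species' presence while controlling for measured gradients and for
   residual spatial autocorrelation.
3. **Hellinger RDA with variance partitioning.** At the abundance level,
   explained variation is decomposed into unique and shared fractions of
   abiotic, biotic and spatial (PCNM) predictor sets, and residual
   cross-species correlations measure association left over after all
   measured predictors are removed.

A synthetic-landscape generator with known truth closes the loop: every
stage is testable for calibration (no false structure on interaction-free
landscapes) and power (planted interactions recovered).

## Null models

For species $i, j$ with occupancy counts $r_i, r_j$ sharing $S_{ij}$ sites,
the checkerboard units are $CU_{ij} = (r_i - S_{ij})(r_j - S_{ij})$, and
the C-score is the mean of $CU_{ij}$ over unordered pairs. SIM9 preserves
both row (site richness) and column (species prevalence) totals; the
sampler repeatedly draws a random $2 \times 2$ submatrix and flips it when
it is a checkerboard. Draws that are not checkerboards count as attempts,
which makes the chain a symmetric Metropolis sampler with a uniform
stationary distribution on the fixed-margin set; unit tests verify
uniformity against exhaustive enumeration on small margins.

The standardized effect size is
$\mathrm{SES} = (\mathrm{obs} - \overline{\mathrm{null}})/\mathrm{SD}_\mathrm{null}$
with the sample standard deviation over replicates, and the 95% limits are
the empirical 2.5/97.5 percentiles. Defaults: 5000 replicates from one
chain, 30,000 burn-in attempts, thinning equal to the number of matrix
cells. These chain mechanics are conventional for sequential-swap practice;
the thinning default keeps successive samples' autocorrelation mild (lag-1
$\approx 0.25$ on a $314 \times 3$ matrix) and the SES stable to well
under 0.5 across seeds. Ties between observed and null replicates count
toward the extreme tail, a conservative choice.

Pairwise tests pool all pairs' null-standardized scores into one reference
distribution (an empirical-Bayes-style shrinkage of the per-pair limits
toward the common null scale) and call a pair non-random only when its SES
falls outside the pooled $\alpha/2$ quantiles *and* its own tail
probability is below $\alpha/2$. The exact decision rule of the historical
Fortran implementation of the pairwise approach is not public; this pooled
rule is a documented approximation, and Benjamini–Hochberg adjusted
p-values are reported alongside. One structural caveat discovered by the
property tests and worth knowing: **a two-species matrix is degenerate
under fixed–fixed margins** (the margins determine the shared-site count),
so pairwise segregation is only testable in communities of three or more
species.

## Gradients

Collinear abiotic and biotic covariates are collapsed by PCA on the
correlation matrix (i.e. after z-scoring; missing values are mean-imputed
and counted). Axes are retained up to a cumulative two-thirds of variance
by default. Axis signs follow the convention that each axis's
largest-magnitude loading is positive. Abiotic and biotic variables are
ordinated separately so that the two predictor sets entering the variance
partition remain disjoint; categorical aspect enters occupancy models as
dummy variables with the most frequent level as reference, not through the
PCA.

## Spatial structure

Moran's I correlograms use binary weights per distance class (equal-count
bins by default, since survey designs rarely justify fixed-width bins) with
two-sided permutation p-values. Spatial eigenvectors follow the classic
PCNM/db-MEM recipe: truncate the distance matrix at the longest
minimum-spanning-tree edge, replace larger distances by four times the
truncation, double-centre, eigen-decompose, and keep positive-eigenvalue
vectors. Forward selection minimizes a multivariate AIC,
$n \log(\mathrm{RSS}_{\mathrm{total}}/n) + 2(k+1)$, summing residual sums
of squares over response columns. This criterion is deliberately the cited
one, but users should know it is liberal: with many orthogonal candidate
vectors the best candidate's expected RSS reduction grows like the maximum
of many $\chi^2$ draws ($\approx 2\ln m$), so pure noise admits several
vectors and the pure-spatial fraction in the variance partition is
correspondingly generous. Hellinger-transformed abundances are the
selection response, matching the RDA context in which the vectors are used.

## Spatial binomial regression by penalized quasi-likelihood

Occupancy models are logistic regressions whose working residuals carry a
spherical spatial correlation,
$\rho(d) = (1-\nu)\,(1 - 1.5\,d/r + 0.5\,(d/r)^3)$ for $d < r$ and $0$
beyond, with nugget $\nu \in [0, 0.9]$ and range $r$ in metres. Each outer
iteration linearizes the model (working response
$z = \eta + (y-\mu)/\mu(1-\mu)$), solves a generalized least-squares
problem with covariance
$\mathrm{diag}(1/w)^{1/2} R(\theta)\, \mathrm{diag}(1/w)^{1/2}$, and
re-estimates $(r, \nu)$ by weighted least squares on the empirical
semivariogram of the Pearson residuals. Estimating the correlogram from
residual variograms rather than profiling it inside the quasi-likelihood
is a transparency/robustness choice; coefficient agreement with fully
profiled implementations is approximate by construction. Standard errors
come from the GLS information matrix and p-values from $t$ with $n - p$
degrees of freedom, the conventional choice for population-level terms.

Numerical safeguards, each of which mattered in practice: the linear
predictor is capped at $\pm 15$ inside the linearization (otherwise
working-response entries of order $1/w$ destabilize the correlated GLS
step); coefficient steps are halved when a proposed update pushes the
predictor past twice the cap; complete separation is detected from the
initial uncorrelated fit and reported as an error rather than a divergent
estimate; duplicate locations get a 1e-8 distance jitter; convergence is
declared when the largest coefficient change falls below 1e-6, within 50
iterations.

## Ordination and variance partitioning

Abundances are Hellinger-transformed ($y' = \sqrt{y_{ij}/y_{i\cdot}}$),
which makes Euclidean least squares appropriate for species count data.
RDA is multivariate linear regression of the column-centred response
followed by a PCA of the fitted values; significance is by row permutation
of the predictors. Variance partitioning computes Ezekiel-adjusted $R^2$
for all seven unions of the abiotic/biotic/spatial sets and decomposes by
inclusion–exclusion; the adjustment is necessary because the sets differ
greatly in size (a handful of gradient axes versus tens of selected
eigenvectors). Negative shared fractions are reported as-is and flagged,
never truncated, so the eight fractions always sum to one exactly.

Residual correlations between species' RDA residual columns are the
abundance-level analogue of the pairwise null-model tests: association
that survives removal of every measured predictor. Note a compositional
caveat: Hellinger shares (square-rooted relative abundances) are closed,
so a strongly dominant species induces some negative residual correlation
with the others mechanically; the generator experiments below quantify how
much.

## The synthetic landscape generator

`preset_config("mdv_like")` encodes the study conditions the package is
calibrated against: 314 sites uniform over a 20 km × 11 km domain;
Gaussian random fields with spherical covariance for two abiotic gradients
(moisture, salinity/elevation; range 4500 m, matching the 4–5 km
autocorrelation neighbourhood the correlograms detect) and two biotic
gradients (microbial richness and biomass; range 3000 m), each with sill 1
and nugget 0.1; three species generated in order of prevalence with
logit-scale gradient coefficients signed after the published occupancy
models (the dominant species prefers dry/saline ground, the others
moister ground); intercepts calibrated by fixed-seed quadrature so
expected occupancies are 289/222/50 of 314; and a single conditional
interaction, a logit shift of $\gamma = -2$ on the rarest species where
the dominant species is present. Abundances are negative binomial
(dispersion $k = 1$, variance $\mu + \mu^2/k$) with log-means tied to the
same gradients at half strength and bases near 600/80/50 individuals per
kg dry soil. Two contrast presets ship alongside: `"null"` (no
interactions, no shared fields — the type-I calibration case) and
`"env_only"` (segregation produced purely by opposing responses to a
shared gradient — the central confound).

Interactions are generated conditionally along the species order (a DAG),
not from a joint Markov random field: this is exactly simulable and
sufficient to produce checkerboard structure, but it is asymmetric by
construction and cannot represent mutual feedback; the occupancy
regressions estimate the association in either direction regardless.
What the generator does *not* emulate: measurement error in covariates,
the real (unpublished) correlation structure among the survey's ~15
covariates, non-uniform site placement, and abundance-level interactions.
Consequently tests passing on these landscapes demonstrate calibration and
recovery of the methods, not that every published percentage is
reproducible — in particular the unique-biotic fraction of the variance
partition depends on covariate structure that only the real data contain.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 314-site landscapes, 5000
null replicates (300 in module tests), 10 landscapes for pipeline-level
summaries, and 40–50 seeded replicates for type-I and recovery
simulations; these sizes give Monte-Carlo standard errors comfortably
below the tolerances asserted. Chain burn-in is 30,000 attempts; PCNM
eigenvalues below $10^{-9}$ of the largest are treated as zero; covariance
factorizations add a 1e-10 diagonal jitter. The pipeline derives one seed
per stage from the global seed with fixed offsets, so disabling a stage
never changes another stage's randomness.

## A worked run

```{r example, eval = FALSE}
land <- simulate_landscape(preset_config("mdv_like", seed = 7))
cfg <- analysis_config_from_landscape(land, null_iters = 1000, seed = 7)
report <- run_full_analysis(cfg)
report$pairwise[, c("pair", "ses", "classification")]
report$glmm$Scottnema
report$ordination$variance_partition
render_report(report, "mdv_report")
```

## Known limitations

- The pooled pairwise decision rule approximates, and was not verified
  against, the historical Pairs program.
- AIC forward selection of spatial eigenvectors over-selects on noise (see
  above); treat the pure-spatial fraction as an upper bound.
- PQL coefficient estimates for binomial responses are first-order
  approximations; simulation shows near-nominal Wald coverage for
  interaction terms at this prevalence structure, but strong
  rare-species/strong-correlation corners can bias estimates.
- Coordinates must be planar metres; no geodesic support.
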