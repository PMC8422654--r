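---
title: "Methods: multivariate divergence of Arctic charr morphs and their hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate divergence of Arctic charr morphs and their hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charrdiv)
```

## The scientific problem

Two sympatric morphs of Arctic charr (*Salvelinus alpinus*) from
Thingvallavatn — the small-benthic (SB) and planktivorous (PL) charr — have
diverged in morphology, life history and behaviour while sharing a lake.
Rearing pure-morph offspring and their first-generation hybrids in a common
garden lets genetically based divergence be separated from environmental
effects. The analytical programme implemented here asks three questions of
such data:

1. Do the cross types differ in *average* trait values along early
   ontogeny (growth, yolk-sac resorption, timing of first feeding, feeding
   behaviour, head shape)?
2. Do they differ in trait *variances and covariances* — the phenotypic
   **P** matrix, used as a surrogate for the genetic covariance structure
   under common-garden rearing?
3. Does multivariate head shape covary with the univariate traits, and does
   the strength of that covariation differ between crosses?

`charrdiv` provides every stage as a tested R function, plus a
synthetic-data generator with known ground truth so the whole pipeline is
testable without the original dataset.

## The synthetic-data generator

The generator (`sim_design()`, `sim_params()`, `simulate_all()`) emulates
the study conditions: 3 cross types (PL x PL, SB x SB, pooled F1 hybrids;
reciprocal hybrids are pooled as in the study), 3 full-sib families per
cross, 40 offspring per family, and four developmental stages on a
thermal-age axis (about 445, 530, 840 and 1100 degree-days: hatching, 20
days post-hatching, and 3-4 and 9-11 weeks after the onset of exogenous
feeding).

Seven focal traits define the P matrices: standard length at hatching (D1)
and at the onset of feeding (D3), growth D1-D2 and D3-D4, yolk-sac area at
D1, yolk conversion, and the latency to start feeding (three records per
individual). A trait vector is cross mean + family effect + individual
effect + residual, each drawn from its own covariance matrix. Default
per-cross trait variances follow the published posterior modes (SB with
inflated post-feeding growth variance, hybrids with reduced variances);
because those published values are on the mean-standardized scale, the
generator converts them to the raw scale with the cross means so that
standardizing during the P fit reproduces them. Default correlations are
modest and concentrated among the size/growth traits, matching the
reported near-absence of trait correlations. The latency variance is not
published; a value of the same magnitude as the other traits was chosen
once.

Growth curves are second-order polynomials of log standard length on
thermal age scaled to `[0, 1]` (the published axis is not recoverable, so
coefficients are reported on the scaled axis throughout). The default
coefficients are the published per-cross estimates: PL 3.09/6.14/-0.70,
SB 2.98/5.77/-1.14, F1 2.98/5.73/-1.00. Individual intercept and slope
deviations are tied to the individual's trait deviations (length at
hatching, post-feeding growth), so growth genuinely covaries with the
P-matrix traits.

Head shapes are 20-landmark configurations (3 anatomical landmarks, 13
head-contour and 4 eye semilandmarks): template + allometric displacement
x (log centroid size - mean) + digitizing noise, then randomly rotated,
translated and scaled, with the nuisance parameters recorded for tests.
The allometry vector is numerically orthogonalized against similarity
transforms of the template so the injected signal survives Procrustes
superimposition exactly.

Behaviour: the propensity to start feeding in a trial comes from a latent
Gaussian thresholded at zero — a probit scale, chosen over the study's
logit because it is conjugate with the Gibbs engine (the standard
conversion factor between the two scales is about 1.6). Attack counts are
Poisson on a log link with a log-normal individual effect (the count family
is not stated in the study; Poisson is an assumption). Defaults imply
latent repeatability of feeding of about 0.4 in PL and about 0 in SB and
F1, and observed feeding propensities near 0.76/0.70/0.65. Daily one-zero
records of first feeding are generated around per-cross onset days, with a
small never-feeding (censored) fraction.

What the generator does *not* emulate: egg-stage mortality, tank-position
effects, digitizing from images, and any non-Gaussian trait skew. Passing
tests therefore demonstrate correctness of the machinery under the stated
generative model, not robustness to the messiness of real images or
non-normal traits.

## Morphometric preprocessing

Semilandmarks are extracted by equidistant arc-length resampling of
digitized curves (`resample_curve()`); there is no semilandmark sliding,
which is out of scope. The yolk-sac area is the absolute shoelace area of
the 200-semilandmark polygon (self-intersection is not checked). Standard
length is the distance from the notochord tip to the farthest of 50 head
semilandmarks.

`gpa()` implements generalized Procrustes analysis: every configuration is
centred, scaled to unit centroid size, and iteratively rotated (2-D SVD,
reflection excluded) to the running consensus until the consensus changes
by less than 1e-10 (at most 100 sweeps, otherwise an error with the last
change). Aligned shapes live in an arbitrary common orientation; all
shape statistics used downstream are invariant to that global rotation.

`rrpp_regression()` fits sequential (type-I) multivariate linear models to
the shape variables and tests each term by randomized residual
permutation: the residuals of the reduced model (all preceding terms) are
permuted and added back to the reduced-model fit, the term's sum of
squares is recomputed, and `Z = (SS_obs - mean SS_perm)/sd SS_perm`,
`p = rank of SS_obs` with the observed value included (so
`p >= 1/(n_perm + 1)`; 999 permutations by default). The nested
family-within-cross terms use the same reduced-model residual permutation
as every other term; the exact permutation scheme for nested terms is not
specified in the source study, and this uniform choice is the documented
interpretation. Disparity (`procrustes_variance()`) is the mean squared
Procrustes distance of group members to their group mean, compared
pairwise by label permutation. Trajectory analysis compares per-group
stage-mean sequences by path length, first-principal-axis angle, and
size-standardized trajectory shape, permuting group labels within stage so
every group x stage cell stays populated.

## The Gibbs mixed-model engine

All Bayesian models run on one engine (`fit_gaussian()`, `fit_binary()`):
a Gibbs sampler for multi-response linear mixed models. Fixed effects and
random effects are drawn from their multivariate-normal full conditionals;
every (co)variance component from its inverse-Wishart full conditional
under the weakly informative prior `V = 1`, `nu = 0.002` (single response)
or `nu` = number of responses (multi-response), matching common practice
for this kind of analysis. Binary traits use Albert-Chib latent-probit
augmentation with the residual variance fixed to 1. Chains are seeded and
reproducible; convergence is reported through effective sample sizes
(Geyer initial positive sequence), not asserted. Because fixed effects, random
effects and covariances are each drawn in conjugate blocks, effective
sample sizes per iteration are high, and the default chains (5,000
iterations, 1,000 burn-in, thinning 4; a few thousand in the analysis
scripts) are much shorter than is customary with single-site samplers;
tests use shorter chains sized so at least 100 draws are stored (the
problem sizes were chosen so every fit completes in seconds).

Two numerical choices deserve note:

* **Balanced-design batching.** When all levels of a random factor share
  the same within-level design cross-product (always true for the
  generator's balanced designs) the level-wise conditional draws are
  vectorized through a single Cholesky factor, which is what makes
  hundreds of fits affordable in the test suite.
* **Population-averaged growth coefficients.** With only three families
  per cross, the per-cross fixed intercept and the mean of the family
  random effects are only jointly identified; a Gibbs chain mixes slowly
  along that ridge. `fit_growth()` therefore reports per-cross
  coefficients as fixed effect + mean random deviation of that cross's
  families and individuals — the realized cohort-mean curve, which is the
  quantity the data identify. The generator exposes the matching realized
  truth (`attr(growth, "realized_coefs")`) for recovery studies.

The multi-response P fit pins the residual covariance to
`1e-6` x trait variance so the individual-level component absorbs the
phenotypic (co)variance (the standard workaround for single-record
traits); latency, the one repeated trait, is averaged per individual
before the fit — consistent with the study's own averaging of latency for
its shape-covariation analysis. On the mean-standardized scale the default
multi-response prior is mildly informative (trait variances are 0.1-0.7
while the prior scale is 1), pulling small variances upward at n = 120 per
cross. It is kept because it is the study's stated prior — the published
variance table, which seeds the generator, carries the same prior — and
because it affects all crosses equally, leaving orderings and angles
intact; `fit_pmatrix()` exposes the prior for users who want a weaker one,
and the machinery-recovery tests use `V = 0.01` to isolate the likelihood.

"Yolk conversion" is not defined in the source study; it is implemented as
`(area_D1 - area_D2) / (length_D2 - length_D1) / area_D1` — relative yolk
consumed per unit growth — behind a single function (`yolk_conversion()`)
so alternatives are swappable. The bivariate yolk model is fitted in
stacked form (rows = individual x stage) with per-stage intercepts,
covariates and cross contrasts, because each response carries its own
log-length covariate; individual and family random intercepts link the two
stages.

## Repeatability

Latent-scale repeatability is `R = V_ind / (V_ind + V_res)` per posterior
draw, summarized by mode and HPD interval; significance is read from the
CrI lower bound against zero. For binary traits the latent estimate is
also transformed to the data scale accounting for Jensen's inequality:
`p(u) = pnorm(mu + u)` is integrated over the latent individual effects by
Gauss-Hermite quadrature (30 nodes) to get the mean probability and its
between-individual variance, and
`R_data = Var(p) / (pbar (1 - pbar))`. The quadrature agrees with a
10^6-draw Monte-Carlo transform to better than 0.01, and data-scale R is
correctly *not* invariant to the latent mean while latent R is. For counts
on the log link the transform is closed-form log-normal.

## P-matrix comparison

`V_tot` is the sum of eigenvalues (equal to the trace), eccentricity is
the ratio of the first two eigenvalues (the study's wording; the
alternative lambda_1 / mean of the rest is not used), and theta is
`acos(|v1 . v2|)` in degrees between leading eigenvectors — sign-invariant
by construction, flagged when a leading eigenvalue is numerically tied.
Theta is summarized by pairing posterior draws by index across the two
fits (the pairing rule is a documented choice; the source study is silent).
The "random matrix" null follows the study: sample 150 individuals from
the pooled pair of crosses, form the sample covariance of family-adjusted,
mean-standardized trait values (a tractable stand-in for a full re-fit,
flagged as an approximation), and record the angle to the focal leading
eigenvector. With fewer than 150 individuals available the resampling
falls back to with-replacement and warns. Because the observed theta is
computed per paired posterior draw — carrying the eigenvector posterior
noise of both fits — the null is measured against per-draw leading
eigenvectors of the focal P rather than a single point estimate, so both
distributions carry comparable posterior uncertainty.

Krzanowski's common subspaces: per posterior draw, `H` is the sum over
groups of projectors onto the first `k` eigenvectors of each group's P;
eigenvalues of `H` near the group count indicate shared subspaces. `k = 3`
by default (not stated in the study; any `k <= floor(7/2)` is valid and
the bound is enforced). The randomized-group null shuffles cross labels
and rebuilds sample-covariance Ps. Non-PSD posterior draws (a numerical
possibility) are clipped to the PSD cone with the count logged. Ellipsoid
projections use the elementwise posterior-mode P of each cross, clipped to
PSD, projected on the reference cross's first three eigenvectors.

## Two-block PLS

`two_block_pls()` takes the SVD of the between-block covariance of the
column-centred blocks; the first paired singular vectors give scores whose
Pearson correlation `r` is the test statistic. Permutation of one block's
rows yields `p` (observed included) and an effect size computed on the
Fisher-z scale, `Z = (z_obs - mean z_perm)/sd z_perm` — the transformed
scale stabilizes the variance of `r`; whether the source study transformed
is unknown, and the choice is isolated in one place. Pairwise comparisons
use `(Z1 - Z2)/sqrt(2)` against a standard normal: each standardized
effect size carries unit sampling variance from its permutation
distribution. Latency is averaged over the three trials before entering
the trait block, as in the study. A leave-one-out report
(`pls_loo()`) flags single influential individuals, motivated by the
study's observation that one individual could flip its pairwise
significance.

## Test design and problem sizes

The suite runs three kinds of checks: exact identities (areas, angles,
`H` eigenvalues, GPA invariances), oracle equivalences (trace vs
eigenvalue sum, fan-triangulation areas, brute-force PLS direction search,
Monte-Carlo repeatability transforms, lme4/vegan cross-checks), and
statistical calibration/recovery under the generator (permutation tests at
their nominal level over 500 replicate null datasets with 199 permutations;
growth-coefficient coverage over 50 replicates; covariance-structure
recovery over 20 replicates at the full design size with reduced chains;
binary repeatability recovery with the PL-vs-others contrast). Scenario
matrices for the covariance-recovery study are prescribed to be clearly
distinct (the hybrid variance pattern scaled down, orthogonal leading axes
with asymmetric magnitudes) because the published per-cross margins — a
14% total-variance gap between PL and F1 — sit at the resolution limit of
120 individuals per cross and are not reliably ordered by *any* estimator
at that size; the vignette records this as a property of the design, not
of the implementation.

## Known limitations

* Semilandmark sliding, 3-D landmarks and thin-plate-spline rendering are
  out of scope.
* The latent-probit behavioural models approximate the study's logit
  models; repeatability comparisons are internally link-consistent.
* The random-angle and randomized-group nulls use sample covariances of
  resampled individuals rather than full Bayesian re-fits.
* Pedigree (animal) models are not implemented; P is interpreted as a
  surrogate for G under common-garden rearing, with family as a fixed
  effect, exactly as in the source design.
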