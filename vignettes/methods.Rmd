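---
title: "Habitat specialization along forest development and elevation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat specialization along forest development and elevation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Mountain forests host communities whose composition changes both with
elevation (a climate gradient) and with forest development after
disturbance (a habitat gradient: gap, establishment, optimum, plenter and
terminal stages). The altitudinal-niche-breadth hypothesis predicts that
species at higher elevation are less specialized because conditions there
are harsher and more variable; lower specialization in turn predicts lower
species richness and weaker compositional differences (beta diversity)
among habitat types. `stagespec` implements the statistical machinery to
test this chain of predictions on plot-by-species incidence data from a
crossed design of five developmental stages by three elevational zones
(submontane, montane, subalpine), and a synthetic metacommunity generator
that produces such data with known ground truth so the whole pipeline can
be validated end to end.

# The specialization measure

For one species and one elevational zone, let $p_i$ be the fraction of its
occupied plots that fall in developmental stage $i$. Niche breadth is the
reciprocal Simpson index

$$B = 1 \Big/ \sum_i p_i^2,$$

ranging from 1 (all occurrences in one stage) to 5 (perfectly even use of
all five stages). Raw breadth is confounded with occupancy: a species
recorded on more plots uses more stages by chance alone. The package
therefore standardizes $B$ against a fixed-margin null model. The zone's
species-by-plot matrix is randomized keeping every row sum (species
occupancy) and column sum (plot richness) fixed; 500 independent null
communities are generated by default; $B$ is recomputed under each; and

$$\mathrm{SES} = -\,\frac{B_{\mathrm{obs}} - \overline{B}_{\mathrm{null}}}{\mathrm{sd}(B_{\mathrm{null}})}$$

with the sign flipped so larger values mean *more* specialization.
Species whose null breadths have zero standard deviation (e.g. a species
occupying every plot of the zone, whose row cannot change under fixed
margins) carry no information and are excluded from SES averaging only —
they still count for richness and beta diversity. SES values are averaged
over the non-excluded species present at each plot, giving one
specialization value per plot.

## Null-model algorithm

Each null matrix is produced by independent restarts from the observed
matrix (a non-sequential design: no continuing Markov chain between
draws). The default algorithm is the curveball trade: two random rows pool
the columns where exactly one of them is present and redistribute that
pool at random; `max(1000, 5 * n_species)` trades are performed per draw.
Curveball mixes quickly and its stationary distribution is uniform on the
fixed-margin class, which the test suite verifies by brute-force
enumeration of a small class (all 3x3 matrices with margins
(2,1,1)/(2,1,1)) and a chi-squared test at 10^4 draws. A classical
trial-swap (checkerboard) sampler is provided as a cross-check; it needs
roughly ten times more steps for comparable mixing and is given them by
default. Per-zone submatrices (plots of the zone, species observed there)
are randomized rather than one global matrix, because breadth and SES are
defined separately per zone; a global randomization would let occurrences
migrate between zones and break the per-zone occupancy margin that the
confound correction relies on. The design-wide alternative remains
available (`ses_specialization(..., matrix_scope = "global")`); null
draws in which a species misses the zone entirely are then dropped from
its null distribution.

# Richness and beta diversity

Species richness is the number of species recorded at a plot. Beta
diversity is the Jaccard dissimilarity $1 - |A \cap B| / |A \cup B|$
computed for every pair of same-zone plots from *different* developmental
stages (a full zone of 50 plots, 10 per stage, yields
$\binom{50}{2} - 5\binom{10}{2} = 1000$ pairs). Pairs whose two plots are
both empty have an undefined Jaccard value and are dropped with a logged
count; values exactly 0 or 1 are kept in the table and shrunk only inside
the beta regression (below).

# Inference

All three model families are fitted by maximum likelihood with `glmmTMB`,
and coefficient uncertainty is represented by multivariate-normal draws
from the joint estimate and covariance — the normal approximation to the
posterior under flat priors. This backend was chosen over a literal
parametric bootstrap (refitting on simulated responses) because it gives
the same first-order uncertainty at a fraction of the cost and is exactly
reproducible under a seed; the test suite includes a small parametric
bootstrap as an independent cross-check of the draw distribution. All
summary operations consume only the draw matrix, so any sampler producing
named draws can stand behind them.

* **Specialization (H I).** Plot-level mean SES is modelled as Gaussian
  with zone-specific means and zone-specific dispersion (a location-scale
  model, `dispformula = ~ 0 + zone`), optionally with a spatial-group
  random intercept. Zone effects are parameterized as cell means so zone
  contrasts are direct coefficient differences.
* **Richness (H II, H IV).** Negative-binomial regression of plot richness
  on stage (gap baseline) crossed with z-scored elevation, an optional
  z-scored day-of-year covariate, and a spatial-group random intercept.
* **Beta diversity (H III).** Beta regression of pairwise Jaccard on zone
  cell means with z-scored spatial and elevational distance (optionally
  quadratic) and day-difference covariates. Responses on the boundary are
  shrunk by $(y(n-1) + 0.5)/n$.

Continuous predictors are always z-transformed (sample SD); the transform
records are stored so predictions are made on the original scale.

## Posterior summaries

Each coefficient or contrast is summarized by

* **MAP** — the mode of a Gaussian-kernel density estimate over the draws
  (Silverman's rule-of-thumb bandwidth), clipped into the HDI if the
  smoothed mode falls marginally outside;
* **95% HDI** — the shortest interval containing 95% of the draws;
* **pd** — probability of direction, `max(P(x > 0), P(x < 0))`, an index of
  effect existence from 0.5 to 1;
* **ROPE %** — the share of the draws *inside the 95% HDI* that fall in the
  region of practical equivalence $\pm 0.1 \cdot \mathrm{SD}_y$ (a flag
  switches to full-posterior ROPE), an index of effect negligibility.

The ROPE scale follows the model's link: the raw response SD for the
Gaussian SES model, the SD of `log1p(richness)` for the count model (so a
log-scale slope is compared against a log-scale yardstick), and the SD of
the logit response for the beta model. Prediction-scale summaries (the
difference-of-differences below) use the raw response SD instead. Percent
changes per SD of elevation are computed per draw as
$(\exp\beta - 1)\cdot 100$, with the ROPE bound mapped through the same
transform.

## Hypothesis contrasts

* **H I / H III:** pairwise differences of zone cell means.
* **H II:** the averaged elevation effect — per draw, the mean over the
  five stages of the stage-specific elevation slope (baseline slope for
  gap, baseline plus interaction for the others) — then the percent change
  per SD of elevation.
* **H IV:** richness is predicted for every stage at each zone's central
  elevation (random intercepts marginalized at zero); per zone the
  absolute gap $d_z(s) = |\hat y_z(s) - \hat y_z(\mathrm{optimum})|$ is
  formed, and the difference-of-differences
  $d_{\mathrm{submontane}}(s) - d_{\mathrm{montane}}(s)$ and
  $d_{\mathrm{submontane}}(s) - d_{\mathrm{subalpine}}(s)$ asks whether
  stage structure is stronger at low elevation. Adding a constant to all
  predictions of one zone leaves its gaps unchanged, a property the tests
  assert.

# The synthetic metacommunity generator

The generator decouples the three quantities the SES must disentangle:

1. **True niche breadth.** Each species draws per-zone stage-affinity
   weights $w \sim \mathrm{Dirichlet}(\kappa_z \mathbf{1}_5)$: small
   $\kappa$ gives specialists, large $\kappa$ generalists.
2. **Occupancy.** A species' per-plot occurrence probability at its
   preferred stages scales with a log-normally spread occupancy rate
   (default spread 1 on the log scale), so occupancies span rare to
   ubiquitous — reproducing the occupancy–breadth confound that the null
   model must remove (and the tests confirm it does).
3. **Richness trends.** Occurrence probability is multiplied by
   $\exp(\beta_{\mathrm{elev}} \cdot \mathrm{elev}_z)$ and a five-vector of
   stage multipliers, entering on the log scale so the downstream
   negative-binomial model is well specified.

Occurrence is then an independent Bernoulli per plot and species, with
probabilities clipped to $(0, 0.99]$. Study designs are generated at the
canonical geometry: 5 stages x 3 zones x 10 replicates = 150 circular
plots of 500 m² (radius 12.62 m), elevations uniform within zone bands
(605–850, 850–1400, 1400–1725 m), coordinates rejection-sampled around
zone cluster centres until all pairwise distances are at least 125 m, and
spatial groups assigned by complete-linkage clustering of the coordinates.

Named scenarios fix the study conditions used throughout the tests:
`H1_gradient` ($\kappa$ = 0.1 / 1 / 10 from submontane to subalpine, 250
species, occupancy 0.2), `null_uniform` (effectively uniform affinities,
$\kappa = 10^6$, 500 species — every downstream contrast centred on zero),
`U_shape` (stage multipliers 1.6 / 0.7 / 0.6 / 0.7 / 1.6), and
`arthropod_decline` (elevation log-slope −0.175 per SD, i.e. about −16%
richness per SD). These parameter values are conventions chosen to
represent, respectively, a strong specialization gradient, a structureless
community, the early/late-stage richness excess familiar from forest
succession, and an arthropod-like elevational decline; real occupancy
distributions are not estimated from any dataset.

What the generator deliberately does **not** emulate: spatially
autocorrelated occupancy fields, phenology beyond a constant sampling-day
column, abundances, and species interactions. Passing tests therefore
demonstrate that the pipeline recovers known structure of this generative
family — not that the models are adequate for any particular field
dataset.

# Numerical choices and degenerate inputs

* Null draws with `sd(B_null) < 1e-12` mark a species excluded (exact-zero
  variation up to floating noise).
* `zscore()` refuses constant vectors; beta responses outside the open
  unit interval are shrunk as above; two-empty-plot Jaccard pairs are
  dropped, not imputed.
* Draw-based summaries require at least 1000 draws; defaults use 4000.
* Master-seed discipline: every random stage derives its seed
  deterministically from the master seed and the stage/taxon labels
  (32-bit safe), so runs are bit-reproducible and adding a taxon never
  changes another taxon's results. R's default Mersenne-Twister generator
  is used throughout, including inside the C++ trade loops (via R's
  `unif_rand`).
* Problem sizes used by the validation suite: 500-species null scenario at
  500 nulls for the SES centring check; 20 seeds per scenario for the
  recovery and calibration checks; 10^4 draws for the null-model
  uniformity test. These sizes give Monte-Carlo error comfortably below
  the asserted tolerances.

# Known limitations

* **Pseudoreplication in zone-level inference on plot means.** Every plot
  of a zone averages SES values of largely the same species, and each
  species contributes one SES value per zone. Zone means therefore carry a
  shared, species-level noise component (about 0.03–0.08 SES units per
  zone under the structureless scenario) that does not shrink with the
  number of plots, while the plot-level Gaussian model sees only
  between-plot variation (zone-mean standard errors near 0.015 at 50
  plots). Confident zone contrasts (pd > 0.975) therefore occur in well
  over half of structureless simulations — far above the nominal rate. The
  Monte-Carlo error of the null model itself is negligible by comparison
  (about 0.003 at 500 nulls). In practice this means pd for zone contrasts
  of mean SES should be read as evidence about *this realized community*,
  not about the generating process; genuinely strong gradients (the
  `H1_gradient` scenario) are nevertheless recovered essentially always.
  A species-level hierarchical model would propagate this uncertainty but
  is a different estimand and out of scope here.
* The dispersion of a negative-binomial fit sits at its boundary when the
  data are underdispersed (synthetic richness built from sums of
  independent Bernoullis often is); the conditional coefficients remain
  valid, but `glmmTMB` warns and the dispersion draws should not be
  interpreted.
* The spatial-group random intercept is a deliberate simplification of a
  full spatial Gaussian process; it absorbs cluster-level correlation but
  no smooth spatial trend.
* MCMC backends, priors, and model-comparison criteria are out of scope;
  the normal approximation is exact only asymptotically and can misstate
  tail probabilities for small zones.
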