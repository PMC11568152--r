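# stagespec

Habitat specialization and biodiversity along forest development and
elevation.

`stagespec` is for community ecologists analysing plot-by-species
incidence data from crossed habitat × climate designs — here, five forest
developmental stages (gap, establishment, optimum, plenter, terminal)
replicated across three elevational zones (submontane, montane,
subalpine). It tests the prediction chain of the altitudinal-niche-breadth
hypothesis: specialization, species richness, and between-stage beta
diversity should all weaken with elevation.

The core statistic is a standardized effect size of habitat
specialization. For each species and zone, niche breadth is the reciprocal
Simpson index of its proportional use `p_i` of the five stages,

    B = 1 / Σ_i p_i²,        B ∈ [1, 5]

and is standardized against a fixed-margin null model (curveball
randomization of the zone's species × plot matrix, preserving every
species' occupancy and every plot's richness, 500 independent null
communities by default):

    SES = −(B_obs − mean(B_null)) / sd(B_null)

sign-flipped so that larger SES = more specialized, and averaged over the
species present at each plot. The fixed margins correct the confound that
species with more occurrences use more stages by chance. Around this
sit per-plot richness, cross-stage pairwise Jaccard dissimilarity, and a
draw-based inference layer (Gaussian location-scale, negative-binomial and
beta regressions via glmmTMB) summarized by MAP, 95% HDI, probability of
direction (pd) and ROPE percentage, with the zone contrasts, averaged
elevation effects, percent changes per SD of elevation, and
difference-of-differences used to test the four hypotheses. A synthetic
metacommunity generator (Dirichlet stage affinities × Bernoulli occupancy)
provides data with known ground truth for end-to-end validation.

## Worked example

Run the whole pipeline on a simulated community with a strong
specialization gradient (Dirichlet concentration 0.1 / 1 / 10 from
submontane to subalpine):

```r
library(stagespec)
cfg <- run_config(scenario = "H1_gradient", n_null = 200,
                  n_draws = 2000, seed = 42)
rep <- run_pipeline(cfg)

rep$descriptives
#>         taxon n_species mean_stages_used mean_plot_richness mean_cross_stage_jaccard
#> 1 H1_gradient       249             4.68               61.7                    0.801

rep$taxa$H1_gradient$h1   # H I: zone contrasts of mean plot SES
#>                     name   map hdi_low hdi_high pd rope_pct
#> 1   submontane - montane 0.946   0.869     1.02  1        0
#> 2 submontane - subalpine 3.534   3.474     3.60  1        0
#> 3    montane - subalpine 2.596   2.524     2.66  1        0

rep$taxa$H1_gradient$h2   # H II: averaged elevation effect on richness
#>                    name    map   hdi_low hdi_high    pd rope_pct
#> 1    averaged_elevation 0.0628 -0.000564    0.125 0.969     8.73
#> 2 percent_change_per_sd 6.4459 -0.056407   13.359 0.969     8.73
```

Reading the output: specialization is much higher in the submontane than
the subalpine zone (MAP of the contrast 3.5 SES units, 95% HDI [3.47,
3.60], pd = 1, 0% of the HDI in the region of practical equivalence) —
the gradient injected by the scenario, recovered by the pipeline. The
richness model finds no convincing elevation trend (pd 0.97, MAP +6.4%
per SD of elevation) — none was injected. `rep$taxa$...$h3` and `$h4`
hold the beta-diversity contrasts and the difference-of-differences
table, and `$exclusions` reports the species lost to zero null variance
(31 of 736 species × zone records here) and the plot pairs dropped for
empty unions (0 here).

Lower-level entry points: `generate_design()` / `generate_communities()`
(simulation), `ses_specialization()` / `plot_mean_ses()` (specialization),
`species_richness()` / `dissimilarity_table()` (diversity),
`fit_ses_model()` / `fit_richness_model()` / `fit_beta_model()`,
`summarize_draws()`, `contrast()`, `averaged_elevation_effect()`,
`predict_richness()`, `difference_of_differences()` (inference). A thin
command-line wrapper with `simulate` / `specialize` / `diversity` / `run`
subcommands is installed at `inst/cli/stagespec.R`. The methods vignette
(`vignettes/methods.Rmd`) documents the models, the generator, and the
design choices.

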