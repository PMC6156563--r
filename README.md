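# occusens

Climate sensitivity of dynamic species occupancy.

`occusens` is for ecologists and biostatisticians who monitor communities
with repeat-visit detection/non-detection surveys (amphibian call surveys,
trapping grids, stream reaches, wetland visits) and want to know how
year-to-year climate variability drives local colonization and
persistence — and what recent climate *trends* therefore imply for
occupancy and local species richness.

## The model

Occupancy of species *k* at site *i* in study area *j* follows an
auto-logistic dynamic occupancy model with imperfect detection:

    logit(ψ_ijk,t+1) = α_jk + δ_jk · z_ijkt + βᵀ X_ijkt
    α_jk ~ Normal(μ_α, σ_α),   δ_jk ~ Normal(μ_δ, σ_δ)
    logit(p_jkt)     ~ Normal(μ_p, σ_p)

so colonization is γ = logit⁻¹(α + βᵀX), persistence is
φ = logit⁻¹(α + δ + βᵀX), and each visit detects a present species with
probability p. X holds five per-site annual climate anomalies — winter
severity (air-freezing index), peak 10-day temperature, winter snow-water
equivalent, 3-month SPEI at peak breeding, summer soil moisture — each
standardized by the site's 30-year mean and SD. The global model
interacts the climate mains with ecoregion, habitat, climate normals,
taxon and life-history traits, with a Bayesian LASSO on the interaction
block. Latent occupancy is marginalized exactly by the forward algorithm
(C++ core) and sampled by adaptive MCMC with split-chain Gelman–Rubin
diagnostics.

From a fitted model the package derives the equilibrium occupancy
ψ\* = γ/(γ + 1 − φ) and its sensitivity to each climate variable by the
chain rule,

    dψ/dX* = (1/ψ*) Σ_{T∈{γ,φ}} (dψ*/dT)(dT/dX*),

attributes 30-year occupancy trends to climate trends
(dψ/dt = Σ (dψ/dX\*)(dX\*/dt), plus a direct 30-year simulation
cross-check), and stress-tests the deterministic/stationary assumptions
behind the sensitivity estimator on a 36-scenario Monte-Carlo grid.
Supporting modules impute missing life-history traits with a phylogenetic
latent-factor model and generate fully synthetic studies (surveys,
weather, traits, phylogenies) with known ground truth.

## Worked example

Simulate a small two-area study with known climate effects
β = (0.4, −0.4, 0.2, 0, 0), fit the model, and derive sensitivities and
expected trends:

```r
library(occusens)

cfg <- simConfig(n_study_areas = 2, n_species = 4, n_sites_per_area = 25,
                 n_years = 8, n_visits = 3,
                 true_beta = c(0.4, -0.4, 0.2, 0, 0), seed = 42)
study <- simulateStudy(cfg)
study$survey
#> SurveyData: 4800 visit records | 2 study areas, 50 sites, 4 species, years 1-8
#>   naive detection frequency: 0.338
#>   simulated data: generating truth attached

design <- buildDesign(study$climate, study$sites, study$species,
                      interactions = FALSE)
fit <- fitOccupancy(study$survey, design,
                    mcmcControl(n_iter = 4000, n_burn = 2000), seed = 1)
fit
#> OccupancyFit: 3 chains x 4000 kept draws of 37 parameters
#>   iterations: 4000 after 2000 burn-in, thin 1
#>   max split R-hat: 1.0255 (converged)

posteriorSummary(fit)[1:5, ]
#>     parameter   mean    sd     lo     hi rhat
#> 1    beta:afi  0.407 0.080  0.254  0.565    1
#> 2 beta:tmax10 -0.490 0.087 -0.667 -0.330    1
#> 3    beta:swe  0.182 0.079  0.032  0.337    1
#> 4   beta:spei -0.134 0.081 -0.298  0.025    1
#> 5   beta:soil -0.043 0.078 -0.201  0.109    1
```

The three nonzero climate effects are recovered (0.41, −0.49, 0.18
against truth 0.4, −0.4, 0.2) and the two null effects have credible
intervals covering zero. Sensitivities per species × study area ×
variable, evaluated at each site's 30-year mean climate:

```r
sens <- posteriorSensitivity(fit)
head(sensitivityTable(sens), 5)
#>   species study_area variable psi_star sens_mean sens_lo sens_hi included
#> 1    sp01        A01      afi     0.83     0.109  0.0402  0.2047     TRUE
#> 2    sp01        A01   tmax10     0.83    -0.132 -0.2429 -0.0476     TRUE
#> 3    sp01        A01      swe     0.83     0.049  0.0068  0.1137     TRUE
#> 4    sp01        A01     spei     0.83    -0.036 -0.0978  0.0064     TRUE
#> 5    sp01        A01     soil     0.83    -0.012 -0.0604  0.0311     TRUE
```

A sensitivity of 0.109 means a +1 SD shift in mean winter severity raises
this population's equilibrium occupancy by about 10.9% of its current
value. Combining sensitivities with climate trends (here: winters warming
at −0.02 SD/yr, summers +0.015 SD/yr, snow −0.01 SD/yr) gives expected
climate-driven occupancy trends per population:

```r
slopes <- setNames(c(-0.02, 0.015, -0.01, 0, 0), climateVariables())
trends <- attributeTrends(sens, slopes)
head(trends[, 1:5], 3)
#>   species study_area psi_star expected_trend pct_annual
#> 1    sp01        A01     0.83        -0.0039      -0.46
#> 2    sp01        A02     0.43        -0.0059      -1.36
#> 3    sp02        A01     0.44        -0.0061      -1.38
attr(trends, "frac_positive")
#> [1] 0
```

Under this (deliberately pessimistic) climate scenario every simulated
population is expected to decline, at roughly 0.5–1.4% of its occupancy
per year.

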