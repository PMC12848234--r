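# photocap

Statistical and optimality modelling of leaf photosynthetic capacity.

`photocap` is an R package for analysing site-level variability in the
maximum RuBisCO carboxylation rate of C3 leaves, V<sub>c,max</sub>
(µmol CO₂ m⁻² s⁻¹) — the quantity that terrestrial biosphere models use to
set photosynthetic capacity. It is written for plant ecophysiologists and
carbon-cycle modellers who want to separate two drivers of global
V<sub>c,max</sub> variability:

1. **Enzyme kinetics** — the instantaneous temperature response of RuBisCO,
   modelled with a peaked (modified) Arrhenius function whose entropy term
   acclimates linearly to growing-season temperature T<sub>g</sub>:

   V<sub>c,max</sub>(T₁) = V<sub>c,max</sub>(T₀) · f(T₀, T₁), with

   f(T₀,T₁) = exp[H<sub>a</sub>(T₁−T₀) / (R·T₀ᴷ·T₁ᴷ)] ·
   (1 + exp[(T₀ᴷΔS − H<sub>d</sub>)/(R·T₀ᴷ)]) /
   (1 + exp[(T₁ᴷΔS − H<sub>d</sub>)/(R·T₁ᴷ)]),
   ΔS = −1.07·T<sub>g</sub> + 668.39,

   with H<sub>a</sub> = 71 513 J mol⁻¹, H<sub>d</sub> = 200 000 J mol⁻¹.

2. **The amount of active RuBisCO** — indexed by V<sub>c,max25</sub>
   (capacity standardized to 25 °C), modelled either empirically (OLS on
   climate, soil and leaf-trait covariates) or with an eco-evolutionary
   optimality model: least-cost optimal χ = c<sub>i</sub>/c<sub>a</sub>
   coupled with coordination of electron transport and carboxylation,
   maximizing net gain A<sub>j</sub> − c·J<sub>max</sub>. The unit carbon
   cost c is either globally constant (0.053) or a linear function of site
   covariates, c<sub>i</sub> = β₀ + Σ<sub>j</sub> β<sub>j</sub>x<sub>ij</sub>,
   calibrated by a genetic algorithm under repeated 5-fold cross-validation.

Model assessment uses r², bias, RMSE and AIC = 2k + n·log(RMSE²);
variable importance uses VIF pruning, exhaustive corrected-AIC subset
selection with Akaike weights (0.8 cutoff) and partial regressions for the
statistical track, and Sobol'–Saltelli variance partitioning for the
optimality track. A synthetic-site generator with known ground truth makes
every stage testable end to end.

## Worked example

```r
library(photocap)

# a synthetic world of 120 sites whose Vcmax25 is linearly driven by leaf N,
# VPD, soil pH, precipitation and elevation
sim <- generate_sites(generator_config(n_sites = 120), seed = 1)
sites <- aggregate_site_means(sim$table)

# kinetics-only model: one global-mean Vcmax25 + temperature response
m1 <- vcmax_model(sites, method = "kinetics")
print(m1)
#> Vcmax model -- method: kinetics
#>   120 sites
#>   Vcmax_Tg : r2 = 0.755  bias = -0.032  RMSE = 8.338  AIC = 511.0  (n = 120, k = 1)
#>   Vcmax_25 : r2 = NA  bias = -0.000  RMSE = 15.379  AIC = 657.9  (n = 120, k = 1)

# kinetics + covariate regression under 5-fold x 20-rep ensemble CV
m2 <- vcmax_model(sites, method = "empirical", cv = cv_scheme(5, 20, seed = 2))
m2$metrics$vcmax_tg$r2
#> [1] 0.9067854
```

The kinetics-only model explains about 76 % of V<sub>c,max</sub> variability
at growing-season temperature here (r² = 0.755): temperature scaling alone
carries most of the signal, as it does in field data. Adding the covariate
regression for V<sub>c,max25</sub> lifts r² to 0.91 and cuts the RMSE from
8.3 to 5.2 µmol m⁻² s⁻¹ — the covariate signal the generator planted. An
`optimality`-method fit predicts V<sub>c,max</sub> from five aboveground
drivers with no fitting at all, and `optimality_dynamic` calibrates the
edaphically varying cost c<sub>i</sub>:

```r
cmp <- run_comparison(sites, scenarios = "edaphic", cv = cv_scheme(5, 5),
                      seed = 3)
print(cmp)   # metrics table for all model tracks + cross-model agreement
```

Sensitivity of the optimality-constant model over broad global input
ranges:

```r
sensitivity_optimality(input_ranges(), n_base = 2^13, seed = 1)
#> First-order Sobol' variance partition (N = 8192, total var = 5288)
#>   variable      S1 contribution_pct
#>        t_g 0.40232          45.6812
#>        par 0.46844          53.1895
#>        vpd 0.00497           0.5643
#>         ca 0.00022           0.0249
#>  elevation 0.00476           0.5401
```

PAR and growing-season temperature dominate modelled V<sub>c,max25</sub>
variance; VPD, CO₂ and elevation contribute little.

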