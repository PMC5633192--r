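# welanopt

Surrogate-assisted optimization of Welan gum fermentation conditions.

Welan gum is a microbial exopolysaccharide (secreted by *Alcaligenes*
strains) whose fermentation yield depends on nine controllable culture
conditions: glucose, yeast extract, KH₂PO₄, MgSO₄, liquid volume, pH,
temperature, rotational speed and inoculation amount. Screening that
nine-dimensional space in the lab is slow and expensive. `welanopt` is for
bioprocess scientists and method developers who instead want to:

1. fit an **ε-support-vector regression surrogate** mapping conditions to
   yield,

   f(x) = Σᵢ (αᵢ − αᵢ\*) K(xᵢ, x) + b,  K(xᵢ, xⱼ) = exp(−‖xᵢ − xⱼ‖² / σ²),

   with the dual quadratic program solved by a built-in
   sequential-minimal-optimization solver (box constraints 0 ≤ αᵢ, αᵢ\* ≤ C,
   equality constraint Σ(αᵢ − αᵢ\*) = 0), the penalty c and kernel parameter
   g = 1/σ² chosen by grid-searched k-fold cross-validated MSE, and accuracy
   reported as the squared Pearson correlation r² on a held-out split;

2. search the bounded condition space with a **real-coded adaptive genetic
   algorithm**: roulette (fitness-proportional) selection, segment crossover
   with generation-decaying probability Pc(t) = max(Pc_max·2^(−t/T_Gen),
   Pc_min), and single-locus mutation whose probability
   exp(−|(f_max−fᵢ)/f_max|)·(1+t/T_Gen)⁻¹·Pm_max adapts to each individual's
   fitness gap, floored at Pm_min.

The package also ships yield-level stratified splitting, min–max
normalization with JSON sidecars, a synthetic fermentation-surface
generator for end-to-end testing without data, model serialization, and a
command-line interface (`inst/cli/welanopt.R`).

## Worked example

```r
library(welanopt)

# a study-sized simulated dataset (67 records, 0.5 g/L noise), full pipeline:
# stratified 70/30 split -> normalize -> grid search -> SVR fit -> GA search
cfg <- pipeline_config(synth_spec(n = 67, noise_sd = 0.5, seed = 1),
                       split_seed = 1)
report <- run_pipeline(cfg)
report
#> Welan gum condition-optimization report
#>   test-set r^2: 0.9716 (n_test = 21)
#>   selected c = 4, g = 0.5 (sigma = 1.41421), CVmse = 0.0118169
#>   predicted maximal production: 42.8562 g/L (best observed 37.1417 g/L, +15.4%)
#>   predicted optimal conditions:
#>            glucose              yeast             kh2po4              mgso4
#>            50.0867             3.4323             5.2807             0.3644
#>      liquid_volume                 ph        temperature   rotational_speed
#>            46.0926             7.6068            31.9501           187.2335
#> inoculation_amount
#>             5.2040
```

The report reads: the surrogate explains 97% of the held-out yield variance
(r² = 0.9716 on the 21 test records); cross-validation selected penalty
c = 4 and kernel parameter g = 0.5; the GA's best medium is predicted to
yield 42.86 g/L, 15.4% above the best simulated record. The generator's true
optimum for this seed peaks at 42 g/L near (glucose 55, yeast 3, …), so the
search has found the right region — see the vignette for how precisely such
optima can be trusted at n = 67.

The 25 published fermentation records ship as plain-text fixtures:

```r
raw <- read_table(system.file("extdata", "table1_raw.csv", package = "welanopt"))
table(assign_level(raw$production))
#>  low  mid high
#>    8   17    0

report_improvement(31.65, 30.63)   # predicted vs best observed yield, %
#> [1] 3.3
```

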