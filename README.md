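# nhpikit

Quantifying **natal habitat preference induction** (NHPI) — the tendency of
dispersing animals to select habitats resembling their natal one — from GPS
tracking data and habitat rasters, with explicit attention to variation
*between* and *within* individuals.

`nhpikit` implements the full chain for an individual-based step-selection
analysis of NHPI:

1. **Natal habitat characterization** — habitat composition (buffer-mean
   elevation + six land-cover class proportions) within a 2 km territory
   buffer around each nest; a scaled PCA over the cohort's natal vectors;
   complete-linkage (furthest-neighbour) clustering of natal territories
   into habitat types.
2. **Step-selection design** — tracks regularized to hourly fixes with
   burst handling, a 35 m/s speed filter, matched strata of 1 used + 10
   available steps (exponential step lengths fitted to the population,
   uniform turning angles), and two covariates at every step end-location:
   the habitat **dissimilarity index**
   `d_i = sqrt((x_o - x_i)^2 + (y_o - y_i)^2)` (Euclidean distance to the
   natal territory in PC1/PC2 space) and the **distance to the natal nest**
   (km).
3. **Conditional logistic regression** per individual-year (Newton
   iteration on the conditional log-likelihood, written in-package), plus
   phase-interaction and year-interaction variants. NHPI is the negative of
   the dissimilarity coefficient.
4. **Six variation metrics** on the coefficients — average, specialization
   (mean magnitude), heterogeneity (SD), phase consistency (mean absolute
   change), reversal (sign-switch proportion), interannual consistency —
   with uncertainty propagated by simulating 1000 replicates of every
   coefficient from `Normal(x, SE)`, and ANOVA/Tukey group comparisons.
5. **Validation** — five-fold cross-validation scoring held-out strata by
   the used step's rank (Spearman rank-frequency correlation).

A first-class **synthetic-data module** generates landscapes on an
elevation gradient, nests stratified across it, and hourly trajectories
from a known step-selection process whose covariates are computed by the
same code the analysis uses — so every stage is testable against ground
truth without downloading anything.

## Worked example

```r
library(nhpikit)

landscape <- generate_landscape(seed = 1)           # 12 x 12 km, 100 m cells
nests     <- place_nests(landscape, 12, seed = 2)   # >= 2 km apart
natal     <- assign_natal_habitats(landscape, nests)
natal$pca
#> <nhpi_pca> 7 variables, 2 retained axes
#>   explained: 70.6%, 20.8%

ind <- list(id = "a", nest = c(nests$x[1], nests$y[1]),
            beta_dissim = -1.5, beta_dist = -0.05, n_steps = 300)
track <- simulate_track(landscape, natal$pca, ind, step_rate = 1/800, seed = 3)

steps  <- build_steps(track)
rate   <- fit_step_length_distribution(steps$length)
design <- build_design(steps, landscape, natal$pca, natal$pca$scores[1, ],
                       nest = ind$nest, rate = rate, seed = 4)
design <- standardize_design(design)
fit_clogit(design, c("dissimilarity_z", "distance_z"))
#> <nhpi_clogit> 299 strata, logLik -667.32
#>             term        beta        se
#>  dissimilarity_z -0.93269861 0.1169775
#>       distance_z -0.02055677 0.2914660
```

The fitted dissimilarity coefficient −0.93 (NHPI = +0.93) recovers the
simulated raw-scale coefficient −1.5, which on this dataset's standardized
scale is −1.03: this individual selects natal-like habitat. The metric
layer then summarizes many such coefficients:

```r
coefs <- simulate_coefficients(40, mean = 0.6, sd = 0.8, se_scale = 0.2, seed = 5)
nhpi_average(coefs$x); nhpi_specialization(coefs$x); nhpi_heterogeneity(coefs$x)
propagate_uncertainty(coefs, n_sim = 1000, seed = 6)
```

`run_pipeline(pipeline_config(out_dir, seed))` orchestrates the whole chain
(synthetic or from CSV/ASCII-grid inputs) and writes every stage product
plus a manifest; reruns with the same seed are byte-identical.

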