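# ivstruct

Spatially structured intraspecific variability in tree growth.

## The problem

Field studies of plant communities consistently find large intraspecific
variability (IV): conspecific individuals differ widely in growth, traits
and other performance proxies. Community models usually encode that
variability as independent random draws around a species mean — implying
that conspecific individuals would perform differently *in the same
environment*, which blurs species differences and muddles inferences about
coexistence. An alternative explanation is dimensional: individuals respond
to many environmental axes (light, water, nutrients, microclimate, soil
biota, ...) that vary at fine spatial scales, but only one or two of those
axes are ever measured. Species-specific responses to the unmeasured,
spatially autocorrelated axes then surface in our models as large
"individual effects" — IV that is real but environmentally structured, not
intrinsic.

`ivstruct` is a toolkit for studying that mechanism, aimed at community
ecologists and forest biometricians. It provides:

* a **virtual landscape experiment** — a deterministic "perfect knowledge"
  attribute model on spatially autocorrelated environmental fields, paired
  with the "imperfect knowledge" hierarchical model an ecologist would fit
  when only one covariate is observed;
* **hierarchical Bayesian growth models** (JAGS backend) for clonal trials
  (block / genotype / date / individual components) and multi-species
  forest inventories (species / individual components), with variance
  partitioning, convergence diagnostics and posterior predictive
  envelopes;
* **census processing** — annualized and mean individual growth, the
  standard filtering rules, Moore-neighbourhood competition indices;
* **spatial diagnostics** — Moran's I screening per species, intra- vs
  interspecific semivariance comparison (Mann-Whitney), and empirical
  semivariograms;
* **synthetic generators** for clonal trials and forest inventories with
  known truth, including an `iv_mode` switch contrasting environmentally
  structured against i.i.d. individual effects at matched variance.

## The models

The perfect-knowledge attribute of individual `i` of species `j` at date
`t` on an `N`-dimensional landscape:

$$\ln Y_{ijt} = \beta_{0,j} + \beta_{1,j}\ln X_{1,ijt} + \beta_{2,j}X_{2,ijt}
  + \cdots + \beta_{N,j}X_{N,ijt}$$

(no noise — conspecifics are clones). The imperfect-knowledge model fitted
to `{Y, X1}` only:

$$\ln Y_{ijt} = \beta'_{0,j} + b_{0,i} + \beta'_{1,j}\ln X_{1,ijt}
  + \varepsilon_{ijt}, \quad b_{0,i} \sim N(0, V_{b_j}),
  \quad \varepsilon_{ijt} \sim N(0, V_j).$$

Clonal-trial growth (z-scored `ln(G + 1)`, diameter `D` and competition `C`
covariates):

$$z_{it} = \beta_0 + b_{0,b} + b_{0,g} + b_{0,t} + b_{0,i}
  + \beta_1 \ln D_{it} + \beta_2 \ln C_{it} + \varepsilon_{it}$$

Forest-inventory growth (z-scored `ln(G + 2)`):

$$z_{ijt} = \beta_0 + b_{0,j} + b_{0,i} + \beta_1 \ln D_{ijt}
  + \varepsilon_{ijt}$$

Each random effect's variance is reported as a percentage of the summed
components (`partition_variance()`). Spatial structure is assessed
separately: Moran's I with binary within-100-m same-plot weights
(one-tailed, randomization variance), and the semivariance — the mean
squared pair difference, without the conventional 1/2 factor — compared
between conspecific and heterospecific pairs per species.

## Worked example

Partition the growth variance of a clonal *Eucalyptus* trial among its
random effects (posterior-mean variance components in, percentages out):

```r
library(ivstruct)
partition_variance(c(V_i = 0.23, V_b = 0.06, V_g = 0.13, V_t = 1.3, V = 0.51))
#>  component variance percentage
#>        V_i     0.23     10.31%
#>        V_b     0.06      2.69%
#>        V_g     0.13      5.83%
#>        V_t     1.30     58.30%
#>          V     0.51     22.87%
```

The individual component (10.31%) is almost twice the genotype component
(5.83%): even among clones in a homogenised plantation, individuals differ
far more than genetics explains — the signature of micro-environmental
variation.

Run the full forest pipeline on a synthetic inventory with environmentally
structured IV (2,500 trees, 25 species, latent fields with a 30 m range):

```r
cfg <- read_run_config(overrides = list(mode = "forest", seed = 1))
out <- run_pipeline(cfg)
out$moran_screen
#> <iv_moran_screen> 25 species, 25 tested: 64.0% significant (84.9% of individuals)
out$semivar_comparison
#> <iv_semivar_comparison> 25 species tested (alpha 0.05)
#>  classification n_species pct_species pct_individuals
#>     intra<inter        17          68        88.52657
#>              ns         8          32        11.47343
#>     intra>inter         0           0         0.00000
```

A majority of species show significantly positive spatial autocorrelation
in mean individual growth, and for 68% of species (88.5% of individuals)
conspecific neighbours are significantly more similar than heterospecific
neighbours — growth is spatially structured and species-specific, exactly
what environmentally driven IV predicts. Rerunning with
`forest = list(iv_mode = "unstructured", sigma2_species = 0)` generates the
same variance as unstructured noise, and both detection rates collapse to
their null levels.

Plotting helpers (`autoplot()` on semivariogram sets, variance partitions
and predictive envelopes) and broom-style `tidy()` / `glance()` methods on
all fitted models round out the interface.

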