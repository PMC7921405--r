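# fjordfe

Benthic iron cycling in glaciated Arctic fjords: reactive-continuum
dissolution kinetics of sediment iron (oxyhydr)oxides, sequential-HCl iron
speciation, radiotracer sulfate-reduction rates, and exponential
transect-gradient analysis — with a deterministic synthetic-data generator
and an end-to-end analysis pipeline.

## Scientific problem

Meltwater from tidewater glaciers delivers large amounts of fresh,
poorly crystalline iron (oxyhydr)oxide ("FeA") to fjord sediments. Whether
that iron ever reaches the ocean as bioavailable dissolved or nanoparticulate
Fe depends on benthic recycling: microbial and chemical reduction of the
oxide pool in the sediment. Two laboratory observables constrain this:

1. **Time-course dissolution extractions.** A sediment aliquot is exposed to
   a reductant (chemical assay: ascorbate; microbial assay: an iron-reducing
   culture, run in triplicate plus an uninoculated control), and dissolved
   Fe is measured on a logarithmically thickening schedule out to 32 h. The
   shape of the cumulative-release curve encodes the *reactivity spectrum*
   of the oxide pool.
2. **Sulfate reduction rates (SRR).** Whole-core incubations with a
   carrier-free ³⁵S–sulfate tracer give the competing terminal metabolism,
   depth-resolved and depth-integrated.

Down-fjord transects of the fitted parameters test whether proximity to the
glacier controls the size and lability of the reducible iron pool.

## Model

Dissolution is described by a reactive continuum: the oxide pool is a
mixture of sites whose first-order rate constants follow a Gamma
distribution. The undissolved mass at time *t* is

```
M(t) = M0 * (a / (a + t))^v
```

and the instantaneous dissolution rate is

```
J(t) = (v / a) * M0 * (M(t) / M0)^(1 + 1/v)
```

with `M0` the initial extractable amount (µmol Fe per g dry sediment), `a`
(s) the lifetime scale of the most reactive sites, and `v` (dimensionless)
the shape of the reactivity distribution. Derived quantities:

| quantity | formula | meaning |
|---|---|---|
| reducibility | `v / a` (s⁻¹) | initial specific rate of the pool |
| composition | `1 + 1/v` | apparent reaction order; heterogeneity |
| lability | `(v / a) * M0` | initial absolute release rate |

`M0` is fixed *operationally* before the kinetic fit: the maximum cumulative
Fe released by the end of the extraction (the plateau rule), with a
stability flag when the last points have not levelled off. Only `a` and `v`
are then estimated, by Levenberg–Marquardt least squares in log-parameters
(`minpack.lm`). SRR follows the standard tracer formula
`SRR = [SO4] * phi * a_TRIS / (a_TRIS + a_SO4) * 1.06 / t`, and transect
gradients are log-linear fits `ln(value) ~ distance`.

## Worked example

Fit a single dissolution curve, first noiseless (exact recovery), then with
realistic 5 % assay noise:

```r
library(fjordfe)

truth <- rcm_params(m0 = 30, a = 5000, v = 1.5)
sched <- extraction_schedule(32 * 3600)   # 0, 300, 600, 1200, ... seconds

# noiseless curve: the fit recovers a and v to machine precision
exact <- dissolution_curve(sched, rcm_dissolved(truth, sched),
                           dry_mass = 0.75, volume = 0.1)
fit_rcm(exact, m0 = 30)
#> <rcm_fit> M0 = 30 (source: fixed), a = 5000 s, v = 1.5
#>   n = 27, RSS = 7.57e-29, v/a = 0.0003 /s, 1+1/v = 1.67

# 5% multiplicative assay noise, plateau M0 rule as in the field workflow
tab <- simulate_dissolution(truth, schedule = sched, noise_sd = 0.05, seed = 42)
curve <- build_dissolution_curve(tab$time_s, tab$conc_uM,
                                 volume = 0.1, dry_mass = 0.75)
fit <- fit_rcm(curve)
fit
#> <rcm_fit> M0 = 32.49 (source: plateau:max), a = 1803 s, v = 0.6912
#>   n = 27, RSS = 90.2, v/a = 0.000383 /s, 1+1/v = 2.45
derive_params(fit)
#> # A tibble: 1 × 3
#>   reducibility composition lability
#>          <dbl>       <dbl>    <dbl>
#> 1     0.000383        2.45   0.0125
```

Note the parameter correlation typical of continuum fits: the individual
`a` and `v` move far under noise while the ratio `v/a` (here 3.83e-4 vs the
true 3e-4) and the lability stay well constrained — these ratios, not raw
`a` and `v`, are the quantities compared across stations.

Tracer and speciation arithmetic:

```r
srr_from_tracer(sulfate_mM = 28, porosity = 0.8,
                a_tris = 100, a_so4 = 99900, t_days = 0.5)
#> [1] 47.488   # nmol cm-3 d-1

hcl_speciation(c(fe2 = 40, fe_total = 100), c(fe2 = 100, fe_total = 500))
#> # A tibble: 2 × 5
#>   step        fe2 fe_total   fe3 clipped
#> 1 0.5 M HCl    40      100    60 FALSE
#> 2 6 M HCl     100      500   400 FALSE

depth_integrate(rate_profile(depth_top = 0:2, thickness = rep(1, 3),
                             rate = c(10, 5, 2)))
#> [1] 17   # nmol cm-2 d-1
```

End-to-end pipeline on the built-in demo transect (7 stations over 30 km,
ninefold FeA gradient, 19-fold lability gradient):

```r
res <- run_pipeline(run_config(scenario = scenario_config(),
                               out_dir = "demo_out", seed = 1))
pipeline_report(res)
#> RCM fits: 35 vessels, 35 converged, 0 flagged
#> gradient m0 [all]: 0.0725 /km, r2 = 1.000, fold change 8.92, significant
#> gradient lability [all]: 0.0962 /km, r2 = 0.997, fold change 18.8, significant
#> depth-integrated SRR: 115-115 nmol cm-2 d-1 across 7 stations
```

The same run is available from the shell via the bundled CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "fjordfe.R", package = "fjordfe"))')" \
  run-all --out-dir demo_out --seed 1
```

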