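# ccturnover

Residence-time inference from competition ChIP (CC) time courses.

Competition ChIP measures how long a transcription factor stays bound at
each of its chromatin sites. Cells carry a constitutive Myc-tagged isoform
of the factor and an HA-tagged competitor isoform that is induced at
*t* = 0; at sites where the factor exchanges quickly, the HA/Myc ChIP
ratio rises almost as fast as the competitor protein accumulates, while
sites holding the factor for minutes lag visibly behind. This package
turns per-site HA/Myc ratio time courses into per-site residence times and
downstream transcription summaries. It is aimed at groups analysing
genome-scale CC ChIP-seq of general transcription factors (or any
chromatin-binding factor) in yeast-like settings, and at methodologists
who want a fully simulated test bed for turnover estimation.

## The model

Competitor protein induction is described by a Hill curve with integer
coefficient,

```
c_B(t)/c_A = X_P (t/t_half_ind)^n / (1 + (t/t_half_ind)^n),
```

fit to Western-blot ratio series with `n` selected by adjusted R².
Each site follows mass-action competition of the two isoforms for one
binding position, with shared effective on-rate `k_a c_A` and off-rate
`k_d`:

```
dθ_B/dt = k_a c_A (c_B(t)/c_A) (1 − θ_A − θ_B) − k_d θ_B
dθ_A/dt = k_a c_A             (1 − θ_A − θ_B) − k_d θ_A
```

The observable is the occupancy ratio `θ_B/θ_A` (0 at *t* = 0, plateau
`X_P` at late times), obtained from the measured ratio `R(t)` by a
per-site descriptive Hill fit that supplies the amplitude `X_CC` and
background `B` for the scaling `θ_B/θ_A = (X_P/X_CC)(R(t) − B)`. The
residence time is `t_half = ln2 / k_d`. Fits pass the reliability filter
when `Δk_d/k_d < 3` and adjusted R² > 0.7 (strict); sites without a
reliable estimate but whose half-time lag behind the induction curve is
under 2 min are classed *reliably fast* (reported as "< 1 min").
Transcription efficiency is `TE = synthesis rate × residence time`
(mRNA per binding event).

## Worked example

Everything below is simulated, with known ground truth, so the pipeline
can be exercised end to end without any sequencing data:

```r
library(ccturnover)

run <- run_pipeline(run_config(n_sites = 40, seed = 7))
run$induction_fit
#> Competitor induction Hill fit
#>   XP = 0.9621, t_half_ind = 42.05 min, n = 4
#>   adjusted R^2 = 0.9834

glance(run$fits)
#> # A tibble: 1 × 5
#>   n_sites n_estimated n_reliably_fast n_unreliable median_adj_r2
#>     <int>       <int>           <int>        <int>         <dbl>
#> 1      40          10              18           12         0.950

head(run$records, 3)
#> # A tibble: 3 × 5
#>   site_id   class         t_half gene_id   distance
#>   <chr>     <chr>          <dbl> <chr>        <dbl>
#> 1 site_0001 estimated       16.8 gene_0001      -48
#> 2 site_0002 reliably_fast   NA   gene_0002     -237
#> 3 site_0003 estimated       14.3 gene_0003      -42
```

The induction fit recovers the simulated induction (true half-time
43 min, n = 4) from noisy Western-style measurements. Of the 40 sites, 10
get numeric residence times, 18 track the induction curve too closely to
resolve (reliably fast, `t_half` reported missing), and 12 are rejected by
the reliability filter. Each record carries the gene assigned within the
−250..+100 bp promoter window and the signed midpoint–TSS distance.

Per-gene transcription efficiency joins the fits to mRNA synthesis rates:

```r
head(run$summary$te, 3)
#> # A tibble: 3 × 7
#>   site_id   gene_id     rate t_half quartile    te log2_te
#>   <chr>     <chr>      <dbl>  <dbl>    <int> <dbl>   <dbl>
#> 1 site_0001 gene_0001 0.0480  16.8         1 0.805 -0.312
#> 2 site_0003 gene_0003 0.0709  14.3         2 1.02   0.0225
#> 3 site_0008 gene_0008 0.315   21.8         4 6.87   2.78
```

`te` is mRNA produced per binding event; `log2_te` below zero means
several binding events per transcript. `autoplot()` on the fit objects and
`plot_quartile_boxes()` / `plot_te_distribution()` on the summary give the
standard figures.

Lower-level entry points mirror the pipeline stages:
`simulate_experiment()`, `fit_hill_induction()`, `depth_normalize()` /
`scale_ha_to_protein()` / `compute_ratio_table()`,
`assign_regions_to_genes()`, `fit_turnover_sites()`, and
`summarize_by_class()`. The methods vignette
(`vignettes/competition-chip-residence-times.Rmd`) documents the model,
defaults and numerical choices.

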