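---
title: "Estimating chromatin residence times from competition ChIP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating chromatin residence times from competition ChIP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccturnover)
library(dplyr)
```

## The measurement and the model

Competition ChIP measures how long a transcription factor stays bound to a
chromatin site. A diploid strain carries two isoforms of the factor: a
Myc-tagged isoform expressed constitutively, and an HA-tagged competitor
whose expression is switched on at $t = 0$ (galactose induction of a
*GAL1*-driven allele). As competitor protein accumulates, sites that
exchange their factor quickly take up the competitor almost as fast as it is
made, while sites holding the factor for minutes lag behind. The per-site
time course of the HA/Myc ChIP ratio therefore encodes the residence time.

Three coupled pieces of machinery turn ratio time courses into residence
times.

**Competitor induction.** The relative competitor protein level
$c_B(t)/c_A$ is fit to a Hill curve
$$\frac{c_B(t)}{c_A} \;=\; X_P\,
  \frac{(t/t_{1/2\mathrm{ind}})^{n}}{1 + (t/t_{1/2\mathrm{ind}})^{n}},$$
with the coefficient $n$ restricted to integers and chosen by adjusted
$R^2$ over a grid (`fit_hill_induction()`, default grid 1–10). Replicate
Western-blot measurements are pooled as independent, unweighted
observations; whether the original analyses pooled or averaged replicates
is not documented, and pooling uses all information without inventing a
variance model. Typical yeast inductions give half-times around 43 min and
coefficients near 4–5, which is why those are the package defaults for
simulation.

**Site occupancy dynamics.** Each site is modelled by mass-action
competition of the two isoforms for a single binding position, with shared
effective on-rate $k_a c_A$ and off-rate $k_d$:
$$\frac{d\theta_B}{dt} = k_a c_A\,\frac{c_B(t)}{c_A}\,(1-\theta_A-\theta_B)
  - k_d\,\theta_B, \qquad
\frac{d\theta_A}{dt} = k_a c_A\,(1-\theta_A-\theta_B) - k_d\,\theta_A.$$
The observable is the occupancy ratio $\theta_B(t)/\theta_A(t)$, which is
0 at $t=0$ and approaches $X_P$ at late times. The residence time is
$t_{1/2} = \ln 2 / k_d$. Only the product $k_a c_A$ enters the equations;
the on-rate and free-protein concentration are not separately
identifiable, and the ratio observable is in fact only weakly sensitive to
the product itself while being strongly sensitive to $k_d$ — this is the
property that makes the assay work.

**Scaling the data onto the model.** Measured ratios $R(t)$ carry a
site-specific amplitude and an additive background. A descriptive Hill fit
per site with the induction fit's $n$ held fixed (`fit_site_hill()`,
starting values $t_{1/2CC} = 40$ min, $X_{CC} = 1$) yields amplitude
$X_{CC}$, half-time rise $t_{1/2CC}$ and background $B$, and the series is
mapped to occupancy-ratio units by
$\theta_B/\theta_A = (X_P/X_{CC})\,(R(t) - B)$, floored at zero. The
background is constrained nonnegative: negative backgrounds have no
physical meaning for ratio data.

## Fitting, initialization and the second pass

`fit_turnover()` minimizes unweighted squared residuals of the
ODE-predicted ratio against the scaled series, parameterized in
$(\log k_a c_A, \log k_d)$ with box bounds $k_d \in [\ln 2/1000,
\ln 2/0.01]$ min$^{-1}$ and $k_a c_A \in [10^{-3}, 10^{3}]$ min$^{-1}$.
The ODEs are integrated with an adaptive, stiffness-switching solver
(`deSolve::lsoda`, rtol $10^{-8}$, atol $10^{-10}$) evaluated exactly at
the measurement times.

The first-pass initial guess exploits the lag
$\Delta t_{1/2} = t_{1/2CC} - t_{1/2\mathrm{ind}}$ of a site's rise behind
the induction curve: $t_{1/2}^{0} = 0.6\,\Delta t_{1/2} + 0.1$ min,
clamped below at 0.1 min. Because the residual surface is flat along the
on-rate direction and can hold shallow local minima, each fit also tries
fallback starts at $t_{1/2} = 0.5$, 5 and 40 min and keeps the solution
with the lowest residual sum of squares; on noise-free data all starts
agree.

The second pass regresses first-pass residence times of reliable fits on
$\Delta t_{1/2}$ with degree-1 and degree-2 polynomials, keeps the better
map by adjusted $R^2$, re-initializes every site from that map, and
refits. Each pass-2 fit additionally warm-starts from the site's pass-1
optimum, so a refit can never end worse than the first pass. The
regression uses reliable fits only (unreliable estimates would contaminate
the map); with fewer than 10 reliable fits the refinement is skipped with
a warning.

Uncertainty on the off-rate, $\Delta k_d$, is the square root of the
corresponding diagonal of the Gauss–Newton covariance
$\hat\sigma^2 (J^\top J)^{-1}$ at the optimum, delta-transformed from the
log scale. The full two-parameter covariance is used deliberately: the
near-flat on-rate direction inflates $\Delta k_d$ exactly when the data do
not pin down the kinetics, which is what the reliability filter keys on. A
fit is **reliable** when $\Delta k_d / k_d < 3$ and adjusted $R^2 > 0.7$
(both strict) and the off-rate did not converge onto its box bound. A
pinned *on-rate* is not penalized — the observable is insensitive to it by
design, and that parameter routinely drifts to a bound without affecting
$k_d$.

Sites without a reliable turnover estimate get a second chance as
**reliably fast**: their ratio series is min–max rescaled to $[0,1]$,
refit to the plain Hill curve with the induction $n$, and classified fast
when $\Delta t_{1/2} < 2$ min (strict). Such sites track the competitor
induction so closely that only an upper bound ("< 1 min") is reportable.
The per-site min–max rescaling is an interpretation choice: the exact
rescaling used historically is not documented, and min–max is the simplest
map onto $[0,1]$.

## From counts to ratios, and onto genes

Raw per-site HA and Myc count matrices over the shared peak set are
normalized in three steps (`depth_normalize()`, `scale_ha_to_protein()`,
`compute_ratio_table()`): equalize column depths within each channel;
rescale each HA column so the genome-wide mean HA/Myc ratio matches the
measured relative protein level at that time point (sequencing destroys
the absolute HA scale; the Western calibration restores it); and divide
the matrices elementwise. The pseudocount defaults to 0 with a hard error
on zero denominators — silently inventing counts is worse than failing —
and can be set for sparse simulations.

Peak regions are assigned to the gene with the nearest TSS by strand-aware
signed distance from the region midpoint (negative = upstream), kept only
inside the promoter window of −250 to +100 bp inclusive, reduced to the
closest region when several hit one gene, and stripped of tRNA
assignments. The midpoint anchor and lexicographic tie-breaking are
conventions chosen for reproducibility; the anchor used by the original
helper tooling is not documented.

Downstream, `transcription_efficiency()` multiplies a gene's mRNA
synthesis rate (mRNA/cell/min, an external input) by the factor's
residence time, giving mRNA produced per binding event; on the log2 scale,
negative values mean several binding events per transcript.
`quartile_split()` bins genes into synthesis-rate quartiles with `ntile`
semantics, and `summarize_by_class()` produces per-class counts and
per-quartile residence distributions. Reliably fast sites carry no numeric
residence time and are excluded from numeric summaries; plotting routines
that need a number use uniform draws on (0, 1) behind a dashed boundary
(seed 42), clearly a display convention and never an estimate.

## The synthetic generator

`simulate_experiment()` produces a full experiment with known truth:
per-site $(k_d, k_a c_A, X_{CC}, B)$, count matrices, a Western-style
calibration series, BED regions, a TSS table and synthesis rates. Defaults
are the study conditions: nine sampling times (0, 10, 20, 25, 30, 40, 60,
90, 120 min), induction $X_P = 1$, $t_{1/2\mathrm{ind}} = 43$ min,
$n = 4$, and residence times drawn log-uniformly over 0.1–30 min to span
the fast and slow classes. Where no published value exists the defaults
are one-time choices of realistic magnitude: site amplitudes lognormal
(sd 0.25) around $X_P$, backgrounds uniform on $[0.05, 0.3]$, on-rate
products log-uniform on $[0.5, 5]$ min$^{-1}$, multiplicative lognormal
ratio noise (CV 0.1), negative-binomial counts (mean depth 200,
dispersion 0.05, Poisson at dispersion 0) and per-column HA library-scale
distortions that the normalization must remove. The emitted calibration
series is the per-time mean of the noise-free site ratios, which makes the
normalization round trip exact in the zero-noise limit; a real Western
measures total protein and matches the ChIP-ratio site mean only
approximately. Gaussian Western noise is censored at zero rather than
truncated-resampled.

What the generator does **not** emulate: read-level artifacts (mapping,
duplicates, GC bias), spatially correlated noise between neighbouring
sites, fragment-length smearing across peak boundaries, chromatin-state
covariates of capture efficiency, or crosslinking kinetics. Passing tests
therefore demonstrate the correctness and calibration of the estimation
machinery, not the absence of systematic biases present in real ChIP-seq.

## Numerical limits worth knowing

A nine-point series with ~10% multiplicative noise carries limited
information about $k_d$. The residual surface is flat in the on-rate
direction, per-site amplitude and background must themselves be estimated
from the same nine points, and noise realizations can imitate a coherent
lag. Individual estimates in the several-minute range consequently carry
relative uncertainties of tens of percent — visible in the reported
$\Delta k_d$ — and occasional fast sites produce confident-looking slow
fits that no threshold on $\Delta k_d/k_d$ or adjusted $R^2$ can detect.
Cohort-level summaries (class counts, quartile medians) are far more
stable than any single site. The sensitivity computation below makes the
point concrete for a 5-minute site:

```{r crlb}
ind <- induction_model()
tp <- cc_timepoints()
kd <- log(2) / 5
th <- solve_turnover_odes(1, kd, ind, tp)$theta_ratio
dth <- (solve_turnover_odes(1, kd * 1.05, ind, tp)$theta_ratio - th) / 0.05
noise_sd <- 0.1 * (th + 0.15)              # 10% CV on the ratio scale
se_log_kd <- 1 / sqrt(sum((dth / noise_sd)^2))
se_log_kd                                   # best case, everything else known
```

Problem sizes used throughout the package's own validation — cohorts of
tens to a few hundred sites at nine time points — were chosen as the
smallest sizes at which cohort statistics stabilize.

## Known limitations

* Only $k_a c_A$ is recoverable, never $k_a$ or $c_A$ alone.
* Residence times longer than roughly a quarter of the observation window
  (here ≳ 30 min) are extrapolations: the series never approaches its
  plateau, the descriptive amplitude $X_{CC}$ becomes uncertain, and the
  scaled data inherit that uncertainty.
* The model assumes a single homogeneous binding position per peak;
  mixtures of fast and slow subpopulations fit to an intermediate rate.
* The reliably-fast class is one-sided: it bounds the residence time above
  by the induction resolution (~1 min) but says nothing more.
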