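---
title: "Derivative-peak analysis of microplate growth and fluorescence curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Derivative-peak analysis of microplate growth and fluorescence curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcderiv)
```

## The problem

Optical-density (OD600) growth curves measured in 96-well microplate
readers deviate from the sigmoid shape that classical growth-curve fitting
assumes: at the culture densities typical of plate work, multiple
scattering flattens and distorts the OD-cell number relation, and
light-scattering reagents (silver nanoparticles are the motivating case)
add baselines and spurious early peaks of their own. Direct Gompertz
fitting of such curves fails or needs ad hoc truncation. Bulk fluorescence
(FL) of a GFP reporter is immune to much of this interference, but an FL
curve keeps rising without a plateau and carries no obvious lag time or
growth rate.

The analysis implemented here works on time derivatives instead. The first
derivative of the OD curve and the second derivative of the FL curve both
show a bell-shaped peak. The peak location tracks the lag time of the
culture, the peak height tracks the growth rate, and — crucially — the
distortions above mostly reshape the *tails* of the derivative curves
(saturation appears as a shoulder to the right of the peak), so the peak
summaries survive conditions under which sigmoid fitting breaks down.

## The model

Cell numbers follow a two-state growth model: dormant cells $n_D$ activate
into dividing cells $n_A$ at rate $\alpha$, and active cells grow
logistically at maximum rate $k_0$ towards carrying capacity $N$:

$$\frac{dn_D}{dt} = -\alpha n_D, \qquad
  \frac{dn_A}{dt} = \alpha n_D + k_0\Bigl(1 - \frac{n_A}{N}\Bigr) n_A .$$

The total $n = n_D + n_A$ is the quantity OD reports. Active cells express
non-fluorescent GFP at rate $g$ per cell; it matures into fluorescent GFP
at rate $k_m$; both species are degraded by shared, saturable machinery
with rate $\gamma$ and capacity $M$:

$$\frac{dp_n}{dt} = g n_A - k_m p_n - \frac{\gamma\, p_n}{p_n + p_f + M},
  \qquad
  \frac{dp_f}{dt} = k_m p_n - \frac{\gamma\, p_f}{p_n + p_f + M}.$$

$p_f$ is the quantity FL reports. Counts are dimensionless and all rates
are per hour. The default parameter set — $\alpha = 1$, $k_0 = 1$ /hr,
$N = 2\times 10^9$, $g = 100$ /hr, $k_m = 1.5$ /hr, $\gamma = 500$ /hr,
$M = 2\times 10^{11}$, with $n_D(0) = 0.05N$ and everything else zero —
produces a classic sigmoid $n(t)$ and an FL curve that rises without a
plateau over a 16-h run, matching what multimode readers record for
GFP-expressing *E. coli* in rich medium.

```{r simulate}
tr <- simulate_growth(growth_params(), gfp_params())
tail(tr$n, 1) / 2e9   # the culture reaches carrying capacity by 16 h
```

### Numerical choices

`simulate_growth()` integrates the four equations with `deSolve::lsoda`
(adaptive, stiff-capable), relative tolerance `1e-8`, absolute tolerance
`1e-6` of the relevant capacity ($N$ for the cell pools, $M$ for the
protein pools). Because the cell equations do not depend on the protein
states, the two-cell subsystem is additionally solved on its own — at
tighter tolerance (`rtol 1e-10`, `atol 1e-10 N`), cheap for two equations —
and its solution is the one reported for $n_D$, $n_A$, $n$. This has two
consequences we rely on: the dormant-pool closed form
$n_D(t) = n_D(0)e^{-\alpha t}$ and the logistic limit are reproduced to
better than $10^{-6}$ relative error, and the cell-derived peak summaries
are *exactly* invariant — bitwise — under any change of the GFP
parameters, reflecting the structure of the equations rather than solver
tolerance. Tolerance-level negative excursions (below $10^{-6}$ of the
capacity scale) are clamped to zero; anything larger aborts.

The default output grid is `dt = 0.01` hr. The default horizon is 16 h,
extended to 100 h when $\alpha < 0.01$ /hr so that the slow-activation
derivative peaks stay inside the window.

## Derivative estimation

Plate readers sample every 10 min; derivatives are estimated exactly as
one estimates them on such data,

$$\left.\frac{dn}{dt}\right|_{t_i} = \frac{n(t_{i+1}) - n(t_i)}{t_{i+1} - t_i},$$

reported at the left grid point, with the second derivative obtained by
applying the same operator twice. Measured curves are processed in the
order: replicate mean, Hanning smoothing, differencing.

The Hann kernel is $w_j = \tfrac12(1 - \cos(2\pi j/(K-1)))$,
$j = 0,\dots,K-1$, normalised to unit sum; its endpoints are zero, so the
effective support of a window of $K$ points is $K-2$. The default window is
11 points (the shortest of the 11–15 range that is standard for 10-min
sampled overnight runs), chosen to distort peak heights least; edge
handling is reflection padding by default with a truncating alternative.
Smoothing is applied once before differencing by default; for second
derivatives of noisy FL curves, `resmooth = TRUE` re-applies the window
between the two differencing passes. Because multiplicative measurement
noise grows with the FL signal while the curvature signal does not, FL
second derivatives are the noisiest stage of the pipeline: at 2% noise the
wider end of the window range together with re-smoothing
(`smooth_window = 15, resmooth = TRUE`) is needed for reliable peak
identification, and the tests exercise exactly that configuration.

### Sampling cadence for simulated summaries

Simulated sweeps (`run_sweep()`, `reproduce_relations()`) sample the
trajectory at the same 10-min cadence before differencing
(`sample_dt = 1/6` hr). This is a deliberate choice: the derivative
estimator above is defined on the measurement grid, and the forward
difference at spacing $h$ carries a systematic label offset (about $h/2$
for the first derivative, $h$ for the second). Computing simulated and
measured summaries with the same estimator at the same cadence keeps them
directly comparable; refining the grid instead changes the fitted
dependency constants in the third decimal and flattens the
location power laws away from their measurement-cadence values.

## Peak characterisation

`find_peak()` reports the time of the global maximum (earliest on ties),
the height there, and a moment-based width: the within-window minimum is
subtracted, the curve is restricted to the contiguous half-height region
around the maximum extended to the surrounding zero crossings, and the
width is the standard deviation of that region treated as a mass
distribution. This estimator is parameter-free and robust for bell-shaped
peaks; a Gaussian-fit width is available behind `method = "gaussian"`. An
optional search window excludes short-time artifact peaks (the
nanoparticle signature). `peak_shift()` differences two peak locations and
quotes the quadrature sum of the two widths as the uncertainty — a
reporting convention, not an error-propagation law.

## Gompertz fitting

The modified Gompertz model
$$\log\frac{n(t)}{n(0)} = A \exp\Bigl\{-\exp\Bigl[\frac{\mu e}{A}(\lambda - t) + 1\Bigr]\Bigr\}$$
is fitted by Levenberg–Marquardt least squares, with starting values from
the standard geometry (asymptote, steepest slope, tangent intercept). The
logarithm is natural by default — the convention the formula, with its
factor $e$, presumes — with base-10 available and $A$, $\mu$ reinterpreted
consistently. Raw OD input can be truncated at a ceiling (default 1.0)
before the ratio is formed, restricting the fit to the regime where OD is
close to proportional to cell number.

```{r gompertz}
fit_gompertz(new_curve(tr$time, log(tr$n / tr$n[1])))
```

## The dependency relations

`reproduce_relations()` re-derives how the peak summaries depend on each
model parameter, using one sweep grid per parameter (activation rate: one
point per decade over $10^{-4}$–$10^2$ /hr; growth rate: 0.5–2.0 /hr in
steps of 0.25; expression rate: 12 log-spaced points over 1–1100 /hr;
maturation rate: geometric doubling 0.04–2.56 /hr). The headline constants
under the default configuration:

* both peak locations are linear in the fitted lag time across the
  activation sweep with a common slope near 1.12, and their difference
  $\tau_{pf} - \tau_p$ is activation-independent;
* the $dn/dt$ peak height is linear in $k_0$ (power-law exponent 1.00)
  while the $d^2p_f/dt^2$ height follows an exponent near 0.84; the
  locations follow negative power laws (near $-0.9$ and $-0.8$);
* the lag time moves by less than 0.5 hr across the whole $k_0$ range even
  though the peak locations move by hours;
* the FL peak height is linear in the expression rate $g$ while its
  location ignores $g$ entirely;
* the maturation rate shifts the FL peak location with a weak negative
  power law and drives the height along a Michaelis–Menten curve with
  half-saturation near 0.26 /hr.

```{r relations, eval = FALSE}
rel <- reproduce_relations()
rel[c("relation", "quantity", "estimate", "expected")]
```

The `expected` column carries the reference value of each constant under
the default study conditions so a rerun can be compared at a glance. Two
caveats are deliberate: the exact sweep grids behind the reference
constants are a package choice (only the ranges are fixed by the study
design), and the location-vs-maturation exponent in particular is
range-sensitive — over the full doubling grid the package obtains about
$-0.14$ against a reference of $-0.11$, and the local log-log slope only
reaches $-0.11$ over the upper half of the grid. We report the full-grid
value rather than selecting the sub-range that matches.

## Synthetic plate data and what passing tests mean

`generate_plate_dataset()` maps simulated kinetics to raw instrument
readings so that every stage of the measured-data pipeline is testable
with known ground truth. The OD map is monotone saturating,
$S(1 - e^{-s n/S})$ plus baseline — linear at low density, flattening at
high density. This is a *test harness* for the saturation phenomenology
(shoulders right of the derivative peak), not a physical model of multiple
scattering; no claim about real OD-cell number calibration is made, and
the package never converts between the two. Defaults put raw OD in
0.04–1.1 (corrected: about 0.1–1.7, with the path-length factor 2.39 of
the reference instrument), inoculum at raw 0.05, FL in the
hundreds-to-thousands range, 3 replicate wells, 10-min sampling for 16 h
(97 points), and 2% multiplicative lognormal noise per reading — the noise
level at which the robustness properties are asserted. An optional
Gaussian early-time OD bump emulates nanoparticle interference.

The ground-truth record stores the peak summaries and Gompertz parameters
of the *noiseless* kinetics computed with the same estimators at the same
cadence. The tests then assert, among others: exact bitwise
reproducibility for a fixed seed; recovery of a known between-condition
peak shift to within 0.5 hr at 2% noise over 20 seeds; and lag-time
recovery to 2% from noiseless data in the linear (low-OD) regime. "Low-OD"
matters: the Gompertz parameters of truncated data differ from the
full-curve fit even on perfect data (the model is an approximation to the
kinetics, so the fit is window-dependent), which is why the recovery
claims are stated against like-for-like windows. What these tests do *not*
establish: behaviour under instrument drift, well-to-well systematic
effects, condensation artifacts, or real scattering optics — none of which
the generator emulates.

## Known limitations

* The derivative method presupposes a maximum in the growth rate; cultures
  that never leave linear or diauxic regimes inside the run do not yield a
  usable peak.
* Differencing amplifies noise; the FL second derivative is usable at the
  default noise level only with the wider smoothing window, and weaker FL
  signals will need longer windows or more replicates.
* The peak-width estimator is a convention; widths from different
  conventions (e.g. Gaussian fits) are not interchangeable, and the
  quadrature uncertainty of a shift inherits that convention.
* Degradation-dominated regimes (very large $\gamma/M$) produce dips and
  left-shifts of the FL peak that the bell-peak summary describes only
  partially.
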