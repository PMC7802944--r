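# gcderiv

Time-derivative analysis of bacterial growth curves from multimode
microplate readers.

## Why

OD600 growth curves from 96-well plate readers are distorted by multiple
scattering at the culture densities where plates operate, and reagents
such as silver nanoparticles add baselines and spurious early peaks of
their own — so direct sigmoid (Gompertz) fitting of the OD curve fails
exactly in the experiments where plate readers are most useful. The bulk
fluorescence of a GFP reporter avoids that interference but rises without
a plateau, so it carries no obvious lag time or growth rate either.

`gcderiv` implements an analysis built on time derivatives instead: the
first derivative of the OD curve, ΔOD/Δt, and the second derivative of
the fluorescence curve, Δ²FL/Δt², both show a bell-shaped peak. The peak
location τ tracks the lag time λ, the peak height η tracks the growth
rate, and the distortions above reshape only the tails of the derivative
curves (saturation appears as a right shoulder), leaving the peak
summaries usable where sigmoid fitting breaks.

The package provides, as testable modules behind one consistent surface:

* a coupled ODE model of dormant→active logistic growth
  (dn_D/dt = −αn_D; dn_A/dt = αn_D + k₀(1 − n_A/N)n_A) and GFP
  expression/maturation/saturable degradation, integrated with `deSolve`
  (`simulate_growth()`);
* forward-difference derivatives and Hanning smoothing exactly as applied
  to 10-min-sampled plate data (`forward_diff()`, `hanning_smooth()`);
* bell-peak characterisation — location, height, moment-based width — and
  peak-shift arithmetic (`find_peak()`, `peak_shift()`);
* modified Gompertz (Zwietering) lag-time fitting of log growth curves
  (`fit_gompertz()`);
* single-parameter sweeps and the linear / power-law / exponential /
  Michaelis–Menten dependency relations that calibrate the method
  (`run_sweep()`, `fit_relation()`, `reproduce_relations()`);
* plate-reader CSV import, 2.39× path-length correction, replicate
  aggregation with SEM, and a full per-condition analysis pipeline
  (`read_plate_csv()`, `correct_od()`, `aggregate_condition()`,
  `analyze_condition()`);
* a synthetic plate-data generator with known ground truth, including a
  saturating OD map and seeded multiplicative noise
  (`generate_plate_dataset()`).

A thin command-line front end over these functions ships in
`inst/cli/gcderiv.R` (subcommands `simulate`, `derive`, `peaks`,
`fit-gompertz`, `sweep`, `reproduce`, `analyze`, `synth`).

## Worked example

Simulate the default culture, extract both derivative peaks, and fit the
lag time:

```r
library(gcderiv)
tr <- simulate_growth(growth_params(), gfp_params(), dt = 1/6)
find_peak(forward_diff(trajectory_curve(tr, "n")))
#> Peak 'dn/dt': tau = 3.5 hr, eta = 4.995e+08, sigma = 1.61 hr
find_peak(forward_diff(forward_diff(trajectory_curve(tr, "pf"))))
#> Peak 'ddpf/dt/dt': tau = 4 hr, eta = 4.643e+10, sigma = 1.82 hr
fit_gompertz(new_curve(tr$time, log(tr$n / tr$n[1])))
#> Gompertz fit: A = 3.003 +/- 0.0021, mu = 0.8688 +/- 0.0044 /hr, lam = 0.6198 +/- 0.0094 hr
#>   (97 points, t in [0, 16] hr)
```

The OD-derivative peak sits at τ_p = 3.5 h and the FL second-derivative
peak lags it at τ_pf = 4 h — the offset reflects GFP maturation, not
growth. The Gompertz lag of the same culture is 0.62 h; across an
activation-rate sweep both τ's move linearly with λ (slope ≈ 1.14), which
is what lets a peak location stand in for a lag time.

The same summaries survive a noisy, saturating measurement. A synthetic
plate with tenfold-slower activation, analysed blind through the
measured-data pipeline:

```r
sp <- generate_plate_dataset(growth = growth_params(alpha = 0.1),
                             meas = measurement_model(seed = 42),
                             condition = "treated")
analyze_condition(aggregate_condition(correct_od(sp$dataset), "treated", "OD600"))
#> <condition_analysis 'treated' OD600>
#> Peak 'dtreated/OD600/dt': tau = 4.83 hr, eta = 0.4197, sigma = 3.11 hr
#> Gompertz fit: A = 2.773 +/- 0.094, mu = 0.5151 +/- 0.0046 /hr, lam = 2.004 +/- 0.02 hr
#>   (31 points, t in [0, 5] hr)
```

Slower activation lengthened the lag, and both the derivative peak
(4.83 h vs ~3 h for a control) and the truncated Gompertz fit (2.0 h) see
it. Peak arithmetic on reported peak centres works directly:

```r
peak_shift(peak_summary(4, sigma = 1.2), peak_summary(9.5, sigma = 1.4))
#> Peak shift: 5.5 +/- 1.84 hr
```

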