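# capnoflow

Dynamic modelling and Kalman inversion of transcutaneous CO2 transport for
an open-chamber capnometry wristband.

A wrist-worn transcutaneous capnometer measures the CO2 that diffuses from
blood-perfused tissue through the stratum corneum into an NDIR optical cell
held against the (heated) skin, while a continuous air flow through a
collection cell carries the gas away. Because the chamber is open, the
measured concentration is a delayed, diluted, low-pass-filtered image of
the blood CO2 content — recovering the clinically relevant blood partial
pressure requires a dynamic model and an on-line inversion.

`capnoflow` provides:

* **Forward model** — a 1D convection–diffusion description of four
  compartments (blood, stratum corneum, measurement cell, collection cell)
  with Henry-law interface conditions
  ($C_+/C_- = H_+/H_-$, diffusive flux continuous), Dirichlet blood
  boundary, zero-flux outer boundary, and a washout exchange representing
  the pumped air (`co2_grid()`); implicit-Euler state-space integration
  $\;(I - \delta t F)\,c_{k+1} = c_k + \delta t\,G\,q_{k+1}$, observation
  $y_k = h^\top c_k + v_k$ (`simulate_direct()`).
* **NDIR measurement model** — dual-wavelength (4.26 µm / 3.91 µm)
  Beer–Lambert log-ratio inversion and the linear-quadratic calibration
  $-\ln(U_{\lambda_1}/U_{\lambda_2}) = \ell + m C^{u} + n C^{2u}$ fitted by
  bounded Levenberg–Marquardt (`fit_calibration()`).
* **Inverse model** — a Kalman filter on the state augmented with an AR(1)
  prior for the unknown blood input
  ($\partial_t C_{in} = \varphi C_{in} + w$), Joseph-form covariance
  update, blood pressure via Henry's law $P = C/\beta$
  (`augment_with_ar1()`, `run_inversion()`).
* **Metrics & scenarios** — settled phase means, relative performance,
  cross-correlation delays, aligned RMSE, global SNR (dB), 10–90 % rise
  time; runners for the capnia step study, the air-flow sweep and a
  clinical chronogram (`run_step_study()`, `run_airflow_sweep()`,
  `run_clinical_study()`).

## Worked example

Simulate the normocapnia → hypercapnia step (40 → 50 mmHg), invert the
noiseless, low-noise and high-noise observations, and print the study
table:

```r
library(capnoflow)
print(run_step_study())
```

```
Step study (40 -> 50 mmHg), phi = 0
                         var=0e+00 var=1e-08 var=1e-06
mu hypercapnia (mol/m3)     1.3738    1.3738    1.3738
mu^ hypercapnia (mol/m3)    1.3744    1.3744    1.3743
rmse aligned (mol/m3)       0.0242    0.0242    0.0244
perf_rel (%)               -0.0464   -0.0453   -0.0384
rsb_global (dB)            34.3571   34.3605   34.2916
t_r (s)                   837.1364  839.3288  834.5097
td_dir (s)                558.0000  562.0000  550.0000
td_inv (s)                  0.0000    0.0000    0.0000
td_global (s)             627.0000  627.0000  622.0000
```

Reading the noiseless column: the true hypercapnia plateau is
1.3738 mol/m³ (= 50 mmHg) and the Kalman estimate settles at 1.3744, a
level error of 0.05 % (`perf_rel`). The CO2 front needs about 560 s to
propagate from blood to the measurement cell (`td_dir`), while the
estimate tracks the observation with no additional lag (`td_inv` = 0).
After aligning estimate and input at the global delay, the residual RMSE
is 0.024 mol/m³, i.e. a 34 dB signal-to-error ratio, and the estimated
blood concentration completes 10–90 % of the step in about 840 s. The
recovered plateau varies by less than 0.1 % across the three observation
noise levels — the filter adapts to the noise without losing the level.

The open-chamber design compromise is one call away:

```r
run_airflow_sweep(flows_ml_min = c(0.1, 1, 10))
#>   flow_ml_min steady_level delay   t_rise
#> 1         0.1  0.672524003   668 5194.963
#> 2         1.0  0.088391149   361 1440.561
#> 3        10.0  0.009285972   226 1167.851
```

— more air flow means a faster response but a weaker signal.

A thin command-line runner over the same functions ships in
`inst/cli/capnoflow.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/capnoflow.R", package="capnoflow"))')" \
    step --out reports --seed 1
```

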