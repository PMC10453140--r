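# rfdry

Coupled heat–mass transfer simulation of hot-air drying of fruit slices,
with and without radio-frequency (RF) volumetric heating.

## The problem

Hot-air drying of thin jujube slices (30 mm × 8 mm, 79.6% initial wet-basis
moisture, 60 °C / 2.5 m/s air) removes surface moisture well but heats the
interior slowly. A 27.12 MHz parallel-plate RF field deposits power
*inside* the tissue — `Q_rf = 2πf·ε₀·ε″·|E|²` — raising the core
temperature and accelerating interior moisture migration. `rfdry` is for
process engineers who want to ask: in a 4.5 h schedule split into three
equal stages, when is RF best applied? The four canonical schedules are HA
(hot air only) and E-/M-/L-HA+RF (RF during the early, middle or late
stage).

The model couples, on an axisymmetric finite-volume grid:

- energy: ρₛCp ∂T/∂t = ∇·(k∇T) + Q_rf
- moisture: ∂C/∂t = ∇·(D_eff ∇C), C = ρ_dm·M_db

with convective–evaporative boundary conditions
(−k∇T·n = h_T(Tₛ−T_air) + h_fg·h_m(Cₛ−C_eq); −D_eff∇C·n = h_m(Cₛ−C_eq)),
measured property regressions Cp(T,W), k(T,W), ε′(T,W), ε″(T,W), a
quasi-static complex Laplace field solver (layered-capacitor closed form or
full 2-D), and Dincer-model drying-kinetics estimators (lag factor Lf,
drying coefficient S, mass Biot number Bi = 1.3·lnLf/(0.2533−lnLf),
μ₁ = atan(0.640443·Bi + 0.380397), D = S·L²/μ₁², h_m = Bi·D/L).

## Worked example

```r
library(rfdry)

mat <- material_properties()
specific_heat(mat, 60, 0.796)      # 2.080412 kJ/kg/K
loss_factor(mat, 60, 0.796)        # 550.7176

res <- run_drying(default_config(), quiet = TRUE)   # hot-air run, 4.5 h
print(res)
#> Drying simulation: HA, 16200 s, 271 records
#>   M_db: 3.902 -> 0.581 kg/kg db; T_center: 22.0 -> 54.4 degC
#>   budget residuals: energy 2.86e-15, moisture 1.64e-13 (relative)
time_to_moisture(res, 1.0)         # 11921.9 s to reach 1.0 kg/kg dry basis

cfg <- default_config(); cfg$schedule$scenario <- "L-HA+RF"
rf <- run_drying(cfg, quiet = TRUE)
max(rf$timeseries$T_center_C)      # 63.06 degC peak core temperature
```

The hot-air run dries from 3.90 to 0.58 kg/kg dry basis with the centre
temperature climbing to ~54 °C (held below the 60 °C air by evaporative
cooling); the conservative finite-volume scheme closes its energy and
moisture budgets to round-off. Applying RF in the late stage drives the
core to 63 °C — hotter than the surface, the signature of volumetric
heating — and reaches the 1.0 kg/kg target sooner than hot air alone
(11 852 s vs 11 922 s; early/middle RF: 11 469 s / 11 397 s). Peak core
temperature orders L > M > E because the drier the slice, the stronger the
in-sample field.

Kinetics fitting works on any (time, M_db) record:

```r
ts <- res$timeseries
curve <- drying_curve(ts$t_s[seq(1, 271, 30)], ts$M_db[seq(1, 271, 30)],
                      Me_db = 0.05)
fit_dincer(curve, L_half = 0.008)
#> Dincer drying-kinetics fit
#>   Lf = 1.02310, S = 0.0001208 1/s (log-linear R2 = 0.9982)
#>   Bi = 0.1288, mu1 = 0.43353 rad (L_half = 0.008 m)
#>   D = 4.114e-08 m2/s, hm = 6.625e-07 m/s
```

A command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","rfdry.R",package="rfdry"))')" \
  simulate --scenario M-HA+RF --out out.csv
```

with subcommands `simulate`, `compare`, `fit-kinetics`,
`calibrate-voltage`, `props`, `make-fixture`, all configured through a YAML
file (see `default_config()` for every key and default).

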