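# nanosorb

Batch-adsorption analysis of doxorubicin (DOX) on carbon nanotubes, as a
tested, reusable R package. Carbon nanotubes (CNTs) are studied as drug
nanocarriers: surface-oxidized multi-wall nanotubes bind the anthracycline
drug doxorubicin with capacities of thousands of mg per gram of adsorbent,
and the binding is characterized by equilibrium isotherms, uptake kinetics,
and — at the molecular scale — by how point-reduced drug molecules
aggregate with each other and with the tube. `nanosorb` implements that
whole analysis chain for experimentalists and modellers working on
nanocarrier loading:

* **Batch mass balances** — uptake capacities from measured concentrations,
  `qe = V (C0 − Ce) / m` and `qt = V (C0 − Ct) / m` (V in mL, m in g,
  concentrations in mg mL⁻¹, capacities in mg g⁻¹), with spectrophotometric
  standard-curve calibration (`fit_calibration()`,
  `concentration_from_absorbance()`).
* **Isotherm fitting** — Freundlich `qe = kF Ce^(1/n)`, Langmuir
  `qe = qmax KL Ce / (1 + KL Ce)` and Temkin `qe = (RT/b) ln(kT Ce)` in the
  classical linearized mode (the convention tabulated values follow) and in
  direct nonlinear mode, with delta-method parameter SDs, validity flags
  for non-physical slopes, and ranking via `compare_isotherms()`. The
  Temkin constant `b` gives the heat of sorption (ΔH = −b).
* **Kinetics fitting** — pseudo-first order (Lagergren), pseudo-second
  order (Ho–McKay), two-segment Weber–Morris intra-particle diffusion with
  an exhaustive-search breakpoint, fractional power, and Elovich models,
  plus `select_kinetic_model()`, which ranks by R² and flags models whose
  fitted `qe` disagrees with the measured plateau.
* **Nanotube geometry** — `build_zigzag()` / `build_mwcnt()` generate ideal
  zigzag (n,0) tubes (diameter √3·a_CC·n/π) and coaxial multi-wall stacks
  with per-atom ring indices.
* **Configuration metrics** — `cluster_molecules()` (single-linkage
  aggregates under periodic boundaries, union-find), `fraction_on_cnt()`
  (percentage adsorbed onto the tube), and `count_inside()` (interior
  occupancy via spheres centered on carbon-ring centroids, duplicates
  counted once), rolled up per frame by `analyze_trajectory()`.
* **Synthetic data with exact ground truth** — `gen_isotherm()`,
  `gen_kinetics()`, `plant_configuration()` and `toy_aggregation()`
  generate every input the pipeline needs with known generating parameters,
  so each stage is testable end to end.

A YAML-driven pipeline (`run_pipeline()`, `render_summary()`) ties the
stages together; `inst/scripts/nanosorb.R` exposes them as shell
subcommands.

## Worked example

Fit the kinetic models to a synthetic uptake curve drawn from the
pseudo-second-order integrated form (qe = 4029 mg g⁻¹,
k2 = 6.92×10⁻⁵ g mg⁻¹ min⁻¹, 1% lognormal noise, the twelve standard
sampling minutes):

```r
library(nanosorb)
data <- gen_kinetics("pseudo_second", list(qe = 4029, k2 = 6.92e-5),
                     noise_sd = 0.01, seed = 42, qe_exp = 3900)
fit <- fit_pseudo_second(data)
fit
#> <pseudo_second fit, linearized mode>
#>   qe           4094.47 +/- 20.4 mg g-1
#>   k2           6.38723e-05 +/- 4.57e-06 g mg-1 min-1
#>   R^2 = 0.999752

fits <- list(suppressMessages(fit_pseudo_first(data)), fit,
             fit_fractional_power(data), fit_elovich(data))
select_kinetic_model(fits, qe_exp = 3900)
#> Kinetic model selection (qe_exp = 3900 mg/g)
#>             model r_squared qe_fit qe_rel_dev                      flagged rank
#>     pseudo_second    0.9998   4094    0.04986                                 1
#>           elovich    0.9636     NA         NA                                 2
#>      pseudo_first    0.9052   2094    0.46309 rejected despite fit quality    3
#>  fractional_power    0.8786     NA         NA                                 4
```

The second-order fit recovers the generating capacity within about 2% and
tops the ranking. The pseudo-first-order model also correlates well
(R² = 0.91) but its fitted equilibrium capacity is less than 54% of the
measured plateau, so the selection report marks it *rejected despite fit
quality* — the capacity-agreement diagnostic that separates a usable rate
law from a merely well-correlated one.

The full pipeline runs from a single config:

```r
bundle <- run_pipeline(system.file("extdata", "demo-config.yaml",
                                   package = "nanosorb"),
                       output_dir = "demo-out")
render_summary(bundle)
```

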