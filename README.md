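# moxiopt

Bioheat simulation and interval uncertainty optimization for mild
moxibustion.

Mild moxibustion warms an acupoint by holding a smoldering moxa stick a
few centimetres above the skin.  Two temperatures summarize a treatment:
the skin surface temperature at the moxibustion point (**ST**), which must
stay below the 45.5 °C comfort threshold, and the **thermal penetration**
(**HPM**), the tissue temperature 5 mm below the surface, which therapy
wants as high as possible.  The operating parameters — moxa burning
temperature *t₁* ∈ [600, 650] °C, stick diameter *d* ∈ [12, 18] mm,
stick-to-skin distance *h* ∈ [25, 35] mm, skin moisture content
*ω_c* ∈ [29, 52] % — fluctuate in practice, so `moxiopt` treats each as a
closed interval *d^I = [d^c − d^ω, d^c + d^ω]* and solves the
reliability-constrained interval program

```
max   HPM(d^c, d^ω)
s.t.  pr( ST(d^c, d^ω) ≤ b ) = (b − ST^L) / (2 ST^ω) ≥ λ ,   b = 45.5 °C
      d_l ≤ d^c − d^ω ≤ d^c + d^ω ≤ d_u
```

where *pr(·)* is the reliability-based possibility degree of interval
(RPDI): values ≥ 1 mean the whole ST interval sits below the allowable.

The package provides, end to end:

* an axisymmetric transient **Pennes bioheat solver** for the three-layer
  skin/fat/muscle domain heated by a radiating disk source
  (`run_simulation()`, `extract_indicators()`,
  `single_factor_analysis()`);
* **Latin hypercube design** and a Gaussian **RBF-network surrogate** of
  the two indicators (`latin_hypercube()`, `rbnn()`, `fit_metrics()`);
* **interval propagation** of parameter uncertainty and reliability
  flagging (`response_interval()`, `analyze_uncertainty()`, `rpdi()`);
* the **nested optimizer** — outer real-coded genetic algorithm over
  interval midpoints, inner bounded multistart local optimization for
  each candidate's response intervals — with grid-oracle verification
  (`interval_optim()`, `rpdi_sweep()`);
* closed-form pseudo-simulators and self-validating toy problems for fast
  testing (`make_pseudo_simulator()`, `make_toy_problems()`), and
  pipeline orchestration (`run_pipeline()`, `moxi_report()`).

## Worked example

Train a surrogate on 50 coarse-grid solver runs, check the unoptimized
condition, then optimize at four reliability levels:

```r
library(moxiopt)

base      <- simulation_config(dr = 1, dz = 1, dt = 2)   # coarse grid
design    <- latin_hypercube(50, seed = 42)
responses <- evaluate_responses(design, simulator_pde(base))
model     <- rbnn(design, responses[, c("HPM", "ST")])

analyze_uncertainty(model, seed = 42)
#> interval uncertainty analysis
#>   HPM: [38.2153, 42.0216] (mid 40.1185, rad 1.90319) degC
#>   ST : [41.3546, 58.9889] (mid 50.1718, rad 8.81713) degC  (allowable 45.5 degC)
#>   reliability: UNRELIABLE: ST may exceed the allowable value (RPDI vs allowable = 0.2351)

rpdi_sweep(interval_problem(model), c(0.8, 0.9, 1.0, 1.1), seed = 42)
#> optimal solutions under different reliability levels
#>  lambda             ST            HPM reliability feasible
#>     0.8 [44.42, 45.77] [39.00, 39.30]      0.8001     TRUE
#>     0.9 [44.31, 45.63] [38.97, 39.27]      0.9001     TRUE
#>     1.0 [44.20, 45.50] [38.94, 39.23]      1.0003     TRUE
#>     1.1 [44.09, 45.37] [38.91, 39.20]      1.1003     TRUE
```

Read: across the *whole* operating domain the surface temperature can
reach ≈ 59 °C — the unoptimized condition is unreliable.  The optimizer
pins the ST interval against the allowable: at λ = 1.0 the upper bound is
45.50 °C (the constraint is active), at λ ≥ 1 the interval lies entirely
below 45.5 °C, at λ < 1 it is allowed to protrude, and the optimal
penetration decreases as λ tightens — reliability costs efficacy.

The full methods account (model, assumptions, calibrated constants,
numerical choices, limitations) is in
`vignettes/moxibustion-interval-optimization.Rmd`.

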