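# exparkit

Kinetic modelling and quantitative analysis of isothermal exponential
amplification (EXPAR) assays for short oligonucleotides such as microRNAs.

EXPAR amplifies a trigger sequence X (e.g. the let-7a miRNA) on a template
carrying two copies of the trigger's reverse complement X′, separated by
the complement of a nicking-endonuclease site: polymerase extension forms
nickable dsDNA, Nt.BstNBI releases a fresh trigger copy, and the cycle
repeats isothermally. Writing φ for the fraction of annealed trigger that
forms the *extensible* duplex at the template's 3′ terminus, the reduced
consecutive-reaction model gives

    c_X(t) = exp(β t) · c_X0,
    β = ( γλ² / (ε(λ+1)) − (1−φ) / (φ(λ+1)) − α ) · c_T0

and a per-cycle mean outcome of (1 + φ)^n per starting molecule — 2^n for
an ideal asymmetric design, 1.5^n for a symmetric template with φ ≈ 0.5.
Assay readouts are handled alongside the kinetics: the POI (point of
inflection, the time of maximum slope of the sigmoidal real-time curve —
EXPAR's Cq) is linear in lg(input copies), melt transitions are read as
peaks of −dF/dT, and specificity against the let-7 family is expressed as
apparent-copy interference percentages.

The package provides, module by module:

* **Kinetics** — `rate_params()`, `beta_growth_rate()`,
  `amplicon_concentration()`, `expected_cycle_outcome()`,
  `simulate_branching()` (binomial branching process),
  `simulate_mass_action()` (deSolve mass-action mechanism).
* **Synthetic data** — logistic amplification curves, whole plates driven
  by a calibration truth with cross-reactivity fractions and a
  single-molecule floor, two-state melt curves, paired method-comparison
  tables (`generate_curve()`, `generate_plate()`, `generate_melt_curve()`,
  `generate_method_comparison()`).
* **Curve analysis** — `extract_poi()` (Savitzky–Golay derivative +
  parabolic refinement), `call_tm()`, `baseline_correct()`.
* **Quantitation** — `fit_calibration()`, `fit_piecewise()`,
  `invert_poi()`, `copies_from_amount()`, `estimate_phi_from_quench()`,
  `relative_error()`, `rsd()`.
* **Template design / specificity** — `reverse_complement()`,
  `build_template()` (standard / biotin / toehold-exchange designs),
  `validate_nease_site()`, `nn_duplex_tm()`, `interference_percent()`,
  `cross_reactivity_report()`.
* **Pipeline I/O** — plate/melt/results CSV and FASTA readers and writers,
  plain-text configs, and `run_pipeline()` tying simulation → POI
  extraction → calibration → specificity → method comparison into one
  deterministic report.

## Worked example

Simulate a 10-decade dilution plate with read noise, analyse it, and
challenge the calibration with two let-7 family interferents:

```r
library(exparkit)

cfg <- run_config(seed = 11, decades = 1:10, noise_sd = 1,
                  cross_reactivity = c("let-7a" = 1, "let-7e" = 0.0993,
                                       "let-7d" = 0.00044),
                  comparison_levels = c(4.05, 0.418),
                  cv_ref = 5, cv_test = 3)
rep <- run_pipeline(cfg)
rep
#> <expar_report> (simulate mode, seed 11)
#>   wells analysed: 10 (10 amplified)
#>   calibration: <calibration_fit> POI = 28.33 -2.092 * lg(copies)  (r = -1)
#>   valid range: 10 - 1e+10 copies, 10 points
#>   specificity: 3 species challenged
#>   method comparison: 2 samples, max |RE| 1.66%

rep$specificity
#> Cross-reactivity report (% of input recovered as apparent target)
#>  species       poi apparent_copies interference_pct n_wells n_amplified
#>   let-7a  7.792120        6.57e+09         109.0000       1           1
#>   let-7e  9.942808        6.15e+08          10.2000       1           1
#>   let-7d 14.941602        2.51e+06           0.0417       1           1
```

The fitted line recovers the generating calibration
(POI = 28.3 − 2.09·lg copies) to about a hundredth of a minute per decade
despite 1-RFU read noise; the injected cross-reactivity fractions (9.93%
and 0.044%) come back as interference percentages of 10.2% and 0.042%
through the inverse calibration, and the method-comparison table carries
per-sample means, RSDs and relative errors.

Individual stages work standalone:

```r
p <- rate_params(gamma = 2, epsilon = 1, lam = 2, alpha = 0.1,
                 phi = 0.8, c_T0 = 0.5)
beta_growth_rate(p)
#> [1] 1.241667

estimate_phi_from_quench(93.1, 36.8)   # biotin-tagged template
#> [1] 0.7167052

sort(as.numeric(call_tm(generate_melt_curve(c(59.9, 51.5)))))
#> [1] 51.54842 59.85158
```

See `vignettes/asymmetric-expar-modelling.Rmd` for the model, the
generator's assumptions, and every numerical choice.

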