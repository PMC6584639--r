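# motorquant

Quantitative analysis of autoinhibited kinesin motors — hydrodynamics,
photobleaching stoichiometry, single-molecule motility, binding isotherms,
and cell-image quantification — with paired synthetic-data generators for
closed-loop validation.

## The problem

Kinesin-3 motors such as KIF1C are regulated by autoinhibition: the stalk
folds back onto the motor domain and blocks microtubule binding until an
activator releases it. Characterising this mechanism quantitatively takes a
battery of small, bespoke analyses that are usually scattered across
ImageJ macros and spreadsheets:

* **Hydrodynamic sizing** — is the motor a dimer or a tetramer? Stokes
  radius from size-exclusion chromatography and sedimentation coefficient
  from glycerol gradients, calibrated against standard proteins, combine
  through the Siegel–Monty relation *M* = 4205 · *R*ₛ · *S* into a native
  molecular weight; the frictional ratio *f/f*min = *S*max/*S* with
  *S*max = 0.00361 · *M*^(2/3) reports how elongated the particle is.
* **Bleach-step stoichiometry** — counting photobleaching steps of
  GFP-tagged motors on microtubules. The step-count histogram of a
  dimer/tetramer mixture follows a mixed binomial,
  *P(k)* = C(2,k) *p*ᵏ(1−*p*)²⁻ᵏ(1−*x*) + C(4,k) *p*ᵏ(1−*p*)⁴⁻ᵏ*x*,
  with *x* the tetramer fraction and *p* the active-GFP fraction,
  conditioned on detection (*k* ≥ 1).
* **Single-molecule TIRF motility** — landing rate (events µm⁻¹ min⁻¹),
  frequency of running motors (speed > 25 nm/s), mean speed and run length,
  extracted from kymographs; plus vesicle-transport statistics (1.5 µm
  stationary rule, directional flux).
* **Binding isotherms** — dissociation constants from thermophoresis
  titrations, fitted with the quadratic (ligand-depletion) isotherm.
* **Cell images** — podosome counts (threshold, 16-px size filter, actin
  coincidence) and tail-enrichment ratios
  (*I*tail − *I*bg)/(*I*cyto − *I*bg).

motorquant packages these analyses as tested R functions, and ships a
synthetic-data generator for each one so that every estimator can be
validated end to end against known ground truth.

## Worked example

Simulate the bleach-step histogram of 108 detected motors from a population
with 12% tetramers and 80% active GFP, then fit the mixed-binomial model:

```r
library(motorquant)
h <- sim_bleach_counts(x = 0.12, p = 0.8, n_motors = 108, seed = 42)
h
#> Bleach-step histogram (108 spots)
#>  1  2  3  4
#> 24 73  8  3
fit_oligomer(h)
#> Mixed-binomial oligomer fit (n = 108 spots, detection-conditioned)
#>   tetramer fraction x = 0.115
#>   active-GFP fraction p = 0.835
#>   logLik = -98.37, chi2 = 4.15 (dof 1)
```

The fitted tetramer fraction (11.5%) and active-GFP fraction (83.5%) recover
the generative values within the uncertainty expected at *n* = 108; across
200 replicate histograms the medians land on 12% and 80%.

A full single-molecule round trip — simulate motors at 0.45 µm/s with
8.6 µm mean run length, render kymographs at 105 nm/px and 0.1 s/frame at
SNR 5, trace them, and summarise:

```r
truth <- motility_truth()   # wild-type defaults
obs  <- lapply(1:10, function(i) sim_motility(15, 3, truth, seed = i))
runs <- do.call(rbind, lapply(seq_along(obs), function(i)
  trace_kymograph(render_kymograph(obs[[i]], seed = 100 + i))))
summarize_motility(runs, obs)
#> Motility summary:
#>   events: 40 (29 running)
#>   mean speed: 0.410 um/s
#>   mean run length (observed): 4.11 um; censoring-corrected MLE: 7.45 um
#>   landing rate: 0.093 /um/min; running frequency: 0.064 /um/min
```

Note the two run-length figures: the observed mean (4.11 µm) is strongly
deflated by truncation at the microtubule plus end, while the
censoring-corrected estimate (7.45 µm at this small sample; 8.6 µm in
expectation) recovers the motor's true run length. And a dissociation
constant from a synthetic 16-point thermophoresis series (37 µM stock,
twofold dilutions, 50 nM receptor, 2% noise):

```r
fit_kd(sim_binding_series(kd = 1, noise_cv = 0.02, seed = 6))
#> Kd fit (quadratic isotherm, n = 16): Kd = 0.986 +/- 0.48 uM
#>   f_free = 798, f_bound = 907, RSS = 3.37e+03
```

The wide standard error is real: a single titration whose top point
(29.6 µM) only weakly pins the bound plateau constrains Kd loosely, which
is why replicate medians are the quantity to report.

## Layout

* `R/` — generators (`sim_*`), hydrodynamics (`fit_calibration`,
  `locate_peak`, `invert_calibration`, `molecular_weight`,
  `frictional_ratio`), bleach steps (`detect_steps`, `fit_oligomer`),
  motility (`trace_kymograph`, `summarize_motility`, vesicle tools),
  binding (`bound_fraction`, `fit_kd`, `decoration_intensity`), cell images
  (`count_podosomes`, `enrichment_ratio`), and orchestration
  (`run_pipeline`, `group_compare`).
* `vignettes/motorquant-methods.Rmd` — the models, defaults, numerical
  choices and limitations, in detail.
* `tests/testthat/` — unit, property and acceptance suites.
* `inst/extdata/` — small plain-text example inputs (synthetic).
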