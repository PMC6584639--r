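---
title: "Models and methods behind motorquant"
author: "motorquant maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind motorquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorquant)
```

motorquant implements the quantitative assays used to characterise
autoinhibited kinesin motors such as KIF1C: hydrodynamic sizing, bleach-step
stoichiometry, single-molecule TIRF motility, binding-isotherm fitting, and
fixed/live-cell image quantification. Every analysis has a paired synthetic
data generator with known ground truth, so the whole pipeline can be
validated as a closed loop: simulate at known parameters, analyse, and check
that the parameters come back. This vignette documents the models, the
defaults and why they were chosen, the numerical decisions, and what the
closed-loop tests do and do not demonstrate.

## Oligomeric state from photobleaching

A spot containing a motor with $n$ GFP tags bleaches in discrete steps; the
number of observed steps $k$ counts the GFPs that matured and are active.
For a mixed population of dimers ($n=2$) and tetramers ($n=4$),

$$P(k) = \binom{2}{k} p^k (1-p)^{2-k} (1-x)
       + \binom{4}{k} p^k (1-p)^{4-k} x,$$

with $x$ the tetramer fraction and $p$ the active-GFP fraction. Spots with
$k=0$ are invisible, so observed histograms follow the detection-conditioned
distribution $P(k)/(1-P(0))$ on $k \in \{1,\dots,4\}$; `fit_oligomer()`
fits this truncated model by default (the unconditioned variant is one flag
away). The fit maximises the multinomial log-likelihood on a $0.01$ grid
over $(x, p)$ followed by bounded quasi-Newton refinement — the likelihood
has a long diagonal ridge (more tetramers with fewer active GFPs mimics
fewer tetramers with more active GFPs), and the grid stage avoids being
trapped on it. A histogram with all mass at $k=1$ leaves $(x, p)$
unidentified; the fit then reports the boundary solution with
`identifiable = FALSE` rather than an arbitrary interior point.

```{r}
h <- sim_bleach_counts(x = 0.12, p = 0.8, n_motors = 108, seed = 1)
fit_oligomer(h)
```

Step counting (`detect_steps()`) segments a trace into piecewise-constant
levels by penalized least-squares change-point detection (optimal
partitioning with PELT-style pruning; penalty $2\hat\sigma^2\log n$, with
$\hat\sigma$ a robust noise estimate from successive differences). Only
downward level changes of at least `min_step` (default $3\hat\sigma$)
count; upward changes (blinking) pass through uncounted. Two fluorophores
bleaching within one frame produce a single double-height drop, so drops
are quantised against the median qualifying drop — the usual stoichiometry
practice. At a signal-to-noise ratio of 5 (unit step 100 AU, noise 20 AU)
the detector recovers the exact count in $\ge 95\%$ of simulated traces for
$k \le 4$; near-simultaneous bleaching sets the ceiling.

## Hydrodynamic sizing

Size-exclusion chromatography calibrates $\log_{10} R_s$ against elution
volume minus void volume; glycerol gradients calibrate the sedimentation
coefficient $S$ against volume from the gradient top (in ml — fraction
number would work equally well, volume is adopted and documented).
`fit_calibration()` is ordinary least squares on the transformed anchor,
`locate_peak()` fits a local Gaussian around the maximal fraction (window
$\pm 3$ fractions) with an intensity-weighted centroid fallback, and
`invert_calibration()` maps a peak volume back to $R_s$ or $S$. Peak
location is never trusted below half a fraction spacing, and calibration
parameter standard errors are propagated to first order — these are the two
error sources that dominate in practice.

Molecular weight follows the Siegel–Monty relation
$M = 4205 \, R_s \, S$ ($R_s$ in nm, $S$ in Svedberg, $M$ in Da), and shape
is summarised by the frictional ratio $f/f_{\min} = S_{\max}/S$ with
$S_{\max} = 0.00361\,M^{2/3}$, the sedimentation coefficient of an ideal
compact sphere of the same mass. Values near 1 indicate a compact particle,
values of 1.5–2 an elongated one; a result below 1 flags mutually
inconsistent inputs. Range checks (expected $R_s$ 1–20 nm, $S$ 1–30 S)
warn on unit mistakes. Partial-specific-volume and buffer-density
corrections are out of scope, as is multi-peak deconvolution.

## Single-molecule motility

`sim_motility()` generates landing events as a Poisson process with rate
$\lambda \cdot L_{MT}$ per minute, uniform landing positions, a static
fraction, truncated-normal speeds and exponential run lengths, truncated at
the microtubule plus end (the motor detaches there by default; an
accumulate-at-end flag keeps it visible, mirroring plus-end accumulation
seen in experiments). Both plus-end and movie-end truncation are recorded
as right-censoring.

`render_kymograph()` draws each track as a Gaussian spot (symmetric PSF,
default $\sigma = 1.3$ px) per frame at 105 nm/px and 0.1 s/frame, plus
additive Gaussian background noise; the default signal 100 AU over noise
20 AU corresponds to SNR 5. Camera physics (EM gain, shot noise) and 3-D
optics are deliberately out of scope.

`trace_kymograph()` automates what is classically done by hand: Gaussian
pre-smoothing ($\sigma = 1.5$ px, which shrinks the noise SD several-fold
while a line-like track keeps most of its ridge amplitude), thresholding at
the background median plus 5 robust SDs (with a fallback for noiseless
images, plus Otsu and absolute options), connected-component labelling, and
a least-squares line fit of per-frame intensity centroids. Three numerical
details matter:

* smoothing extends a component by a few stationary frames at each end,
  which flattens the fitted slope; the fit trims those frames, and the run
  extent subtracts the expected blur extension;
* components whose line-fit RMS residual exceeds `max_rms` (0.35 µm) are
  almost always two crossing tracks merged into one and are flagged
  `multitrack`; they count as detections but are excluded from speed and
  run-length summaries, since a single line through two tracks has a
  meaningless slope. Proper disentangling of crossing tracks is a known
  limitation of component-based tracing;
* a run is right-censored if it reaches the last ~0.5 µm of the microtubule
  or the end of the movie. Entering at the field edge does *not* censor the
  observed extent: exponential run lengths are memoryless, so the remaining
  run of a motor already attached is drawn from the same distribution.

Runs faster than 25 nm/s are classified as running (strict inequality);
landing rate is pooled events per µm of microtubule per minute, which makes
the estimate exactly invariant to splitting observation windows.

Mean run length needs care. With a mean run of 8.6 µm on 15 µm
microtubules, roughly half of all runs are truncated at the plus end, and
the plain mean of observed extents underestimates the motor's run length by
40–50%. `summarize_motility()` therefore reports both the uncorrected
observed mean (`mean_run_length`, matching the classical manual scoring)
and the censored-exponential maximum-likelihood estimate
(`run_length_mle` = total observed run length / number of uncensored runs),
which is consistent for the generative mean under end- and movie-censoring.
Closed-loop recovery uses the corrected estimate; the uncorrected mean is
what one would compare against manually scored data processed the same way.

```{r, eval = FALSE}
truth <- motility_truth()          # 0.45 um/s, 8.6 um, 0.1 /um/min
obs <- sim_motility(15, 3, truth, seed = 1)
kymo <- render_kymograph(obs, seed = 2)
runs <- trace_kymograph(kymo)
summarize_motility(runs, obs)
```

Where the paper behind these methods is silent, the generator defaults were
fixed once at values a single-molecule practitioner would call typical for
this motor: speed SD 0.12 µm/s, static fraction 0.3, wild-type landing rate
0.1 events µm⁻¹ min⁻¹, mean static dwell 30 s. Vesicle analyses use the
1.5 µm total-displacement rule for stationary classification and count
signed crossings of a line per direction for flux.

## Binding isotherms

Because the labelled receptor (50 nM) is not entirely negligible against a
~1 µM dissociation constant, the default model is the quadratic
(ligand-depletion) isotherm

$$f_b = \frac{(R + L + K_d) - \sqrt{(R + L + K_d)^2 - 4RL}}{2R},$$

which reduces to the hyperbola $L/(L+K_d)$ as $R \to 0$ (used directly when
$R$ is numerically negligible, avoiding cancellation). The titration
generator reproduces the standard mixing scheme: a 37 µM stock in a
twofold, 16-point dilution series, mixed 4:1 with receptor so the top
ligand point is $37 \times 0.8 = 29.6$ µM and the receptor stays at 50 nM.
`fit_kd()` log-parameterises $K_d$, profiles the two amplitude parameters
(they enter linearly), refines with Levenberg–Marquardt, and weights by
$1/y^2$ — the constant-CV error model appropriate for multiplicative noise.
Thermophoresis-specific normalisation is abstracted to a generic signal
column. A caveat worth knowing: with a transition amplitude that is ~12% of
the baseline signal, 2% multiplicative noise corresponds to ~16% of the
dynamic range, and single-series $K_d$ estimates scatter substantially
(quartiles roughly 0.65–1.45 µM around a true 1 µM); the weak constraint on
the bound plateau from a 29.6 µM top point is the dominant contributor, as
it is in real titrations that do not reach saturation.

## Cell-image quantification

`count_podosomes()` mirrors the classical workflow: threshold the cortactin
z-projection, label connected components, discard objects under 16 px
(2.58 µm² at the adopted 0.402 µm/px calibration), and accept an object
only if its mean actin intensity is at least 1.5× the median actin outside
all objects — an automated stand-in for the visual actin-coincidence check.
An optional distance-transform watershed splits clustered podosomes. The
default threshold is the midpoint between the background median and the
99.9th intensity percentile; Otsu is available but misbehaves when objects
cover a tiny pixel fraction, which is the normal situation here.

`enrichment_ratio()` computes, per channel,
$(\bar I_{tail} - \bar I_{bg}) / (\bar I_{cyto} - \bar I_{bg})$
over user-supplied disjoint masks (minimum 25 px each), plus the
channel-over-channel ratio of ratios. The ratio is exactly invariant to
affine intensity rescaling of a channel, which is what makes it comparable
across imaging sessions.

## Statistics and orchestration

`group_compare()` deliberately delegates to the standard tests (equal
variance two-sample t, Mann–Whitney U, Kolmogorov–Smirnov, one-way ANOVA
with Tukey HSD) with Bonferroni or step-down Holm–Šídák correction; these
are not re-derived. `run_pipeline()` executes configuration-driven
closed-loop stages with per-stage sub-seeds derived deterministically from
the run seed, so an identical configuration and seed reproduce a
byte-identical report (`write_report()`).

## What the synthetic tests show — and what they do not

The generators emulate the statistical structure the analyses assume:
mixed-binomial step counts with detection thinning, Poisson landings with
exponential runs rendered through a Gaussian PSF, Gaussian elution peaks on
exact calibration lines, quadratic-isotherm titrations with multiplicative
noise, and disc-shaped podosomes. Passing closed-loop tests therefore
demonstrates that the estimators are correct and well-calibrated *under the
assumed models*. They do not demonstrate robustness to what real data add:
non-Gaussian camera noise, uneven illumination, motor pausing and
re-binding, microtubule curvature, chromatic offsets between channels, or
podosomes that are not discs. The test-suite problem sizes (for example 60
microtubules in the round-trip suite, 100–200 replicate fits elsewhere)
were chosen so the full suite exercises every guarantee at realistic sample
sizes while remaining quick to run; the acceptance script uses 100
microtubules and 100–200 replicates per quantity.
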