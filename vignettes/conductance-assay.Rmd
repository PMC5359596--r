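---
title: "Electro-optical conductance assays: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electro-optical conductance assays: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement principle

A cell in a uniform extracellular current pulse polarizes along the field
axis: the membrane facing the cathode depolarizes, the membrane facing the
anode hyperpolarizes, and the local potential change of a membrane element
whose outward normal makes angle $\theta$ with the field is, in the lumped
passive model this package implements,

$$\Delta V(\theta, t) \;=\; k\,A\,\frac{r_{rel}}{g}\,
  \cos\theta\,\left(1 - e^{-t g / \tau_m}\right),$$

with $A$ the pulse drive (arbitrary units proportional to the injected
current $I$), $r_{rel}$ the baseline relative membrane resistance, $g$ the
total conductance fold relative to control, $\tau_m$ the membrane time
constant and $k$ a calibration constant of the simulator. At the plateau of
a pulse lasting several time constants this is Ohm's law, $\Delta V = I R$:
for a fixed current, the local potential change is proportional to membrane
resistance.

A fast voltage-sensitive dye converts $\Delta V$ linearly into fluorescence:
each membrane pixel reports $\Delta F / F_R = s\,\Delta V$, where $F_R$ is
the pre-pulse (resting) fluorescence, $F_S$ the plateau fluorescence,
$\Delta F = F_S - F_R$, and $s$ the dye sensitivity (negative for
di-4-ANEPPS-like dyes, so depolarizations are negative deflections).
Normalizing each passage to its own resting frame cancels bleaching and
illumination changes.

The assay compares two passages over the same field of cells: a *reference*
passage before compound administration and a *test* passage after. Because
the same current is applied in both, each pixel's pair of responses
satisfies

$$\frac{\Delta F_d / F_{Rd}}{\Delta F_c / F_{Rc}}
  = \frac{\Delta V_d}{\Delta V_c} = \frac{R_d}{R_c},$$

so the slope of the per-pixel scatter (test vs reference) estimates the
relative membrane resistance $R_d/R_c$, and its reciprocal the relative
conductance $G_d/G_c$. Plotting $G_d/G_c$ against log concentration and
fitting a four-parameter logistic yields the EC50 (or, for antagonist runs
at a fixed agonist challenge, the IC50).

Two consequences of the $\cos\theta$ geometry are worth noting, because the
package's tests rely on them as structural nulls: the whole-cell average
response of a symmetric cell is zero (depolarized and hyperpolarized sides
cancel), and membrane elements perpendicular to the field show no response
at all.

## What the simulator emulates

`simulate_plate()` renders the full two-passage, two-frames-per-passage
protocol for a row of wells (up to 9 sampling areas per well):

* **Cells** are membrane annuli (bright ring of configurable width over a
  dim interior) - the dye is membrane-localized, and the analysis mask is a
  ring. Radii and positions are drawn per sampling area from a per-area RNG
  stream seeded from `(master seed, well, area)`, so any subset of a plate
  reproduces identically regardless of execution order.
* **Pharmacology** is a Hill-type ground truth:
  $g(c) = 1 + (g_{max}-1)\,c^{h}/(c^{h} + EC_{50}^{h})$. Rectification is
  modeled by scaling the *drug-added* conductance on the hyperpolarized
  hemisphere by the rectification factor, so both hemispheres are exactly at
  control conductance at zero dose and split slopes emerge only with drug
  on board. (Scaling the *total* conductance instead would produce a
  spurious split at zero dose, contradicting the control behavior the assay
  is validated against.)
* **Camera**: Poisson shot noise on expected counts, Gaussian read noise,
  rounding and clipping to the bit depth. With noise disabled the frames
  are exact closed-form expectations, which is what makes the
  pipeline-vs-forward-model oracle tests possible at `1e-6` tolerances.
* **Nuisance effects**: multiplicative bleaching between passages, a rigid
  integer stage repositioning error (default up to 3 px, exercising
  registration), and an optional uniform resting-potential offset in the
  test passage.

It deliberately does **not** model: optical point-spread, sub-pixel drift,
channel gating kinetics or desensitization, electroporation, 3-D cell
shapes, or EM-CCD multiplication noise. Passing tests therefore demonstrate
the correctness and robustness of the *analysis* under the stated physics,
not performance on real microscope data - in particular, real data can
violate the linear-dye and integer-shift assumptions in ways the generator
never does.

## Default study conditions

Chosen once, on physical grounds:

| Parameter | Default | Rationale |
|---|---|---|
| frame | 160 x 160 px | ~5 cells of radius 20-26 px with placement margin |
| `f_rest` | 40000 counts | bright staining; 16-bit headroom at +3.5% dF/F |
| `dye_sens` | -0.001 / mV | ~10% dF/F per 100 mV, fast-dye regime |
| `k` | 35 mV | control plateau dF/F ~3.5%, inside the 2-5% band |
| `tau_m` | 5 ms | pulse (100 ms, sampled at 90 ms) lasts many time constants, so the plateau is established to ~1e-8 |
| bleach | 3% | few-percent inter-passage loss |
| shift | <= 3 px | sub-cell repositioning error |
| read noise | 3 counts | negligible against shot noise at 40000 counts |

The shot-noise level matters for one subtle reason: the scatter regression
has noise in the *x* variable (reference dF/F), and errors-in-variables
attenuate a least-squares slope by roughly
$\Sigma x^2 / (\Sigma x^2 + n\sigma_x^2)$. At the default brightness this
bias is ~1-2% (visible as control $G_d/G_c$ slightly above 1 and a fitted
bottom asymptote near 1.02); because it is a common multiplicative factor
across concentrations it is absorbed by the free asymptotes and leaves the
EC50 essentially unbiased. At substantially dimmer settings it would not
be negligible - which is exactly why the analysis averages raw counts
(4X binning) *before* forming ratios, the lower-variance order for
Poisson-dominated noise.

## The analysis pipeline

`analyze_area()` runs, per sampling area:

1. **Registration** - integer-pixel translation maximizing normalized
   cross-correlation within ±`max_shift`, ties broken toward the smaller
   shift (lexicographically on $(|dr|+|dc|, dr, dc)$). Sub-pixel
   interpolation is deliberately omitted: the platform's residual error is
   below pixel size, and interpolation would smooth dF/F structure. Flat
   frames are rejected as unregistrable; uncovered edge pixels become `NA`
   and are excluded downstream.
2. **Binning** - 4X block averaging of raw counts.
3. **Shape mask** - built *once*, from the binned reference resting frame:
   smoothing by a 3x3 uniform filter, thresholding at 20% of the 99.5th
   percentile intensity (relative, hence illumination-invariant; the
   platform's own threshold is not published, so both the value and the
   quantile are exposed as parameters), then keeping the ring within
   `ring_depth = 3` binned pixels of the object boundary (erosion
   difference) and dropping components below 9 px. The same mask is applied
   to both passages - pixel pairing requires identical support.
4. **dF/F maps** - per mask pixel, with exclusion of pixels whose resting
   value is at or below a floor (2000 counts) or whose |dF/F| exceeds 0.5;
   more than 50% exclusions invalidates the area.
5. **Slope** - least squares through the origin (the Ohm relation has no
   offset; a free-intercept diagnostic and a Theil-Sen fallback sit behind
   flags), after removing pairs with reference |dF/F| < 0.002, which carry
   no slope information. Split slopes on the two response signs give the
   rectification index; the reciprocal slope gives $G_d/G_c$.

Per-well statistics are the mean ± SE of per-area values (not a pooled
regression over all pixels), matching how replicate sampling areas are
treated as independent measurements of the same well.

## Curve fitting and QC

`fit_crc()` fits
$f(c) = bottom + (top - bottom)/(1 + (EC_{50}/c)^{h})$ on
$\log_{10} c$ by Levenberg-Marquardt (`minpack.lm`), weighted by $1/SE^2$
when well SEs exist. Numerical choices: start values from the low/high-dose
responses and the concentration nearest the half-response; Hill constrained
to [0.3, 5] to stabilize sparse 8-point designs; $\log_{10} EC_{50}$
bounded to the tested range ±2 decades; convergence tolerances $10^{-15}$
so noiseless fits recover parameters to ~1e-12. Degenerate inputs are
resolved rather than mis-fitted: a response range below `flat_tol = 0.1`
(in $G_d/G_c$ units, the scale on which control scatter is a few percent)
is the explicit "flat curve, no EC50" control outcome; an EC50 outside the
tested concentrations is reported with a censoring flag, not extrapolated.
The low-dose asymptote is left free by default (a `bottom_fixed = 1` mode
exists) - fixing it would hide the small attenuation bias discussed above
rather than expose it.

Antagonist runs (`ic50_from_antagonist_run()`) require agonist-alone anchor
wells and >= 3 decades of antagonist concentration; compounds are called
inactive when maximal inhibition is under 50% of the agonist window, and
fully-inhibited-everywhere runs are censored below the tested range.

QC follows the standard screening statistics: $Z = 1 - 3(\sigma_p +
\sigma_n)/|\mu_p - \mu_n|$ with sample standard deviations (replicate
counts are small), Z' computed between lowest- and highest-concentration
wells, per-concentration CV with `cv_max` as the reported figure, and EC50
fold change defined as max/min (always >= 1). A max-relative-deviation
variant is also reported by `ec50_summary()`, since fold-change values
below 1 sometimes quoted for inter-plate variation cannot arise from the
max/min definition; the package asserts nothing about which a given
instrument report used.

## Problem sizes in the shipped tests

The test-suite and acceptance script run the generator at the defaults
above: single areas for the noiseless oracles; one mock plate and twenty
seed-varied drug plates (8 half-decade concentrations around 1 µM, 5 areas
per well) for the control-flatness and EC50-recovery properties; 6 areas
per dose for rectification; 100 random frames for registration. These sizes
were chosen so the whole suite exercises every contract at full default
noise while remaining a desk-scale computation; they are smaller than an
instrument's throughput (thousands of cells per area) but large enough that
every statistical acceptance band is met with wide margin.

## Known limitations

* Ratios only: absolute resistance in ohms is not identified by the method,
  and the simulator's current drive is in arbitrary units (matching the
  unpublished absolute stimulation intensity).
* The lumped $\cos\theta$ model is not a cable/Schwan field solution; it
  reproduces exactly the property the analysis relies on (Ohm's law at
  plateau) and nothing more.
* Least squares through the origin is the primary estimator because the
  derivation prescribes a zero intercept; data violating that (e.g.
  stimulus-correlated artifacts) are better served by the free-intercept
  diagnostic.
* Integer registration cannot correct rotation or scale changes between
  passages.
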