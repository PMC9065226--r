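---
title: "Modelling a gravity-method Lutathera infusion and characterizing extravasation from dose-rate readings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a gravity-method Lutathera infusion and characterizing extravasation from dose-rate readings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extravasim)
```

## The clinical problem

Peptide receptor radionuclide therapy delivers ~7.4 GBq of
^177^Lu-DOTATATE (Lutathera) intravenously over about 40 minutes. With the
gravity infusion method, saline dripped into the sealed vial displaces the
radiopharmaceutical into the patient's line, so the vial volume stays
constant and its activity concentration is *diluted over time*. If the
cannula leaks, activity accumulates in the forearm tissue instead of the
bloodstream; because the local absorbed dose of a beta emitter tracks the
*activity concentration* of the pool, an early, small, concentrated
extravasation is the dangerous case, and a bedside survey meter held 1 cm
from the injection site is the only real-time observable. This package
implements the full chain from infusion physics to that observable and
back: simulate the activity transport, convert it to an equivalent dose
rate (EDR), and invert a measured EDR into the activity, volume and
concentration of a hypothetical extravasated pool.

## Infusion model

**Vial dilution.** With constant vial volume $V_V$ and flow schedule
$Q_j$ (phases ending at $T_j$), the vial activity obeys
$\dot A_V = -\alpha_j A_V$ with $\alpha_j = Q_j/V_V$, i.e. chained
exponentials

$$A_V(t) = A_0\, e^{-\sum_j \alpha_j\, \Delta t_j},$$

where $\Delta t_j$ is the time spent in phase $j$ up to $t$. Defaults are
the clinical protocol: $A_0 = 7232$ MBq, $V_V = 25$ mL, 50/100/200 mL/h
with switches at 10 and 20 min and $T_\mathrm{inf} = 40$ min. Over the
full infusion the exponent is $1/3 + 2/3 + 8/3 = 11/3$, so the residual
vial activity is $A_0 e^{-11/3} \approx 184.9$ MBq — the model's
"apparatus residual" (`vial_activity(40)`); radioactive decay is neglected
(the infusion is 0.4% of the ^177^Lu half-life).

**Transport.** The line (115 cm) and forearm vein (30 cm, same calibre)
form one pipe of internal radius $R$. The Reynolds numbers of the clinical
flow rates are of order 10 (`reynolds_number()`), so the flow is laminar
Poiseuille with the parabolic profile
$v_j(r) = 2\,\bar v_j (1 - r^2/R^2)$, $\bar v_j = Q_j/(\pi R^2)$. A fluid
element at radius $r$ and abscissa $s$ carries the vial concentration it
left with, delayed by the transit time $T_\mathrm{delay}(s, r, t)$
obtained by walking the distance $s$ backwards through the flow phases at
the radius-specific velocities (`time_delay()`); the concentration is zero
ahead of the advancing front $D(r,t)$ (`front_distance()`). Segment
activities are midpoint quadratures of
$C_V(t - T_\mathrm{delay})\, 2\pi r$ over the axial window and the pipe
section (`segment_activity()`), and `simulate_infusion()` books the
activity into vial / tubing / vein / patient, the patient being the
conservation remainder.

**The radius question.** Stated specifications of the administration set
quote a 2.5 mm *internal diameter*, and the kinematics demand it: with
$R = 1.25$ mm the fastest parcel needs $\approx 3.4$ min to traverse the
115 cm line and the vein activity peaks at 12 min, both consistent with
the reference observations; with $R = 2.5$ mm everything would be four
times slower. The default geometry therefore uses $R = 1.25$ mm, while
`reynolds_number()` takes the radius as an explicit argument so that
regime checks can be evaluated for any quoted pipe size (the reference
values 3.5/7.0/13.9 correspond to $R = 2.5$ mm).

## Extravasation model

A leak starting at $t_E$ does not alter the upstream pressure balance, so
the vial and line dynamics are unchanged; everything that leaves the
vial + tubing compartment after $t_E$ accumulates at the injection site:

$$A_E(t, t_E) = [A_V + A_T](t_E) - [A_V + A_T](t), \qquad
V_E(t, t_E) = \int_{t_E}^{t} Q\,\mathrm d u, \qquad
C_E = A_E / V_E.$$

The pool is assumed perfectly mixed (no spatial gradient). For onsets
before the activity front reaches the arm ($t_E \lesssim 3.4$ min) the
pool fills with saline first, which is exactly why early-onset pools can
be large yet dilute — the behaviour emerges from the equations above
without special-casing. At $t = t_E$ the concentration is a 0/0 and the
package signals a distinct degenerate-pool condition rather than
returning `NaN`.

## From activity to dose rate

The survey meter is calibrated by stepping a point source of activity
$A_\mathrm{cal} = 11.01$ MBq along the tubing at the fixed 1 cm standoff
and fitting

$$H_T(s) = a\,(s^2 + b^2)^{c/2},$$

with defaults $a = 516.4$, $b = 4.065$ cm, $c = -1.917$
(`calibration_curve()`; `fit_point_response()` refits user measurements by
Levenberg–Marquardt). The 1 cm standoff is inside the fitted constants, so
no extra 3-D distance correction is applied anywhere.

For a nonextravasated infusion the reading at the injection site $s_a$ is
the windowed line integral of the linear activity density $\lambda(s,t)$:

$$\mathrm{EDR}(t) = \frac{1}{A_\mathrm{cal}}
\int_{s_a - m}^{s_a + m} \lambda(s, t)\, H_T(s_a - s)\,\mathrm d s,$$

with $m = 20$ cm (activity further away does not register), clipped at
the physical ends of the line. For an extravasated pool the reading is the
integral of $H_T$ over the elliptical footprint of the pool,

$$\mathrm{EDR}(t) = \frac{C_E}{A_\mathrm{cal}}
\int_0^{2\pi}\!\!\int_0^{r(\theta)} H_T(r)\, r\,\mathrm d r\,\mathrm d\theta,$$

where the ellipse (aspect ratio $\mathrm{AR} = \beta/\alpha$, slab
thickness $2R$ matching the calibration tube) has
$\alpha\beta = V_E/(2R\pi)$. Two conventions are worth making explicit
because they are easy to get wrong:

* the polar equation $r(\theta)$ is written so that $r(0) = \alpha$: the
  angle is measured from the *across-arm* (minor) axis;
* the conversion follows the calibration geometry literally — in-plane
  distances in cm and $C_E$ in MBq/mL, with the slab thickness absorbed
  into $H_T$ (which was itself measured for a source inside the same
  2.5 mm tube). The formula is a calibration convention, not a radiation
  transport model.

Elongating the pool at fixed volume pushes activity away from the
detector, so the reading *decreases* with AR; AR = 2 is therefore the
precautionary assumption — a measured EDR is explained by the smallest
(and most concentrated per unit volume) pool.

## Inversion and charts

`characterize(t, edr, AR)` scans the onset time over $[0, t]$ on the
1-min grid for sign changes of the forward EDR against the reading and
refines each bracket by bisection. Each root is reported with its
$(A_E, V_E, C_E)$; when several onsets explain one reading (typical at
early measurement times, where a recent concentrated pool and an older
saline-diluted one give the same signal) all are returned and the
maximum-concentration one is flagged precautionary. `build_abacus()`
tabulates the same inversion for a grid of EDR levels (default 1–10
mSv/h) and aspect ratios (2–5), and `detect()` screens a monitoring
series against the empirical 1 mSv/h alarm threshold with a strict,
two-consecutive-sample debounce.

One subtlety the charts expose: at fixed reading and time, the AR = 2
solution has the smallest volume *and* the smallest activity, but the
inferred *concentration* is nearly flat across aspect ratios (activity
and volume shrink together), and can even increase marginally with AR.
The precautionary ordering is therefore stated — and tested — on volume
and activity, not on concentration.

## Numerical choices

* **Quadratures.** Midpoint rule throughout, at the reference resolution
  by default: 1 mm axial bins, 0.005 mm radial bins (250 across the
  1.25 mm radius), 1-min time sampling; 0.5° angular and 0.1 mm radial
  bins for the elliptical disc. All steps are configurable through
  `simulation_grid()`; a guard requires at least 50 radial bins. Halving
  the axial and radial steps moves segment activities by well under 1%.
* **Phase boundaries.** Intervals are half-open $(T_{j-1}, T_j]$:
  evaluation exactly at a switch uses the earlier phase. All piecewise
  quantities are continuous there regardless.
* **Inversion.** The root scan uses a cached tabulation of
  $A_V + A_T$ on a 0.05-min grid aligned with the phase boundaries
  (linear interpolation; the vial part stays closed-form), and bisection
  narrows each bracket to $2\times10^{-4}$ min so that every reported
  solution reproduces the measured EDR to better than 0.1%. The public
  extravasation operations do not interpolate: they evaluate the
  transport quadrature directly at any continuous time.
* **Degenerate inputs.** Zero-volume pools and $t = t_E$ concentrations
  raise a distinct `extravasim_degenerate` condition; wall fluid
  ($r = R$) has an infinite transit delay, returned as `Inf`.
* **Problem sizes.** The package's own test suite runs the full-resolution
  checks (287,500 spatial cells, 41 time samples) for the end-to-end
  results and a 50-bin coarsened grid for unit-level properties, keeping
  the default suite around two minutes.

## The synthetic monitoring generator

`synthesize_monitoring()` produces fixture series the way the bedside
protocol would: the model EDR sampled every 2 min, with multiplicative
Gaussian noise of relative standard deviation 0.2 — the stated ±20%
accuracy class of the calibrated survey meter — and an optional seed for
reproducibility. It emulates *operator-free* measurement conditions only:
it does not model detector-distance jitter, arm repositioning, patient
self-attenuation, or the growing background from activity already in the
patient (the dominant reasons real readings exceed the simulated curve
late in the infusion). Passing detection tests on synthetic series
therefore demonstrates the logic of the alarm rule, not its clinical
sensitivity or specificity.

## Known limitations

* Blood pressure and in-vein dilution by blood flow are not modelled; the
  flow rate in the vein equals the pump-imposed rate even during a leak.
* The extravasated pool is homogeneous, elliptical, of fixed thickness
  $2R$, with no lymphatic clearance or back-pressure on the line — the
  model is a radiation-protection screening tool, not a dosimetry code.
* The nonextravasated EDR underestimates late-infusion readings because
  activity already delivered to the patient contributes to real
  measurements but is outside the model's ±20 cm window.
* The calibration raw data are not distributed; the default constants are
  used as fixed inputs, and `fit_point_response()` exists for sites that
  measure their own response.
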