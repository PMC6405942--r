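---
title: "Models and methods: detecting, tracking and analyzing dynamic microtubules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: detecting, tracking and analyzing dynamic microtubules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MTdyn)
```

## The problem

In the standard in vitro reconstitution assay, GMPCPP-stabilized
microtubule seeds are immobilized on a coverglass and imaged by TIRF
microscopy in one channel, while dynamic microtubules polymerize from the
seed ends in a second channel. Dynamic instability is summarized by four
parameters: the growth velocity $v_g$ (nm/s), the shrinkage velocity $v_s$
(nm/s), the catastrophe frequency $f_c$ (1/s, growth to shrinkage) and the
rescue frequency $f_r$ (1/s, shrinkage to growth). MTdyn automates the
chain from raw images to these parameters: seed detection, per-frame tip
localization, and event segmentation of the length-versus-time traces.

Throughout, pixel centers sit at integer coordinates with the origin
`(0, 0)` at the top-left pixel center, x rightward, y downward, 0-based.
Lengths are reported in nm, times in s, angles in degrees.

## Filament intensity model

A filament's image is modelled as a chain of 2D Gaussians of PSF width
placed at constant arc spacing $ds$ along a path, plus a constant
background:
$$F_i = A\,\big(G_{\mathrm{start},i} + \textstyle\sum_j G_{j,i} +
G_{\mathrm{end},i}\big) + Bg, \qquad
G_{j,i} = \exp\!\Big(-\frac{(i_x-\mu_{x,j})^2}{2\sigma_x^2}
                     -\frac{(i_y-\mu_{y,j})^2}{2\sigma_y^2}\Big).$$
The PSF widths $\sigma_x, \sigma_y$ are user input derived from the
measured FWHM ($\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$), not fit
parameters. For seeds the path is a straight line; for dynamic
microtubules it is a third-order polynomial
$y = I x^3 + b x^2 + m x + c$, which accommodates bending and crossing
filaments. The slope $m$ is eliminated through the two endpoints, so the
path passes through both for any $(b, I)$; near-vertical filaments are
fitted in the x/y-swapped frame, where the polynomial parameterization is
well conditioned.

Fitting minimizes $\chi^2(\theta) = \sum_i (I_i - F_i(\theta))^2$ with a
Levenberg-Marquardt solver and analytic derivatives. The free parameters
are the endpoint coordinates (the seed end is held fixed in the dynamic
channel), the spacing $ds$, the amplitude $A$, the background $Bg$, and
for the polynomial model the curvature $b$ and inflection $I$.

### Chain geometry and the analytic gradient

The interior chain is explicit model state: it is rebuilt from the current
parameters between solver iterations, and within one geometry the model
responds linearly — the terminal Gaussians follow the endpoint parameters
exactly, while interior Gaussian $j$ is displaced by
$j\,[(ds - ds_0)\vec B_j + (b - b_0)\vec J_j + (I - I_0)\vec L_j]$, with
$\vec B_j$ the unit tangent at Gaussian $j$ and $\vec J_j$, $\vec L_j$ the
curvature/inflection direction fields derived from the per-Gaussian
tangent. The analytic derivatives are exact for this model, which is the
same function the solver minimizes and the finite-difference tests
differentiate. Endpoint derivatives involve only the terminal Gaussians:
the chain anchor is part of the geometry, not of the endpoint response.

### Solver

The approximate Hessian keeps only the first-order term
$H = 2 D^\top D$; the step is $\delta = -(H + \lambda_d\,
\mathrm{diag}\,H)^{-1} g$ with the damping factor divided by 10 after an
accepted step and multiplied by 10 after a rejected one (initial
$10^{-3}$; stop at $|\Delta\chi^2|/\chi^2 < 10^{-10}$, step
$< 10^{-4}$ px, or 100 iterations). Accepted steps never increase
$\chi^2$, evaluated under the rebuilt geometry. Because the
frozen-geometry gradient has its stationary point a few hundredths of a
pixel from the exact optimum, the fit ends with a short damped
Gauss-Newton polish of the exact objective using a central
finite-difference Jacobian; an optional thorough mode additionally probes
the neighbouring Gaussian-count branches of the chain, across which
$\chi^2$ is discontinuous (used in the solver validation tests, where it
recovers noiseless optima to machine precision).

### End-point refinement

End points are refined with an iterative Gaussian-mask fit. The weight
mask is the sum of two Gaussians, one at the current estimate and one at
$ds$ towards the filament interior. Because the filament continues under
the mask, the plain mask-weighted image centroid has its fixed point
displaced inward; the update therefore moves the estimate by the
difference between the mask-weighted centroid of the
(background-subtracted) image and the mask-weighted centroid of a model
tip profile (a dense Gaussian chain ending at the current estimate).
For images that follow the model, the fixed point of this iteration is
exactly the true tip, so the refinement is unbiased by construction along
the filament axis. Tolerance $10^{-3}$ px, at most 50 iterations, and an
estimate drifting more than $3\sigma$ from its start is returned
unrefined and flagged.

## Seed detection

Seeds are segmented with maximally stable extremal regions (MSER) on the
component tree of the image's upper level sets: a region is reported where
its relative area growth across `delta` quantized gray levels is a local
minimum along its branch and below `max_variation`, with area bounds and
nested-duplicate suppression (only the most stable node of a nested chain
survives). Each region carries the centroid and second central moments
$(p, q, r)$ of its pixel set; the major axis of the equivalent ellipse,
with $d_r = \sqrt{p^2 + 4q^2 - 2pr + r^2}$, has slope
$m = (r - p + d_r)/(2q)$ and passes through the centroid; axis-aligned
ellipses ($q = 0$) are handled by the eigen decomposition directly,
including the vertical-axis case. The line model is initialized from the
extreme projections of the region pixels onto that axis and fitted in a
window equal to the region bounding box dilated by $3\sigma$ (so the
background is estimable), with initial $ds = \sigma_x$, amplitude
`max - median` and background `median` of the window.

Two detector defaults differ deliberately from textbook MSER practice on
natural images, because TIRF data are Poisson-limited:

* the image is presmoothed with a Gaussian of $\sigma = 1$ px (a matched
  filter; the PSF $\sigma$ at 156 nm pixels is about 0.54 px). Smoothing
  bridges single-pixel dropouts along a noisy ridge so a seed stays one
  component across thresholds. It is kept at 1 px so that two ridges 5 px
  apart — the separation regime in which one-to-one detection is expected
  to hold — are not blurred into one region. All model fits run on the
  raw image, so localization is unaffected;
* the stability `delta` is 25 gray levels of the 8-bit-normalized image,
  i.e. roughly two to three photon counts at typical scaling. A delta
  below one count makes every noise excursion "maximally stable".

Both are exposed in `mser_config()` together with `min_area` (10 px),
`max_area` (10% of the image) and `max_variation` (0.5).

## Tracking

Per dynamic frame, MSER regions are detected, and each track projects a
ray from its fixed seed end along the chord from the seed end to the
previous accepted tip. (The tip tangent of the fitted cubic was evaluated
and rejected for this purpose: its angle inherits the noise of the
higher-order coefficients, and a few degrees of rotation walks the ray
off a one-pixel-wide ridge.) Candidate regions are those the ray crosses;
within a region the end-point guess is the farthest ray point whose
intensity reaches 50% of the region maximum (region maximum, i.e. local
context). The polynomial model is fitted with the start fixed at the seed
end, using the previous frame's $(b, I)$ as the initial guess (zero in
the first frame, per the seed line).

A fit is rejected as a gap when the chord direction turns by more than
20 degrees, or when $b$ or $I$ jumps by more than 10 running standard
deviations — with the SD floored at the coefficient change that deflects
the tip by one pixel ($1/L^2$ and $1/L^3$ for length $L$ px), so
fluctuations below a pixel of deflection are never rejected. Near-zero
length filaments have no defined direction, so the rules apply only once
the tip clears the seed end by 5 px. When several regions intersect the
ray, all are fitted and the tip nearest the last known position wins.
Gaps do not advance the track before its first accepted point (the
microtubule may not have nucleated yet); afterwards a track closes after
`max_gap = 5` consecutive gaps. Contour length is the arc length of the
fitted path from the seed end to the mask-refined tip, by adaptive
quadrature, times the pixel size.

## Event segmentation and dynamics parameters

Length-versus-time tracks are segmented by iterative RANSAC. Growth is
assumed near-linear: minimal samples of 4 points (spanning at least 5
frames) seed a third-order polynomial fit ridge-penalized towards a line
($\lambda_{reg} = 10^3$ in normalized units); inliers are points within
$\varepsilon$ of the fit; the largest run of inliers consecutive in time
wins, its points are removed from the sampling set (which therefore
shrinks strictly, guaranteeing termination), and the search repeats until
no event with at least 3 points remains. Every reported slope comes from
a plain linear refit to the event's inliers. A run may bridge up to 2
frames missing from the track (dropouts) but never a measured point
outside $\varepsilon$: a present outlier is evidence of another phase.
Shrinkage is then segmented the same way on the remaining points with a
linear model restricted to fast decline (slope below $-2 v_g$ of the same
track by default). The default $\varepsilon$ is 3 times the per-frame
localization noise estimated from the track's high-frequency differences
(a robust MAD of `diff(length)` divided by $\sqrt 2$); events shorter
than 3 frames are discarded as noise. RANSAC uses 500 iterations per
event and a fixed seed (default 42) for reproducibility.

Transitions are classified against the seed baseline (length 0): a
shrinkage followed by growth resuming at or below baseline (within
$\varepsilon$) is a total catastrophe, above it a rescue; a track ending
mid-shrink leaves the transition incomplete. The length at the transition
is read at the intersection of the shrink and growth lines (the kink of
the sawtooth) — the growth line evaluated at its own first inlier sits a
frame or two after the true valley and would misclassify total
catastrophes as shallow rescues. Frequencies are events over
time in the censored-exponential form: $f_c$ counts growth events whose
immediately following event is a shrinkage (an observed catastrophe) over
the summed durations of exactly those growth events; $f_r$ counts rescues
over the summed durations of complete shrinkage events. Durations are
reduced by a detection dead time (`min_inliers` frame intervals): events
shorter than about 3 frames are undetectable, and for a memoryless
switching process an event known to have survived the dead time carries
no switching risk during it, so the subtraction keeps the events/time
estimator consistent. Velocities are averaged over complete events when
any exist: an event whose bounding transition went undetected may
straddle a phase corner and bias its slope, and completeness is
independent of the event's own slope, so the restriction removes bias
without selection effects. When both seed ends are tracked, the faster
growing end (larger mean growth slope, ties broken by total length
gained) is labeled the plus end.

Two limitations are intrinsic rather than implementation choices:
catastrophe excursions shorter than about $2\varepsilon$ in length are
invisible at tolerance $\varepsilon$ (two events merge), and shrinkage
phases shorter than 3 frames cannot be segmented. Both deflate the
apparent event counts at a rate governed by
$\exp(-2\varepsilon f_c / v_g)$ and the frame interval; under the
validation conditions below they are percent-level effects.

## The length distribution

Given $(v_g, v_s, f_c, f_r)$ the two-state advection equations
$$\partial_t p_g = -v_g \partial_x p_g - f_c p_g + f_r p_s, \qquad
  \partial_t p_s = +v_s \partial_x p_s + f_c p_g - f_r p_s,$$
with the shrinking flux through $x = 0$ re-entering the growing state at
the seed, are integrated on a length grid (first-order upwind, 400 cells
over eight mean lengths, `deSolve::lsoda`). In the bounded regime
($v_g f_r < v_s f_c$) the time-averaged distribution is exponential with
decay constant $f_c/v_g - f_r/v_s$ per nm; the implementation reports the
long-time average and raises a distinct non-stationarity condition in the
unbounded regime (including $f_c = 0$), where only distributions at
finite time are available.

## What the simulator emulates — and what it does not

The generator renders filaments as dense Gaussian chains (spacing
$\sigma/3$, finer than fit-time spacing, with both chain ends exactly at
the filament end points) along lines or third-order polynomials, scaled
so the ridge intensity equals the configured amplitude, on a constant
background, and draws per-pixel Poisson counts. The intensity scale is
calibrated so the measured SNR — the mean over the standard deviation of
the pixel intensities along a background-subtracted ridge line scan —
matches the target: the ridge mean $\lambda$ solves
$\lambda/\sqrt{\lambda + Bg} = \mathrm{SNR}$, which reduces to the
familiar $\mathrm{SNR} = \sqrt\lambda$ on zero background. Trajectories
follow the two-state telegraph process: exponential waiting times with
rates $f_c$ (growth) and $f_r$ (shrinkage), shrinkage clamped at the seed
with an immediate regrowth recorded as a total catastrophe. The paper
trail for Figure-style accuracy claims does not state a switching
schedule; the telegraph choice is the natural memoryless model and is
also what the frequency estimators assume.

Not emulated: camera EM gain and read noise, photobleaching, fluorophore
labeling density, out-of-focus excursions, and pixel-area integration
(the renderer samples the PSF at pixel centers, as does the model, so the
two are consistent with each other but idealize a real detector). Passing
tests on these simulations therefore demonstrate the correctness of the
algorithms under Poisson noise at calibrated SNR, not robustness to every
camera artifact.

Default optics follow the experimental setup the package targets: 156 nm
pixels, PSF FWHM 199 nm (seed channel) and 205 nm (dynamic channel), i.e.
$\sigma \approx 0.54$ px; image size 512 px; experimental growth speeds
of roughly 0.4-3 um/min motivate the validation conditions
$v_g = 8$ nm/s, $v_s = 50$ nm/s, $f_c = 0.008$/s, $f_r = 0.02$/s,
2 s frames, 300 frames per track and 10 nm track noise (about 0.06 px).
Validation problem sizes were chosen once as the smallest sets whose
binomial or Poisson sampling error is comfortably below the effects being
checked: 8 seed fields of 15 seeds (512 px) for detection accuracy in the
test suite, with the reproduction script running the full 20-field
experiment; at least 100 seeds per SNR for endpoint localization; 16
movies of 30 frames for tracking accuracy; 100 telegraph tracks for
parameter recovery; and 10 crossing geometries at 30-90 degrees.

## Numerical choices and degenerate inputs

* Degenerate ellipses ($q = 0$) use the eigen decomposition directly;
  vertical major axes are parameterized by their abscissa.
* Zero-length filaments render and model as a single Gaussian spot.
* $ds$ is clamped to $[\sigma/3, 5\sigma]$ and the amplitude to positive
  values during fitting; trial steps are clamped, not rejected.
* A singular normal system raises the damping instead of failing; fits
  that still fail drop the region (seed channel) or record a gap
  (dynamic channel) — never a hard error.
* A constant scan yields an infinite SNR, distinct from failure; scans
  read nearest-pixel intensities because interpolation would smooth the
  noise and inflate the SNR.
* The RANSAC sampling set shrinks strictly every iteration, so the event
  search terminates; with a fixed seed the segmentation is reproducible
  run to run.
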