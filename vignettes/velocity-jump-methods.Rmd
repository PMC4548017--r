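---
title: "Velocity-jump processes with resting states: models, numerics and estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity-jump processes with resting states: models, numerics and estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vjump)
```

## The model

`vjump` implements a two-state generalised velocity-jump (VJ) process: an
agent alternates between *runs*, during which it moves with a constant
velocity, and *rests*, during which it is stationary but remembers its
orientation. Three stochastic ingredients specify the process:

* the run-duration law $f_\tau(t)$ and the rest-duration law
  $f_\omega(t)$, each an exponential, gamma or inverse-Gaussian
  distribution (`time_dist()`), all with analytic Laplace transforms;
* a separable reorientation kernel: on returning to a run the turn angle
  relative to the stored heading follows a von Mises law
  $\Theta(\theta) = e^{\kappa\cos\theta} / (2\pi I_0(\kappa))$ and the new
  speed is drawn independently of the old one (`turning_kernel()`).

Two scalar summaries of the reorientation kernel govern everything
downstream: the index of persistence
$\psi_d = I_1(\kappa)/I_0(\kappa) \in [0,1)$, the mean cosine of a turn,
and the mean squared speed $S_T^2 = E[s^2]$.

Because the duration laws need not be exponential, the process is
non-Markovian: the density-level description involves renewal-type *delay
kernels* defined in Laplace space by
$$\bar\Phi_i(\lambda) = \frac{\lambda \bar f_i(\lambda)}{1 - \bar f_i(\lambda)},
  \qquad i \in \{\tau, \omega\},$$
which collapse to constant rates exactly when the durations are
exponential. In the time domain each kernel decomposes as
$\Phi(t) = c\,\delta(t) + \Phi_{\mathrm{reg}}(t)$ with impulse weight
$c = \lim_{\lambda\to\infty} \lambda\bar f(\lambda) = f(0^+)$: the rate
for exponential laws, zero for inverse-Gaussian and for gamma with shape
above one, and divergent for gamma shapes below one — those laws are
rejected by the moment solver (the sample-path simulator handles them
fine). Equivalently, $\Phi$ is the distributional derivative of the
renewal density, which is how the test suite validates the reconstructed
kernels: the double time-integral of $c\,\delta + \Phi_{\mathrm{reg}}$
must match Monte-Carlo renewal counts.

## Numerical Laplace inversion

$\Phi_{\mathrm{reg}}$ rarely has a closed form, so it is recovered on a
grid by numerically inverting $\bar\Phi(\lambda) - c$
(`invert_laplace()`, `kernel_on_grid()`). Two independent methods are
provided and cross-checked to $10^{-6}$ in the tests:

* **fixed-contour Talbot** quadrature (default 32 nodes); the contour is
  evaluated at points proportional to $1/t$, so inversion at a whole time
  grid costs one transform evaluation per node;
* **Euler summation** of the Bromwich series (discretisation parameter
  $A = 18.4$, 18 terms plus 15-term binomial averaging).

Branch handling: the gamma and inverse-Gaussian transforms carry a branch
point on the negative real axis; transforms are evaluated with principal
roots and both contours stay clear of the cut for every supported
parameterisation. A transform evaluation that lands on the cut raises an
error rather than returning a wrong branch.

## The moment equations for the MSD

A full space–velocity solution of the transport equations is impractical;
instead the package solves the closed system of eight Volterra
integro-differential equations for the moment functionals
$N_p, N_r$ (counts), $B_p, B_r$ (velocity–displacement correlations),
$V_p^2, V_r^2$ (squared-velocity functionals) and $D_p^2, D_r^2$ (squared
displacements), from which the population mean squared displacement is
$(D_p^2 + D_r^2)/N_0$. The convolutions carry time-weighted kernels
($(t-s)$ and $(t-s)^2$ factors) that encode the spatial delays of the
non-Markovian transport equations.

`solve_moments()` offers two independent routes:

* **time domain** (the default): trapezoidal quadrature for the
  convolution integrals and a Crank–Nicolson step for the differential
  operators, both second order, so halving `dt` cuts the error about
  fourfold (asserted in the tests against a stiff-ODE oracle for the
  exponential case, where the system reduces exactly to a Markovian ODE
  system). The delta component of each kernel contributes its full weight
  at the current time — the endpoint convention that reproduces the
  Markovian limit exactly; time-weighted kernels carry no impulse since
  $t^k \delta(t) = 0$ for $k \ge 1$. Weighted kernel tables are built
  once per solve; the total cost is $O(n^2)$ in the number of steps.
* **Laplace domain**: the transformed system is a lower-triangular
  cascade of $2\times2$ linear solves (the time-weighted convolutions
  become analytic kernel derivatives $-\bar\Phi'$ and $+\bar\Phi''$),
  inverted by Talbot quadrature at each output time. This route involves
  no time stepping at all and serves as the independent cross-check: the
  two solvers agree to better than $10^{-5}$ relative on all eight series
  for both exponential and inverse-Gaussian kernels.

Initial conditions follow the convention that phases in progress at
$t = 0$ started at $t = 0$ (no stationary-age correction, no history
function). All series start at zero except the counts and
$V_p^2(0) = S_T^2 N_p(0)$: each initial runner carries a freshly drawn
speed. The default step is `min(mean run, mean rest)/50`; a warning is
raised when a user-supplied step is too coarse to resolve the kernels.

## Large-time diffusion

At large times the MSD grows linearly and the process behaves like
diffusion with
$$D_{\mathrm{eff}} = \frac{S_T^2}{n}\,
  \frac{\mu_\tau^2}{\mu_\tau + \mu_\omega}
  \left[\frac{1}{1-\psi_d}
  + \frac{1}{2}\Bigl(\frac{\sigma_\tau^2}{\mu_\tau^2} - 1\Bigr)\right],$$
implemented in `effective_diffusion()`. The bracket's second term is the
non-Markovian correction: it vanishes for exponential runs and grows with
the run-duration variance, while the rest law enters only through its
mean. The observable read off an empirical MSD curve is the growth rate
$2 n D_{\mathrm{eff}}$ (`msd_slope()`); for the bacterial parameter set
(exponential runs at 2.30 s$^{-1}$, rests at 11.98 s$^{-1}$,
$\psi_d = 0.46$, $S_T^2 = 9.26\,\mu$m$^2$/s) this evaluates to
12.51 $\mu$m$^2$/s, and for the gull set (inverse-Gaussian runs
IG(1.26, 1.22) days, rests IG(10.79, 7.42) days, $\psi_d = 0.42$,
$S_T^2 = 1.03\times10^5$ km$^2$/day) to $4.72\times10^4$ km$^2$/day.

```{r}
msd_slope(from_model(time_dist("exp", 2.30), time_dist("exp", 11.98),
                     psi_d = 0.46, S_T2 = 9.26))
```

One caveat the tests quantify deliberately: with the bacterial
parameters the *window-averaged* MSD slope over $t \in [3, 4]$ s is still
about 2% below $2nD_{\mathrm{eff}}$, because the slowest mode of the
correlation subsystem decays at only $\approx 1.13$ s$^{-1}$; the
instantaneous growth rate at $t = 4$ s is within 1.2%. "Has entered the
diffusive regime by 4 s" is thus accurate to about the 2% level, not
better, and the corresponding acceptance assertion is expected to sit
marginally outside a 2% band.

## Sample-path simulation

`simulate_path()`/`ensemble_msd()` generate exact sample paths by direct
Gillespie-style sampling: alternating durations from the two laws, a
fresh speed and a von-Mises-turned heading at each run start (the first
post-rest turn uses the orientation stored in the rest), truncation of
the final phase at `T_end`. Von Mises draws use the Best–Fisher rejection
sampler; inverse-Gaussian durations use the Michael–Schucany–Haas
transformation. Ensembles stream: the MSD accumulates path by path, so
$3\times10^4$ paths need no more memory than one.

The planar benchmark configurations (unit speed, uniform turning,
exponential or gamma durations with means one) connect all three layers:
simulated ensembles match the moment solver within Monte-Carlo error, and
at $t = 100$ the positional density cross-section matches the Gaussian
heat kernel with the predicted $D_{\mathrm{eff}} = 1/4$. For the
high-variance gamma pair (run Gamma(1/7, 7), rest Gamma(1/14, 14),
$D_{\mathrm{eff}} = 1$) the MSD *slope* reaches $2nD_{\mathrm{eff}}$
within a few percent by $t = 100$ while the MSD *level* is still ~5%
below the Gaussian line — convergence to the parabolic limit is slow for
heavy-tailed durations, so the level-based goodness-of-fit test is run
only for the exponential pair and the gamma pair is asserted through its
slope.

## Parameter extraction from tracks

Two data situations are supported.

**Finely sampled labelled tracks** (`extract_phase_stats()`): states are
an input column; durations are maximal constant-state sample stretches,
per-run headings and speeds come from net displacements (exact for
straight runs), and turn angles are taken between runs separated by
exactly one rest. The final phase is right-censored by the record end and
never enters the duration lists; the first phase is also censored (the
track starts mid-phase) but kept by default — the bias is small when
phases are short relative to the record, and `truncate_first_phase`
removes it when records afford it. Fitting is standard maximum
likelihood per family (`fit_duration_dist()`), with the von Mises
concentration solved from $I_1(\kappa)/I_0(\kappa) = \overline{\cos\theta}$
(`fit_vonmises_kappa()`).

**Coarse GPS tracks** (`segment_track()`, `gps_phase_stats()`,
`fit_track_parameters()`): states are inferred by thresholding the
convex-hull diameter of a sliding 24 h window (10 evaluations/day,
threshold 52 km by default; hull diameter computed as the maximum
pairwise haversine distance, which is equivalent and simpler than a
minimum bounding circle; Earth radius 6371 km). Resting phases shorter
than 2 days are relabelled as running. Window evaluation times sit on a
regular grid anchored at the track's first midnight; edge windows use
the available fixes.

Thresholded segmentation has three systematic biases, each corrected by
the package as its own methodology:

1. **Boundary shift.** A rest is only labelled "resting" once the window
   no longer contains enough run movement, so each detected rest is
   labelled short by roughly $\delta = W/2 - d_{thr}/s$ per side. Rather
   than applying this geometric formula, `gps_phase_stats()` exploits the
   spatial stationarity of rests: the contiguous stretch of fixes at the
   rest's centroid delimits its true extent to within half a fix
   interval, independent of window geometry.
2. **Left truncation.** Rests that fail the 2-day filter are
   unobservable. Since a boundary can be mislabelled by at most half a
   window, any rest longer than `min_rest + window` (3 days by default)
   is guaranteed to survive, and the rest law is fitted by maximum
   likelihood left-truncated exactly there. Final in-progress rests enter
   as right-censored survivor terms — dropping them would length-bias
   the fit low, because long rests are the ones most likely to straddle
   the record end.
3. **Run merging.** Runs glued across missed short rests would inflate
   run durations by ~20%. Missed rests are directly visible inside an
   observed run as stretches of fixes below the detectability speed
   `threshold/window`; observed runs are split there, transition times
   are sharpened using the residual displacement of the boundary
   segments, and the resulting pieces are fitted directly. Conversely, a
   run too slow to break the threshold welds two rests together; such
   welded rests are recognised by their two stationary clusters and
   excluded from the rest sample.

Turn angles are measured between local fix-to-fix headings just inside
the two runs flanking each detected rest (robust to merging elsewhere,
and the two segments are nearly co-located so spherical bearing
differences are well defined); $S_T^2$ averages squared fix-to-fix
segment speeds inside corrected runs, excluding sub-floor segments —
time-weighting, which equals per-run weighting because the model draws
speed independently of duration.

## Synthetic data and what the tests do (and do not) show

`fixture_spec()` locks five scenarios to the case-study parameter sets
(bacterial: exponential 2.30/11.98 s$^{-1}$, $\psi_d = 0.46$,
$S_T^2 = 9.26$; gull: IG(1.26, 1.22)/IG(10.79, 7.42) days,
$\psi_d = 0.42$, $S_T^2 = 1.03\times10^5$; and the three planar
benchmarks). Speed-law families are not pinned down by the summary
statistics, so both data-like scenarios use lognormal speeds with the
matched second moment (spread 0.25 on the log scale) — only $S_T^2$
matters downstream. Initial-state fractions follow the published counts
(66/1868 running for the bacteria, 6/62 for the gulls). Gull tracks
default to 120 days at 10 fixes/day, giving ~10 run/rest cycles per
track; planar paths are wrapped onto the sphere by inverse
azimuthal-equidistant projection about (52°N, 4.5°E), which keeps local
distances accurate to well under a percent at these excursions and is
valid at any displacement.

The generators emulate the *model*, not everything about real data:
rests are exactly stationary (no central-place foraging loops), runs are
exactly straight, there are no day–night cycles, coastlines or
measurement gaps, and GPS jitter is optional isotropic Gaussian noise.
Passing recovery tests therefore demonstrates that the estimation
pipeline inverts the segmentation process correctly — not that the model
captures every feature of real tracking data.

Sample sizes in the tests are chosen to balance statistical resolution
against runtime: 2000 labelled tracks of 10 s for the bacterial recovery
(sampled at 5 ms so that rests of mean 83 ms are resolved), 200 GPS
tracks of 120 days for the gull recovery, $3\times10^4$ paths for the
planar ensemble comparison. At the gull study size the sampling noise of
the rest-law fit is ~3.5% (one sigma) *even with perfectly measured
phases* — a floor set by ~1500 usable rests — so single replicates can
stray outside a 10% band by luck alone; the recovery acceptance test
therefore asserts the median error across three independent replicates,
with per-replicate results reported alongside.

## Known limitations

* Gamma duration laws with shape below one are supported by the
  simulator and the diffusion formula but not by the moment solver
  (divergent kernel impulse); gamma shapes in $(1, 2)$ have a singular
  kernel regular part at $t = 0^+$ and the solver substitutes the first
  grid value with a warning.
* Heavy-tailed laws with infinite variance (fractional-diffusion
  regimes) are out of scope throughout.
* The small-time behaviour of the MSD for non-exponential kernels has no
  closed reference; only the large-time slope is validated analytically.
* Segmentation corrections assume rests are spatially tight relative to
  the threshold scale and runs are fast relative to
  `threshold/window`; species with slow, diffuse movement between camps
  would need different tuning.
* Rotational/translational diffusion during phases, chemotaxis and
  agent–agent or agent–environment interactions are not modelled.
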