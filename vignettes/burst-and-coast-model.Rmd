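---
title: "A burst-and-coast model of schooling fish under variable light"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A burst-and-coast model of schooling fish under variable light}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishschool)
```

## The model

Rummy-nose tetra (*Hemigrammus rhodostomus*) swim intermittently: a brief
burst (a "kick") sets a new heading, followed by a passive glide along a
straight line with quasi-exponentially decaying speed. Because heading
decisions are concentrated at kick onsets, a trajectory can be treated as a
sequence of discrete decisions, and the behavioral rules can be written at
the level of single kicks.

`fishschool` implements this picture for `N` fish in a circular arena of
radius `R` (default 250 mm). The `n`-th kick of a fish is described by its
onset time, duration `tau`, length `l`, and new heading `phi[n+1] = phi[n] +
dphi`. During the glide, the distance covered a time `dt` after the onset is

    l * (1 - exp(-dt / tau0)) / (1 - exp(-tau / tau0)),

with `tau0` the glide decay time, so peak speed, duration and length obey
`l = v_peak * tau0 * (1 - exp(-tau / tau0))` (`kick_length_from_speed()`).
Kicks of different fish are asynchronous; the event loop
(`simulate_school()`) always advances the fish whose kick ends first,
interpolating every other fish to that instant with the glide formula.

The heading change at a kick is an additive combination of three terms:

* **Spontaneous noise** — Gaussian with standard deviation
  `gamma_R * (1 - alpha * exp(-(r_w / l_w)^2))`: heading fluctuations are
  damped near the wall (`spontaneous_dphi()`).
* **Wall avoidance** — `f_w(r_w) * O_w(theta_w)` with a Gaussian radial
  fall-off `f_w = gamma_w * exp(-(r_w / l_w)^2)` and the odd angular profile
  `O_w ~ sin(theta_w)[1 + 0.8 cos(2 theta_w)]` (`wall_dphi()`). `theta_w`
  is the heading relative to the local wall normal; `+/- 90` degrees is
  tangential swimming, and the sign convention makes the fish turn away
  from the wall on the side it occupies.
* **Social interactions** — a sum of pairwise attraction and alignment
  (`social_dphi()`), each a product of a radial intensity and two angular
  profiles with fixed parity:
  attraction `f_Att(d) O_Att(psi) E_Att(delta_phi)` is odd in the viewing
  angle `psi` and even in the relative orientation `delta_phi`, repulsive
  below `d_att`; alignment `f_Ali(d) O_Ali(delta_phi) E_Ali(psi)` is odd in
  `delta_phi` and even in `psi` and vanishes at contact. In groups a fish
  attends only to its `k = 2` most influential neighbors, influence being
  the absolute social contribution (`influence()`, `select_neighbors()`).

All angular profiles are normalized so their mean square over a period is
one (`normalize_angular()`); intensities therefore live in the radial
factors. The combined wall profile normalizes to 1.9612, which the test
suite checks to four decimals.

A candidate kick is accepted only if the point `l + l_c` ahead of the fish
stays inside the arena — the fish keeps a comfort distance `l_c` to the
wall. On rejection the noise term, duration and length are resampled
jointly (the wall and social terms are frozen: they describe the state at
the decision instant, which does not change inside the loop). After 1000
failures the spontaneous term is drawn uniformly on `(-pi, pi)` until a
kick fits; if even that stalls because the sampled length itself is too
long, duration and length are resampled as well, which guarantees progress.

Durations are drawn from the two-exponential family
`-0.5 * tau_bar * log(r1 r2)` (mean `tau_bar`), resampled below `tau_min`;
peak speeds use the same family. For pairs, kick lengths are drawn with the
distance-modulated mean `F_m(d) = l_m - gamma_m (d + d_m) exp(-d / l_m)`
("the closer the fish, the shorter the kick"); the exponent is a decay so
that `F_m` saturates at `l_m` for distant fish, and the modulation is
strongest at `d = l_m - d_m`. For `N >= 3` the modulation is dropped and
the mean kick length `l_bar` is used directly.

## Parameters and packaged defaults

One light condition (0.5, 1, 1.5, 5 or 50 lx) is a full parameter vector
(`light_params()`); packaged defaults exist for all five conditions and
four group sizes (`default_light_params()`, files under
`inst/extdata/params/`). Entries fall into two classes:

* **Measured anchors** taken from the experimental literature on this
  species and setup: the single-fish noise intensities `gamma_R` (0.26 to
  0.43 rad from 0.5 to 50 lx), the glide decay times `tau0` for singles
  (0.34 to 0.87 s) and pairs (0.39 to 0.79 s), the duration sampler mean
  `tau_bar = 0.45 s` and threshold `tau_min = 0.22 s` at 50 lx, and mean
  kick lengths (31 to 62 mm) anchoring `l_bar` and the modulation
  saturation `l_m`.
* **Documented placeholders** for everything only published in
  supplementary tables: wall parameters, near-wall noise reduction `alpha`,
  the social intensities and ranges, and the comfort distance
  `l_c = 15 mm`. These were chosen once, before the test suite was frozen,
  to reproduce the qualitative regimes the biology dictates, and they are
  the package's *definition* of its five conditions rather than estimates
  of the original ones.

The placeholder choices encode the reported trends: wall repulsion
intensity and range grow with light, attraction strengthens with light,
alignment intensity falls while its range grows. With them the model
reproduces, at the packaged defaults:

* a single fish wall-following at a mean wall distance falling from about
  32 mm (0.5 lx) to about 22 mm (50 lx) — driven mostly by the kick length:
  the farther a fish glides per kick, the harder it is to escape a concave
  wall, which the stochastic-ordering test isolates by varying only the
  kick-length scale;
* pairs swimming about 67 mm apart at 50 lx with the geometrical leader
  (the fish with the larger absolute viewing angle) closer to the wall;
* groups of 5 forming a cohesive polarized school (polarization near 0.9,
  radius of gyration near 50 mm);
* groups of 25 spreading along the wall into a rotating, tank-spanning
  mill (milling index near 0.9, negligible polarization).

Two placeholder decisions deserve emphasis. First, the group parameter
tables use a heading-noise intensity (about 0.12 to 0.15 rad) well below
the printed single-fish values; the printed values are explicitly
single-fish measurements, and in this model the polarized and milling
regimes do not form if fish in groups are assumed to turn as noisily as
fish swimming alone. Second, the noise-reduction factor `alpha` increases
with light (0.15 to 0.8): near-wall damping of heading fluctuations is
treated as vision-mediated, so it weakens in the dark. Both are exposed as
ordinary parameters and can be overridden.

The ranges appearing in the noise reduction and in the wall force share the
symbol `l_w`; they are fitted from different observables, so the container
exposes an optional override `l_w_noise` (defaulting to `l_w`).

## Measurement pipeline

`pixels_to_mm()` converts tracker output (pixels at 25 Hz) to centered
metric coordinates at 0.478 mm/pixel. `resolve_identities()` repairs label
swaps by minimum-total-displacement assignment between consecutive frames
(a hand-written shortest-augmenting-path solver, `lap_solve()`, checked
against exhaustive permutation search); frames with missing detections
split the data into independently relabeled segments.
`activity_filter()` removes stopping behavior: windows where the fastest
fish stays below 40 mm/s for more than 2 s.

`detect_kicks()` segments a single-fish trajectory into kicks: speeds from
centered differences, smoothed with a degree-3 Savitzky-Golay filter over
0.36 s, split into acceleration/deceleration phases, phases shorter than
0.08 s merged, onsets at acceleration starts. Because the model treats the
burst as instantaneous, a simulated kick whose new peak speed is below the
previous glide's tail produces no speed minimum; the detector therefore
also splits phases at frame-to-frame speed ratios impossible under glide
decay (ratio outside `[1/1.25, 1.25]`). On continuous real-world speed
profiles that rule never fires. On simulator output, over 80% of onsets
are recovered within one frame; the residual misses are transitions where
consecutive kicks happen to have nearly equal speeds and are invisible in
any speed-based segmentation. Per-kick heading changes are measured as the
difference between successive glide directions (net displacement between
onsets), which matches the model's definition exactly.

`mirror_augment()` doubles a data set with its `y -> -y` reflection,
enforcing the left/right symmetry of swimming statistics and halving the
variance of reconstructed angular profiles.

## Reconstruction

The reconstruction inverts the model from kick tables:

* `fit_gamma_R()` — the standard deviation of heading changes at kicks far
  from the wall (`r_w > 60 mm`, where the wall influence is negligible).
* `fit_tau0()` — least-squares exponential fit to within-kick speed
  profiles normalized at the kick instant.
* `bin_wall_interaction()` / `extract_wall_product()` — the mean heading
  change on a `(r_w, theta_w)` grid (10 mm and 16-bin angular resolution by
  default), antisymmetrized in `theta_w` to cancel the even-in-angle noise
  component, then factorized into `f_w(r_w) * O_w(theta_w)` by
  count-weighted alternating projection to a rank-1 fixed point
  (initialized from marginal means, converged when factors change by less
  than 1e-8). The angular factor carries the unit-mean-square convention,
  the radial factor the intensity.
* `fit_wall_params()` — multi-start least squares of the Gaussian wall form
  restricted to `r_w <= 80 mm`: occupancy beyond 80 mm is a small residual
  weight and the reconstruction fluctuates there; the residual weight is
  reported alongside the fit.
* `extract_social()` — the four-term symmetrization over
  `(+/-psi, +/-delta_phi)` separates the attraction component (odd in
  `psi`, even in `delta_phi`) from alignment (the reverse parity) exactly;
  each component is factorized on a `(d, psi, delta_phi)` grid by the
  3-way analog of the alternating projection. Kicks with `r_w <= 60 mm`
  are excluded so the wall term cannot leak into the social estimate.
* `fit_social_params()` / `fit_modulation()` — multi-start least squares of
  the analytic radial forms, weighted by bin occupancy; `d_ali` stays fixed
  (it only sets the scale that renders `gamma_ali` dimensionless).

Multi-start Nelder-Mead over a coarse grid of starting points is used for
all nonlinear fits to avoid local minima; the grids are fixed in code.

The package's main validation is *closed-loop identifiability*: kick data
generated with known parameters (either by the full simulator or by
`make_kick_table()`, which samples states from prescribed marginals and
applies the heading-change law exactly) are pushed through the pipeline
and the generating parameters recovered — within 15% for the wall and
modulation parameters and 20% for the social ones at the kick counts used
in the tests (5e4 wall kicks, 1e5 pair kicks), and within 10% for
`gamma_R` recovered from a full 600 s single-fish simulation.

## What the synthetic data does and does not emulate

`make_tracker_file()` produces tracker-dialect output with pixel
quantization, label permutations and injected stops; `make_kick_table()`
bypasses the simulator for fast reconstruction tests. The synthetic data
contains no detection dropouts at crossings, no body-posture tracking
noise, no reflections at the glass, and the state marginals of
`make_kick_table()` are uniform rather than the strongly wall-concentrated
occupancy of real recordings. Passing tests therefore demonstrate that the
algorithms are correct and the model identifiable under its own dynamics —
not that the packaged placeholder values equal those of any particular
real data set.

## Numerical choices and limitations

* Output sampling (default 25 Hz) is independent of the kick events; the
  final kick is clamped at its endpoint.
* Event ties (two fish kicking at the same instant) are processed in
  fish-id order, making runs bit-reproducible given `(seed, params)`.
* Initial conditions: positions uniform in the disk of radius `R - 2 l_c`,
  headings uniform; first kicks decided at time 0 by the ordinary rule.
  Group observables in the tests discard a 150-300 s burn-in so the
  initial scatter does not bias the averages.
* Barycenter velocity uses centered differences on the output grid
  (one-sided at the ends); the milling index is computed in the barycenter
  frame.
* Test problem sizes (runs of 150-800 s, 2-4 replicates, 3e4-1e5 synthetic
  kicks) were chosen as the smallest sizes at which the Monte-Carlo error
  is comfortably below the asserted tolerances.
* The model has no hydrodynamics, no body size, no vision-based occlusion:
  interactions are the pairwise analytic forms throughout, and large-group
  behavior rests on the two-most-influential-neighbors rule.

## A worked example

```{r example, eval = FALSE}
p <- default_light_params(50, n_fish = 5)
sim <- simulate_school(p, n_fish = 5, duration = 400, seed = 1)
obs <- school_observables(sim$trajectory)
summarize_observables(obs[obs$time_s > 150, ])
```
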