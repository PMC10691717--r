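# fishschool

Burst-and-coast modelling of schooling rummy-nose tetra
(*Hemigrammus rhodostomus*) in a circular arena, across light conditions.

Small characins swim intermittently: a brief burst (a *kick*) sets a new
heading, then the fish glides along a straight line while its speed decays
quasi-exponentially. Heading decisions thus live at discrete kick onsets,
which makes the behavior both simulable and *measurable*: the per-kick
heading change can be binned against the state of the fish, and the
interaction rules reconstructed from trajectories. `fishschool` implements
the full loop for people studying collective motion in confined fish
schools under varying illuminance:

* an **asynchronous kick-event simulator** of N fish in a circular arena
  (radius 250 mm). The heading change of fish *i* at a kick is

  `dphi = dphi_R + dphi_W + dphi_S`

  — Gaussian spontaneous noise with near-wall damping,
  `gamma_R (1 - alpha exp(-(r_w/l_w)^2)) g`; wall avoidance
  `gamma_w exp(-(r_w/l_w)^2) O_w(theta_w)` with the odd profile
  `O_w ∝ sin(theta_w)[1 + 0.8 cos(2 theta_w)]`; and pairwise social terms,
  attraction `f_Att(d) O_Att(psi) E_Att(delta_phi)` plus alignment
  `f_Ali(d) O_Ali(delta_phi) E_Ali(psi)`, summed over the k = 2 most
  influential neighbors. Kicks are rejected until the fish keeps a comfort
  distance to the wall. Angular profiles are normalized to unit mean
  square over a period.
* **collective observables**: dispersion (radius of gyration),
  polarization, milling index, nearest-neighbor and wall distances, and
  the geometrical leader/follower classification for pairs.
* a **preprocessing pipeline** for tracker output: pixel-to-mm conversion,
  identity resolution by minimum-displacement assignment, activity
  filtering (40 mm/s, 2 s rule), Savitzky-Golay kick segmentation, and
  left/right mirror symmetrization.
* the **reconstruction procedure**: binned conditional means of the
  per-kick heading change, parity decomposition into attraction and
  alignment, rank-1 factorization into radial and angular profiles, and
  multi-start least-squares fits of the analytic forms — validated by
  closed-loop parameter recovery on simulated data.
* **packaged parameter sets** for five light conditions (0.5, 1, 1.5, 5,
  50 lx) and four group sizes (1, 2, 5, 25), mixing measured anchors with
  documented placeholders (see the methods vignette).

## A worked example

```r
library(fishschool)

p <- default_light_params(50, n_fish = 5)   # 50 lx, 5-fish parameter table
sim <- simulate_school(p, n_fish = 5, duration = 400, seed = 1)
obs <- school_observables(sim$trajectory)
summarize_observables(obs[obs$time_s > 150, ])   # discard the burn-in
#>   observable       mean se
#> 1        r_w 30.9354909 NA
#> 2        nnd 40.6189836 NA
#> 3          D 57.0807411 NA
#> 4          P  0.9475807 NA
#> 5          M  0.2562197 NA
```

A polarized, cohesive school: mean polarization 0.95, radius of gyration
57 mm (an order of magnitude below the tank radius), nearest neighbors
about 41 mm (about one body length) apart, swimming about 31 mm from the
wall. Running the same at `n_fish = 25` flips the regime: polarization
collapses (~0.2) and the milling index rises to ~0.86 — the school spreads
along the wall and rotates coherently around the tank.

The same pipeline measures trajectories: `kick_table()` segments a
trajectory into kicks with their state variables, and, e.g.,
`fit_gamma_R()` recovers the spontaneous heading-noise intensity,

```r
kt <- kick_table(simulate_school(default_light_params(50, 1), 1, 600, seed = 11)$trajectory)
coef(fit_gamma_R(kt))
#>   gamma_R
#> 0.4467198    # generating value: 0.43
```

A command-line interface wrapping the same functions is installed at
`system.file("cli/fishschool", package = "fishschool")` with subcommands
`simulate`, `observables`, `segment`, `reconstruct`, `fixtures`.

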