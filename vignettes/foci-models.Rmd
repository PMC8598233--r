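---
title: "Models and observables for membrane-less nuclear foci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and observables for membrane-less nuclear foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focisim)
```

## The two physical pictures

Nuclear foci — membrane-less condensates a few hundred nanometres across in
which specific proteins (e.g. repair factors after a DNA double-strand
break) are strongly concentrated — can be produced by at least two distinct
physical mechanisms, and `focisim` implements both as single-particle
simulators together with the statistics that can tell them apart from
tracking data.

**Liquid Phase Model (LPM).** The focus is a droplet formed by liquid–liquid
phase separation. A tracer experiences a radially symmetric potential
$U(r)$ and position-dependent diffusivity $D(r)$, both sigmoidal with
midpoint at the focus radius $r_f$ and steepness $b$:
$D(r) = D_0 + (D_n - D_0)\,\sigma(b(r-r_f))$,
$U(r) = A\,\sigma(b(r-r_f))$, with $\sigma$ the logistic function. The
potential is low inside, so the equilibrium density is enhanced by $e^{A}$
(energies in $k_BT$; the package sets $k_BT \equiv 1$ and never models
temperature explicitly). The dynamics is the overdamped Itô Langevin
equation
$$\mathrm{d}\mathbf{r} = \left[\nabla D - D\,\nabla U\right]\mathrm{d}t +
\sqrt{2D}\,\mathrm{d}\mathbf{W},$$
whose $\nabla D$ term (the Itô "spurious drift") is required for the
stationary law to be Boltzmann when $D_0 \ne D_n$.

**Polymer Bridging Model (PBM).** The focus is a cluster of
$N = \tfrac{4}{3}\pi\rho r_f^3$ partially absorbing spheres of radius
$r_b$ (chromatin-borne binding sites) confined to the focus and diffusing
slowly at $D_b$. An unbound tracer diffuses at $D_n$ everywhere; crossing a
site surface it is absorbed with probability $p_b$ per step, otherwise
reflected; while bound it rides its site rigidly and unbinds at rate
$k_-$.

Default parameter values are the typical operating point used throughout
(lengths in µm, times in s): $r_f = 0.1$, $r_n = 0.5$, $D_n = 1.0$,
$D_0 = 0.05$, $A = 5$, $b = 1000$, $\rho = 4.8\times 10^4$, $D_b = 0.005$,
$r_b = 0.01$, $\kappa = 100$, $k_- = 500$, localization noise
$\sigma = 30$ nm; all are overridable everywhere.

## Numerical choices

### Absorption probability

The Robin (partially absorbing) boundary condition
$D_n\,\partial_n p = \kappa p$ with $\kappa$ in µm/s discretizes, for a
random-walk step of length $\mathrm{d}t$, to a per-crossing absorption
probability
$$p_b = \kappa \sqrt{\pi\,\mathrm{d}t / D_n},$$
which is dimensionless and scales as $\sqrt{\mathrm{d}t}$
(`absorption_probability()`). This is the standard half-space result for a
partially absorbing wall and is the package's definition of the
$\kappa \leftrightarrow p_b$ mapping. Above $p_b \approx 0.2$ the mapping
acquires $O(p_b)$ corrections — the scheme then still simulates a
well-defined partially absorbing site, just at a slightly different
effective absorptivity — and the simulator refuses configurations with
$p_b > 0.35$; `pbm_stable_dt()` returns a compliant step.

### Integrators

The LPM integrator is Milstein: because $D$ depends only on $r$, the
multiplicative-noise correction $\tfrac12 D'(r)\,(x_i/r)\,(\Delta W_i^2 -
\mathrm{d}t)$ acts along the radial direction. $\nabla D$ and $\nabla U$
are evaluated analytically from the sigmoid profiles, never by finite
differences. An Euler–Maruyama fallback (`milstein = FALSE`) passes the
same stationarity tests at a ~10× smaller step. The nucleus boundary is a
radial mirror: $|\mathbf{r}| \to 2 r_n - |\mathbf{r}|$, direction kept.
The default step $\mathrm{d}t = 10^{-6}$ s resolves the boundary layer
$1/b$ at the default steepness; the integrator warns when the
deterministic drift would traverse the layer in one step.

The PBM stepper resolves every tracer–site encounter: the nearest site is
tested first, a rejected crossing is reflected to distance $2 r_b -
\Delta r$ from that site's centre, and the reflected position is re-tested
against the remaining sites. On binding the tracer attaches at the surface
intersection point and keeps that offset rigidly; on release it resumes
free diffusion in place, so *rebinding to the same site is explicit* (see
below). Sites do not interact and may overlap; their confinement to the
focus is a reflecting wall at $r_f$, which keeps their stationary density
uniform in the focus ball. For performance the C++ core keeps a Verlet-type
neighbour list around the tracer with a conservative displacement budget
(list rebuilds are triggered before any stale site could possibly be
reached, with a 5-sigma allowance for site drift, capped by confinement);
far sites are advanced lazily by a single Gaussian step of variance
$2 D_b\,\mathrm{lag}\,\mathrm{d}t$, exact while they are away from the
boundary and distribution-preserving at it. A bulk mode replaces the
nucleus by a periodic box at constant site density, isolating bulk binding
effects from focus-boundary effects (`simulate_pbm_bulk()`,
`unwrap_trajectory()`).

### Rebinding and the mean-field rate constants

The mean-field description uses the Smoluchowski on-rate for a partially
absorbing sphere, $k_+ = 4\pi D_n r_b / (1 + D_n/(r_b \kappa))$; at the
typical operating point $k_+\rho \approx 3.0\times10^3\,\mathrm{s}^{-1}$.
Because the simulator releases a tracer *at* the site surface, immediate
rebinding is frequent, and the microscopic equilibrium follows
surface-exchange detailed balance instead:
$$p_{in}/p_{out} = 1 + 4\pi r_b^2 \kappa\,\rho/k_-
 = 1 + \left(1 + \kappa r_b / D_n\right) k_+\rho/k_-.$$
The factor $1 + \kappa r_b/D_n$ is precisely the classical rebinding
renormalization of the unbinding rate; the two expressions coincide in the
reaction-limited regime $\kappa r_b \ll D_n$
(`pbm_equilibrium_enhancement()`). None of the discriminating statistics
depend on this distinction — the scaling identity below compares measured
quantities with measured quantities — but parameter-level predictions of
occupancy should use the renormalized form.

## Discriminating observables

Tracks are observed through a measurement model mirroring a 50 Hz
single-particle-tracking experiment: 2D projection, a ±150 nm visible
z-slab that splits trajectories at exits, and 30 nm i.i.d. Gaussian
localization noise (`apply_measurement_model()`). Estimators use $d = 2$
and the 2D (Rayleigh) jump-length density for such tracks, and $d = 3$ and
the Maxwell form for raw 3D trajectories.

* **Displacement histograms / KS detectability.** Slow exchange
  ($k_-\,\delta t \lesssim 1$) produces an excess of near-zero
  displacements; a two-sided KS test against the fitted single-diffusivity
  reference detects it, with power degraded by fast exchange and by
  localization noise (`ks_detectability()`).
* **Scaling identity.** The binding-site picture forces
  $p(r) \propto 1/(\tilde D(r) - D_b)$, i.e.
  $(D_0 - D_b)/(D_n - D_b) = p_{out}/p_{in}$ for the measured plateaus;
  `scaling_test()` reports both sides, their relative deviation, and the
  site diffusivity $D_b^\*$ that would force equality. Droplet parameters
  with $(D_0, A)$ decoupled violate it by orders of magnitude.
* **Radial drift.** Under spherical symmetry the effective description
  predicts
  $\langle\delta r\rangle = \delta t\,(-\tilde D\,\partial_r\tilde U +
  \partial_r \tilde D + (d-1)\tilde D/r)$ with
  $\tilde U = -\ln p + \text{const}$. (The sign convention is
  Boltzmann-consistent: density maxima are potential minima.) With
  immobile sites ($D_b = 0$) this drift cannot be negative; an inward dip
  at the boundary is a droplet signature. The **maximal positive
  difference** — the largest excess of the observed drift over this
  prediction in the boundary window $[0.5 r_f, 1.5 r_f]$ — is the
  binding-site rejection statistic (`maximal_positive_difference()`); the
  window is centred on the boundary because the discrepancy is a boundary
  effect.
* **Angle distributions.** Angles between consecutive displacement vectors
  are uniform for free diffusion and reversal-enriched by confinement in a
  droplet (`angle_distribution()`; zero-length displacements are skipped).
  A bulk binding-site medium could in principle add reversals at
  observation intervals comparable to the binding time, but across the
  studied parameter ranges (including immobile sites and added
  localization noise) the mean displacement-angle cosine of bulk
  simulations stays within ~0.005 of the free baseline, so this package
  treats the angle statistic as a confinement probe, not a binding probe.

Numerically, `predicted_radial_drift()` evaluates the drift in the
equivalent conservative form
$\delta t\,\partial_r(r^{d-1}\tilde D p)/(r^{d-1} p)$, differencing the
*product* $r^{d-1}\tilde D p$: across the focus boundary the density rise
and diffusivity drop nearly cancel in the product (the scaling identity),
so this discretization remains accurate exactly where term-by-term finite
differences of the steep individual profiles ring badly. Profile bins
default to $10^{-3}$ µm; empty bins are flagged, never interpolated.

## First-passage theory

For a perfectly absorbing target of radius $r_0$ at the focus centre, the
steady-state-flux construction gives
$$\tau_a = \int_{r_0}^{r_n} \mathrm{d}r\; r^2 e^{-U(r)}
  \int_{r_0}^{r} \frac{\mathrm{d}r'\,e^{U(r')}}{D(r')\,r'^2},$$
which is identically the mean first-passage time of a tracer *started on
the nucleus boundary* ($\tau_a = T(r_n)$, as the double integral shows on
inspection), and reduces to the Smoluchowski time $r_n^3/(3 D_n r_0)$ for
flat profiles. For this reason `simulate_first_passage()` defaults to the
`"nucleus-edge"` start rule; Boltzmann-restricted and uniform starts are
available but average $T(r)$ over their start law and therefore fall below
the closed form by design, not by error. With a sharp boundary the double
integral evaluates in closed form (`mfpt_closed_form()`, checked against
the quadrature to $10^{-6}$), simplifying for $r_0 \ll r_f \ll r_n$ and
strong attraction to the two-stage time
$r_f^3/(3D_0 r_0) + r_n^3/(3 D_n r_f)$. The search time has an interior
minimum in $r_f$ iff $D_0 e^{A} > D_n$, located at
$r_f^{*4} = r_0 r_n^3 (D_0/D_n - e^{-A}) / (3(1 - e^{-A}))$; the
binding-site constraint between $\tilde D$ and $\tilde U$ forces instead
$r_f^{*4} = r_0 r_n^3 D_b/(3 D_n)$, which vanishes for immobile sites —
binding-site foci sequester the tracer without accelerating its search.
Poisson statistics of the $\sim 4\pi c r_n^3 t/(3\tau_a)$ target arrivals
bound the relative concentration-sensing error,
$\delta c/c \sim \sqrt{3\tau_a/(4\pi c r_n^3 t)}$, recovering the classic
perfectly absorbing-sphere limit $1/\sqrt{4\pi D_n c\, r_f t}$ when the
target fills the focus (`sensing_relative_error()`).

Target detection uses the step-endpoint test at the integration step
($10^{-6}$ s by default); a Brownian-bridge crossing correction would be a
straightforward extension but is not the default, giving a small upward
bias ($\lesssim 1\text{–}2\%$ at the default step) that stays well inside
the Monte-Carlo error at the sample sizes used.

## What the generator emulates, and problem sizes

The synthetic tracks emulate: equilibrium single-tracer dynamics in a
fixed, spherical, concentric focus/nucleus geometry; event-resolved
binding with explicit rebinding; 2D projection, z-slab truncation, frame
subsampling, and localization noise. They do **not** emulate: focus
formation or dissolution, non-spherical or off-centre foci, tracer–tracer
interactions, a polymer model of chromatin (sites are independent
spheres), photophysics (blinking/bleaching), or localization-error
correlations. Passing tests therefore validate the estimators and theory
under the models' own assumptions, not those aspects of real data.

Test-suite problem sizes were chosen so that Monte-Carlo standard errors
sit well inside the tolerances they are compared to: occupancy ratios use
ensembles of equilibrium-started trajectories (24–96 runs of 4 s; the
between-trajectory scatter gives an honest standard error, since in/out
exchange makes within-run frames strongly correlated); the scaling grid
uses 40 s of dynamics per parameter set at 0.25 ms frames with plateaus
read at $r < 0.6 r_f$ (inside) and $1.5 r_f < r < 0.9 r_n$ (outside,
where a short lag avoids confinement bias); drift comparisons use 0.25 ms
frame intervals over 30–40 s of dynamics with radial bins of
$5\times10^{-3}$ µm. First-passage means use 2000 trajectories.

The scaling-identity grid runs at $\rho = 2.4\times10^4$ µm⁻³, the lower
end of the studied density range. This is deliberate: at
$\rho = 4.8\times10^4$ the binding sites occupy 20% of the focus volume
and excluded-volume effects — measurably depressing the unbound in-focus
density (by the factor $1-\phi$) while barely touching the effective
diffusivity — genuinely shift the identity by ~15%. That shift is
microscopic physics outside the dilute, non-interacting-site assumptions
of the mean-field description, and it is the main known limitation of the
identity at high site density; a high-density set is retained in the
module tests under a correspondingly wider band.

## Known limitations

* The mean-field rate constants are accurate in the reaction-limited
  regime; at $\kappa r_b \sim D_n$ use the renormalized equilibrium
  constants (above) for parameter-level predictions.
* At site volume fractions $\gtrsim 15\%$ excluded-volume corrections to
  the scaling identity become comparable to its measurement error.
* Radial profiles from slab-projected 2D tracks use a thin-slab
  deprojection (annulus area × slab thickness, attributed to the mean 3D
  radius of the slab bin); for slabs comparable to the focus size a full
  Abel-type inversion would be needed.
* Radial-drift comparisons (and the non-negativity of the binding-site
  drift) apply away from the reflecting nucleus wall, whose confinement
  drift is negative in any model; bins within about two displacement
  lengths of $r_n$ are excluded from such checks.
* Periodic (bulk) trajectories must be recorded densely enough that no
  frame displacement approaches half the box, or minimum-image unwrapping
  corrupts the displacement tails; `unwrap_trajectory()` warns when this
  is violated.
* The focus is static: no formation/dissolution kinetics, fixed size, and
  one tracer per trajectory (ensembles come from seeds).
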