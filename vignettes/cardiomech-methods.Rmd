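---
title: "Discrete cardiac electromechanics with cardiomech: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete cardiac electromechanics with cardiomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardiomech` simulates a two-dimensional sheet of human ventricular tissue in
which electrical excitation and mechanical contraction are solved as one
coupled system, and uses it to ask how stretch-activated channels reshape the
action potential, restitution, and spiral-wave dynamics under two mechanical
conditions: a constantly stretched medium and a medium that deforms because
it contracts. This vignette documents the models, the numerical scheme, every
tunable that matters, and the design decisions that were genuinely open.

## Electrophysiology

Excitation follows the ten Tusscher–Panfilov 2006 (TP06) ionic model of the
human epicardial myocyte: a monodomain reaction–diffusion equation for the
transmembrane potential $V$,

$$\partial_t V = D\,\nabla^2 V - \frac{1}{C_m}\,(I_{ion} + I_{stim} + I_{sac}),$$

where $I_{ion}$ sums twelve membrane currents (fast sodium, L-type calcium,
transient outward, rapid and slow delayed rectifier, inward rectifier,
sodium–potassium pump, sodium–calcium exchanger, plateau and background
currents), each gated by Hodgkin–Huxley-type variables
$\dot g = (g_\infty(V) - g)/\tau_g(V)$, with full intracellular calcium
handling (cytosol, subspace, and sarcoplasmic reticulum pools with analytic
steady-state buffering). The complete epicardial parameter table ships as a
plain-text file (`inst/extdata/tp06_epi.txt`) so that tests pin it and users
can substitute a modified table.

Units are fixed throughout the package: ms, mV, mM, mm, kPa; currents in
pA/pF; diffusivity $D = 0.154\ \mathrm{mm^2/ms}$; space step
$h = 0.25$–$0.5$ mm; time step $\Delta t = 0.02$ ms. A stability guard
rejects settings with $D\,\Delta t/h^2 \ge 1/4$.

**Gating integrator.** Voltage and ion concentrations advance by explicit
Euler. Gating variables default to the exponential (Rush–Larsen) update
$g \leftarrow g_\infty - (g_\infty - g)\,e^{-\Delta t/\tau_g}$, which is the
integration scheme of the TP06 reference implementation: at
$\Delta t = 0.02$ ms a plain forward-Euler gate update is outside the
stability region of the fast sodium activation gate
($\tau_m < 3\,\mathrm{\mu s}$ near rest), so the exponential update is the
only way the documented time step can be used at all. Forward-Euler gating
remains available (`tp06_params(gates = "euler")`) and is used by the
first-order convergence tests at reduced step sizes. Both updates keep gates
strictly inside $[0,1]$; a gate that leaves the unit interval is treated as
an integration failure, never clamped.

The tissue kernel evaluates the voltage-dependent rate expressions from a
lookup table on a 0.02 mV grid with linear interpolation (the standard
finite-difference-solver optimization); single-cell entry points keep the
direct analytic path, and the table can be disabled (`em_run(lut = FALSE)`).

## Excitation–contraction coupling

Active tension follows the Niederer–Hunter–Smith 2006 (NHS) model: troponin-C
calcium binding with tension-dependent unbinding, a tropomyosin kinetics
variable $z$ (the fraction of actin sites available for crossbridge
formation), a length-dependent calcium sensitivity, and a three-component
fading-memory model for the force–velocity response. The tension decomposes
as

$$T_a = T_{lv}\; g(\lambda)\; h(Q),$$

with $T_{lv} = T_{ref}\, z/z_{max}$ the length/velocity-independent tension,
$g(\lambda) = 1 + \beta_0(\lambda - 1)$ the filament-overlap factor, and
$h(Q)$ the fading-memory velocity factor
($Q = \sum_i Q_i$, $\dot Q_i = A_i\,\dot\lambda - \alpha_i Q_i$). The rat
parameter table of the original model ships in
`inst/extdata/nhs_rat.txt`; the human adjustments — doubling of the two
crossbridge relaxation rates, $T_{ref} = 120$ kPa, and $\mathrm{pCa}_{50} =
6.2$ — are isolated in `human_adjustments()` so they can be swapped as a
unit. The length laws are evaluated on $\lambda$ clipped to $[0.8, 1.15]$,
the validity range of the overlap function.

**Stretch-rate input.** The fading memory is driven by a stretch-rate
estimate smoothed over `dlam_tau` = 2 ms (an exponential moving average of
the per-step rate). The memory kernel's own time constants are
$1/\alpha_i = 1.6$–$33$ ms, so the smoothing is invisible to the physics; it
exists because the raw per-step rate $(\lambda_n - \lambda_{n-1})/\Delta t$
couples to the tension with gain $\sim T_a\,h'(Q)\sum_i A_i$, far exceeding
the lattice stiffness, and turns the otherwise stable explicit coupling into
a growing period-two oscillation. Setting `dlam_tau = 0` restores the raw
rate for comparison.

## Mass-lattice mechanics

The tissue is a square lattice of mass points. Direct neighbours are joined
by *active* springs (passive elasticity plus contractile force), diagonal
neighbours by *passive* springs with rest length $\sqrt2\,l_0$. Each spring
contributes a Hooke force $k\,(\ell - \ell_0)$, a damping force
$c\,\dot\ell$ along the spring, and (active springs) a contractile force
$T_a/(\rho\,l_0)$ pulling its endpoints together, where $\rho = 1/l_0^2$ is
the mass-point surface density. The extra factor $1/l_0$ relative to a bare
$T_a/\rho$ makes the converged strain field independent of the lattice
resolution, which the refinement tests require. The smallest area elements
are the quadrilaterals of four direct neighbours; the pseudo normalized
sarcomere length is $\lambda = \sqrt{S/S_0}$ with $S$ the (shoelace) element
area and $S_0 = l_0^2$. The outer boundary ring is fixed in space (isometric
contraction, mimicking isovolumic phases); a free boundary is available for
calibration runs.

**Isotropy and stiffness.** For this central-force lattice, matching the
strain energy of an isotropic 2D continuum requires the passive/active
stiffness ratio $k_p/k_a = 1/2$; the resulting Lamé coefficients are
$\lambda_L = \mu = k_p$ and the 2D Young modulus is $E = \tfrac{4}{3}k_a$
(Poisson ratio $1/3$). `mech_params()` therefore derives $k_a = 3E/4$ from
the configured modulus. The default $E = 280$ kPa makes a free fibre shorten
by $\approx 12\%$ at peak twitch tension, the mid-range of contracting
myocytes; cardiac tissue is stiffer at small strain but strongly nonlinear,
and this choice reproduces physiologic deformation magnitudes. The oracle
`measure_small_strain_response()` imposes an affine deformation, relaxes,
and reports the virial Cauchy stress; tests verify the modulus to 2%,
axis-vs-diagonal isotropy to 1%, and that at 10% biaxial stretch the
generalized Hooke law with Almansi's finite strain tensor (the Seth
material) fits the lattice better than the small-strain form.

**Tension on springs.** $T_{lv}\,h(Q)$ lives on the area elements (calcium
is read at the element-centre electrical node); an active spring receives
the mean of its adjacent elements. The filament-overlap factor is evaluated
from each spring's *own* stretch $\ell/\ell_0$ rather than the element-area
$\lambda$: the sarcomere lies along the fibre, and tying the length feedback
to the spring length also suppresses an area-hourglass mode that an
area-based factor cannot sense (adjacent elements can exchange area at
constant spring lengths).

## Damped Verlet relaxation and the update method

Mechanics are assumed elastostatic: after every electrical step the lattice
is relaxed to equilibrium under the frozen $T_{lv} h$ field by position
Verlet iteration,

$$x_{t+\Delta t_m} = 2x_t - x_{t-\Delta t_m} + a_t\,\Delta t_m^2,$$

with the half-acceleration first step $x_0 + \tfrac12 a_0 \Delta t_m^2$ at
zero pseudo-velocity, velocities estimated by the central difference over
$2\Delta t_m$, and iteration until the net force on every free mass point is
below the threshold $F_{th}$. Inside the loop the filament-overlap factor is
re-evaluated from the trial configuration each iteration — the "update
method" that keeps the strongly coupled system stable — while the velocity
factor is held at its committed stretch rate for the duration of one
electrical step (re-evaluating it from the trial rate makes the explicit
iteration stiff, as above; over one 0.02 ms step it changes by well under
0.1%). Mechanics are updated after every electrical step.

Numerical choices, all exposed in `mech_params()`:

* `dt_mech`: 50% of the Verlet stability limit computed with a stiffness
  allowance (`tension_stiffness`, default 900 kPa) for the length-dependence
  of the active tension, which acts as extra spring stiffness inside the
  loop.
* `damping_ratio` ($c/k$, dimensionless): default 0.05, which critically
  damps the slowest lattice mode at desk-scale mesh sizes and converges a
  cold-started localized-tension problem in a few hundred iterations and a
  warm-started coupled step in typically 1–10.
* damping cap: whenever a spring's damping force would exceed its Hooke
  force, it is capped at `cap_frac` (default 0.9) of the Hooke force. In the
  heavily damped regime ($c$ numerically equal to $k$) this cap is the
  difference between convergence in a few iterations and a crawl — the test
  suite demonstrates it on a localized tension shock. At high damping with
  very tight thresholds the capped (friction-like) damping can enter a
  stick-slip limit cycle, which is why the default damping ratio is small.
* `f_th_rel`: $F_{th} = 10^{-4}\,k\,l_0$. The threshold must be well below
  the per-step force increments or the lattice silently stops tracking the
  tension field; halving and quartering it changes converged stretch fields
  by far less than 1% (the convergence-robustness test).

Area elements with non-positive signed area (mesh tangling) abort the run;
vertex order is fixed counter-clockwise at build time.

## Mechano-electrical feedback

The stretch-activated current is linear and time-independent:

$$I_{sac} = G_s\,\frac{\lambda - 1}{\lambda_{max} - 1}\,(V - E_s),$$

gated to stretch ($\lambda > 1$; an unrectified variant is available) and
with the normalized stretch clamped at 1. $\lambda_{max} = 1.1$, so a medium
held at constant stretch 1.1 exposes every cell to the full conductance
$G_s$ — which is why constant-stretch mode applies $I_{sac}$ with
$\lambda \equiv 1.1$ *without deforming the medium*. $\lambda$ for the
feedback is interpolated bilinearly from the element centres to the
electrical nodes; the effect of deformation on the diffusion metric is
neglected (gap junctions dominate intercellular resistance), so diffusion
always uses the undeformed stencil.

$E_s$ deserves a note. Reported reversal potentials for the non-selective
cation stretch-activated channel span roughly $0$ to $-30$ mV. With
$E_s = -20$ mV the current is outward over most of the plateau and
*shortens* the action potential under constant stretch; with $E_s = 0$ mV it
is inward below the plateau and prolongs it, and the whole constant-stretch
phenomenology (rising resting potential, longer APD, depressed upstroke and
conduction, loss of the sodium-driven upstroke at the largest $G_s$) emerges
monotonically across the sweep. The package default is $E_s = 0$ mV, with
the sweep $G_s \in \{0, 0.01, 0.02, 0.03\}$ nS/pF spanning no effect to
upstroke failure.

## Protocols and measurements

* **Initial conditions:** reaching steady calcium dynamics takes many beats,
  so tissue runs start every node from a single cell paced to a calcium
  fixed point (`pace_to_steady_state()`, which returns the state at the
  calcium peak of the final beat; `paced_initial_state()` continues it to
  end-diastole for tissue use).
* **Pacing/restitution:** plane waves from an edge strip; APD measured
  between the interpolated crossings of the level
  $V_{base} + (1-f)\,(V_{peak}-V_{base})$ (default $f = 0.9$, i.e. APD90);
  CV from the upstroke arrival-time difference of two probes 10 mm apart
  along propagation (threshold $-20$ mV) — in a contracting medium this is
  an average velocity. Conduction block is recorded as a failed capture,
  and the minimal captured period is reported per $G_s$.
* **Spiral waves:** S1–S2 initiation (plane wave, then a premature
  half-field stimulus with an automated timing scan), a conditioning
  interval with $G_s = 0$, and tip tracking as the intersection of the
  $V = -40$ mV isoline with the $\dot V = 0$ isoline, solved sub-cell from
  the two bilinear interpolants per grid cell and linked by nearest match.
  Rotation is counted from the winding of the tip heading (robust to core
  meander and drift); the drift velocity is the displacement of the
  rotation-averaged centre over the analysis window divided by its
  duration, and the core radius is the RMS distance of drift-corrected tip
  positions from that moving centre.

## What the synthetic fixtures do and do not show

The oracle fixtures — rigidly rotating Archimedean phase fields with
prescribed centre/period/drift, trapezoidal action potentials with
analytically known APD, offset sigmoidal fronts, twitch-like stretch
waveforms — validate the *measurement* machinery exactly, because their
ground truth is known by construction. They do not probe model physiology;
the physiological checks are qualitative (directions of change,
mode contrasts, event orderings) on reduced sheets.

Desk-scale domains (10–50 mm) are much smaller than an excitation
wavelength (CV × APD ≈ 165 mm), and this has a structural consequence for
the *contracting* condition: with fixed boundaries, a near-uniformly
excited medium is undeformed, so the stretch field only develops transient
gradients of λ ≈ 1 ± 0.015 — at most ~15% of full SAC activation. Two
phenomena that depend on this amplitude therefore do not reach
measurability at desk scale, and their acceptance checks fail by design
rather than be weakened: the negative CV-restitution band (the
preexcitation CV boost is present with the right period dependence, ~+0.7%
at 380 ms pacing on an 80 mm strip, but is an order of magnitude below the
intrinsic restitution slope) and the growth of spiral drift with $G_s$
(the rotor's baseline meander wander exceeds the mechano-electric drift,
and larger $G_s$ in fact compacts the core). Quantitative magnitudes at
this scale should not be read as tissue-scale predictions; the shipped
`config-full.yaml` stub records the full-scale settings these phenomena
require.

## Known limitations

Two-dimensional only; no anisotropy, hyperelasticity, or area conservation
in the lattice; no stretch-rate dependence in $I_{sac}$; deformation does
not feed back on the diffusion operator; endo/mid-myocardial cell variants
are out of scope. The NHS human adjustments are adopted constants isolated
in one place, not fits to data performed here.

## Reproducing the headline analyses

`scripts/acceptance.R` (repository root) re-runs the constant-stretch and
contracting suites, the restitution scans, the spiral experiment, and the
mechanics oracles at desk scale and writes the resulting quantities to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The model is deterministic; the seed only feeds the (unused) RNG so that
reruns are byte-reproducible.
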