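---
title: "occlusim: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{occlusim: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`occlusim` simulates platelet-driven thrombus formation and occlusion in
two-dimensional tortuous arterioles by coupling a D2Q9 BGK
lattice-Boltzmann (LBM) plasma flow solver to an unresolved
discrete-element model (DEM) of rigid spherical platelets.  This vignette
documents the governing model, the tunable parameters, and the numerical
and design decisions a user or reviewer is likely to question.

## Fluid model

The flow field evolves by collide-and-stream of D2Q9 populations
$f_i(\vec x, t)$ under the single-relaxation-time BGK operator,

$$f_i(\vec x + \vec c_i \delta t, t + \delta t) = f_i(\vec x, t)
  - \tfrac{1}{\tau}\left[f_i - f_i^{(eq)}\right] + 3 w_i \vec F \cdot \vec c_i,$$

with the standard quadratic equilibrium
$f_i^{(eq)} = \rho w_i [1 + 3(\vec c_i\cdot\vec u) +
\tfrac92 (\vec c_i\cdot\vec u)^2 - \tfrac32 \vec u\cdot\vec u]$
(weights $4/9$, $1/9$, $1/36$), density and velocity from the bare
moments $\rho = \sum_i f_i$, $\rho\vec u = \sum_i f_i \vec c_i$, and
relaxation time $\tau = (6\nu + 1)/2$ in lattice units.  Macroscopic
kinematic viscosity is $\nu = 1.2\times10^{-6}\,$m$^2$/s and density
$\rho = 1030\,$kg/m$^3$ (plasma-like; red and white cells are not
modelled).

**Pressure drive.**  The channels are periodic in the axial direction; a
pressure drop $\Delta p$ over the channel length $L$ is applied as the
uniform body-force density $\Delta p / L$ through the forcing term above.
For a fully periodic channel this is exactly equivalent to a
pressure-jump boundary and avoids a bespoke boundary condition.  The
simple $3 w_i \vec F\cdot\vec c_i$ forcing (without a half-force velocity
shift) leaves an $O(F\,\delta t)$ bias in $\vec u$; at these force
magnitudes that is below $0.2\%$ of the channel velocity and is accepted
for fidelity to the model as stated.

**Walls and the effective channel width.**  Walls are staircase
(node-based) with half-way bounce-back.  Bounce-back with BGK carries a
$\tau$-dependent numerical slip: measured on a one-dimensional
force-driven channel, the apparent wall sits a fraction $\delta(\tau, N)$
of a lattice spacing outside the half-way plane ($\delta \approx +0.17$
at the validation $\tau = 3.15$ with 48 rows, near zero at
$\tau \approx 1$, scaling like $1/N$).  `bounceback_wall_offset()`
measures this offset at run time on a cheap 1D probe, and the lattice is
sized so the *effective* wall-to-wall distance equals the target
diameter $D$: straight validation channels adjust `dx`
(`straight_channel()`), tortuous channels shrink the mask half-width
(`build_channel(wall_shift = )`).  Without this correction the flow rate
at the validation grid would be biased by $+2.2\%$ purely by the
boundary scheme.

**Stress extraction.**  The deviatoric stress is computed locally from
the non-equilibrium populations,
$\sigma_{\alpha\beta} = -(1 - \tfrac{1}{2\tau})\sum_i f_i^{neq}
c_{i\alpha} c_{i\beta}$, and reported as the maximum-shear scalar
$\tau_{max} = \sqrt{((\sigma_{xx}-\sigma_{yy})/2)^2 + \sigma_{xy}^2}$,
which reduces to $|\mu\, du/dy|$ in unidirectional shear.  This is local
(no wall stencils) and is verified in the tests against $\mu |du/dy|$ of
the measured profile.  "Wall" shear stress is the field value at
wall-adjacent fluid nodes, i.e. sampled half a spacing off the wall
plane; for plane Poiseuille flow that value is $(1 - \Delta x/H)$ times
the wall-extrapolated stress.

## Channel geometry

The vessel centerline is a two-period cosine,
$g(x) = A\cos(2\pi x/\lambda)$ on $0 \le x \le 2\lambda$, with
tortuosity index $TI = A/\lambda$ and diameter $D = 25\,\mu$m.  The
lattice covers $0 \le y \le 2A + D$ plus two solid margin rows.

**Wall rule.**  By default a node is fluid iff its *Euclidean* distance
to the centerline curve is at most $D/2$ (`wall_rule = "normal"`): the
walls are the true parallel offsets of the centerline and the channel's
perpendicular width is $D$ everywhere.  The alternative
`wall_rule = "vertical"` classifies by vertical distance $|y - g(x)|$;
at $TI = 0.16$ the centerline slope reaches $\approx 1$, so vertical
offsets would pinch the perpendicular width to $D\cos\theta \approx
0.7D$ on the flanks and roughly halve the particle-free flow rate, which
is inconsistent with the matched-flow operating points this package
ships as presets.  The normal rule is therefore the default.

**Tortuosity presets.**  A fixed axial length and a fixed arc length
cannot both hold across $TI$ levels.  `ti_preset()` offers both
readings: the default `"fixed-length"` ($\lambda = L/2 = 157\,\mu$m,
$A = TI\,\lambda$), which matches an axial grid of fixed node count, and
`"equal-arc"`, which solves $\lambda$ for a prescribed centerline arc
length.  Curvature diagnostics: `radius_of_curvature_min()` returns
$1/(A(2\pi/\lambda)^2)$ (the radius at the cosine extrema, e.g.
$\approx 11\,\mu$m for $A = D = 25\,\mu$m) and `dean_number()` the usual
$(\rho V D/\mu)\sqrt{D/R_c}$; all presets sit at $Dn \lesssim 0.1$, so
neglecting secondary flow in 2D is self-consistent.

## Platelet model

Platelets are rigid spheres (radius $a$, plasma density, so buoyancy is
neglected) restricted to the plane.  Translational and rotational
dynamics follow

$$m_p \dot{\vec v} = \vec F_d + \vec F_{coll} + \vec F_{adh}, \qquad
  I\,\dot\Omega_z = M_{F,z},$$

with Stokes drag $\vec F_d = -6\pi a \mu(\vec V_p - \vec V_f)$, fluid
torque $M_{F,z} = 8\pi\mu a^3(\omega_{xy} - \Omega_z)$, soft-sphere
contacts and spring adhesion as below.  The moment of inertia
$I = \tfrac25 m_p a^2$ (solid sphere) is inserted for dimensional
consistency; the rotational equation as often printed omits it.  A
configuration switch (`vorticity_factor = 0.5`) exposes the classical
rotational Stokes torque based on half the vorticity; the default (1)
uses the vorticity as printed in the source model, without guessing
author intent.

**Contacts.**  $\vec F_{coll} = k_{coll}\,\delta_n \hat n -
\eta\,( \vec v_{rel}\cdot\hat n)\hat n$ with $k_{coll} =
0.005\,$N/m.  The damping coefficient is clamped at the pair's critical
damping $\eta = \min(\eta_{coll},\ 2\sqrt{k_{coll} m_{red}})$: the
nominal $\eta_{coll} = 0.005\,$N$\,$s/m is several orders of magnitude
above critical for micron-scale platelets, and an explicit term at
$\delta t = 2\times10^{-7}\,$s would be violently unstable (the damping
time $m/\eta \sim 10^{-12}\,$s cannot be resolved by any practical
substepping).  Critical damping preserves the intent — maximally
dissipative, non-bouncing contacts that prevent significant overlap —
while remaining integrable.  Damping acts on the normal component only,
so contacts exert no tangential force and no contact torque.

**Adhesion.**  Only activated platelets adhere.  A bond forms on first
surface contact of an activated platelet with another activated platelet
(rest length = centre distance at formation) or with the wall (anchor =
nearest wall point).  A stretched bond pulls back with
$k_{adh}\,\delta_n$, $k_{adh} = 0.008\,$N/m (a 10 nm extension gives
80 pN, the physiological order of magnitude), and ruptures when the
extension exceeds `delta_break` (default 50 nm): a deterministic
finite-extension rendering of "detaches when drag and collision overcome
adhesion", which the source model leaves unspecified.

**Activation.**  A platelet activates iff the shear stress interpolated
at its centre reaches $\tau_{crit} = 0.65\,$Pa, or it touches an already
activated platelet (chemical-agonist proxy).  Activation is irreversible
and has no time accumulation: sub-threshold shear never activates
regardless of exposure.  Note the operating margin is deliberately thin:
the straight-channel wall shear at the matched flow rate is
$\approx 0.64$ Pa, i.e. within a few percent of the threshold, so which
tortuosity levels activate depends delicately on the discrete near-wall
shear (see "Scaled runs and what tests show").

**Time integration.**  The drag and torque relaxation times,
$m/6\pi a\mu \approx 0.33\,\mu$s and $I/8\pi\mu a^3 \approx 0.08\,\mu$s,
are comparable to or smaller than the $0.2\,\mu$s step, so plain
(semi-)implicit Euler would distort the relaxation by tens of percent.
The integrator treats the linear drag/torque exactly (exponential
integrator) with the remaining forces held constant over the step, then
advances the position with the end-of-step velocity.  Contact springs
are resolved by integer DEM substepping whenever
$\delta t > T_{contact}/10$.

**Injection and the depth conventions.**  The fluid is per-unit-depth
while the particle force laws are 3D, so two assumed depths bridge the
dimensions.  Point forces become per-depth densities through
$b_{depth}$ = platelet diameter (the particle spans only its own
diameter out of plane).  The volume concentration becomes a 2D arrival
rate through $b_{inject}$ = channel diameter $D$: new platelets enter at
the inlet as a Bernoulli-per-step approximation of Poisson arrivals with
rate $C\,Q\,b_{inject}$ ($C = 3\times10^{5}$ platelets/mm$^3$), at a
uniform wall-safe transverse position, moving with the local fluid;
platelets leaving the outlet are removed.  Runs start with 50 platelets
placed uniformly at random (non-overlapping, wall-safe) in the channel.
The two depths deliberately differ: with a single
$b$ = platelet diameter the steady census $C\cdot\text{area}\cdot b$
would be about 6 platelets, so the prescribed 50 initial platelets would
wash out within one residence time; with $b_{inject} = D$ the steady
census is $\approx 59$, consistent with the 50-platelet initial
condition and with a channel that is about one diameter deep.  The
time-averaged concentration $N/(\text{area}\cdot b_{inject})$ is what
the injection test checks.

## Two-way coupling

Platelets are unresolved: the fluid velocity is sampled at each platelet
and the drag reaction $-\vec F_d$ is returned to the lattice through the
forcing term.  Both directions use the same quartic disc kernel
$w \propto (1 - r^2/r_k^2)^2$ over fluid nodes within
$r_k = 1.25\max(a, \Delta x)$, normalised to unit sum, making
interpolation and spreading adjoint so that the total spread force
equals the total platelet reaction to round-off (checked every run).
A point-wise bilinear kernel is *not* usable here: platelets
(1.9–3.1 µm) are larger than the thrombosis-grid spacing
(~1 µm), and concentrating the reaction on one cell makes the explicit
exchange gain $\gamma_{lat} = 6\pi a\mu\,\delta t/(\rho\,b_{depth}
\Delta x^2)$ exceed the stability limit.  In addition, the drag sink is
applied *diagonally implicitly*: the spread force at a node is split
into its velocity-independent part $C$ and the drag-sink coefficient
$B = \sum_p \gamma_{lat} w_p^2$, and the node momentum update solves
$u^{new} = (j + g + C)/(\rho + B)$ with applied force $C - B u^{new}$.
Linear analysis shows that temporal under-relaxation of an explicit
exchange merely slows divergence once the gain exceeds one (dense
thrombi reach per-node gains well above one at coarse time steps),
whereas the implicit form is stable for any gain and transmits the full
force in steady state.  The platelet-side drag remains the plain Stokes
law; only the fluid-side application is implicit, and the spread-target
bookkeeping (total spread force = total platelet reaction) is checked
every run.

Adhered thrombi are *not* converted into solid lattice nodes: blockage
emerges from the aggregated drag reaction of the (nearly) stationary
bonded platelets.  Occlusion is therefore defined on the flow rate, not
on geometric closure: `occlusion_time` is set when $Q$ stays below 5% of
the initial particle-free value for a sustained window ($10^4$ steps by
default; both thresholds are configuration options, as the source model
specifies none).

## Validation and scenario presets

`run_validation()` reproduces the plane-Poiseuille checks: steady flow
rate against $Q = H^3\Delta p/(12\mu L)$ and wall shear against
$\tau_w = H\Delta p/(2L)$ for $\Delta p \in \{5, 10, 15, 20, 30\}$ Pa on
a $600\times48$ grid ($\delta t = 2\times10^{-7}$ s) and a coarse
$300\times24$ grid.  `calibrate_pressure_for_flow()` secant-iterates the
(linear, Stokes-regime) $Q(\Delta p)$ map to realise matched-initial-flow
conditions; the shipped operating points are $\Delta p = \{17.30, 20.00,
24.47\}$ Pa for $TI = \{0.08, 0.16, 0.24\}$ at
$Q \approx 5.39\times10^{-8}$ m$^2$/s, plus a constant-$\Delta p = 20$ Pa
sweep and a platelet-diameter sweep $\{1.9, 2.4, 3.1\}\,\mu$m at
$TI = 0.16$.

## Scaled runs and what the tests do (and do not) show

Full production runs use the physical step $\delta t = 2\times10^{-7}$ s
and 320 axial nodes for about 1 s of simulated time.  The test suite
exercises the same code path at reduced cost: coupled property tests run
a $64\times16$ straight channel at $\delta t = 4\times10^{-7}$ s for a
few thousand steps, and the thrombosis property runs use 160 axial
nodes, $\delta t = 10^{-6}$ s and 0.15–0.2 s of simulated time.
Because thrombus growth at the physiological supply rate only begins to
depress the flow after $\sim$0.3 s, the thrombosis property runs also
*accelerate the supply kinetics*: five-fold platelet concentration,
seeded at the matching steady census ($\approx 300$ platelets).
Orderings and mechanism checks are relative properties preserved under
supply scaling.  These scaled runs demonstrate mechanism and invariants
(activation monotonicity, bond-endpoint activation, Newton's third law,
mass conservation, spread-force bookkeeping, flow decline after
thrombus onset, platelet-size ordering of partial blockage measured as
the median terminal flow fraction over five seeds), not quantitative
occlusion times: full occlusion of a 25 µm vessel takes
$\sim$0.5–1 s of simulated time and is outside the scaled window.

Two caveats the synthetic conditions make explicit.  First, the
generator emulates plasma with point-particle platelets: no red-cell
margination (which in vivo pushes platelets wall-ward and accelerates
thrombosis), no agonist transport, no receptor kinetics, no platelet
shape.  Second, with the activation threshold only a few percent above
the mean wall shear, the *discrete* near-wall shear decides whether the
lowest-tortuosity channel activates at all; in this implementation the
platelet-accessible shear at $TI = 0.08$, matched flow, sits marginally
above the threshold (staircase walls carry shear noise of several
percent, well above the 2% activation margin), so rare activations do
occur there.  This is a genuine sensitivity of the model class, not a
tunable defect.

## Numerical parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `nu`, `rho` | 1.2e-6 m²/s, 1030 kg/m³ | plasma-like fluid |
| `D`, `L` | 25 µm, 314 µm | vessel diameter, axial length |
| `dt` | 2e-7 s | LBM/DEM step (scaled runs: up to 1e-6 s) |
| `nx` | 320 (600 validation) | axial lattice nodes |
| `k_coll`, `eta_coll` | 0.005 N/m, 0.005 N·s/m (clamped) | contact stiffness/damping |
| `k_adh`, `delta_break` | 0.008 N/m, 50 nm | adhesion spring, rupture extension |
| `tau_crit` | 0.65 Pa | activation threshold |
| `diameter` | 2.4 µm (1.9/3.1 presets) | platelet size |
| `concentration` | 3e14 /m³ | inlet platelet concentration |
| `n_init` | 50 | initial random platelets |
| `b_depth` | platelet diameter | 2D/3D depth convention |
| `occl_frac`, `occl_sustain` | 0.05, 1e4 steps | occlusion criterion |
| `steady rtol` | 1e-8 / 100 steps | particle-free convergence |

## Known limitations

Single straight-or-cosine 2D channels only (no branching, stenoses or
3D); Newtonian plasma; drag-only thrombus blockage (no pore-scale
resistance beyond aggregated Stokes drag); no adhesion maturation or
shear-history activation; the activation threshold's razor-thin margin
over the operating wall shear makes low-tortuosity activation counts
sensitive to grid resolution and wall discretisation.
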