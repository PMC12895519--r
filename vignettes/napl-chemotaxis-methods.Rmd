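---
title: "Methods: chemotaxis to a NAPL-water interface under shear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemotaxis to a NAPL-water interface under shear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the parameters that matter, and the
places where genuinely open design choices were made.

## The physical setting

A shallow microfluidic macrochannel (20 µm deep, 2.5 mm wide) carries a
uniform suspension of motile bacteria at mean velocities of 0.5–10 m/d
(5.8–116 µm/s). A side capillary filled with naphthalene-laden mineral
oil meets one side wall over a 50 µm segment, forming a stable
NAPL–water interface that releases naphthalene at its aqueous
equilibrium concentration $a_0 = 0.25$ mol/m³. Chemotactic cells can
swim up the dissolution plume and accumulate against the interface;
the faster the flow, the shorter their exposure to the plume (50 µm at
the mean velocity gives 8.6 s at 0.5 m/d down to 0.43 s at 10 m/d) and
the weaker the observed accumulation.

Package conventions: $x$ increases downstream with $x = 0$ at the
upstream edge of the interface segment; $y = 0$ on the interface wall.
Internal units are µm, s and mol/m³; diffusivities quoted in cm²/s are
converted once (1 cm²/s = 10⁸ µm²/s), and velocities quoted in m/d are
converted by $10^6/86400$.

Two reporting conventions are worth stating explicitly, because neither
is the textbook default:

* **Wall shear rate** is reported as $\gamma = 2\bar v/h$ with $h$ the
  20 µm depth, which reproduces the conventional figures for this
  geometry (0.58, 1.16, 5.79, 11.57 s⁻¹ at 0.5–10 m/d). The
  plane-Poiseuille wall shear $6\bar v/h$ is three times larger and is
  available via `convention = "poiseuille"`. The $2\bar v/h$ form is
  the midplane-gradient convention $\bar v/(h/2)$.
* **Residence times** are displayed truncated to one significant digit
  (0.864 s → 0.8 s), matching how such exposure times are quoted.

## Attractant transport

Naphthalene obeys $\partial_t a = D_a \nabla^2 a - \mathbf v_f \cdot
\nabla a$ with $D_a = 7.5\times10^{-6}$ cm²/s, solved on the 2-D $x$–$y$
plane with $a = a_0$ on the interface segment (Dirichlet), no flux on
the remaining walls, $a = 0$ at the inlet and a purely convective
outflow. Consumption by bacteria and NAPL depletion are neglected (the
experiment is short relative to both).

The in-plane flow is plane Poiseuille across the full 2.5 mm width,
$u(y) = 6\bar v\,(y/W)(1-y/W)$. This matches a 2-D no-slip
Navier–Stokes view of the channel cross-section. It is worth noting
that a depth-averaged (Hele-Shaw) treatment would instead give
near-plug flow recovering within $\sim h/\pi \approx 6$ µm of the side
wall — a much faster near-wall velocity. We keep the 2-D no-slip
profile as the baseline because the accumulation magnitudes reported
for this system are reproduced with it (see the transport-form
discussion below); `flow_profile` objects carry a plain `u(y)` closure,
so alternative profiles drop in without touching the solvers.

**Discretisation.** Conservative finite volumes on a rectilinear
stretched grid: 2.5 µm cells from the interface wall out to 250 µm,
10 µm cells within ±300 µm of the interface in $x$, geometric
stretching (ratio 1.15, capped at ~150 µm) to the far boundaries. The
default window is 4000 × 2500 µm with the interface segment centred in
$x$; the tests verify that doubling the window length changes
interface-band profiles by well under 1%. Face fluxes use the hybrid
central/upwind scheme keyed to the face Peclet number, so the 10 m/d
case stays monotone without oscillation; the steady problem is linear
and solved directly (sparse LU). The maximum cell Peclet number is
attached to each solution and a warning is raised above 40.

**Transient option.** An implicit-Euler marcher (unconditionally
stable; `dt` controls accuracy only) exists to confirm the timing
story: starting from $a \equiv 0$, the near-interface region is within
1% of steady by ~10 minutes of simulated time at 0.5 m/d, consistent
with the experimental pump-settling wait. The far field keeps filling
for hours — the steady solver, not the marcher, is the production path.

## Bacterial transport and the form of the drift term

Bacteria follow a modified advection–diffusion equation with the
receptor-law chemotactic velocity

$$\mathbf V_C = \frac{2v}{3}\,\tanh\!\Big[\frac{\chi_0}{2v}
\frac{K_C}{(K_C+a)^2}\,\nabla a\Big],$$

$v = 49$ µm/s, $K_C = 0.016$ mol/m³, $D_b = 3.2\times10^{-6}$ cm²/s,
$\chi_0 = 7.2\times10^{-5}$ cm²/s at 0.5 m/d. The receptor factor
$K_C/(K_C+a)^2$ peaks at $a = K_C$, so with $a_0 \gg K_C$ the most
sensitive region sits on the fringe of the plume, not at the interface.
The tanh caps the drift at $2v/3 \approx 33$ µm/s however steep the
gradient — a property the test suite asserts.

The governing equation is implemented in its advective (as-written)
form
$$\partial_t b = D_b \nabla^2 b - (\mathbf v_f + \mathbf V_C)\cdot\nabla b,$$
with $b = 1$ at the inlet, zero total flux at walls and interface, and
convective outflow. In this form drift convergence does not itself
concentrate cells; accumulation is driven by the zero-total-flux wall
condition, and with the parameter set above the steady near-interface
peak at 0.5 m/d is ≈ 1.35, the reported magnitude. The conservative
Keller–Segel alternative $\partial_t b = \nabla\cdot(D_b\nabla b -
(\mathbf v_f + \mathbf V_C) b)$ is implemented behind
`form = "conservative"`; it conserves mass exactly but accumulates to
≈ 7 at the same parameters — a factor-of-five disagreement that makes
the choice of form a first-order modelling decision, not a numerical
detail. We default to the advective form because it is the equation as
conventionally written for this analysis and the only one consistent
with the reported density scale.

At a fixed $\chi_0$ the model's peak is nearly velocity-independent
(the shorter residence time is offset by steeper confined gradients).
The observed monotone loss of accumulation with velocity is expressed
through a velocity-dependent *apparent* sensitivity, `apparent_chi()`:
$7.2\times10^{-5}$ at 0.5 m/d, half that at 1 m/d, an order of
magnitude lower at ≥ 5 m/d. Fitting, not assuming, that reduction is
the point of the `fit_chi()` stage.

**Profile reduction.** Densities are normalized by the inlet value, so
control scenarios read exactly 1 (`chi_o = 0` or a zero field yields
$b \equiv 1$ to solver precision — an exact internal control). The
$y$-profile averages $x \in [0, 50]$ µm over $y \in [0, 200]$ µm; the
$x$-profile averages $y \in [0, 50]$ µm over $x \in [-100, 150]$ µm.
The averaging boxes are configurable; these defaults correspond to the
plotted observation windows. `accumulation_extent()` reports the
contiguous interval above a 1.05 threshold with linearly interpolated
crossings.

## Estimating the apparent sensitivity

`fit_chi()` minimises the joint SSE between observed and simulated
profiles over $\chi_0$: a log-spaced coarse scan (default 11 points
over $[10^{-7}, 10^{-3}]$ cm²/s) followed by bounded scalar
minimisation in $\log_{10}\chi_0$ between the bracketing grid points.
Simulated profiles are interpolated linearly onto the observed
coordinates. Replicates are averaged point-wise before fitting. A scan
whose SSE range is below 1% of its maximum is flagged
`unidentifiable` (flat/control data); an optimum within half a grid
step of a bound is flagged `at_bound`.

For Monte-Carlo recovery studies the forward model can be replaced by
`make_chi_surrogate()`: continuum profiles precomputed on a dense
$\chi_0$ grid and interpolated in $\log\chi_0$. The surrogate matches
the full solver to well below the replicate noise (verified in the
tests) and makes each fit essentially free; the noiseless recovery
test still exercises the full-solver path. Measured performance under
the default study conditions: noiseless self-fits recover $\chi_0$
within 5%; with 0.05 noise sd and triplicate averaging, the median of
20 seeded fits is within 10% of truth at 0.5 and 1 m/d.

## The run-reverse agent-based model

Agents in a 400 × 800 µm window against the interface wall carry
position, heading and speed. Per 0.1 s step (one reorientation
decision) each agent:

1. computes the experienced derivative $Da/Dt$ as the difference
   quotient of the attractant sampled at its successive positions
   (bilinear interpolation of the imported continuum field), which
   automatically contains both the swimming and advective
   contributions;
2. reverses with probability $\min(p\,\Delta t, 1)$ where
   $p = p_0 \exp[-\sigma^* K_C/(K_C+a)^2\,Da/Dt]$ (natural logarithm
   convention; exponent clamped at ±50). Reversal means heading +180°
   plus a deviation drawn from Normal(0°, 30°) truncated to ±90°, and a
   fresh speed from Normal(44, 15) µm/s truncated to [5, 100] µm/s;
3. moves by its swimming velocity plus the local Poiseuille velocity
   $u(y)$ (the 2.5 mm-width parabola evaluated on the near-wall window
   $y \in [0, 400]$ µm).

$\sigma^* = \chi_0/v^2 \approx 3.7$ s (displayed 4 s) links the
single-cell rule to the population coefficient; $p_0 = 0.5$ s⁻¹ in
still liquid, with reduced values (0.2, 0.1 s⁻¹) representing
flow-suppressed reversal at higher velocities.

**Boundaries.** Side walls re-emit colliding agents at a random inward
angle drawn from the flux-weighted (Lambert cosine, pdf ∝ sin θ)
distribution. This choice matters: uniform-in-angle re-emission
over-populates shallow exit angles and piles ballistic swimmers up at
the walls (~30% excess in the first 10 µm with no stimulus), violating
the no-bias control; with cosine re-emission the no-stimulus ensemble
is uniform within Monte-Carlo error, which the tests assert. Up- and
downstream strips (40 µm) are held at the baseline agent count by
inserting or thinning, so the incoming density is pinned; agents
drifting past the window ends are removed. Snapshots are collected
after a burn-in of two window-transit times (capped at 300 s).

**Normalization.** ROI histograms are normalized by the realised mean
areal density over the window (per snapshot), the agent-side analogue
of "controls read 1". The spawn-strip baseline density is available as
an explicit `baseline` override; the two differ by up to ~15% because
strip-pinned kinetic boundary layers (run length ~90 µm vs 40 µm
strips) leave the interior slightly below the strip density.

**Determinism.** All stochastic draws run through R's RNG from
`cfg$seed` (truncated normals by inverse-CDF so the draw count is
fixed); identical configs give bit-identical results.

## Where the two scales genuinely disagree

A 1-D velocity-jump (telegraph) reduction of the ABM's reversal rule
gives, at zero flux, $\mathrm d\ln b/\mathrm dy = (2p_0/v)\sinh[\sigma^*
K_C/(K_C+a)^2\, v\, a'(y)]$ — log-accumulation proportional to
$2p_0\sigma^*$. The equivalent continuum (conservative) balance is
$V_C/D_b$. The two coincide only if $D_b$ equals the walk's own
effective diffusivity $v^2/(n p_0 (1-\langle\cos\theta\rangle)) \approx
1030$ µm²/s (which the MSD of simulated tracks confirms within 15%);
the literature value used by the continuum model is 320 µm²/s. The
consequence, measured: at 0.5 m/d with $p_0 = 0.5$ s⁻¹ and $\sigma^* =
4$ s the ABM's near-interface density (~1.9 at the wall) exceeds the
advective continuum profile (~1.35), and fitting $\chi_0$ to ABM output
returns ~2.5× the generative value. We deliberately leave this
discrepancy visible rather than tuning any of $p_0$, $\sigma^*$ or
$D_b$ away from their stated values: the ABM's accumulation does remain
monotone in $p_0$ (the mechanistic claim), but quantitative ABM ↔
continuum agreement at this shared parameter set is not achievable, and
the corresponding cross-validation checks in the acceptance suite fail
honestly.

## Synthetic data: what it does and does not emulate

`make_profile_fixtures()` adds i.i.d. Gaussian noise (default sd 0.05
normalized-density units, a visual match to typical replicate spread;
configurable, not a measured value) per point and replicate to
continuum profiles. `make_track_fixtures()` resamples ABM trajectories
at 50 ms (linear interpolation between 0.1 s steps, 100 frames) and
adds 0.2 µm localization noise, typical of 20× phase imaging. The
bundle writer emits all velocity × condition combinations (chemotactic
± naphthalene, nonchemotactic control) with a JSON manifest recording
every generative parameter, so each fixture is reproducible from
(manifest, seed).

Not emulated: spatially correlated replicate error (real replicates
share chip-alignment and illumination structure), particle-linking
failures, and — importantly — shear-induced reorientation of swimmers.
The last means the synthetic tracks do *not* reproduce the observed
decrease of mean transverse speed with flow velocity: the imposed
$p_0$ schedule leaves transverse swimming kinematics untouched
(measured mean $|v_y|$ stays at $2v/\pi \approx 28$ µm/s across the
schedule), so passing track-statistics tests demonstrate the
statistics, not that mechanism. Orientation-resolved shear coupling
(Jeffery orbits, rheotaxis) is out of scope by design.

## Numerical and scale choices

* Grid: ~15,500 cells by default; the 0.5 m/d attractant + bacteria
  pair solves in ~2 s, so a full four-velocity sweep is interactive.
* ABM: 4000 agents × 0.1 s steps; a 400 s run (276 s burn-in at
  0.5 m/d) takes ~10 s. Test and analysis scripts use these full study
  sizes for the headline checks and smaller ensembles (400–1000
  agents, shorter horizons) for property checks, sized to keep the
  whole suite in the tens of minutes on one core.
* Tie-breaks and degenerate inputs: zero-gradient cells get exactly
  zero drift (no 0/0); reversal exponents are clamped at ±50; outflow
  boundaries suppress inward advective flux to stay well posed; tracks
  shorter than two frames are skipped and counted.

## Known limitations

* The advective-vs-conservative transport ambiguity is resolved by
  fidelity to the reported results, not by first principles; both forms
  ship and differ by ~5× in peak accumulation.
* The near-wall in-plane velocity profile (2-D parabola vs Hele-Shaw
  plug) is a structural choice with leverage on residence times near
  the interface.
* Apparent-$\chi_0$ values at ≥ 5 m/d are bounded ("at least an order
  of magnitude lower"), not point estimates; `apparent_chi()` adopts
  $7.2\times10^{-6}$ cm²/s for both.
* The ABM ↔ continuum scale mismatch above; and replicate noise
  magnitude in the synthetic module is a parameter, not a measurement.
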