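---
title: "Modelling protein adsorption on a TEVG under pulsatile flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling protein adsorption on a TEVG under pulsatile flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tevgsim)
```

`tevgsim` is a desk-scale, fully testable reimplementation of a coupled
pressure-waveform / hemodynamics / elastic-wall / adsorption-kinetics model of
albumin and fibrinogen deposition on the luminal (intima) surface of a
small-diameter tissue-engineered vascular graft (TEVG). The reference system
is a decellularized porcine carotid scaffold: 4.00 mm internal diameter,
0.90 mm wall, 60.00 mm length, Young's modulus 1.34 MPa, Poisson ratio 0.49,
perfused with water at the experimental pump flow rate of
3.33×10⁻⁷ m³/s (Re ≈ 106, laminar).

The original study chained three commercial solvers (a two-way FSI model and a
multiphysics transport model). This package replaces each stage by a
reduced-order model with the same observables, chosen so that every stage has
either a closed-form solution or an independent numerical oracle.

## 1. Pressure waveforms

Periodic pressure (or pressure-gradient) signals are represented by the
one-sided real Fourier series

$$P(t) = A_0 + \sum_{n=1}^{N} A_n\cos(n\omega t) + B_n\sin(n\omega t),$$

so that $A_0$ is the arithmetic mean over one period. `fit_dft()` is a
least-squares projection on the harmonic basis, which coincides with the
discrete Fourier transform for uniform sampling over whole periods but remains
well behaved with trailing partial samples. The Nyquist limit (at least two
samples per period of the highest harmonic) is enforced with an explicit
error.

No experimental recording is distributed with the package, so
`synthesize_trace()` generates a surrogate: a band-limited (8-harmonic)
periodic pulse with a systolic upstroke and diastolic decay, exact requested
mean, and deterministic output (optional seeded measurement noise is off by
default). Two conventions are fixed once:

* **Period 1.5 s.** The printed fundamental of the source reconstruction
  (0.8184 rad/s) implies a 7.68 s period, inconsistent with the 1.5 s
  simulations it drives. The fitting routine therefore treats the fundamental
  as a free argument — reconstruction-style fits can use 0.8184 rad/s — while
  the synthetic generator uses $2\pi/1.5$ rad/s, one full cycle per simulated
  window.
* **Phase.** The systolic peak sits at 0.786 of the cycle (t = 1.179 s) and
  the minimum near 0.2 (t = 0.3 s), matching the pressure-extreme labels of
  the reported concentration snapshots.

What the generator emulates: a physiological pulse shape, exact mean values
(11,819 Pa inlet, 12,784 Pa outlet), band-limitedness (so fit/evaluate
round-trips are exact to 1e-9). What it does not emulate: beat-to-beat
variability, measurement noise spectra, or the high-harmonic content (N = 125)
of a real catheter trace. Tests that pass on synthetic traces therefore
validate the projection/evaluation algebra and the pipeline plumbing, not the
fidelity of any specific experimental recording.

## 2. Pulsatile hemodynamics

Fully developed laminar flow of an incompressible Newtonian fluid in a rigid
cylindrical lumen, driven by $-\partial P/\partial z$ expressed as mean plus
harmonics. Dropping the nonlinear convective term (the standard fully
developed approximation — here Re ≈ 106 and Womersley number
$\alpha = R\sqrt{\omega\rho/\mu} \approx 1.8$ at the printed fundamental)
makes the per-harmonic Womersley solution exact:

$$\hat u_n(r) = \frac{C_n}{i\rho n\omega}\left[1 -
  \frac{J_0(i^{3/2}\alpha_n r/R)}{J_0(i^{3/2}\alpha_n)}\right],$$

superposed on the Poiseuille parabola of the mean gradient. Complex-argument
$J_0, J_1$ are evaluated by the ascending power series, which for the
arguments this solution needs ($z = i^{3/2}s$, $s\le\alpha$) keeps ~9
significant digits up to $\alpha \approx 20$; the packaged scenarios stay
below $\alpha_8 \approx 12$. The late-cycle "s"-shaped profiles seen in the
reference data arise from fluid inertia and are captured by the harmonic
solution.

Diagnostics follow the field's standard definitions: Re = ρv̄D/μ,
Hagen–Poiseuille ΔP = 8μLQ/(πR⁴), and wall shear stress
τ_w = μ|∂u_z/∂r| at r = R by a second-order one-sided difference on the
radial grid (64 points by default, sine-clustered toward the wall where the
oscillatory boundary layer lives).

**Mean gradient choice.** The difference of the printed mean pressures
(11,819 Pa inlet vs 12,784 Pa outlet) over 60 mm would imply a retrograde
~16 kPa/m gradient and ~8 m/s flow — evidently transducer offsets, not a
hydraulic gradient. The packaged scenarios instead derive the mean gradient
from the experimental flow rate via Hagen–Poiseuille (52.3 Pa/m, i.e. the
reported ~3.1 Pa drop over the graft). The oscillatory gradient uses the
synthetic pulse shape, scaled so the flow waveform has pulsatility index
$(Q_{max}-Q_{min})/\bar Q = 3$, a mid-range arterial value; this was fixed
once as a modelling choice, before any end-to-end comparison.

## 3. Wall mechanics

The graft wall responds quasi-statically: the pulse timescale (~1 s) is far
slower than the wall's elastic timescale, so wall inertia is neglected and
the thick-wall Lamé solution is evaluated pointwise in time. Hoop stress at
the inner surface is $\sigma_\theta = P(r_i^2+r_o^2)/(r_o^2-r_i^2)$; radial
displacement uses the plane-strain closed form (fixed ends), which is linear
in P, with hoop strain $u/r_i$ and safety factor UTS/σ_θ against the
0.49 MPa reference strength of native porcine arteries. ν = 0.5 exactly is
rejected (singular in plane strain). The dynamic FEM values of the reference
study (0.084 MPa peak stress, 4.18% strain) are treated as order-of-magnitude
context only; the packaged scenarios give peak hoop stress ~0.04 MPa and
~3% strain at physiological pressures, below the UTS with a safety factor
well above 1 — the same conclusion, by design of the surrogate.

Compliant-radius feedback into the flow solution is available in principle by
re-gridding on R(t), but the packaged scenarios use the rigid-wall Womersley
field: the coupling that matters for the transport observables is the
exported space–time velocity function.

## 4. Adsorption kinetics (well-mixed)

The two-state Langmuir scheme: protein P binds free surface sites S
reversibly (k_f forward, k_r reverse) to a complex P·S, which converts
irreversibly (k_i) to P̄·S̄. The default right-hand side is the
conservation-consistent form

$$\frac{d[P\cdot S]}{dt}=k_f[P][S]-(k_r+k_i)[P\cdot S],\quad
  \frac{d[\bar P\cdot \bar S]}{dt}=k_i[P\cdot S],$$
$$\frac{d[S]}{dt}=-k_f[P][S]+k_r[P\cdot S],\quad
  \frac{d[P]}{dt}=-k_f[P][S]+k_r[P\cdot S]+\text{inflow},$$

under which $[S]+[P\cdot S]+[\bar P\cdot\bar S]$ is exactly conserved. The
source table's printed desorption terms (+k_r[S], +k_r[P]) are dimensionally
inconsistent with the complex equation and do not conserve sites; they are
retained behind `literal_printed_equations = TRUE` for comparison, but all
defaults use the standard form.

Unit and convention normalizations, recorded in every pipeline summary:

* k_r (printed m³/(s·mol)) and k_i (printed L/s) are first-order rates and are
  used as 1/s with their printed magnitudes; k_i defaults to 1×10⁻⁴ /s, with
  the pulse-demonstration value k_i = 1 /s as `fig4_kinetic_params()`.
* The reaction area 2.00×10⁴ m² is used as 2.00×10⁻⁴ m² and the albumin
  maximum inlet concentration "mol/m²" as mol/m³ (both obvious exponent/unit
  slips given the geometry).
* Surface species enter the well-mixed model as volumetric concentrations via
  a configurable area-to-volume ratio, default the graft lumen's 2/R =
  1000 /m.
* Both printed "initial S" rows (G₀ = 1×10⁻⁵ and CS₀ = 9.9×10⁻⁶ mol/m²) start
  as free sites, with both complexes at zero — this honours the stated
  zero-product initial condition and makes the conserved site total G₀+CS₀.
* A pulse (start, duration, concentration) delivers its stated concentration
  over its duration as a source term of concentration/duration mol/(m³·s);
  the source model gives no reactor throughput, so no outflow term is
  imposed.
* Water released on hydrolysis (the stoichiometric counts m, n, r, v) is
  tracked as an audit column only; at 55,600 mol/m³ water never limits rates.

Integration is adaptive `lsoda`, piecewise between pulse boundaries so the
discontinuous source is handled exactly, with non-negativity projection and
output on a fixed 0.009 s grid (the reference discretization step).
`saturation_time()` reports the first time a trajectory reaches a stated
fraction (default 99%) of its final plateau, by linear interpolation, and
refuses trajectories whose relative end slope exceeds 1e-4 /s unless the
caller explicitly accepts the end-of-run value as the plateau (the pipeline
does, since the 1.5 s window is fixed).

## 5. Transport–adsorption (spatially resolved)

The 3D quarter-cylinder with discrete 0.1 mm spherical reaction sites of the
reference model is replaced by an axisymmetric continuum with a uniformly
reactive wall of site density G₀+CS₀: the discrete sites are sub-grid at desk
scale and only wall-aggregate quantities are reported. Finite volumes on a
cell-centred (r, z) grid, default nz = 120 × nr = 24 over 60 mm × 2 mm:

* **Advection**: first-order upwind, explicit, with a CFL guard
  (max|u|·dt/Δz ≤ 0.9 checked before stepping). Inlet Dirichlet from the
  scenario's concentration profile, advective outflow at the outlet
  (zero-gradient on backflow).
* **Diffusion**: central, implicit; the axisymmetric operator is assembled
  once as a weighted graph Laplacian, symmetrized by the cell volumes, and
  factorized once (sparse Cholesky), so each step is a single triangular
  solve. Diffusivity is Stokes–Einstein at 310 K by default
  (albumin 5.3×10⁻¹¹, fibrinogen 2.5×10⁻¹¹ m²/s from the printed shapes).
* **Wall reaction**: per axial station, the (C_wall, Γ_PS, Γ_irr) system is
  advanced by an explicit midpoint step, with the bulk update slaved to the
  surface update so bulk+bound moles balance exactly; Γ_S is carried as
  G₀+CS₀−Γ_PS−Γ_irr, making site conservation exact by construction. A
  species mass-balance audit (boundary influx vs inventory change) is
  attached to every result; packaged runs close to ~1e-14.

**Velocity closure.** The advecting velocity is uniform in z and follows the
scenario's outlet condition, the physically equivalent closure for a fully
developed model: constant mode is a plug value everywhere (0.047 m/s in the
packaged constant scenarios), and v(x,t) mode resamples the Womersley field
by nearest-neighbour interpolation at 22 radial points and 0.009 s steps, the
export convention of the reference coupling. The 22 samples sit at
cell-centred radii on [0, R]: sampling the no-slip node r = R itself would
make the entire wall ring of the transport grid permanently stagnant under
nearest-neighbour snapping — a grid artifact, not physics.

**Inlet profile.** The transport scenarios sustain the inlet concentration at
the protein's maximum (fibrinogen 0.0118, albumin 0.753 mol/m³) for the whole
1.5 s window. A 1.0 s rectangular pulse was considered instead (mirroring the
well-mixed pulse protocol), but the reported concentration trajectories keep
rising past 1.0 s (albumin to its maximum at 1.39 s), which implies sustained
supply during the coupled runs; the pulse protocol remains the default of the
well-mixed module, where it belongs.

**Probes.** `surface_stats()` reports max/mean over the axial extent of the
wall-adjacent cell ring (the reported "TEVG surface concentration" carries
bulk units, i.e. wall-adjacent bulk, not a Γ-type density) with linear
interpolation between the 0.009 s output frames; the pipeline probes 0.3 s
and 1.179 s, the snapshot times of the reference figures, and defines each
scenario's saturation time as the 99%-of-plateau crossing of the near-wall
maximum trajectory.

## 6. Problem sizes and runtime

Packaged scenarios use nz = 120 × nr = 24 cells, internal dt = 1 ms over a
1.5 s window with 0.009 s outputs, a 64-point radial × 0.003 s Womersley
grid, and 8 gradient harmonics. One coupled scenario runs in a few seconds on
one CPU; the four packaged scenarios plus the full test suite complete in
well under 15 minutes. These sizes were chosen as the natural desk-scale
discretization of the reference setup (whose own export grid was 22 radial
points × 0.009 s).

## 7. Known limitations

* **Sub-grid wall boundary layer.** With molecular diffusivities of order
  10⁻¹¹ m²/s, the adsorption boundary layer √(Dt) ≈ 10 µm is thinner than any
  desk-scale radial cell (83 µm at nr = 24). Bulk-field statistics (domain
  maximum, volume mean) are grid-converged to well under 5%, but wall-ring
  quantities are anchored to the ring position and shift under refinement;
  they should be read as "concentration in the wall-adjacent ~80 µm", the
  same effective convention as the reference model's 0.1 mm reaction sites.
* **Well-mixed equivalence has a finite Biot number.** Against the well-mixed
  oracle in a closed box, the PDE's bulk trajectory matches to a fraction of
  a percent at D = 10⁻⁶ m²/s, but the surface trajectory retains a ~3%
  deficit there: the adsorption Biot number k_f·Γ_tot·R/(2D) ≈ 0.36 is not
  yet small. The deficit falls to ~0.6% at D = 5×10⁻⁶ and ~0.3% at 10⁻⁵,
  confirming convergence to the CSTR limit; the test suite asserts exactly
  this behaviour.
* **Near-wall saturation timescale.** The near-wall trajectory approaches its
  plateau at the surface relaxation rate k_f·C + k_r + k_i, which for
  fibrinogen at its inlet concentration is ≈ 1.1 /s; a 99%-of-plateau
  criterion therefore cannot land much below ~1.3 s within a 1.5 s window
  under the packaged kinetic constants, regardless of the flow. Reported
  sub-second saturation for fibrinogen is not reachable in this closure
  without altering those constants, which this package deliberately does not
  do.
* **Constant-velocity closure.** The plug-everywhere reading of "constant
  outlet velocity" advects protein along the wall at the full 0.047 m/s,
  which overstates near-wall delivery relative to a model that retains
  no-slip walls internally; consequently the constant-velocity scenario can
  reach near-wall concentrations comparable to, or above, the pulsatile one
  at matched times. The pulsatile scenario remains the physically grounded
  one (analytic Womersley field).
* Single-protein solutions only (no competitive adsorption), Newtonian fluid,
  laminar axisymmetric flow, no electrostatics or charge anisotropy, and no
  3D FEM stress fields — all outside the scope of this reduced-order model.

## 8. A minimal run

```{r example, eval = FALSE}
res <- run_pipeline(preset_scenario("fibrinogen_vxt"))
print(res)
surface_stats(res$transport, 0.3)
```

The four packaged presets (`list_presets()`) reproduce the headline scenario
matrix; `scripts/acceptance.R` at the repository root recomputes the
published observables from scratch and writes them as JSON.
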